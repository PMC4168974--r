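# Ground-truth generator: rigid Fv-like assemblies at controlled poses, pose
# families, and toy pMHC complexes with known docking angles and tunable
# steric proximity. Every consumer of real structures operates on labelled
# CA/CB positions, so the scaffold is a pseudo beta-sandwich of ideal-geometry
# CA traces rather than real coordinates; physical side chains, energetics
# and sequence realism are deliberately out of scope.

# IMGT positions absent from the scaffold, by domain type. The CDR3 block
# gives the field-typical loop lengths: VL 9 residues, Valpha 13, VH/Vbeta 12.
SCAFFOLD_ABSENT <- list(
  VH     = c(32, 33, 34, 60, 61, 62, 111),
  VL     = c(32, 33, 34, 60, 61, 62, 110, 111, 112, 113),
  Vbeta  = c(32, 33, 34, 60, 61, 62, 112),
  Valpha = c(32, 33, 34, 60, 61, 62)
)

# glycines (virtual CB = CA) at two framework positions
SCAFFOLD_GLYCINES <- c(8L, 75L)

scaffold_sequence <- function(positions) {
  pool <- strsplit("AVLIFSTYDEKRNQHPMG", "")[[1]]
  aa <- pool[(positions %% length(pool)) + 1L]
  aa[positions == 23L] <- "C"
  aa[positions == 104L] <- "C"
  aa[positions == 41L] <- "W"
  aa[positions %in% SCAFFOLD_GLYCINES] <- "G"
  aa
}

#' Deterministic scaffold variable domain
#'
#' A pseudo beta-sandwich CA/CB trace over the IMGT 1-128 grid (eight
#' strands of sixteen positions in two sheets), with the field-standard
#' framework/CDR annotation and domain-type-specific CDR3 occupancy. The
#' geometry is keyed on the IMGT position, so all domain types share an
#' identical framework trace.
#'
#' @param domain_type One of `"VH"`, `"VL"`, `"Vbeta"`, `"Valpha"`.
#' @param chain Chain identifier to stamp on the residues.
#' @return An `fv_domain`.
#' @export
scaffold_domain <- function(domain_type = "VH", chain = "H") {
  domain_type <- match.arg(domain_type, DOMAIN_TYPES)
  positions <- setdiff(1:128, SCAFFOLD_ABSENT[[domain_type]])
  p <- positions
  s <- (p - 1L) %/% 16L
  t <- (p - 1L) %% 16L
  x <- ifelse(s %% 2L == 0L, t, 15L - t) * 3.4 + 0.25 * sin(3 * p)
  y <- (s %% 4L) * 4.8 + 0.3 * sin(1.3 * p)
  z <- (s %/% 4L) * 6.8 + 0.3 * cos(1.7 * p)
  ca <- cbind(x, y, z)
  updown <- ifelse(s < 4L, 1, -1) * ifelse(p %% 2L == 0L, 1, -1)
  vdir <- cbind(0.15 * sin(2 * p), 0.34 * (-1)^p, 0.93 * updown)
  vdir <- vdir / sqrt(rowSums(vdir^2))
  cb <- ca + 1.53 * vdir
  aa <- scaffold_sequence(p)
  cb[aa == "G", ] <- ca[aa == "G", ]
  tab <- data.frame(chain = chain, resno = seq_along(p), ins = "",
                    imgt = p, imgt_ins = "", aa = aa,
                    stringsAsFactors = FALSE)
  fv_domain(tab, ca, cb, domain_type)
}

#' Pose specification for the synthetic generator
#'
#' @param HL,HC1,HC2,LC1,LC2 Target orientation angles in degrees.
#' @param dc Target pivot-axis length in Angstrom (> 5).
#' @param noise Isotropic Gaussian coordinate noise SD in Angstrom (>= 0).
#' @param seed Integer seed for the noise draw.
#' @return An object of class `pose_spec`.
#' @export
pose_spec <- function(HL = -60, HC1 = 70, HC2 = 115, LC1 = 120, LC2 = 82,
                      dc = 16, noise = 0, seed = 1L) {
  stopifnot(dc > 5, noise >= 0)
  structure(list(HL = HL, HC1 = HC1, HC2 = HC2, LC1 = LC1, LC2 = LC2,
                 dc = dc, noise = noise, seed = as.integer(seed)),
            class = "pose_spec")
}

# in-plane unit vectors realising bend angles (ang1 with `along`, ang2 for
# the orthogonal partner); returns e1 and e2 as rows. `along` is +z here.
bend_pair <- function(ang1, ang2, sign_z) {
  a1 <- ang1 * pi / 180; a2 <- ang2 * pi / 180
  s1 <- sin(a1)
  if (abs(s1) < 1e-9) stop("unreachable pose: bend angle of 0 or 180 degrees")
  k <- -cos(a1) * cos(a2) / s1
  disc <- sin(a2)^2 - k^2
  if (disc < -1e-9) stop("unreachable pose: angle combination inconsistent")
  disc <- max(disc, 0)
  # e1 at azimuth 0; e2 determined up to the branch sign (the + branch is
  # the package convention)
  e1 <- c(s1, 0, sign_z * cos(a1))
  e2 <- c(k, sqrt(disc), sign_z * cos(a2))
  list(e1 = e1, e2 = e2)
}

rotate_about_z <- function(v, phi_deg) {
  a <- phi_deg * pi / 180
  c(cos(a) * v[1] - sin(a) * v[2], sin(a) * v[1] + cos(a) * v[2], v[3])
}

# rotation matrix about unit axis u by angle degrees (Rodrigues)
axis_rotation <- function(u, angle_deg) {
  u <- u / sqrt(sum(u^2))
  a <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3L, 3L,
              byrow = TRUE)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# rigid placement mapping a local frame (origin, e1, e2) onto a world frame
placement_transform <- function(local, world_origin, world_e1, world_e2) {
  le3 <- crossprod_vec(local$e1, local$e2)
  we3 <- crossprod_vec(world_e1, world_e2)
  B_local <- cbind(local$e1, local$e2, le3)
  B_world <- cbind(world_e1, world_e2, we3)
  rot <- B_world %*% t(B_local)
  rigid_transform(rot, world_origin - as.numeric(rot %*% local$origin))
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Build a synthetic Fv at a requested orientation
#'
#' Two copies of the deterministic scaffold are placed so that the package's
#' own frame construction recovers exactly the requested six measures: the
#' pivot axis is laid along +z with the L-side frame origin at the origin of
#' coordinates, the frame vectors are solved analytically from the requested
#' angles, and each scaffold is moved rigidly onto its solved frame.
#' Isotropic Gaussian noise is then added to all CA/CB coordinates.
#'
#' @param spec A [pose_spec()].
#' @param receptor_class `"tcr"` or `"antibody"`.
#' @param pdb_id Identifier for the generated structure.
#' @return An [fv_structure()] with a `ground_truth` attribute recording the
#'   requested pose, noise and seed.
#' @export
make_fv <- function(spec = pose_spec(), receptor_class = c("tcr", "antibody"),
                    pdb_id = NULL) {
  receptor_class <- match.arg(receptor_class)
  types <- if (receptor_class == "tcr") c("Vbeta", "Valpha") else c("VH", "VL")
  chains <- if (receptor_class == "tcr") c("B", "A") else c("H", "L")
  domH <- scaffold_domain(types[1L], chains[1L])
  domL <- scaffold_domain(types[2L], chains[2L])
  caH <- domH$ca; rownames(caH) <- imgt_keys(domH)
  caL <- domL$ca; rownames(caL) <- imgt_keys(domL)
  frameH <- domain_frame(caH, DEFAULT_INTERFACE)
  frameL <- domain_frame(caL, DEFAULT_INTERFACE)
  # world frames: pivot axis along +z, L origin at 0, H origin at (0,0,dc)
  originL <- c(0, 0, 0)
  originH <- c(0, 0, spec$dc)
  L <- bend_pair(spec$LC1, spec$LC2, sign_z = -1)  # angles against -z
  H <- bend_pair(spec$HC1, spec$HC2, sign_z = +1)  # angles against +z
  # azimuth of the H-side e1 fixed by the requested HL torsion
  torsion_of <- function(phi) {
    e1H <- rotate_about_z(H$e1, phi)
    torsion_angle(originH + e1H, originH, originL, originL + L$e1)
  }
  t0 <- torsion_of(0)
  slope <- sign(wrap_angle(torsion_of(1) - t0))
  phi <- slope * wrap_angle(spec$HL - t0)
  if (abs(wrap_angle(torsion_of(phi) - spec$HL)) > 1e-6) {
    f <- function(p) wrap_angle(torsion_of(p) - spec$HL)
    grid <- seq(-180, 180, by = 5)
    vals <- vapply(grid, f, 0)
    i <- which.min(abs(vals))
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
    phi <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  }
  e1H <- rotate_about_z(H$e1, phi)
  e2H <- rotate_about_z(H$e2, phi)
  trH <- placement_transform(frameH, originH, e1H, e2H)
  trL <- placement_transform(frameL, originL, L$e1, L$e2)
  domH <- transform_domain(domH, trH)
  domL <- transform_domain(domL, trL)
  if (spec$noise > 0) {
    set.seed(spec$seed)
    jiggle <- function(d) {
      d$ca <- d$ca + matrix(stats::rnorm(length(d$ca), 0, spec$noise),
                            ncol = 3L)
      d$cb <- d$cb + matrix(stats::rnorm(length(d$cb), 0, spec$noise),
                            ncol = 3L)
      d
    }
    domH <- jiggle(domH); domL <- jiggle(domL)
  }
  if (is.null(pdb_id)) pdb_id <- sprintf("syn%05d", spec$seed %% 100000L)
  fv <- fv_structure(domH, domL, receptor_class, pdb_id)
  attr(fv, "ground_truth") <- list(measures = spec[c("HL", "HC1", "HC2",
                                                     "LC1", "LC2", "dc")],
                                   noise = spec$noise, seed = spec$seed)
  fv
}

#' Generate a family of structures around a central pose
#'
#' The five angles are drawn independently from Gaussians centred on the
#' central spec with standard deviation `spread`; `dc` and the coordinate
#' noise SD are taken from the central spec.
#'
#' @param center A [pose_spec()] giving the family centre.
#' @param spread Angular SD in degrees.
#' @param n Number of structures (>= 2).
#' @param seed Integer seed; member seeds are derived from it.
#' @param receptor_class Passed to [make_fv()].
#' @param id_prefix Prefix for member identifiers.
#' @return List of [fv_structure()] objects.
#' @export
make_pose_family <- function(center = pose_spec(), spread = 2, n = 10L,
                             seed = 1L, receptor_class = "tcr",
                             id_prefix = "fam") {
  stopifnot(n >= 2L)
  set.seed(seed)
  angle_draws <- matrix(stats::rnorm(5L * n, sd = spread), nrow = n)
  member_seeds <- sample.int(.Machine$integer.max - 1L, n)
  lapply(seq_len(n), function(i) {
    sp <- pose_spec(HL = center$HL + angle_draws[i, 1L],
                    HC1 = center$HC1 + angle_draws[i, 2L],
                    HC2 = center$HC2 + angle_draws[i, 3L],
                    LC1 = center$LC1 + angle_draws[i, 4L],
                    LC2 = center$LC2 + angle_draws[i, 5L],
                    dc = center$dc, noise = center$noise,
                    seed = member_seeds[i])
    make_fv(sp, receptor_class, pdb_id = sprintf("%s%03d", id_prefix, i))
  })
}

#' Build a toy pMHC complex with a known docking angle
#'
#' The peptide is nine CA/CB residues along the +x axis; the MHC is a
#' two-layer slab of pseudo-residues below and flanking the peptide with a
#' groove channel; the receptor Fv is rotated so its 104-104 interface
#' cysteine vector makes exactly the requested angle with the peptide axis
#' and is lowered until its minimum separation from the MHC/peptide equals
#' `groove_gap`.
#'
#' @param docking_spec Requested docking angle in degrees, in \[0, 180).
#' @param groove_gap Minimum receptor-MHC/peptide separation in Angstrom.
#' @param seed Seed passed to the receptor generator.
#' @param pose A [pose_spec()] for the receptor's inter-domain orientation.
#' @param receptor_class Passed to [make_fv()].
#' @return A [pmhc_complex()] with a `ground_truth` attribute.
#' @export
make_pmhc <- function(docking_spec = 51.4, groove_gap = 5, seed = 1L,
                      pose = pose_spec(seed = seed),
                      receptor_class = "tcr") {
  stopifnot(docking_spec >= 0, docking_spec < 180)
  fv <- make_fv(pose, receptor_class)
  # peptide along +x (N to C)
  np <- 9L
  pep_ca <- cbind(3.5 * (seq_len(np) - 1L), 0, 0)
  pep_cb <- pep_ca + cbind(0, 0, 1.2 * (-1)^(seq_len(np)))
  pep <- list(tab = data.frame(chain = "P", resno = seq_len(np), ins = "",
                               aa = strsplit("GILGFVFTL", "")[[1L]][seq_len(np)],
                               stringsAsFactors = FALSE),
              ca = pep_ca, cb = pep_cb)
  # slab: two layers below the peptide plane, groove channel in the top one
  gx <- seq(-10.5, 38.5, by = 3.5)
  gy <- seq(-14, 14, by = 3.5)
  grid <- expand.grid(x = gx, y = gy)
  top <- grid[abs(grid$y) > 3, , drop = FALSE]          # groove channel
  slab_xyz <- rbind(cbind(top$x, top$y, -3.5),
                    cbind(grid$x, grid$y, -7.0))
  slab <- list(tab = data.frame(chain = "M", resno = seq_len(nrow(slab_xyz)),
                                ins = "", aa = "A", stringsAsFactors = FALSE),
               ca = slab_xyz, cb = slab_xyz)
  # orient the receptor: 104-104 vector (Valpha/VL -> Vbeta/VH) at the
  # requested angle to the +x peptide axis, lying horizontally
  v <- cys104_ca(fv$first) - cys104_ca(fv$second)
  vhat <- v / sqrt(sum(v^2))
  th <- docking_spec * pi / 180
  d <- c(cos(th), sin(th), 0)
  axis <- crossprod_vec(vhat, d)
  if (sqrt(sum(axis^2)) < 1e-9) {
    rot <- if (sum(vhat * d) > 0) diag(3) else axis_rotation(c(0, 0, 1), 180)
  } else {
    ang <- acos(min(1, max(-1, sum(vhat * d)))) * 180 / pi
    rot <- axis_rotation(axis, ang)
  }
  fv <- transform_fv(fv, rigid_transform(rot, c(0, 0, 0)))
  # centre the receptor over the peptide midpoint, well above the slab
  cen <- (colMeans(fv$first$ca) + colMeans(fv$second$ca)) / 2
  fv <- transform_fv(fv, rigid_transform(diag(3),
                                         c(14, 0, 60) - cen))
  # lower until the minimum separation equals groove_gap
  env <- rbind(slab_xyz, pep_ca, pep_cb)
  rec_xyz <- function(f) rbind(f$first$ca, f$first$cb, f$second$ca,
                               f$second$cb)
  min_sep <- function(dz) {
    xyz <- rec_xyz(fv)
    xyz[, 3L] <- xyz[, 3L] + dz
    d2 <- outer(rowSums(xyz^2), rowSums(env^2), "+") - 2 * xyz %*% t(env)
    sqrt(max(min(d2), 0))
  }
  f <- function(z) min_sep(z) - groove_gap
  lo <- 0
  while (f(lo) > 0 && lo > -200) lo <- lo - 10
  if (f(lo) > 0) stop("could not bracket the groove-gap placement")
  dz <- stats::uniroot(f, c(lo, 120), tol = 1e-9)$root
  fv <- transform_fv(fv, rigid_transform(diag(3), c(0, 0, dz)))
  cx <- pmhc_complex(fv, list(M = slab), pep, mhc_class = "I")
  attr(cx, "ground_truth") <- list(docking_angle = docking_spec,
                                   groove_gap = groove_gap, seed = seed,
                                   pose = pose)
  cx
}

#' Twisted decoys that lean a native receptor toward the MHC groove
#'
#' Starting from the receptor of a [make_pmhc()] complex, the H-side
#' (VH/Vbeta) domain is rotated about a horizontal axis placed at the height
#' of its lowest atom on the far side of the L-side domain, with the
#' rotation sign chosen so the H-side domain centroid moves downward: the
#' moved domain sweeps into the groove like a closing lid. Grafting these
#' decoys back into the native complex produces steric interpenetration
#' that grows with the twist.
#'
#' @param complex A [pmhc_complex()] from [make_pmhc()].
#' @param angles Twist angles in degrees.
#' @return List of decoy [fv_structure()] objects, one per angle.
#' @export
make_twist_decoys <- function(complex, angles = c(0, 10, 20, 30)) {
  fv <- complex$receptor
  cH <- colMeans(fv$first$ca)
  cL <- colMeans(fv$second$ca)
  lateral <- cH - cL
  lateral[3L] <- 0
  nl <- sqrt(sum(lateral^2))
  lateral <- if (nl < 1e-6) c(1, 0, 0) else lateral / nl
  pivot <- c(cL[1:2] - 20 * lateral[1:2], min(fv$first$ca[, 3L]))
  axis <- crossprod_vec(lateral, c(0, 0, 1))
  axis <- axis / sqrt(sum(axis^2))
  lapply(angles, function(a) {
    pick <- function(sgn) {
      rot <- axis_rotation(axis, sgn * a)
      tr <- rigid_transform(rot, pivot - as.numeric(rot %*% pivot))
      transform_domain(fv$first, tr)
    }
    plus <- pick(1); minus <- pick(-1)
    moved <- if (mean(plus$ca[, 3L]) <= mean(minus$ca[, 3L])) plus else minus
    out <- fv
    out$first <- moved
    out$pdb_id <- sprintf("%s_tw%03.0f", fv$pdb_id, a)
    out
  })
}
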