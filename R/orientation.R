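# The two quantifications of inter-domain orientation:
#  (1) the bidirectional orientation RMSD with complete-linkage clustering;
#  (2) six absolute measures (HL, HC1, HC2, LC1, LC2 in degrees; dc in
#      Angstrom) built from coresets, consensus domains and reference frames
#      registered onto each query by coreset superposition.
#
# Domain "sides" pool the equivalent antibody/TCR types: the H side holds VH
# and Vbeta, the L side VL and Valpha, so one frame system serves both
# receptor classes.

domain_side <- function(domain_type) {
  if (domain_type %in% c("VH", "Vbeta")) "H" else "L"
}

# default interface positions: the beta-sheet faces forming the dimer
# interface (user-overridable)
DEFAULT_INTERFACE <- as.character(c(38:50, 87:104))

#' Bidirectional inter-domain orientation RMSD
#'
#' Measures the difference in relative domain orientation between two paired
#' structures. In one direction the structures are aligned on the CA atoms of
#' their shared L-side (VL/Valpha) framework positions, the H-side (VH/Vbeta)
#' domains are then superposed independently, and the RMSD is taken between
#' the first structure's H-side domain in its native pose and in the pose
#' implied by the independent superposition. The same is done with the roles
#' of the two domains swapped, and the mean of the two values is returned;
#' the measure is symmetric in its arguments by construction.
#'
#' @param x,y [fv_structure()] objects sharing at least `min_shared`
#'   framework positions per domain.
#' @param min_shared Minimum shared framework positions per domain.
#' @return Orientation RMSD in Angstrom.
#' @export
orientation_rmsd <- function(x, y, min_shared = 20L) {
  sh1 <- intersect(framework_keys(x$first), framework_keys(y$first))
  sh2 <- intersect(framework_keys(x$second), framework_keys(y$second))
  if (length(sh1) < min_shared || length(sh2) < min_shared) {
    stop("insufficient shared framework positions: H side ", length(sh1),
         ", L side ", length(sh2), " (need >= ", min_shared, ")")
  }
  one_direction <- function(anchor_x, anchor_y, anchor_keys,
                            free_x, free_y, free_keys) {
    # align y onto x via the anchor domain
    tr_align <- superpose(domain_ca_at(anchor_y, anchor_keys),
                          domain_ca_at(anchor_x, anchor_keys))$transform
    y_free_aligned <- apply_transform(domain_ca_at(free_y, free_keys), tr_align)
    # independently superpose x's free domain onto y's aligned free domain
    x_free <- domain_ca_at(free_x, free_keys)
    tr_free <- superpose(x_free, y_free_aligned)$transform
    coord_rmsd(x_free, apply_transform(x_free, tr_free))
  }
  d1 <- one_direction(x$second, y$second, sh2, x$first, y$first, sh1)
  d2 <- one_direction(x$first, y$first, sh1, x$second, y$second, sh2)
  (d1 + d2) / 2
}

#' Pairwise orientation-RMSD distance matrix
#'
#' @param structures List of [fv_structure()] objects.
#' @param min_shared Passed to [orientation_rmsd()].
#' @return Symmetric zero-diagonal matrix; entries for failed pairs are `NA`
#'   (with a warning naming the pair).
#' @export
orientation_distance_matrix <- function(structures, min_shared = 20L) {
  n <- length(structures)
  if (n < 1L) stop("need at least one structure")
  ids <- vapply(seq_len(n), function(i) {
    id <- structures[[i]]$pdb_id
    if (is.null(id) || id == "none") paste0("s", i) else id
  }, "")
  ids <- make.unique(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      v <- tryCatch(orientation_rmsd(structures[[i]], structures[[j]],
                                     min_shared),
                    error = function(e) {
                      warning("pair (", ids[i], ", ", ids[j], ") failed: ",
                              conditionMessage(e))
                      NA_real_
                    })
      m[i, j] <- m[j, i] <- v
    }
  }
  m
}

#' Complete-linkage clustering of an orientation distance matrix
#'
#' Structures whose pairwise distances could not be computed (`NA` rows) are
#' dropped with a warning before clustering. The merge height of any
#' complete-linkage cluster equals the maximum pairwise distance within it.
#'
#' @param dmat Symmetric distance matrix from
#'   [orientation_distance_matrix()].
#' @param k Number of clusters to cut at (or `NULL`).
#' @param h Height to cut at (used when `k` is `NULL`).
#' @return List with `hclust` (the stats::hclust tree), `labels` (named
#'   integer cluster memberships) and `dropped` (ids removed due to failed
#'   distances). A single structure yields one cluster and a `NULL` tree.
#' @export
cluster_orientations <- function(dmat, k = 2L, h = NULL) {
  bad <- apply(dmat, 1L, function(r) anyNA(r))
  dropped <- rownames(dmat)[bad]
  if (length(dropped)) {
    warning("dropping structures with failed distances: ",
            paste(dropped, collapse = ", "))
    dmat <- dmat[!bad, !bad, drop = FALSE]
  }
  if (nrow(dmat) == 1L) {
    return(list(hclust = NULL,
                labels = stats::setNames(1L, rownames(dmat)),
                dropped = dropped))
  }
  hc <- stats::hclust(stats::as.dist(dmat), method = "complete")
  labels <- if (is.null(k)) stats::cutree(hc, h = h) else
    stats::cutree(hc, k = min(k, nrow(dmat)))
  list(hclust = hc, labels = labels, dropped = dropped)
}

#' Export a dendrogram as Newick
#' @param hc An `hclust` object (e.g. from [cluster_orientations()]).
#' @param file Optional output path; when `NULL` the Newick string is
#'   returned.
#' @return Newick string, invisibly when written to file.
#' @export
dendrogram_newick <- function(hc, file = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(file)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = file)
  invisible(ape::write.tree(phy))
}

# ---- ensemble alignment ------------------------------------------------

# Named CA matrices (rownames = IMGT keys) for a list of domains
named_ca <- function(domains) {
  lapply(domains, function(d) {
    m <- d$ca
    rownames(m) <- imgt_keys(d)
    m
  })
}

# Iteratively superpose an ensemble onto its evolving mean over `positions`.
# Returns aligned member matrices and the converged per-position mean over
# the union of keys.
align_ensemble <- function(mats, positions, tol = 1e-4, max_iter = 100L) {
  ref_keys <- positions
  mean_at <- function(mats, keys) {
    out <- matrix(NA_real_, length(keys), 3L, dimnames = list(keys, NULL))
    for (k in seq_along(keys)) {
      rows <- do.call(rbind, lapply(mats, function(m) {
        if (keys[k] %in% rownames(m)) m[keys[k], , drop = FALSE] else NULL
      }))
      out[k, ] <- colMeans(rows)
    }
    out
  }
  # initial reference: first member
  target <- mats[[1L]]
  for (iter in seq_len(max_iter)) {
    aligned <- lapply(mats, function(m) {
      keys <- intersect(ref_keys, intersect(rownames(m), rownames(target)))
      if (length(keys) < 3L) stop("fewer than 3 shared alignment positions")
      tr <- superpose(m[keys, , drop = FALSE],
                      target[keys, , drop = FALSE])$transform
      apply_transform(m, tr)
    })
    allkeys <- unique(unlist(lapply(aligned, rownames)))
    new_mean <- mean_at(aligned, allkeys)
    if (iter > 1L) {
      common <- intersect(rownames(target), allkeys)
      shift <- max(sqrt(rowSums((new_mean[common, , drop = FALSE] -
                                   target[common, , drop = FALSE])^2)))
      if (shift < tol) return(list(aligned = aligned, mean = new_mean))
    }
    mats <- aligned
    target <- new_mean
  }
  stop("ensemble alignment did not converge in ", max_iter, " iterations")
}

# per-position RMS spread around the mean over observing members
position_spread <- function(aligned, mean_mat, keys) {
  vapply(keys, function(k) {
    rows <- do.call(rbind, lapply(aligned, function(m) {
      if (k %in% rownames(m)) m[k, , drop = FALSE] else NULL
    }))
    sqrt(mean(rowSums(sweep(rows, 2L, mean_mat[k, ])^2)))
  }, 0)
}

#' Derive a coreset of structurally conserved framework positions
#'
#' Starting from all framework positions present in at least `presence` of
#' the ensemble, members are iteratively superposed on the current coreset
#' and the position with the highest positional spread is dropped, until all
#' remaining positions have spread at most `max_spread` or the floor of
#' `floor_size` positions is reached.
#'
#' @param ensemble List of `fv_domain` objects of one interface side.
#' @param presence Minimum fraction of members observing a position.
#' @param max_spread Spread ceiling in Angstrom.
#' @param floor_size Minimum number of retained positions.
#' @return List with `side`, `positions` (character keys) and `spread`
#'   (named, Angstrom) — the coreset.
#' @export
derive_coresets <- function(ensemble, presence = 0.95, max_spread = 1.0,
                            floor_size = 20L) {
  if (length(ensemble) < 5L) stop("coreset derivation needs >= 5 structures")
  side <- domain_side(ensemble[[1L]]$domain_type)
  fw <- lapply(ensemble, framework_keys)
  counts <- table(unlist(fw))
  qualifying <- names(counts)[counts >= presence * length(ensemble)]
  if (length(qualifying) < floor_size) {
    stop("only ", length(qualifying), " qualifying framework positions ",
         "(need >= ", floor_size, ")")
  }
  mats <- named_ca(ensemble)
  core <- qualifying
  repeat {
    al <- align_ensemble(mats, core)
    spread <- position_spread(al$aligned, al$mean, core)
    worst <- which.max(spread)
    if (spread[worst] <= max_spread || length(core) <= floor_size) {
      return(list(side = side, positions = core, spread = spread))
    }
    core <- core[-worst]
  }
}

# frame of a single domain geometry: origin + first two principal axes of the
# interface CAs, signs fixed toward IMGT 104 (e1) and IMGT 50 (e2)
domain_frame <- function(ca_named, interface_keys) {
  keys <- intersect(interface_keys, rownames(ca_named))
  if (length(keys) < 4L) stop("fewer than 4 interface positions for frame")
  pts <- ca_named[keys, , drop = FALSE]
  pa <- principal_axes(pts)
  e1 <- pa$axes[, 1L]; e2 <- pa$axes[, 2L]
  anchor1 <- intersect("104", rownames(ca_named))
  anchor2 <- intersect("50", rownames(ca_named))
  if (!length(anchor1) || !length(anchor2)) {
    stop("frame sign anchors (IMGT 104 and 50) absent")
  }
  if (sum(e1 * (ca_named[anchor1, ] - pa$centroid)) < 0) e1 <- -e1
  if (sum(e2 * (ca_named[anchor2, ] - pa$centroid)) < 0) e2 <- -e2
  list(origin = pa$centroid, e1 = e1, e2 = e2)
}

#' Build consensus domains and the reference frame system
#'
#' Consensus domains are per-position mean CA coordinates after iterative
#' superposition of each side's ensemble onto its evolving mean (converged
#' when the maximum mean shift drops below `tol`). A frame is fitted per
#' side: its origin is the centroid of the interface-position consensus CAs
#' and e1/e2 are the first two principal axes of those points, signs fixed
#' toward the consensus CAs of IMGT 104 and 50 respectively. The pivot axis
#' C joins the two frame origins with the consensus pair registered onto a
#' reference paired structure (the first of `fvs`).
#'
#' @param fvs List of [fv_structure()] objects (both sides are pooled under
#'   the VH-Vbeta / VL-Valpha equivalence).
#' @param interface_positions Character vector of interface position keys
#'   (default: IMGT 38-50 and 87-104).
#' @param coresets Optional named list (`H`, `L`) of coresets from
#'   [derive_coresets()]; derived from `fvs` when `NULL`.
#' @param presence,max_spread,floor_size Passed to [derive_coresets()].
#' @param tol Convergence tolerance for the consensus mean (Angstrom).
#' @return An object of class `frame_system` with per-side consensus
#'   coordinates, coreset keys, frames, the reference pivot axis and the
#'   reference-pose measures.
#' @export
build_consensus_and_frames <- function(fvs,
                                       interface_positions = DEFAULT_INTERFACE,
                                       coresets = NULL, presence = 0.95,
                                       max_spread = 1.0, floor_size = 20L,
                                       tol = 1e-4) {
  stopifnot(length(fvs) >= 2L)
  ens <- list(H = lapply(fvs, function(f) f$first),
              L = lapply(fvs, function(f) f$second))
  if (is.null(coresets)) {
    coresets <- lapply(ens, derive_coresets, presence = presence,
                       max_spread = max_spread, floor_size = floor_size)
  }
  sides <- lapply(c(H = "H", L = "L"), function(s) {
    mats <- named_ca(ens[[s]])
    al <- align_ensemble(mats, coresets[[s]]$positions, tol = tol)
    counts <- table(unlist(lapply(mats, rownames)))
    keep <- names(counts)[counts >= presence * length(mats)]
    consensus <- al$mean[intersect(rownames(al$mean), keep), , drop = FALSE]
    spread <- position_spread(al$aligned, al$mean, rownames(consensus))
    frame <- domain_frame(consensus, interface_positions)
    list(consensus = consensus, coreset = coresets[[s]]$positions,
         spread = spread, frame = frame)
  })
  fs <- structure(list(H = sides$H, L = sides$L,
                       interface_positions = interface_positions),
                  class = "frame_system")
  # reference pose: consensus registered onto the first supplied structure
  reg <- register_frames(fs, fvs[[1L]])
  fs$reference <- list(pdb_id = fvs[[1L]]$pdb_id,
                       C = reg$H$origin - reg$L$origin,
                       measures = measures_from_frames(reg))
  fs
}

#' @export
print.frame_system <- function(x, ...) {
  cat("<frame_system> coresets: H ", length(x$H$coreset), " / L ",
      length(x$L$coreset), " positions; consensus: H ",
      nrow(x$H$consensus), " / L ", nrow(x$L$consensus), " positions\n",
      sep = "")
  if (!is.null(x$reference)) {
    cat("  reference pose (", x$reference$pdb_id, "): ", sep = "")
    print(x$reference$measures)
  }
  invisible(x)
}

# register both consensus frames onto a query Fv by coreset superposition
register_frames <- function(frames, query, min_shared = 20L) {
  one <- function(side, domain) {
    cons <- frames[[side]]$consensus
    keys <- intersect(frames[[side]]$coreset,
                      intersect(rownames(cons), imgt_keys(domain)))
    if (length(keys) < min_shared) {
      stop("query shares only ", length(keys), " coreset positions on the ",
           side, " side (need >= ", min_shared, ")")
    }
    sp <- superpose(cons[keys, , drop = FALSE], domain_ca_at(domain, keys))
    f <- frames[[side]]$frame
    list(origin = apply_transform(f$origin, sp$transform),
         e1 = rotate_vector(f$e1, sp$transform),
         e2 = rotate_vector(f$e2, sp$transform),
         rmsd = sp$rmsd)
  }
  list(H = one("H", query$first), L = one("L", query$second))
}

# the six measures from a pair of registered frames
measures_from_frames <- function(reg) {
  C <- reg$H$origin - reg$L$origin
  dc <- sqrt(sum(C^2))
  hl <- torsion_angle(reg$H$origin + reg$H$e1, reg$H$origin,
                      reg$L$origin, reg$L$origin + reg$L$e1)
  out <- list(HL = hl,
              HC1 = vector_angle(C, reg$H$e1),
              HC2 = vector_angle(C, reg$H$e2),
              LC1 = vector_angle(-C, reg$L$e1),
              LC2 = vector_angle(-C, reg$L$e2),
              dc = dc,
              registration_rmsd = c(H = reg$H$rmsd, L = reg$L$rmsd),
              unreliable = (reg$H$rmsd > 2.5 || reg$L$rmsd > 2.5))
  class(out) <- "orientation_measures"
  out
}

#' Compute the six absolute orientation measures for a query structure
#'
#' Registers each side's consensus frame onto the query by coreset
#' superposition, takes the pivot axis C between the registered origins and
#' reports: `HL` (torsion of the two e1 vectors about C), `HC1`/`HC2` (angle
#' of C with the H-side e1/e2), `LC1`/`LC2` (angle of -C with the L-side
#' e1/e2), all in degrees, and `dc = |C|` in Angstrom. A registration RMSD
#' above 2.5 Angstrom on either side sets the `unreliable` flag (with a
#' warning).
#'
#' @param query An [fv_structure()].
#' @param frames A `frame_system` from [build_consensus_and_frames()].
#' @param min_shared Minimum shared coreset positions per side.
#' @return An `orientation_measures` object.
#' @export
compute_measures <- function(query, frames, min_shared = 20L) {
  reg <- register_frames(frames, query, min_shared)
  m <- measures_from_frames(reg)
  if (m$unreliable) {
    warning("registration RMSD exceeds 2.5 A (H ",
            sprintf("%.2f", reg$H$rmsd), ", L ",
            sprintf("%.2f", reg$L$rmsd), "); frame may be unreliable")
  }
  m
}

#' @export
print.orientation_measures <- function(x, ...) {
  cat(sprintf("HL %7.2f  HC1 %7.2f  HC2 %7.2f  LC1 %7.2f  LC2 %7.2f deg;  dc %6.2f A%s\n",
              x$HL, x$HC1, x$HC2, x$LC1, x$LC2, x$dc,
              if (isTRUE(x$unreliable)) "  [unreliable registration]" else ""))
  invisible(x)
}

#' Measures for a list of structures as a data frame
#'
#' @param structures List of [fv_structure()] objects.
#' @param frames A `frame_system`.
#' @param min_shared Passed to [compute_measures()].
#' @return data.frame with one row per structure (pdb_id, receptor_class,
#'   the six measures, registration RMSDs and the unreliable flag).
#' @export
measures_table <- function(structures, frames, min_shared = 20L) {
  rows <- lapply(structures, function(s) {
    m <- suppressWarnings(compute_measures(s, frames, min_shared))
    data.frame(pdb_id = s$pdb_id, receptor_class = s$receptor_class,
               HL = m$HL, HC1 = m$HC1, HC2 = m$HC2, LC1 = m$LC1,
               LC2 = m$LC2, dc = m$dc,
               reg_rmsd_H = m$registration_rmsd[["H"]],
               reg_rmsd_L = m$registration_rmsd[["L"]],
               unreliable = m$unreliable,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a measures table as CSV
#' @param tab data.frame from [measures_table()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_measures_csv <- function(tab, file) {
  utils::write.csv(tab, file, row.names = FALSE)
  invisible(file)
}
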