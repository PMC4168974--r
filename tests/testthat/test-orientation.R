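# Shared synthetic objects for the orientation tests (noiseless, exact poses)
base_fv <- make_fv(pose_spec(seed = 100L))
ref_ensemble <- make_pose_family(pose_spec(), spread = 4, n = 6, seed = 200L)
frames <- build_consensus_and_frames(ref_ensemble)

shift_domain <- function(fv, slot, v) {
  fv[[slot]] <- fvorient:::transform_domain(
    fv[[slot]], rigid_transform(diag(3), v))
  fv
}

rotate_structure <- function(fv, axis, angle, point = c(0, 0, 0)) {
  rot <- fvorient:::axis_rotation(axis, angle)
  tr <- rigid_transform(rot, point - as.numeric(rot %*% point))
  fvorient:::transform_fv(fv, tr)
}

test_that("orientation RMSD matches analytic values for identity and rigid shifts", {
  expect_equal(orientation_rmsd(base_fv, base_fv), 0, tolerance = 1e-9)
  shifted <- shift_domain(base_fv, "second", c(0, 1.2, 1.6))  # |v| = 2
  expect_equal(orientation_rmsd(base_fv, shifted), 2, tolerance = 1e-6)
  expect_equal(orientation_rmsd(shifted, base_fv),
               orientation_rmsd(base_fv, shifted), tolerance = 1e-9)
})

test_that("orientation RMSD of a rotated domain matches the literal-recipe oracle", {
  centroid <- colMeans(base_fv$first$ca)
  rotated <- base_fv
  rot <- fvorient:::axis_rotation(c(0.3, -0.5, 0.81), 10)
  rotated$first <- fvorient:::transform_domain(
    rotated$first, rigid_transform(rot, centroid - as.numeric(rot %*% centroid)))
  got <- orientation_rmsd(base_fv, rotated)
  expect_gt(got, 0.5)
  expect_equal(got, oracle_orientation_rmsd(base_fv, rotated),
               tolerance = 1e-6)
})

test_that("orientation RMSD is invariant under a common rigid motion", {
  other <- make_fv(pose_spec(HC2 = 105, seed = 101L))
  base <- orientation_rmsd(base_fv, other)
  moved <- rotate_structure(other, c(1, 2, -1), 77, point = c(5, -3, 10))
  moved <- fvorient:::transform_fv(moved, rigid_transform(diag(3), c(30, -12, 4)))
  expect_equal(orientation_rmsd(base_fv, moved), base, tolerance = 1e-9)
})

test_that("pairwise matrix is symmetric with zero diagonal and clusters families", {
  famA <- make_pose_family(pose_spec(), spread = 2, n = 4, seed = 1,
                           id_prefix = "a")
  famB <- make_pose_family(pose_spec(HC2 = 100), spread = 2, n = 4, seed = 2,
                           id_prefix = "b")
  dmat <- orientation_distance_matrix(c(famA, famB))
  expect_equal(dmat, t(dmat))
  expect_equal(diag(dmat), rep(0, 8), ignore_attr = TRUE)
  cl <- cluster_orientations(dmat, k = 2L)
  membership <- split(names(cl$labels), cl$labels)
  expect_setequal(vapply(membership, function(x) {
    paste(sort(unique(substr(x, 1, 1))), collapse = "")
  }, ""), c("a", "b"))
})

test_that("a single structure yields one cluster and no dendrogram", {
  dmat <- orientation_distance_matrix(list(base_fv))
  cl <- cluster_orientations(dmat, k = 2L)
  expect_null(cl$hclust)
  expect_equal(unname(cl$labels), 1L)
})

test_that("complete-linkage merge heights equal an O(n^3) oracle", {
  set.seed(15)
  for (trial in 1:5) {
    pts <- matrix(runif(12), ncol = 2L)
    d <- as.matrix(stats::dist(pts))
    hc <- cluster_orientations(d, k = 2L)$hclust
    expect_equal(sort(hc$height), oracle_complete_linkage_heights(d),
                 tolerance = 1e-12)
  }
})

test_that("coreset derivation drops jittered and rarely observed positions", {
  doms <- lapply(ref_ensemble, function(f) f$first)
  cs <- derive_coresets(doms)
  expect_gte(length(cs$positions), 20L)
  expect_true(all(cs$spread <= 1.0 + 1e-9))
  # identical members: every qualifying position is retained
  same <- lapply(1:5, function(i) doms[[1L]])
  cs_same <- derive_coresets(same)
  expect_setequal(cs_same$positions, framework_keys(doms[[1L]]))

  # inject 5 A jitter at one framework position of every member
  jit <- lapply(seq_along(doms), function(i) {
    d <- doms[[i]]
    j <- match("20", imgt_keys(d))
    d$ca[j, ] <- d$ca[j, ] + 5 * c(sin(i), cos(2 * i), sin(3 * i))
    d
  })
  cs_jit <- derive_coresets(jit)
  expect_false("20" %in% cs_jit$positions)

  # a position absent from 10 percent of members fails the presence rule
  partial <- doms
  partial[[1L]] <- local({
    d <- doms[[1L]]
    j <- match("30", imgt_keys(d))
    fv_domain(d$tab[-j, ], d$ca[-j, ], d$cb[-j, ], d$domain_type)
  })
  cs_part <- derive_coresets(partial, presence = 0.95)
  expect_false("30" %in% cs_part$positions)
})

test_that("consensus equals members for identical ensembles and midpoints for pairs", {
  dom <- ref_ensemble[[1L]]$first
  mats <- fvorient:::named_ca(list(dom, dom, dom))
  al <- fvorient:::align_ensemble(mats, framework_keys(dom))
  expect_equal(al$mean[imgt_keys(dom), ], unname(mats[[1L]]),
               tolerance = 1e-9, ignore_attr = TRUE)

  # two members differing by jitter: consensus is the aligned midpoint
  set.seed(9)
  d2ca <- dom$ca + matrix(rnorm(length(dom$ca), sd = 0.1), ncol = 3L)
  mats2 <- list(a = dom$ca, b = d2ca)
  rownames(mats2$a) <- rownames(mats2$b) <- imgt_keys(dom)
  al2 <- fvorient:::align_ensemble(mats2, framework_keys(dom), tol = 1e-8)
  mid <- (al2$aligned[[1L]] + al2$aligned[[2L]]) / 2
  expect_equal(al2$mean[rownames(mid), ], mid, tolerance = 1e-6)
})

test_that("frame vectors are orthonormal and the reference pose is self-consistent", {
  for (s in c("H", "L")) {
    f <- frames[[s]]$frame
    expect_equal(sqrt(sum(f$e1^2)), 1, tolerance = 1e-9)
    expect_equal(sqrt(sum(f$e2^2)), 1, tolerance = 1e-9)
    expect_equal(sum(f$e1 * f$e2), 0, tolerance = 1e-9)
  }
  # query = the reference structure itself reproduces the stored measures
  m <- compute_measures(ref_ensemble[[1L]], frames)
  ref <- frames$reference$measures
  for (k in c("HL", "HC1", "HC2", "LC1", "LC2", "dc")) {
    expect_equal(m[[k]], ref[[k]], tolerance = 1e-9)
  }
})

test_that("rotation about the pivot axis shifts HL only; translation changes dc only", {
  m0 <- compute_measures(base_fv, frames)
  # the generator lays the pivot axis along +z with origins on it
  rotated <- base_fv
  rot <- fvorient:::axis_rotation(c(0, 0, 1), 10)
  rotated$first <- fvorient:::transform_domain(
    rotated$first, rigid_transform(rot, c(0, 0, 0)))
  m1 <- compute_measures(rotated, frames)
  expect_equal(abs(fvorient:::wrap_angle(m1$HL - m0$HL)), 10,
               tolerance = 1e-6)
  expect_equal(m1$dc, m0$dc, tolerance = 1e-6)
  expect_equal(m1$HC1, m0$HC1, tolerance = 1e-6)
  expect_equal(m1$HC2, m0$HC2, tolerance = 1e-6)

  translated <- shift_domain(base_fv, "first", c(0, 0, 1))  # along C (+z)
  m2 <- compute_measures(translated, frames)
  expect_equal(m2$dc, m0$dc + 1, tolerance = 1e-6)
  for (k in c("HL", "HC1", "HC2", "LC1", "LC2")) {
    expect_equal(m2[[k]], m0[[k]], tolerance = 1e-6)
  }
})

test_that("measures are invariant under rigid motion of the whole query", {
  m0 <- compute_measures(base_fv, frames)
  moved <- rotate_structure(base_fv, c(2, -1, 0.5), 123, point = c(4, 4, -2))
  moved <- fvorient:::transform_fv(moved,
                                   rigid_transform(diag(3), c(-7, 13, 21)))
  m1 <- compute_measures(moved, frames)
  for (k in c("HL", "HC1", "HC2", "LC1", "LC2", "dc")) {
    expect_equal(m1[[k]], m0[[k]], tolerance = 1e-6)
  }
})

test_that("orientation RMSD correlates with distance in six-measure space", {
  set.seed(44)
  fam <- make_pose_family(pose_spec(), spread = 3, n = 10, seed = 77)
  tab <- measures_table(fam, frames)
  msp <- as.matrix(tab[, c("HL", "HC1", "HC2", "LC1", "LC2", "dc")])
  d_measures <- as.matrix(stats::dist(msp))
  d_rmsd <- orientation_distance_matrix(fam)
  lower <- lower.tri(d_rmsd)
  rho <- stats::cor(d_rmsd[lower], d_measures[lower], method = "spearman")
  expect_gte(rho, 0.9)
})

test_that("measure tables and Newick export round through files", {
  fam <- make_pose_family(pose_spec(), spread = 2, n = 4, seed = 3)
  tab <- measures_table(fam, frames)
  expect_equal(nrow(tab), 4L)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_measures_csv(tab, csv)
  back <- utils::read.csv(csv)
  expect_equal(back$HC2, tab$HC2, tolerance = 1e-9)
  dmat <- orientation_distance_matrix(fam)
  hc <- cluster_orientations(dmat, k = 2L)$hclust
  nwk <- dendrogram_newick(hc)
  expect_match(nwk, "^\\(")
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, rownames(dmat))
})
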