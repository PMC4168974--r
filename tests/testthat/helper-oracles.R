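# Independent oracles: brute-force or third-party reimplementations used to
# check package results. They never call the code paths they validate.

# numeric-optimiser superposition oracle: minimise RMSD over Euler angles and
# translation from several starts
oracle_min_rmsd <- function(mobile, target, n_starts = 8L) {
  euler <- function(a) {
    cz <- cos(a[1]); sz <- sin(a[1])
    cy <- cos(a[2]); sy <- sin(a[2])
    cx <- cos(a[3]); sx <- sin(a[3])
    rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    rz %*% ry %*% rx
  }
  obj <- function(p) {
    moved <- mobile %*% t(euler(p[1:3])) +
      matrix(p[4:6], nrow(mobile), 3L, byrow = TRUE)
    sqrt(mean(rowSums((moved - target)^2)))
  }
  set.seed(99)
  best <- Inf
  starts <- rbind(rep(0, 6),
                  matrix(stats::runif(6 * (n_starts - 1L), -pi, pi),
                         ncol = 6L))
  starts[, 4:6] <- 0
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[i, ], obj, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-14))
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-15))
    if (fit$value < best) best <- fit$value
  }
  best
}

# literal-recipe orientation RMSD using bio3d's fitting (independent of the
# package's Kabsch implementation): align y on x via the shared L-side
# framework, independently fit x's H-side onto y's aligned H-side, take the
# CA RMSD of x's H-side native vs fitted; average over both directions.
oracle_orientation_rmsd <- function(x, y) {
  keys_fw <- function(d) {
    k <- paste0(d$tab$imgt, d$tab$imgt_ins)
    k[!(d$tab$imgt %in% c(27:38, 56:65, 105:117))]
  }
  ca_at <- function(d, keys) {
    d$ca[match(keys, paste0(d$tab$imgt, d$tab$imgt_ins)), , drop = FALSE]
  }
  one <- function(xa, ya, xf, yf) {
    ka <- intersect(keys_fw(xa), keys_fw(ya))
    kf <- intersect(keys_fw(xf), keys_fw(yf))
    # move y (anchor + free) onto x's anchor domain
    fixed <- as.numeric(t(ca_at(xa, ka)))
    ymob <- as.numeric(t(rbind(ca_at(ya, ka), ca_at(yf, kf))))
    na <- length(ka)
    moved <- bio3d::fit.xyz(fixed, ymob,
                            fixed.inds = bio3d::atom2xyz(seq_len(na)),
                            mobile.inds = bio3d::atom2xyz(seq_len(na)))
    yf_aligned <- matrix(moved[-seq_len(3L * na)], ncol = 3L, byrow = TRUE)
    # fit x's free domain onto y's aligned free domain
    xf_ca <- ca_at(xf, kf)
    fitted <- bio3d::fit.xyz(as.numeric(t(yf_aligned)),
                             as.numeric(t(xf_ca)),
                             fixed.inds = bio3d::atom2xyz(seq_len(nrow(xf_ca))),
                             mobile.inds = bio3d::atom2xyz(seq_len(nrow(xf_ca))))
    fitted <- matrix(fitted, ncol = 3L, byrow = TRUE)
    sqrt(mean(rowSums((xf_ca - fitted)^2)))
  }
  (one(x$second, y$second, x$first, y$first) +
     one(x$first, y$first, x$second, y$second)) / 2
}

# O(n^3) complete-linkage agglomeration: returns sorted merge heights
oracle_complete_linkage_heights <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric()
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best) { best <- h; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  sort(heights)
}

# all-pairs CB contact scan
oracle_contact_count <- function(complex, cutoff = 7.0) {
  rec <- rbind(complex$receptor$first$cb, complex$receptor$second$cb)
  env <- do.call(rbind, c(lapply(complex$mhc_chains, `[[`, "cb"),
                          list(complex$peptide$cb)))
  n <- 0L
  for (i in seq_len(nrow(rec))) {
    for (j in seq_len(nrow(env))) {
      if (sqrt(sum((rec[i, ] - env[j, ])^2)) < cutoff) n <- n + 1L
    }
  }
  n
}

# CB-fallback clash scan for one receptor domain against MHC + peptide
oracle_clash_count <- function(complex, slot = "first", cutoff = 3.0) {
  dom <- complex$receptor[[slot]]$cb
  env <- do.call(rbind, c(lapply(complex$mhc_chains, `[[`, "cb"),
                          list(complex$peptide$cb)))
  n <- 0L
  for (i in seq_len(nrow(dom))) {
    for (j in seq_len(nrow(env))) {
      if (sqrt(sum((dom[i, ] - env[j, ])^2)) < cutoff) n <- n + 1L
    }
  }
  n
}

# greedy redundancy filter on a sequence matrix (rows named), resolutions and
# ids supplied separately
oracle_greedy_filter <- function(seqmat, resolutions, ids, threshold) {
  resolutions[is.na(resolutions)] <- Inf
  ord <- order(resolutions, ids)
  kept <- integer()
  for (i in ord) {
    keep <- TRUE
    for (j in kept) {
      shared <- !is.na(seqmat[i, ]) & !is.na(seqmat[j, ])
      ident <- if (!any(shared)) 0 else
        sum(seqmat[i, shared] == seqmat[j, shared]) / sum(shared)
      if (ident >= threshold) { keep <- FALSE; break }
    }
    if (keep) kept <- c(kept, i)
  }
  ids[kept]
}

# exhaustive two-sample KS: statistic and exact permutation p-value
oracle_ks <- function(a, b) {
  pooled <- c(a, b)
  dstat <- function(x, y) {
    grid <- sort(unique(c(x, y)))
    fx <- vapply(grid, function(g) mean(x <= g), 0)
    fy <- vapply(grid, function(g) mean(y <= g), 0)
    max(abs(fx - fy))
  }
  d0 <- dstat(a, b)
  idx <- utils::combn(length(pooled), length(a))
  ds <- apply(idx, 2L, function(ii) dstat(pooled[ii], pooled[-ii]))
  list(statistic = d0, p = mean(ds >= d0 - 1e-12))
}

# Mann-Whitney U by exhaustive pair counting + permutation p-value
oracle_mann_whitney <- function(a, b) {
  u <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  pooled <- c(a, b)
  idx <- utils::combn(length(pooled), length(a))
  us <- apply(idx, 2L, function(ii) {
    x <- pooled[ii]; y <- pooled[-ii]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  })
  mu <- length(a) * length(b) / 2
  p <- mean(abs(us - mu) >= abs(u - mu) - 1e-12)
  list(U = u, p = p)
}
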