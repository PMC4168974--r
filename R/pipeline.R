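# Orchestration of the two experiments end-to-end: the orientation survey
# (measures + two-sample Kolmogorov-Smirnov tests + orientation-RMSD
# clustering with class-mixing summary) and the decoy grafting experiment
# (clash/contact counts, cohort medians, Mann-Whitney U). No multiple-testing
# correction is applied across the six measures.

MEASURE_NAMES <- c("HL", "HC1", "HC2", "LC1", "LC2", "dc")

#' Orientation survey of two cohorts
#'
#' Builds coresets, consensus domains and frames from the pooled cohorts
#' (or uses supplied `frames`), computes the six orientation measures per
#' structure, compares each measure between cohorts with a two-sided
#' two-sample Kolmogorov-Smirnov test, and clusters the pooled pairwise
#' orientation-RMSD matrix by complete linkage, summarising how much the two
#' classes mix across clusters.
#'
#' @param cohortA,cohortB Lists of [fv_structure()] objects (>= 2 each).
#' @param labels Length-2 cohort names.
#' @param frames Optional prebuilt `frame_system`; built from the pooled
#'   cohorts when `NULL`.
#' @param k Number of clusters for the complete-linkage cut.
#' @param interface_positions Passed to [build_consensus_and_frames()].
#' @param min_shared Passed to the measure and RMSD computations.
#' @return An object of class `survey_report`: measures table, per-measure
#'   KS results, cluster labels, mixing summary and the frame system.
#' @export
run_survey <- function(cohortA, cohortB, labels = c("A", "B"), frames = NULL,
                       k = 2L, interface_positions = DEFAULT_INTERFACE,
                       min_shared = 20L) {
  stopifnot(length(cohortA) >= 2L, length(cohortB) >= 2L)
  pooled <- c(cohortA, cohortB)
  cohort <- rep(labels, c(length(cohortA), length(cohortB)))
  if (is.null(frames)) {
    frames <- build_consensus_and_frames(pooled, interface_positions)
  }
  tab <- measures_table(pooled, frames, min_shared)
  tab$cohort <- cohort
  ks <- lapply(MEASURE_NAMES, function(m) {
    a <- tab[[m]][cohort == labels[1L]]
    b <- tab[[m]][cohort == labels[2L]]
    kt <- suppressWarnings(stats::ks.test(a, b, exact = NULL))
    data.frame(measure = m, statistic = unname(kt$statistic),
               p_value = kt$p.value, stringsAsFactors = FALSE)
  })
  ks <- do.call(rbind, ks)
  dmat <- orientation_distance_matrix(pooled, min_shared)
  cl <- cluster_orientations(dmat, k = k)
  keep <- !(rownames(dmat) %in% cl$dropped)
  mixing <- {
    cls <- split(cohort[keep], cl$labels)
    mean(vapply(cls, function(x) length(unique(x)) > 1L, TRUE))
  }
  structure(list(measures = tab, ks = ks, distance_matrix = dmat,
                 clustering = cl, mixing = mixing, labels = labels,
                 frames = frames),
            class = "survey_report")
}

#' @export
print.survey_report <- function(x, ...) {
  cat("<survey_report> ", nrow(x$measures), " structures (",
      sum(x$measures$cohort == x$labels[1L]), " ", x$labels[1L], " / ",
      sum(x$measures$cohort == x$labels[2L]), " ", x$labels[2L], ")\n",
      sep = "")
  cat("  Kolmogorov-Smirnov (two-sided, per measure, uncorrected):\n")
  for (i in seq_len(nrow(x$ks))) {
    cat(sprintf("    %-3s D = %.3f  p = %.3g\n", x$ks$measure[i],
                x$ks$statistic[i], x$ks$p_value[i]))
  }
  cat(sprintf("  clusters: %d; fraction mixing both classes: %.2f\n",
              length(unique(x$clustering$labels)), x$mixing))
  invisible(x)
}

#' Summary of a survey report
#' @param object A `survey_report`.
#' @param ... Unused.
#' @return data.frame of per-measure cohort means and KS results.
#' @export
summary.survey_report <- function(object, ...) {
  tab <- object$measures
  out <- object$ks
  for (lab in object$labels) {
    means <- vapply(MEASURE_NAMES, function(m) {
      mean(tab[[m]][tab$cohort == lab])
    }, 0)
    out[[paste0("mean_", lab)]] <- means
  }
  out
}

#' Write survey outputs
#'
#' Writes the measures table and distance matrix as CSV and the dendrogram
#' as Newick into a directory.
#'
#' @param report A `survey_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_survey <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_measures_csv(report$measures, file.path(dir, "measures.csv"))
  utils::write.csv(report$distance_matrix,
                   file.path(dir, "orientation_rmsd.csv"))
  utils::write.csv(report$ks, file.path(dir, "ks_tests.csv"),
                   row.names = FALSE)
  if (!is.null(report$clustering$hclust)) {
    dendrogram_newick(report$clustering$hclust,
                      file.path(dir, "dendrogram.nwk"))
  }
  invisible(dir)
}

#' Decoy orientation-grafting experiment
#'
#' For every decoy in each cohort and for both anchoring choices (Valpha
#' anchored with the Vbeta side moving, then the roles swapped), the decoy's
#' inter-domain orientation is grafted into the native complex and
#' receptor-MHC/peptide clashes and contacts are counted. Total clash counts
#' (moved + anchored domain, summed over both anchorings) are compared
#' between cohorts with a two-sided Mann-Whitney U test.
#'
#' @param native A [pmhc_complex()].
#' @param decoysA,decoysB Lists of decoy [fv_structure()] objects.
#' @param labels Length-2 cohort names.
#' @param anchors Anchoring choices to run.
#' @param clash_overlap,contact_cutoff,min_shared Passed to
#'   [graft_orientation()].
#' @return An object of class `graft_report` with the per-decoy table,
#'   cohort medians and the rank-test result. Individual decoy failures are
#'   logged as warnings and excluded.
#' @export
run_graft_experiment <- function(native, decoysA, decoysB,
                                 labels = c("A", "B"),
                                 anchors = c("Valpha", "Vbeta"),
                                 clash_overlap = 0.4, contact_cutoff = 7.0,
                                 min_shared = 20L) {
  stopifnot(length(decoysA) >= 1L, length(decoysB) >= 1L)
  run_cohort <- function(decoys, label) {
    rows <- lapply(seq_along(decoys), function(i) {
      res <- tryCatch({
        per_anchor <- lapply(anchors, function(an) {
          g <- graft_orientation(native, decoys[[i]], anchored = an,
                                 min_shared = min_shared,
                                 clash_overlap = clash_overlap,
                                 contact_cutoff = contact_cutoff)
          data.frame(decoy_id = g$decoy_id, cohort = label, anchored = an,
                     moved_domain = g$moved_domain,
                     clashes_moved = g$clashes_moved_domain,
                     clashes_anchored = g$clashes_anchored_domain,
                     contacts = nrow(g$contact_pairs),
                     stringsAsFactors = FALSE)
        })
        do.call(rbind, per_anchor)
      }, error = function(e) {
        warning("decoy ", decoys[[i]]$pdb_id, " failed: ",
                conditionMessage(e))
        NULL
      })
      res
    })
    do.call(rbind, rows)
  }
  tab <- rbind(run_cohort(decoysA, labels[1L]),
               run_cohort(decoysB, labels[2L]))
  totals <- stats::aggregate(cbind(total_clashes = clashes_moved +
                                     clashes_anchored) ~ decoy_id + cohort,
                             data = tab, FUN = sum)
  medians <- stats::aggregate(clashes_moved ~ cohort + moved_domain,
                              data = tab, FUN = stats::median)
  names(medians)[3L] <- "median_clashes_moved"
  a_tot <- totals$total_clashes[totals$cohort == labels[1L]]
  b_tot <- totals$total_clashes[totals$cohort == labels[2L]]
  mw <- if (length(a_tot) && length(b_tot)) {
    suppressWarnings(stats::wilcox.test(a_tot, b_tot, exact = NULL))
  } else NULL
  structure(list(per_graft = tab, totals = totals, medians = medians,
                 mann_whitney = mw, labels = labels),
            class = "graft_report")
}

#' @export
print.graft_report <- function(x, ...) {
  cat("<graft_report> ", nrow(x$per_graft), " grafts\n", sep = "")
  print(x$medians, row.names = FALSE)
  if (!is.null(x$mann_whitney)) {
    cat(sprintf("  Mann-Whitney U on total clashes: W = %.1f, p = %.3g\n",
                unname(x$mann_whitney$statistic), x$mann_whitney$p.value))
  }
  invisible(x)
}

#' Write graft experiment outputs
#'
#' Per-graft results as CSV and a JSON summary with cohort medians.
#'
#' @param report A `graft_report`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_graft <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$per_graft, file.path(dir, "grafts.csv"),
                   row.names = FALSE)
  summary <- list(
    medians = report$medians,
    median_total_by_cohort = lapply(split(report$totals$total_clashes,
                                          report$totals$cohort),
                                    stats::median),
    mann_whitney_p = if (!is.null(report$mann_whitney))
      report$mann_whitney$p.value else NA
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
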