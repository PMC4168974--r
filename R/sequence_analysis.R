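# IMGT-position-wise sequence analyses: conservation, domain-equivalence
# support, divergent conserved interface positions, CDR3 length
# distributions, and a greedy sequence-identity redundancy filter.
#
# An IMGT-indexed sequence set is a character matrix: one row per sequence,
# columns named by IMGT position key ("1".."128", insertion keys like "111A"
# allowed); unobserved positions are NA. Gap/unobserved positions are
# excluded from both numerator and denominator of every frequency.

#' IMGT-indexed sequence matrix from domains
#'
#' @param domains List of `fv_domain` objects (or an [fv_structure()] list
#'   via [fv_sequence_matrix()]).
#' @param ids Optional row names.
#' @return Character matrix, rows = sequences, columns = IMGT position keys
#'   in grid order.
#' @export
imgt_sequence_matrix <- function(domains, ids = NULL) {
  keysets <- lapply(domains, imgt_keys)
  allkeys <- unique(unlist(keysets))
  base <- suppressWarnings(as.integer(gsub("[A-Za-z]+$", "", allkeys)))
  allkeys <- allkeys[order(base, allkeys)]
  m <- matrix(NA_character_, length(domains), length(allkeys),
              dimnames = list(ids, allkeys))
  for (i in seq_along(domains)) {
    m[i, keysets[[i]]] <- domains[[i]]$tab$aa
  }
  m
}

#' Concatenated two-domain sequence matrix for paired structures
#'
#' H-side positions are prefixed `H:` and L-side positions `L:` so the two
#' domains share one IMGT-indexed grid.
#'
#' @param structures List of [fv_structure()] objects.
#' @return Character matrix, one row per structure.
#' @export
fv_sequence_matrix <- function(structures) {
  ids <- make.unique(vapply(structures, function(s) s$pdb_id, ""))
  h <- imgt_sequence_matrix(lapply(structures, function(s) s$first), ids)
  l <- imgt_sequence_matrix(lapply(structures, function(s) s$second), ids)
  colnames(h) <- paste0("H:", colnames(h))
  colnames(l) <- paste0("L:", colnames(l))
  cbind(h, l)
}

#' Read an IMGT-indexed FASTA file
#'
#' Each header must carry the occupied IMGT position keys as
#' `imgt=key1,key2,...` (comma-separated, in sequence order); the sequence
#' length must equal the number of keys.
#'
#' @param path FASTA file path.
#' @return Character matrix as in [imgt_sequence_matrix()].
#' @export
read_imgt_fasta <- function(path) {
  fa <- seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE,
                           whole.header = TRUE)
  seqs <- lapply(fa, function(s) toupper(as.character(s)))
  headers <- names(fa)
  keys <- lapply(headers, function(h) {
    m <- regmatches(h, regexpr("imgt=[^ ]+", h))
    if (!length(m)) stop("FASTA header lacks imgt= position list: ", h)
    strsplit(sub("^imgt=", "", m), ",", fixed = TRUE)[[1L]]
  })
  ids <- vapply(strsplit(headers, " ", fixed = TRUE), `[`, "", 1L)
  for (i in seq_along(seqs)) {
    if (length(seqs[[i]]) != length(keys[[i]])) {
      stop("sequence/position-list length mismatch for ", ids[i])
    }
  }
  allkeys <- unique(unlist(keys))
  base <- suppressWarnings(as.integer(gsub("[A-Za-z]+$", "", allkeys)))
  allkeys <- allkeys[order(base, allkeys)]
  m <- matrix(NA_character_, length(seqs), length(allkeys),
              dimnames = list(make.unique(ids), allkeys))
  for (i in seq_along(seqs)) m[i, keys[[i]]] <- seqs[[i]]
  m
}

#' Amino-acid frequency profile of one IMGT position
#'
#' @param seqs IMGT-indexed sequence matrix.
#' @param position Position key (e.g. `"50"`).
#' @return List with `position`, `freq` (named frequencies over observed
#'   residues, summing to 1) and `n_observed`.
#' @export
position_profile <- function(seqs, position) {
  col <- if (position %in% colnames(seqs)) seqs[, position] else
    rep(NA_character_, nrow(seqs))
  obs <- col[!is.na(col) & col != "-"]
  freq <- if (length(obs)) sort(table(obs) / length(obs), decreasing = TRUE)
          else table(character())
  list(position = position, freq = c(freq), n_observed = length(obs))
}

#' Conserved residue of one IMGT position
#'
#' A position is conserved when one amino acid reaches the threshold
#' frequency over the sequences observing it (at least 50 percent by default). An
#' exact two-way tie at 0.5/0.5 is flagged ambiguous and returns `NA` with a
#' warning.
#'
#' @param seqs IMGT-indexed sequence matrix (at least 2 observing
#'   sequences).
#' @param position Position key.
#' @param threshold Conservation threshold (fraction).
#' @param strict Use a strict `>` comparison instead of `>=`.
#' @return List with `residue` (`NA` when not conserved), `frequency`,
#'   `n_observed` and `flag` (`""`, `"ambiguous"` or `"zero-coverage"`).
#' @export
column_conservation <- function(seqs, position, threshold = 0.5,
                                strict = FALSE) {
  pr <- position_profile(seqs, position)
  if (pr$n_observed == 0L) {
    return(list(residue = NA_character_, frequency = NA_real_,
                n_observed = 0L, flag = "zero-coverage"))
  }
  f <- pr$freq
  top <- f[1L]
  pass <- if (strict) top > threshold else top >= threshold
  if (pass && sum(abs(f - top) < 1e-12) > 1L) {
    warning("ambiguous tie at position ", position)
    return(list(residue = NA_character_, frequency = unname(top),
                n_observed = pr$n_observed, flag = "ambiguous"))
  }
  list(residue = if (pass) names(f)[1L] else NA_character_,
       frequency = unname(top), n_observed = pr$n_observed, flag = "")
}

# conserved residue (or NA) for every position of a key set
conservation_vector <- function(seqs, positions, threshold = 0.5,
                                strict = FALSE) {
  vapply(positions, function(p) {
    suppressWarnings(column_conservation(seqs, p, threshold, strict)$residue)
  }, "")
}

#' Positional support for the two domain-equivalence hypotheses
#'
#' For the VH-Vbeta/VL-Valpha pairing, a position argues for the alternative
#' (VH-Valpha/VL-Vbeta) when VH and Valpha conserve the same residue while
#' VL conserves a different one; the mirrored pattern (VH and Vbeta share a
#' conserved residue, VL differs) argues for VH-Vbeta/VL-Valpha. Both
#' tallies and the contributing positions are returned.
#'
#' @param vh,vl,vb,va IMGT-indexed sequence matrices for the four domain
#'   types.
#' @param threshold Conservation threshold (default at least 50 percent).
#' @return List with `support` (named counts for `VH_Vbeta_VL_Valpha` and
#'   `VH_Valpha_VL_Vbeta`) and `positions` (lists of contributing keys).
#' @export
equivalence_support <- function(vh, vl, vb, va, threshold = 0.5) {
  positions <- sort(unique(c(colnames(vh), colnames(vl), colnames(vb),
                             colnames(va))))
  ch <- conservation_vector(vh, positions, threshold)
  cl <- conservation_vector(vl, positions, threshold)
  cb <- conservation_vector(vb, positions, threshold)
  ca <- conservation_vector(va, positions, threshold)
  for_alt <- !is.na(ch) & !is.na(ca) & !is.na(cl) & ch == ca & cl != ch
  for_main <- !is.na(ch) & !is.na(cb) & !is.na(cl) & ch == cb & cl != ch
  list(support = c(VH_Vbeta_VL_Valpha = sum(for_main),
                   VH_Valpha_VL_Vbeta = sum(for_alt)),
       positions = list(VH_Vbeta_VL_Valpha = positions[for_main],
                        VH_Valpha_VL_Vbeta = positions[for_alt]))
}

#' Divergent conserved interface positions
#'
#' Positions where both sequence sets are conserved (strictly above 50 percent by
#' default) but with different residues. A divergent position is flagged
#' antibody-compatible when set B's conserved residue also occurs at a
#' background frequency of at least `compat_threshold` in set A.
#'
#' @param setA,setB IMGT-indexed sequence matrices (e.g. antibodies and
#'   TCRs).
#' @param interface Character vector of interface position keys.
#' @param compat_threshold Background-frequency threshold for compatibility
#'   (default 2 percent).
#' @param threshold Conservation threshold.
#' @param strict Strict `>` conservation comparison (default `TRUE`, as for
#'   the divergent-position tabulation).
#' @return data.frame with one row per divergent position: the conserved
#'   residue and percentage in each set and the `compatible` flag.
#' @export
divergent_interface_positions <- function(setA, setB, interface,
                                          compat_threshold = 0.02,
                                          threshold = 0.5, strict = TRUE) {
  rows <- lapply(interface, function(p) {
    a <- suppressWarnings(column_conservation(setA, p, threshold, strict))
    b <- suppressWarnings(column_conservation(setB, p, threshold, strict))
    if (is.na(a$residue) || is.na(b$residue) || a$residue == b$residue) {
      return(NULL)
    }
    bg <- position_profile(setA, p)$freq
    bfreq <- if (b$residue %in% names(bg)) bg[[b$residue]] else 0
    data.frame(position = p,
               residue_A = a$residue, percent_A = 100 * a$frequency,
               residue_B = b$residue, percent_B = 100 * b$frequency,
               background_freq_A = bfreq,
               compatible = bfreq >= compat_threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(position = character(), residue_A = character(),
                      percent_A = numeric(), residue_B = character(),
                      percent_B = numeric(), background_freq_A = numeric(),
                      compatible = logical(), stringsAsFactors = FALSE)
  }
  out
}

#' CDR3 length distribution of a set of domains
#'
#' CDR3 residues occupy IMGT positions 105-117 inclusive (plus any
#' insertions in the 111/112 block).
#'
#' @param domains List of `fv_domain` objects.
#' @return List with `lengths` (per-domain counts), `histogram` (table of
#'   counts per length) and `mode` (most frequent length; ties resolved to
#'   the smallest).
#' @export
cdr3_length_distribution <- function(domains) {
  lens <- vapply(domains, function(d) length(cdr_keys(d, "cdr3")), 0L)
  if (any(lens == 0L)) {
    warning(sum(lens == 0L), " domain(s) with zero CDR3 residues")
  }
  hist <- table(lens)
  mode <- as.integer(names(hist)[which.max(hist)])
  list(lengths = lens, histogram = hist, mode = mode)
}

# position-wise sequence identity over shared observed positions
pairwise_identity <- function(a, b) {
  shared <- !is.na(a) & !is.na(b)
  if (!any(shared)) return(0)
  sum(a[shared] == b[shared]) / sum(shared)
}

#' Greedy sequence-identity redundancy filter
#'
#' Structures are ordered by resolution (ascending, `NA` last) and then
#' lexicographically by identifier; a structure is kept iff its position-wise
#' identity (matches over shared observed positions of the concatenated
#' two-domain IMGT sequence) to every already-kept structure is below the
#' threshold. The result is independent of the input order.
#'
#' @param structures List of [fv_structure()] objects.
#' @param identity_threshold Fraction (default 0.90).
#' @return The retained sublist, in the greedy selection order.
#' @export
filter_redundant <- function(structures, identity_threshold = 0.90) {
  if (!length(structures)) return(structures)
  m <- fv_sequence_matrix(structures)
  res <- vapply(structures, function(s) {
    if (is.null(s$resolution) || is.na(s$resolution)) Inf else s$resolution
  }, 0)
  ids <- vapply(structures, function(s) s$pdb_id, "")
  ord <- order(res, ids)
  kept <- integer()
  for (i in ord) {
    ok <- all(vapply(kept, function(j) {
      pairwise_identity(m[i, ], m[j, ]) < identity_threshold
    }, TRUE))
    if (ok) kept <- c(kept, i)
  }
  structures[kept]
}
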