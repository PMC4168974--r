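# pMHC-facing computations: the receptor-MHC docking angle with canonical
# classification, the decoy orientation-grafting protocol, and steric
# clash / contact quantification.

# fixed van der Waals radii (Angstrom); user-overridable in count_clashes
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

# CA coordinate of IMGT position 104 of a domain, with a named error
cys104_ca <- function(domain) {
  idx <- match("104", imgt_keys(domain))
  if (is.na(idx)) {
    stop("interface cysteine anchor (IMGT position 104) absent in ",
         domain$domain_type, " domain")
  }
  domain$ca[idx, ]
}

#' The receptor-pMHC docking angle
#'
#' The angle between the major axis of the peptide (first principal axis of
#' its CA atoms, oriented from the N to the C terminus) and the vector
#' between the CA atoms of the interface cysteines (IMGT position 104),
#' directed from the VL/Valpha domain to the VH/Vbeta domain. A canonical
#' TCR docking angle lies between 40 and 85 degrees.
#'
#' @param complex A [pmhc_complex()] whose peptide has at least 3 residues.
#' @param canonical_band Length-2 numeric, the canonical angle range in
#'   degrees.
#' @return An object of class `docking_geometry` with `angle` (degrees in
#'   \[0, 180)), `canonical`, `peptide_axis` and `cys_vector` (unit vectors).
#' @export
docking_angle <- function(complex, canonical_band = c(40, 85)) {
  stopifnot(inherits(complex, "pmhc_complex"))
  pep <- complex$peptide$ca
  if (nrow(pep) < 3L) stop("peptide must have at least 3 residues")
  axis <- principal_axes(pep)$axes[, 1L]
  ca_b <- cys104_ca(complex$receptor$first)   # VH / Vbeta side
  ca_a <- cys104_ca(complex$receptor$second)  # VL / Valpha side
  cysv <- ca_b - ca_a
  ncys <- sqrt(sum(cysv^2))
  if (ncys < 1e-9) stop("coincident interface cysteines")
  ang <- vector_angle(axis, cysv)
  if (ang >= 180) ang <- 0
  structure(list(angle = ang,
                 canonical = ang >= canonical_band[1L] &&
                   ang <= canonical_band[2L],
                 peptide_axis = axis, cys_vector = cysv / ncys),
            class = "docking_geometry")
}

#' @export
print.docking_geometry <- function(x, ...) {
  cat(sprintf("docking angle %.1f deg (%s)\n", x$angle,
              if (x$canonical) "canonical" else "non-canonical"))
  invisible(x)
}

#' Graft a decoy inter-domain orientation into a native complex
#'
#' The decoy's anchored-equivalent domain is superposed onto the native
#' anchored domain via their shared framework CA positions; the native
#' partner domain is then independently superposed onto the decoy's partner
#' domain in that aligned context, so it assumes the decoy's inter-domain
#' pose. The MHC, peptide and anchored domain are untouched.
#'
#' @param native A [pmhc_complex()].
#' @param decoy An [fv_structure()] providing the target orientation.
#' @param anchored `"Valpha"` (VL/Valpha side stays native, the VH/Vbeta
#'   side moves) or `"Vbeta"` (roles swapped).
#' @param decoy_id Identifier recorded in the result.
#' @param min_shared Minimum shared framework positions per superposition.
#' @param clash_overlap,contact_cutoff Passed to [count_clashes()] and
#'   [contact_pairs()].
#' @return An object of class `graft_result` with the grafted complex, the
#'   moved-domain and anchored-domain clash counts and the contact pairs.
#' @export
graft_orientation <- function(native, decoy, anchored = c("Valpha", "Vbeta"),
                              decoy_id = decoy$pdb_id, min_shared = 20L,
                              clash_overlap = 0.4, contact_cutoff = 7.0) {
  anchored <- match.arg(anchored)
  anchor_slot <- if (anchored == "Valpha") "second" else "first"
  moved_slot <- if (anchored == "Valpha") "first" else "second"
  nat_anchor <- native$receptor[[anchor_slot]]
  nat_moved <- native$receptor[[moved_slot]]
  dec_anchor <- decoy[[anchor_slot]]
  dec_moved <- decoy[[moved_slot]]
  sh_a <- intersect(framework_keys(nat_anchor), framework_keys(dec_anchor))
  sh_m <- intersect(framework_keys(nat_moved), framework_keys(dec_moved))
  if (length(sh_a) < min_shared || length(sh_m) < min_shared) {
    stop("insufficient shared framework positions for grafting (anchor ",
         length(sh_a), ", moved ", length(sh_m), ")")
  }
  # place the whole decoy so its anchored-equivalent domain sits on the
  # native anchored domain
  tr1 <- superpose(domain_ca_at(dec_anchor, sh_a),
                   domain_ca_at(nat_anchor, sh_a))$transform
  dec_moved_placed <- apply_transform(domain_ca_at(dec_moved, sh_m), tr1)
  # native partner domain assumes the decoy partner's placed pose
  tr2 <- superpose(domain_ca_at(nat_moved, sh_m), dec_moved_placed)$transform
  grafted <- native
  grafted$receptor[[moved_slot]] <- transform_domain(nat_moved, tr2)
  cl <- count_clashes(grafted, moved = moved_slot, overlap = clash_overlap)
  structure(list(decoy_id = decoy_id,
                 moved_domain = if (anchored == "Valpha") "Vbeta" else "Valpha",
                 anchored = anchored,
                 grafted_complex = grafted,
                 clashes_moved_domain = cl$moved,
                 clashes_anchored_domain = cl$anchored,
                 contact_pairs = contact_pairs(grafted,
                                               cutoff = contact_cutoff)),
            class = "graft_result")
}

#' @export
print.graft_result <- function(x, ...) {
  cat("<graft_result> decoy ", x$decoy_id, ": moved ", x$moved_domain,
      " clashes ", x$clashes_moved_domain, ", anchored clashes ",
      x$clashes_anchored_domain, ", ", nrow(x$contact_pairs),
      " contacts < 7 A\n", sep = "")
  invisible(x)
}

# heavy-atom coordinate matrix + element vector of one receptor residue
residue_atoms <- function(domain, i) {
  if (!is.null(domain$atoms) && !is.null(domain$atoms[[i]])) {
    a <- domain$atoms[[i]]
    list(xyz = as.matrix(a[, c("x", "y", "z")]), element = a$element)
  } else NULL
}

# clash between two residues given their atom sets or CB fallback coords
pair_clashes <- function(xyzA, elA, cbA, xyzB, elB, cbB, overlap, cb_cut) {
  if (!is.null(xyzA) && !is.null(xyzB)) {
    rA <- unname(VDW_RADII[elA]); rA[is.na(rA)] <- 1.70
    rB <- unname(VDW_RADII[elB]); rB[is.na(rB)] <- 1.70
    for (i in seq_len(nrow(xyzA))) {
      d2 <- rowSums(sweep(xyzB, 2L, xyzA[i, ])^2)
      lim <- (rA[i] + rB - overlap)^2
      if (any(d2 < lim)) return(TRUE)
    }
    FALSE
  } else {
    sum((cbA - cbB)^2) < cb_cut^2
  }
}

# gather the MHC + peptide side of a complex as a list of chains
mhc_peptide_chains <- function(complex) {
  c(complex$mhc_chains, list(peptide = complex$peptide))
}

#' Count receptor-MHC/peptide residue clashes
#'
#' A receptor residue and an MHC/peptide residue clash when any heavy-atom
#' pair overlaps by at least `overlap` Angstrom of the summed van der Waals
#' radii (C 1.70, N 1.55, O 1.52, S 1.80, others 1.70). When only CA/CB
#' coordinates are available the fallback criterion is a CB-CB distance
#' below `cb_cutoff`. Each residue pair is counted at most once.
#'
#' @param complex A [pmhc_complex()].
#' @param moved Which receptor domain slot (`"first"`/`"second"`) is the
#'   moved one; counts are reported for both.
#' @param overlap van der Waals overlap threshold (Angstrom).
#' @param cb_cutoff CB-CB fallback distance (Angstrom).
#' @return List with `moved` and `anchored` clash counts.
#' @export
count_clashes <- function(complex, moved = "first", overlap = 0.4,
                          cb_cutoff = 3.0) {
  env_chains <- mhc_peptide_chains(complex)
  chain_atoms <- function(ch, j) {
    if (!is.null(ch$atoms) && !is.null(ch$atoms[[j]])) {
      a <- ch$atoms[[j]]
      list(xyz = as.matrix(a[, c("x", "y", "z")]), element = a$element)
    } else NULL
  }
  count_for <- function(domain) {
    n <- nrow(domain$tab)
    if (n == 0L) return(0L)
    all_atom <- !is.null(domain$atoms)
    total <- 0L
    for (ch in env_chains) {
      m <- nrow(ch$tab)
      if (m == 0L) next
      # coarse prefilter on CB distance before any atom-level work
      d2 <- outer(rowSums(domain$cb^2), rowSums(ch$cb^2), "+") -
        2 * domain$cb %*% t(ch$cb)
      if (!all_atom || is.null(ch$atoms)) {
        total <- total + sum(d2 < cb_cutoff^2)
      } else {
        cand <- which(d2 < 12^2, arr.ind = TRUE)
        for (r in seq_len(nrow(cand))) {
          i <- cand[r, 1L]; j <- cand[r, 2L]
          aA <- residue_atoms(domain, i)
          aB <- chain_atoms(ch, j)
          if (pair_clashes(aA$xyz, aA$element, domain$cb[i, ],
                           aB$xyz, aB$element, ch$cb[j, ],
                           overlap, cb_cutoff)) {
            total <- total + 1L
          }
        }
      }
    }
    total
  }
  moved_dom <- complex$receptor[[moved]]
  anch_dom <- complex$receptor[[setdiff(c("first", "second"), moved)]]
  list(moved = count_for(moved_dom), anchored = count_for(anch_dom))
}

#' Receptor-MHC/peptide contact pairs
#'
#' All inter-molecular residue pairs (receptor residue against MHC or
#' peptide residue) whose CB-CB distance is below `cutoff` (glycine uses its
#' CA as virtual CB), sorted by distance.
#'
#' @param complex A [pmhc_complex()].
#' @param cutoff Distance cutoff in Angstrom.
#' @return data.frame with receptor chain/residue, partner chain/residue and
#'   distance.
#' @export
contact_pairs <- function(complex, cutoff = 7.0) {
  env_chains <- mhc_peptide_chains(complex)
  rows <- list()
  for (slot in c("first", "second")) {
    d <- complex$receptor[[slot]]
    for (nm in names(env_chains)) {
      ch <- env_chains[[nm]]
      if (nrow(ch$tab) == 0L || nrow(d$tab) == 0L) next
      d2 <- outer(rowSums(d$cb^2), rowSums(ch$cb^2), "+") -
        2 * d$cb %*% t(ch$cb)
      hit <- which(d2 < cutoff^2, arr.ind = TRUE)
      if (nrow(hit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          receptor_domain = d$domain_type,
          receptor_chain = d$tab$chain[hit[, 1L]],
          receptor_resno = d$tab$resno[hit[, 1L]],
          receptor_imgt = paste0(d$tab$imgt, d$tab$imgt_ins)[hit[, 1L]],
          partner_chain = ch$tab$chain[hit[, 2L]],
          partner_resno = ch$tab$resno[hit[, 2L]],
          distance = sqrt(pmax(d2[hit], 0)),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(receptor_domain = character(), receptor_chain = character(),
                      receptor_resno = integer(), receptor_imgt = character(),
                      partner_chain = character(), partner_resno = integer(),
                      distance = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$distance), , drop = FALSE]
}
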