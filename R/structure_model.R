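# Parsing of PDB files plus IMGT-numbering sidecars into validated domain /
# receptor / complex objects, and writing transformed structures back out.
#
# A domain is stored as a list with a residue table and coordinate matrices:
#   tab   : data.frame(chain, resno, ins, imgt, imgt_ins, aa)
#   ca,cb : n x 3 matrices (cb falls back to ca when no CB atom exists,
#           e.g. glycine)
#   atoms : optional list (per residue) of data.frame(name, element, x, y, z)
#           with all heavy atoms, used for the van der Waals clash criterion
# IMGT positions are keyed as "<imgt><imgt_ins>", e.g. "104" or "111A".

DOMAIN_TYPES <- c("VH", "VL", "Vbeta", "Valpha")

# IMGT CDR definitions on the 1-128 grid
IMGT_CDR <- list(cdr1 = 27:38, cdr2 = 56:65, cdr3 = 105:117)

#' IMGT position keys of a domain
#' @param domain An `fv_domain`.
#' @return Character vector of position keys, e.g. `"104"`, `"111A"`.
#' @export
imgt_keys <- function(domain) {
  paste0(domain$tab$imgt, domain$tab$imgt_ins)
}

#' Framework position keys of a domain
#'
#' Framework positions are all occupied IMGT positions outside the three CDRs
#' (CDR1 27-38, CDR2 56-65, CDR3 105-117).
#'
#' @param domain An `fv_domain`.
#' @return Character vector of position keys.
#' @export
framework_keys <- function(domain) {
  cdr <- domain$tab$imgt %in% unlist(IMGT_CDR)
  imgt_keys(domain)[!cdr]
}

#' CDR position keys of a domain
#' @param domain An `fv_domain`.
#' @param which One of `"cdr1"`, `"cdr2"`, `"cdr3"`.
#' @return Character vector of position keys.
#' @export
cdr_keys <- function(domain, which = "cdr3") {
  rng <- IMGT_CDR[[match.arg(which, names(IMGT_CDR))]]
  imgt_keys(domain)[domain$tab$imgt %in% rng]
}

#' Construct a variable-domain object
#'
#' @param tab data.frame with columns chain, resno, ins, imgt, imgt_ins, aa.
#' @param ca,cb n x 3 coordinate matrices (Angstrom). `cb` defaults to `ca`
#'   rows for residues without a side-chain carbon.
#' @param domain_type One of `"VH"`, `"VL"`, `"Vbeta"`, `"Valpha"`.
#' @param atoms Optional per-residue list of heavy-atom tables.
#' @return An object of class `fv_domain`.
#' @export
fv_domain <- function(tab, ca, cb = NULL, domain_type, atoms = NULL) {
  domain_type <- match.arg(domain_type, DOMAIN_TYPES)
  ca <- as.matrix(ca)
  if (is.null(cb)) cb <- ca else cb <- as.matrix(cb)
  stopifnot(nrow(tab) == nrow(ca), nrow(ca) == nrow(cb), ncol(ca) == 3L)
  if (any(tab$imgt < 1L | tab$imgt > 128L)) {
    stop("IMGT positions must lie in 1..128")
  }
  keys <- paste0(tab$imgt, tab$imgt_ins)
  if (anyDuplicated(keys)) {
    stop("duplicate IMGT position(s) in domain: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  if (any(tab$imgt_ins != "" & !(tab$imgt %in% 105:117))) {
    stop("IMGT insertion codes are only allowed in the CDR3 block (105-117)")
  }
  ord <- order(tab$imgt, tab$imgt_ins)
  structure(list(tab = tab[ord, , drop = FALSE],
                 ca = ca[ord, , drop = FALSE],
                 cb = cb[ord, , drop = FALSE],
                 atoms = if (is.null(atoms)) NULL else atoms[ord],
                 domain_type = domain_type),
            class = "fv_domain")
}

#' @export
print.fv_domain <- function(x, ...) {
  cat("<fv_domain> ", x$domain_type, ": ", nrow(x$tab), " residues (chain ",
      x$tab$chain[1L], "), ", length(framework_keys(x)), " framework positions\n",
      sep = "")
  invisible(x)
}

#' Construct a paired variable fragment (Fv)
#'
#' @param first Domain on the heavy-chain side (VH or Vbeta).
#' @param second Domain on the light-chain side (VL or Valpha).
#' @param receptor_class `"antibody"` or `"tcr"`.
#' @param pdb_id Identifier string.
#' @param resolution Crystallographic resolution (Angstrom) or `NA`.
#' @return An object of class `fv_structure`.
#' @export
fv_structure <- function(first, second, receptor_class = c("antibody", "tcr"),
                         pdb_id = "none", resolution = NA_real_) {
  receptor_class <- match.arg(receptor_class)
  want <- if (receptor_class == "antibody") c("VH", "VL") else c("Vbeta", "Valpha")
  if (first$domain_type != want[1L] || second$domain_type != want[2L]) {
    stop("domain types (", first$domain_type, ", ", second$domain_type,
         ") inconsistent with receptor class ", receptor_class)
  }
  structure(list(first = first, second = second,
                 receptor_class = receptor_class,
                 pdb_id = pdb_id, resolution = resolution),
            class = "fv_structure")
}

#' @export
print.fv_structure <- function(x, ...) {
  cat("<fv_structure> ", x$pdb_id, " (", x$receptor_class, "): ",
      x$first$domain_type, " ", nrow(x$first$tab), " res / ",
      x$second$domain_type, " ", nrow(x$second$tab), " res",
      if (!is.na(x$resolution)) sprintf(", %.2f A", x$resolution), "\n",
      sep = "")
  invisible(x)
}

#' Construct a receptor-pMHC complex
#'
#' @param receptor An [fv_structure()].
#' @param mhc_chains Named list of MHC chain tables, each a list with `tab`
#'   (chain, resno, ins, aa) and `ca`, `cb` matrices (author numbering only).
#' @param peptide A single chain in the same layout, ordered N to C.
#' @param mhc_class `"I"`, `"II"` or `NULL` to infer from the chain count.
#' @return An object of class `pmhc_complex`.
#' @export
pmhc_complex <- function(receptor, mhc_chains, peptide, mhc_class = NULL) {
  stopifnot(inherits(receptor, "fv_structure"), length(mhc_chains) >= 1L)
  if (nrow(peptide$tab) < 1L) stop("peptide chain is empty")
  if (is.null(mhc_class)) {
    mhc_class <- if (length(mhc_chains) >= 2L) "II" else "I"
  }
  mhc_class <- match.arg(mhc_class, c("I", "II"))
  structure(list(receptor = receptor, mhc_chains = mhc_chains,
                 peptide = peptide, mhc_class = mhc_class),
            class = "pmhc_complex")
}

#' @export
print.pmhc_complex <- function(x, ...) {
  cat("<pmhc_complex> class ", x$mhc_class, ": receptor ",
      x$receptor$pdb_id, ", ", length(x$mhc_chains), " MHC chain(s), peptide ",
      nrow(x$peptide$tab), " residues\n", sep = "")
  invisible(x)
}

#' Read an IMGT-numbering sidecar table
#'
#' Tab-separated with columns `chain`, `author_number`, `insertion_code`,
#' `imgt_position` and optionally `imgt_insertion`. Insertion codes use `""`
#' or `"-"` for none.
#'
#' @param path File path (or a character vector of lines).
#' @return data.frame with normalised columns.
#' @export
read_numbering <- function(path) {
  if (length(path) > 1L || grepl("\n", path[1L], fixed = TRUE)) {
    path <- textConnection(paste(path, collapse = "\n"))
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", comment.char = "#")
  need <- c("chain", "author_number", "insertion_code", "imgt_position")
  if (!all(need %in% names(tab))) {
    stop("numbering sidecar must have columns: ", paste(need, collapse = ", "))
  }
  tab$author_number <- as.integer(tab$author_number)
  tab$insertion_code[tab$insertion_code %in% c("-", ".")] <- ""
  tab$imgt_position <- as.integer(tab$imgt_position)
  if (!"imgt_insertion" %in% names(tab)) tab$imgt_insertion <- ""
  tab$imgt_insertion[tab$imgt_insertion %in% c("-", ".")] <- ""
  dup <- duplicated(tab[, c("chain", "author_number", "insertion_code")]) |
    duplicated(tab[, c("chain", "imgt_position", "imgt_insertion")])
  if (any(dup)) stop("duplicate mapping in numbering sidecar")
  tab
}

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
            GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
            MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
            TYR = "Y", VAL = "V", MSE = "M")

# Parse PDB content into a per-chain/per-residue structure. `pdb` may be a
# file path or character vector of record lines. Keeps the highest-occupancy
# altloc (ties broken by altloc identifier order); HETATM ignored except MSE.
parse_pdb_chains <- function(pdb, all_atoms = FALSE) {
  if (length(pdb) == 1L && !grepl("\n", pdb, fixed = TRUE) && file.exists(pdb)) {
    pdbfile <- pdb
  } else {
    pdbfile <- tempfile(fileext = ".pdb")
    on.exit(unlink(pdbfile), add = TRUE)
    writeLines(unlist(strsplit(paste(pdb, collapse = "\n"), "\n", fixed = TRUE)),
               pdbfile)
  }
  p <- bio3d::read.pdb(pdbfile, rm.alt = FALSE, verbose = FALSE)
  at <- p$atom
  keep <- at$type == "ATOM" | (at$type == "HETATM" & at$resid == "MSE")
  at <- at[keep, , drop = FALSE]
  at$resid[at$resid == "MSE"] <- "MET"
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  # altloc resolution per (chain, resno, insert, atom name)
  if (any(at$alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
    ord <- order(key, -at$o, at$alt)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                               sep = "|")), , drop = FALSE]
    at <- at[order(at$eleno), , drop = FALSE]
  }
  rkey <- paste(at$chain, at$resno, at$insert, sep = "|")
  ridx <- match(rkey, unique(rkey))
  res <- split(seq_len(nrow(at)), ridx)
  out <- lapply(res, function(ii) {
    a <- at[ii, , drop = FALSE]
    ca <- a[a$elety == "CA", , drop = FALSE]
    cb <- a[a$elety == "CB", , drop = FALSE]
    list(chain = a$chain[1L], resno = a$resno[1L], ins = a$insert[1L],
         aa = unname(AA3TO1[a$resid[1L]]),
         ca = if (nrow(ca)) as.numeric(ca[1L, c("x", "y", "z")]) else NULL,
         cb = if (nrow(cb)) as.numeric(cb[1L, c("x", "y", "z")]) else NULL,
         atoms = if (all_atoms) {
           heavy <- a[a$elesy != "H" | is.na(a$elesy), , drop = FALSE]
           data.frame(name = heavy$elety,
                      element = ifelse(is.na(heavy$elesy) | heavy$elesy == "",
                                       substr(gsub("[0-9]", "", heavy$elety), 1, 1),
                                       heavy$elesy),
                      x = heavy$x, y = heavy$y, z = heavy$z,
                      stringsAsFactors = FALSE)
         } else NULL)
  })
  out
}

# assemble one fv_domain from parsed residues + sidecar rows for one chain
build_domain <- function(residues, map, chain, domain_type, all_atoms = FALSE,
                         min_framework = 50L) {
  map <- map[map$chain == chain, , drop = FALSE]
  chain_res <- Filter(function(r) r$chain == chain, residues)
  if (!length(chain_res)) stop("no residues found for chain ", chain)
  rk <- vapply(chain_res, function(r) paste(r$resno, r$ins, sep = "|"), "")
  mk <- paste(map$author_number, map$insertion_code, sep = "|")
  hit <- match(mk, rk)
  if (any(is.na(hit))) {
    map <- map[!is.na(hit), , drop = FALSE]
    hit <- hit[!is.na(hit)]
  }
  unmapped <- setdiff(seq_along(chain_res), hit)
  if (length(unmapped)) {
    warning(length(unmapped), " residue(s) of chain ", chain,
            " lack an IMGT mapping and were excluded from the domain")
  }
  rows <- lapply(seq_along(hit), function(i) {
    r <- chain_res[[hit[i]]]
    if (is.null(r$ca)) {
      stop("missing CA atom for mapped residue ", chain, " ", r$resno, r$ins)
    }
    r
  })
  tab <- data.frame(chain = chain,
                    resno = map$author_number, ins = map$insertion_code,
                    imgt = map$imgt_position, imgt_ins = map$imgt_insertion,
                    aa = vapply(rows, function(r) r$aa %||% "X", ""),
                    stringsAsFactors = FALSE)
  ca <- do.call(rbind, lapply(rows, function(r) r$ca))
  cb <- do.call(rbind, lapply(rows, function(r) r$cb %||% r$ca))
  atoms <- if (all_atoms) lapply(rows, function(r) r$atoms) else NULL
  dom <- fv_domain(tab, ca, cb, domain_type, atoms)
  if (length(framework_keys(dom)) < min_framework) {
    stop("chain ", chain, ": only ", length(framework_keys(dom)),
         " mapped framework positions (need >= ", min_framework, ")")
  }
  dom
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a paired variable fragment from PDB content
#'
#' Residues lacking a sidecar mapping are excluded from the domain (with a
#' warning); glycines and other residues without a CB atom take their CA
#' coordinate as the virtual CB.
#'
#' @param pdb PDB file path or character vector/string of PDB records.
#' @param numbering Sidecar table (see [read_numbering()]) or a path to one.
#' @param receptor_class `"antibody"` or `"tcr"`.
#' @param chains Length-2 character vector naming the heavy-side and
#'   light-side chains, in that order.
#' @param pdb_id,resolution Provenance fields.
#' @param all_atoms Keep all heavy atoms per residue (needed for the van der
#'   Waals clash criterion); otherwise only CA/CB are retained.
#' @param min_framework Minimum mapped framework positions per domain; a
#'   domain below this is a hard error. The default suits complete variable
#'   domains; lower it for deliberately truncated fixtures.
#' @return An [fv_structure()].
#' @export
read_fv_structure <- function(pdb, numbering, receptor_class = c("antibody", "tcr"),
                              chains, pdb_id = "none", resolution = NA_real_,
                              all_atoms = FALSE, min_framework = 50L) {
  receptor_class <- match.arg(receptor_class)
  if (is.character(numbering)) numbering <- read_numbering(numbering)
  stopifnot(length(chains) == 2L)
  residues <- parse_pdb_chains(pdb, all_atoms = all_atoms)
  types <- if (receptor_class == "antibody") c("VH", "VL") else c("Vbeta", "Valpha")
  first <- build_domain(residues, numbering, chains[1L], types[1L], all_atoms,
                        min_framework)
  second <- build_domain(residues, numbering, chains[2L], types[2L], all_atoms,
                         min_framework)
  fv_structure(first, second, receptor_class, pdb_id, resolution)
}

# plain chain (MHC / peptide): author numbering only
build_plain_chain <- function(residues, chain) {
  chain_res <- Filter(function(r) r$chain == chain, residues)
  if (!length(chain_res)) stop("no residues found for chain ", chain)
  tab <- data.frame(chain = chain,
                    resno = vapply(chain_res, function(r) r$resno, 0L),
                    ins = vapply(chain_res, function(r) r$ins, ""),
                    aa = vapply(chain_res, function(r) r$aa %||% "X", ""),
                    stringsAsFactors = FALSE)
  ca <- do.call(rbind, lapply(chain_res, function(r) r$ca %||% r$cb))
  cb <- do.call(rbind, lapply(chain_res, function(r) r$cb %||% r$ca))
  list(tab = tab, ca = ca, cb = cb)
}

#' Read a receptor-pMHC complex from PDB content
#'
#' @param pdb PDB file path or character content.
#' @param numbering Sidecar table or path (receptor chains only).
#' @param chain_roles Named character vector mapping chain id to one of
#'   `"receptor1"` (VH/Vbeta side), `"receptor2"` (VL/Valpha side), `"mhc"`,
#'   `"peptide"`.
#' @param receptor_class `"antibody"` or `"tcr"`.
#' @param mhc_class Optional override; inferred from the MHC chain count
#'   (one chain = class I, two = class II) when `NULL`.
#' @param pdb_id,resolution Provenance fields.
#' @param all_atoms Keep all heavy atoms per residue.
#' @param min_framework Passed to [read_fv_structure()].
#' @return A [pmhc_complex()].
#' @export
read_pmhc_complex <- function(pdb, numbering, chain_roles,
                              receptor_class = c("tcr", "antibody"),
                              mhc_class = NULL, pdb_id = "none",
                              resolution = NA_real_, all_atoms = FALSE,
                              min_framework = 50L) {
  receptor_class <- match.arg(receptor_class)
  if (is.character(numbering)) numbering <- read_numbering(numbering)
  roles <- chain_roles
  if (!any(roles == "peptide")) stop("chain_roles must name a peptide chain")
  if (!any(roles == "mhc")) stop("chain_roles must name at least one MHC chain")
  if (sum(roles == "receptor1") != 1L || sum(roles == "receptor2") != 1L) {
    stop("chain_roles must name exactly one receptor1 and one receptor2 chain")
  }
  residues <- parse_pdb_chains(pdb, all_atoms = all_atoms)
  receptor <- read_fv_structure(pdb, numbering, receptor_class,
                                chains = c(names(roles)[roles == "receptor1"],
                                           names(roles)[roles == "receptor2"]),
                                pdb_id = pdb_id, resolution = resolution,
                                all_atoms = all_atoms,
                                min_framework = min_framework)
  mhc <- lapply(names(roles)[roles == "mhc"], function(ch) {
    build_plain_chain(residues, ch)
  })
  names(mhc) <- names(roles)[roles == "mhc"]
  pep <- build_plain_chain(residues, names(roles)[roles == "peptide"][1L])
  pmhc_complex(receptor, mhc, pep, mhc_class)
}

# ---- writing -----------------------------------------------------------

# flatten a structure into parallel atom-record vectors for bio3d::write.pdb
flatten_for_pdb <- function(x) {
  recs <- list()
  add_domain <- function(d) {
    n <- nrow(d$tab)
    aa3 <- names(AA3TO1)[match(d$tab$aa, AA3TO1)]
    aa3[is.na(aa3)] <- "UNK"
    if (!is.null(d$atoms)) {
      for (i in seq_len(n)) {
        a <- d$atoms[[i]]
        recs[[length(recs) + 1L]] <<- data.frame(
          elety = a$name, resid = aa3[i], chain = d$tab$chain[i],
          resno = d$tab$resno[i], insert = d$tab$ins[i],
          x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
      }
    } else {
      has_cb <- rowSums((d$ca - d$cb)^2) > 1e-12
      recs[[length(recs) + 1L]] <<- data.frame(
        elety = "CA", resid = aa3, chain = d$tab$chain, resno = d$tab$resno,
        insert = d$tab$ins, x = d$ca[, 1], y = d$ca[, 2], z = d$ca[, 3],
        stringsAsFactors = FALSE)
      cbrec <- data.frame(
        elety = "CB", resid = aa3, chain = d$tab$chain, resno = d$tab$resno,
        insert = d$tab$ins, x = d$cb[, 1], y = d$cb[, 2], z = d$cb[, 3],
        stringsAsFactors = FALSE)[has_cb, , drop = FALSE]
      recs[[length(recs) + 1L]] <<- cbrec
    }
  }
  if (inherits(x, "fv_structure")) {
    add_domain(x$first); add_domain(x$second)
  } else if (inherits(x, "pmhc_complex")) {
    add_domain(x$receptor$first); add_domain(x$receptor$second)
    for (m in x$mhc_chains) add_domain(list(tab = m$tab, ca = m$ca, cb = m$cb,
                                            atoms = NULL))
    add_domain(list(tab = x$peptide$tab, ca = x$peptide$ca, cb = x$peptide$cb,
                    atoms = NULL))
  } else if (inherits(x, "fv_domain")) {
    add_domain(x)
  } else stop("cannot write object of class ", class(x)[1L])
  at <- do.call(rbind, recs)
  # stable within-residue ordering: CA before CB before side chain
  at
}

#' Write a structure as PDB
#'
#' Writes an `fv_domain`, `fv_structure` or `pmhc_complex` to PDB format,
#' preserving chain identifiers and author numbering.
#'
#' @param x Structure object.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_pdb <- function(x, file) {
  at <- flatten_for_pdb(x)
  xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  n <- nrow(at)
  bio3d::write.pdb(file = file, xyz = xyz, resno = at$resno, resid = at$resid,
                   chain = at$chain, insert = ifelse(at$insert == "", NA,
                                                    at$insert),
                   elety = at$elety, o = rep(1, n), b = rep(0, n),
                   verbose = FALSE)
  invisible(file)
}

#' Numbering sidecar for a structure
#'
#' Builds the tab-separated IMGT sidecar table corresponding to a structure's
#' receptor domains, suitable for [read_fv_structure()] round trips.
#'
#' @param x An `fv_structure` or `pmhc_complex`.
#' @return data.frame in sidecar layout.
#' @export
numbering_table <- function(x) {
  if (inherits(x, "pmhc_complex")) x <- x$receptor
  stopifnot(inherits(x, "fv_structure"))
  one <- function(d) data.frame(chain = d$tab$chain,
                                author_number = d$tab$resno,
                                insertion_code = ifelse(d$tab$ins == "", "-",
                                                        d$tab$ins),
                                imgt_position = d$tab$imgt,
                                imgt_insertion = ifelse(d$tab$imgt_ins == "",
                                                        "-", d$tab$imgt_ins),
                                stringsAsFactors = FALSE)
  rbind(one(x$first), one(x$second))
}

#' Write a numbering sidecar TSV
#' @param x An `fv_structure` or `pmhc_complex`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_numbering <- function(x, file) {
  utils::write.table(numbering_table(x), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

# Ca coordinates of a domain at given position keys (order preserved)
domain_ca_at <- function(domain, keys) {
  idx <- match(keys, imgt_keys(domain))
  if (anyNA(idx)) stop("positions absent from domain: ",
                       paste(keys[is.na(idx)], collapse = ", "))
  domain$ca[idx, , drop = FALSE]
}

# apply a rigid transform to every coordinate of a domain
transform_domain <- function(domain, tr) {
  domain$ca <- apply_transform(domain$ca, tr)
  domain$cb <- apply_transform(domain$cb, tr)
  if (!is.null(domain$atoms)) {
    domain$atoms <- lapply(domain$atoms, function(a) {
      xyz <- apply_transform(as.matrix(a[, c("x", "y", "z")]), tr)
      a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
      a
    })
  }
  domain
}

transform_plain_chain <- function(chain, tr) {
  chain$ca <- apply_transform(chain$ca, tr)
  chain$cb <- apply_transform(chain$cb, tr)
  chain
}

transform_fv <- function(fv, tr) {
  fv$first <- transform_domain(fv$first, tr)
  fv$second <- transform_domain(fv$second, tr)
  fv
}
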