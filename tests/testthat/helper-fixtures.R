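# Fixture builders: hand-written PDB text and tiny in-memory structures.

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          altloc = "", icode = "", occ = 1, b = 0,
                          element = substr(name, 1L, 1L), record = "ATOM") {
  name_field <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name_field, altloc, resname, chain, resno, icode,
          x, y, z, occ, b, element)
}

# a residue as CA (+ optional CB) records; returns lines
pdb_residue <- function(serial, resname, chain, resno, ca, cb = NULL, ...) {
  lines <- pdb_atom_line(serial, "CA", resname, chain, resno,
                         ca[1], ca[2], ca[3], ...)
  if (!is.null(cb)) {
    lines <- c(lines, pdb_atom_line(serial + 1L, "CB", resname, chain, resno,
                                    cb[1], cb[2], cb[3], ...))
  }
  lines
}

sidecar_text <- function(rows) {
  c("chain\tauthor_number\tinsertion_code\timgt_position\timgt_insertion",
    vapply(rows, function(r) paste(r, collapse = "\t"), ""))
}

# 6-residue two-chain fixture: 3 residues per chain, one glycine without CB
tiny_fv_fixture <- function() {
  lines <- c(
    pdb_residue(1L, "ALA", "H", 1L, c(0, 0, 0), c(0.5, 0.5, 1)),
    pdb_residue(3L, "GLY", "H", 2L, c(3.8, 0, 0)),                 # no CB
    pdb_residue(4L, "CYS", "H", 3L, c(7.6, 1, 0), c(8, 1.5, 1.2)),
    pdb_residue(6L, "LEU", "L", 1L, c(0, 10, 0), c(0.5, 10.5, 1)),
    pdb_residue(8L, "PHE", "L", 2L, c(3.8, 10, 0), c(4.2, 10.4, 1.1)),
    pdb_residue(10L, "CYS", "L", 3L, c(7.6, 11, 0), c(8, 11.5, 1.2)),
    "END")
  numbering <- sidecar_text(list(
    c("H", 1, "-", 1, "-"), c("H", 2, "-", 2, "-"), c("H", 3, "-", 104, "-"),
    c("L", 1, "-", 1, "-"), c("L", 2, "-", 2, "-"), c("L", 3, "-", 104, "-")))
  list(pdb = lines, numbering = numbering)
}

# small pmhc with all-atom residues for the vdW clash criterion:
# one-residue domains placed a controlled distance from a one-residue "MHC"
atom_residue <- function(names, elements, xyz) {
  data.frame(name = names, element = elements,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

# minimal all-atom pmhc: receptor first-domain residue(s) at given atom sets
clash_fixture <- function(domain_atoms, env_atoms) {
  ndom <- length(domain_atoms)
  dom_tab <- data.frame(chain = "B", resno = seq_len(ndom), ins = "",
                        imgt = seq_len(ndom), imgt_ins = "",
                        aa = "A", stringsAsFactors = FALSE)
  dom_ca <- t(vapply(domain_atoms, function(a) {
    as.numeric(a[1L, c("x", "y", "z")])
  }, numeric(3)))
  dom <- fv_domain(dom_tab, dom_ca, dom_ca, "Vbeta", atoms = domain_atoms)
  far_tab <- data.frame(chain = "A", resno = 1L, ins = "", imgt = 1L,
                        imgt_ins = "", aa = "A", stringsAsFactors = FALSE)
  far <- fv_domain(far_tab, matrix(c(500, 500, 500), 1L), NULL, "Valpha")
  fv <- fv_structure(dom, far, "tcr", pdb_id = "clashfix")
  nenv <- length(env_atoms)
  env_tab <- data.frame(chain = "M", resno = seq_len(nenv), ins = "",
                        aa = "A", stringsAsFactors = FALSE)
  env_ca <- t(vapply(env_atoms, function(a) {
    as.numeric(a[1L, c("x", "y", "z")])
  }, numeric(3)))
  mhc <- list(tab = env_tab, ca = env_ca, cb = env_ca, atoms = env_atoms)
  pep <- list(tab = data.frame(chain = "P", resno = 1L, ins = "", aa = "G",
                               stringsAsFactors = FALSE),
              ca = matrix(c(900, 900, 900), 1L),
              cb = matrix(c(900, 900, 900), 1L))
  pmhc_complex(fv, list(M = mhc), pep, mhc_class = "I")
}

# an fv_domain with a prescribed set of IMGT positions on a rough grid
grid_domain <- function(positions, domain_type = "Vbeta", chain = "B",
                        aa = NULL, shift = c(0, 0, 0)) {
  n <- length(positions)
  if (is.null(aa)) aa <- rep("A", n)
  ca <- cbind(3.8 * seq_len(n) + 0.31 * sin(positions),
              4.8 * (positions %% 7) + 0.2 * cos(positions),
              2.1 * (positions %% 3) + 0.15 * sin(2 * positions))
  ca <- sweep(ca, 2L, -shift)
  tab <- data.frame(chain = chain, resno = seq_len(n), ins = "",
                    imgt = positions, imgt_ins = "", aa = aa,
                    stringsAsFactors = FALSE)
  fv_domain(tab, ca, ca + 1.0, domain_type)
}

# sequence matrix from explicit column lists: list("50" = c("L","L","F"), ...)
seq_matrix <- function(cols, n = NULL) {
  if (is.null(n)) n <- max(vapply(cols, length, 0L))
  m <- matrix(NA_character_, n, length(cols),
              dimnames = list(NULL, names(cols)))
  for (k in names(cols)) m[seq_along(cols[[k]]), k] <- cols[[k]]
  m
}

# serialize a numbering_table() data frame back to sidecar TSV lines
numbering_to_text <- function(tab) {
  c(paste(names(tab), collapse = "\t"),
    vapply(seq_len(nrow(tab)), function(i) {
      paste(unlist(tab[i, ], use.names = FALSE), collapse = "\t")
    }, ""))
}
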