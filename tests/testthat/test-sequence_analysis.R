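test_that("column conservation applies the 50 percent rule with tie handling", {
  m <- seq_matrix(list("10" = c("L", "L", "L", "F", "F"),
                       "11" = c("L", "F", "A", "G", "S"),
                       "12" = c("L", "L", "F", "F", NA)))
  c10 <- column_conservation(m, "10")
  expect_equal(c10$residue, "L")
  expect_equal(c10$frequency, 0.6)
  expect_equal(c10$n_observed, 5L)

  expect_true(is.na(column_conservation(m, "11")$residue))

  expect_warning(c12 <- column_conservation(m, "12"), "ambiguous")
  expect_true(is.na(c12$residue))
  expect_equal(c12$flag, "ambiguous")

  c99 <- column_conservation(m, "99")
  expect_equal(c99$flag, "zero-coverage")
  expect_true(is.na(c99$residue))

  # strict mode: exactly 50 percent no longer qualifies
  m2 <- seq_matrix(list("5" = c("W", "W", "A", "G")))
  expect_equal(column_conservation(m2, "5", strict = FALSE)$residue, "W")
  expect_true(is.na(column_conservation(m2, "5", strict = TRUE)$residue))
})

test_that("conservation decisions are invariant to sequence order", {
  set.seed(123)
  cols <- list("7" = sample(c(rep("L", 6), rep("F", 4))),
               "8" = sample(c(rep("Y", 5), rep("W", 5))))
  m <- seq_matrix(cols)
  for (perm in 1:5) {
    mp <- m[sample(nrow(m)), , drop = FALSE]
    expect_equal(suppressWarnings(column_conservation(mp, "7")$residue),
                 suppressWarnings(column_conservation(m, "7")$residue))
    expect_equal(suppressWarnings(column_conservation(mp, "8")$flag),
                 suppressWarnings(column_conservation(m, "8")$flag))
  }
})

test_that("equivalence support attributes positions to the right pairing", {
  # position 10: VH and Valpha conserve A, VL conserves G
  #   -> evidence for the VH-Valpha/VL-Vbeta alternative
  vh <- seq_matrix(list("10" = rep("A", 4), "11" = rep("T", 4)))
  va <- seq_matrix(list("10" = rep("A", 4), "11" = rep("T", 4)))
  vl <- seq_matrix(list("10" = rep("G", 4), "11" = rep("T", 4)))
  vb <- seq_matrix(list("10" = rep("G", 4), "11" = rep("T", 4)))
  es <- equivalence_support(vh, vl, vb, va)
  expect_equal(unname(es$support["VH_Valpha_VL_Vbeta"]), 1L)
  expect_equal(es$positions$VH_Valpha_VL_Vbeta, "10")
  expect_equal(unname(es$support["VH_Vbeta_VL_Valpha"]), 0L)

  # mirrored pattern: VH and Vbeta share S, VL conserves K
  vh2 <- seq_matrix(list("20" = rep("S", 4)))
  vb2 <- seq_matrix(list("20" = rep("S", 4)))
  vl2 <- seq_matrix(list("20" = rep("K", 4)))
  va2 <- seq_matrix(list("20" = rep("K", 4)))
  es2 <- equivalence_support(vh2, vl2, vb2, va2)
  expect_equal(unname(es2$support["VH_Vbeta_VL_Valpha"]), 1L)

  # same residue conserved everywhere, or nothing conserved: both tallies 0
  same <- seq_matrix(list("1" = rep("C", 4)))
  es3 <- equivalence_support(same, same, same, same)
  expect_equal(unname(es3$support), c(0L, 0L))
  none <- seq_matrix(list("1" = c("A", "C", "D", "E")))
  es4 <- equivalence_support(none, none, none, none)
  expect_equal(unname(es4$support), c(0L, 0L))
})

test_that("divergent interface positions follow the conservation and 2 percent rules", {
  # position 103: A conserves Y at 80 percent with F at 5 percent background;
  # B conserves F at 62 percent -> listed and compatible
  a103 <- c(rep("Y", 80), rep("F", 5), rep("S", 15))
  b103 <- c(rep("F", 62), rep("Y", 38))
  # position 52: both conserve W -> not listed
  a52 <- rep("W", 100); b52 <- c(rep("W", 70), rep("L", 30))
  # position 60: A conserves W (95), B conserves L (72), L at 0.5 percent in A
  a60 <- c(rep("W", 190), "L", rep("S", 9))
  b60 <- c(rep("L", 72), rep("W", 28))
  setA <- seq_matrix(list("103" = a103, "52" = a52, "60" = a60))
  setB <- seq_matrix(list("103" = b103, "52" = b52, "60" = b60))
  div <- divergent_interface_positions(setA, setB, c("103", "52", "60"))
  expect_setequal(div$position, c("103", "60"))
  r103 <- div[div$position == "103", ]
  expect_equal(r103$residue_A, "Y"); expect_equal(r103$percent_A, 80)
  expect_equal(r103$residue_B, "F"); expect_equal(r103$percent_B, 62)
  expect_true(r103$compatible)
  r60 <- div[div$position == "60", ]
  expect_false(r60$compatible)

  # role swap lists the same positions with A/B columns exchanged
  div2 <- divergent_interface_positions(setB, setA, c("103", "52", "60"))
  expect_setequal(div2$position, div$position)
  expect_equal(div2[div2$position == "103", "residue_A"], "F")
})

test_that("divergence tallies equal a brute-force recount on random profiles", {
  set.seed(321)
  aas <- c("A", "L", "S", "Y")
  for (trial in 1:100) {
    pos <- as.character(1:6)
    setA <- matrix(sample(aas, 60, TRUE), 10, 6, dimnames = list(NULL, pos))
    setB <- matrix(sample(aas, 60, TRUE), 10, 6, dimnames = list(NULL, pos))
    div <- divergent_interface_positions(setA, setB, pos,
                                         compat_threshold = 0.2)
    brute <- 0L
    for (p in pos) {
      ta <- sort(table(setA[, p]), decreasing = TRUE)
      tb <- sort(table(setB[, p]), decreasing = TRUE)
      if (ta[1L] / 10 > 0.5 && tb[1L] / 10 > 0.5 &&
          sum(ta == ta[1L]) == 1L && sum(tb == tb[1L]) == 1L &&
          names(ta)[1L] != names(tb)[1L]) {
        brute <- brute + 1L
      }
    }
    expect_equal(nrow(div), brute)
  }
})

test_that("CDR3 lengths reflect the IMGT 105-117 block", {
  # scaffold loop lengths: VL 9, VH 12, Valpha 13
  vls <- lapply(1:4, function(i) scaffold_domain("VL", "L"))
  expect_equal(cdr3_length_distribution(vls)$mode, 9L)
  mixed <- c(lapply(1:1, function(i) scaffold_domain("VH", "H")),
             lapply(1:2, function(i) scaffold_domain("Valpha", "A")))
  dist <- cdr3_length_distribution(mixed)   # lengths 12, 13, 13
  expect_equal(dist$mode, 13L)
  expect_equal(unname(dist$lengths), c(12L, 13L, 13L))
  # brute-force recount of mapped positions
  brute <- vapply(mixed, function(d) {
    sum(d$tab$imgt >= 105L & d$tab$imgt <= 117L)
  }, 0L)
  expect_equal(unname(dist$lengths), brute)
  # a domain without CDR3 residues counts as length 0 with a warning
  bare <- grid_domain(c(1:45, 66:104), "Vbeta", "B")
  expect_warning(d0 <- cdr3_length_distribution(list(bare)), "zero CDR3")
  expect_equal(unname(d0$lengths), 0L)
})

test_that("the greedy redundancy filter keeps the better-resolved representative", {
  dom <- function(aa_seed, type, chain) {
    positions <- c(1:26, 39:55, 66:104, 118:128)
    set.seed(aa_seed)
    grid_domain(positions, type, chain,
                aa = sample(c("A", "L", "S", "Y", "G"), length(positions),
                            TRUE))
  }
  mk <- function(seedH, seedL, id, res) {
    fv_structure(dom(seedH, "Vbeta", "B"), dom(seedL, "Valpha", "A"),
                 "tcr", pdb_id = id, resolution = res)
  }
  # identical sequences, different resolution: the 1.8 A structure wins
  x1 <- mk(1, 2, "xaa", 2.6); x2 <- mk(1, 2, "xbb", 1.8)
  kept <- filter_redundant(list(x1, x2), 0.90)
  expect_equal(length(kept), 1L)
  expect_equal(kept[[1L]]$pdb_id, "xbb")
  # identity below the threshold: both retained
  y <- mk(3, 4, "ycc", 2.0)
  expect_equal(length(filter_redundant(list(x1, y), 0.90)), 2L)
})

test_that("greedy filtering equals a brute-force oracle and ignores input order", {
  positions <- c(1:26, 39:55, 66:104, 118:128)
  set.seed(77)
  pool <- lapply(1:10, function(i) {
    base <- sample(c("A", "L"), length(positions), TRUE)
    if (i > 5L) {  # five structures are mutations of the first five
      parent <- i - 5L
      set.seed(1000 + parent)
      base <- sample(c("A", "L"), length(positions), TRUE)
      base[1:3] <- "S"
    }
    fv_structure(grid_domain(positions, "Vbeta", "B", aa = base),
                 grid_domain(positions, "Valpha", "A", aa = rev(base)),
                 "tcr", pdb_id = sprintf("s%02d", i),
                 resolution = 1.5 + 0.1 * i)
  })
  thr <- 0.9
  kept <- filter_redundant(pool, thr)
  m <- fv_sequence_matrix(pool)
  want <- oracle_greedy_filter(m, vapply(pool, `[[`, 0, "resolution"),
                               vapply(pool, `[[`, "", "pdb_id"), thr)
  expect_equal(vapply(kept, `[[`, "", "pdb_id"), want)
  # input order must not matter
  set.seed(5)
  shuffled <- pool[sample(10)]
  kept2 <- filter_redundant(shuffled, thr)
  expect_setequal(vapply(kept2, `[[`, "", "pdb_id"),
                  vapply(kept, `[[`, "", "pdb_id"))
})

test_that("IMGT FASTA round trip preserves the position grid", {
  fam <- make_pose_family(pose_spec(), spread = 2, n = 3, seed = 9)
  m <- imgt_sequence_matrix(lapply(fam, function(f) f$first),
                            ids = c("a", "b", "c"))
  fa <- withr::local_tempfile(fileext = ".fasta")
  lines <- unlist(lapply(rownames(m), function(id) {
    keys <- colnames(m)[!is.na(m[id, ])]
    c(sprintf(">%s imgt=%s", id, paste(keys, collapse = ",")),
      paste(m[id, keys], collapse = ""))
  }))
  writeLines(lines, fa)
  back <- read_imgt_fasta(fa)
  expect_equal(back[, colnames(m)], m)
})
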