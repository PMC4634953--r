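match_rows <- function(peptides, starts, scores) {
  data.frame(peptide = peptides, score = scores, ref_start = starts,
             stringsAsFactors = FALSE)
}

test_that("consensus assembly fills covered sites and leaves X elsewhere", {
  cs <- assemble_consensus(match_rows(c("GPA", "GPR"), c(0, 5), c(60, 60)), 8)
  expect_equal(as.character(cs), "GPAXXGPR")
  expect_equal(cs$support, c(1, 1, 1, 0, 0, 1, 1, 1))
  empty <- assemble_consensus(match_rows(character(0), integer(0),
                                         numeric(0)), 5)
  expect_equal(as.character(empty), "XXXXX")
})

test_that("conflicting residue calls resolve by summed score, ties to X", {
  m <- match_rows(c("A", "A", "S"), c(0, 0, 0), c(50, 30, 30))
  cs <- suppressWarnings(assemble_consensus(m, 1))
  expect_equal(cs$seq, "A")
  expect_equal(attr(cs, "conflicts"), 1L)
  tie <- match_rows(c("A", "S"), c(0, 0), c(40, 40))
  expect_warning(cs2 <- assemble_consensus(tie, 1), "conflict")
  expect_equal(cs2$seq, "X")
})

test_that("non-X sites equal the union of peptide coverage", {
  set.seed(61)
  for (rep in 1:10) {
    n <- 60
    k <- sample(3:8, 1)
    starts <- sample(0:(n - 8), k, replace = TRUE)
    peps <- vapply(starts, function(s)
      paste(rep("G", sample(4:8, 1)), collapse = ""), character(1))
    m <- match_rows(peps, starts, runif(k, 40, 80))
    m <- m[m$ref_start + nchar(m$peptide) <= n, , drop = FALSE]
    cs <- assemble_consensus(m, n)
    cov <- collagenphylo:::covered_positions(
      data.frame(peptide = m$peptide, ref_start = m$ref_start), n)
    expect_identical(which(cs$seq != "X") - 1L, cov)
    expect_equal(100 * sum(cs$seq != "X") / n,
                 coverage_percent(data.frame(peptide = m$peptide,
                                             ref_start = m$ref_start,
                                             is_decoy = FALSE), n))
  }
})

test_that("isobaric I/L harmonisation replaces fossil calls by abundance", {
  aln <- rbind(ref1 = c("L", "G"), ref2 = c("L", "G"), ref3 = c("L", "G"),
               ref4 = c("I", "G"), fossil = c("I", "L"))
  out <- normalize_isobaric(aln, proteomic = "fossil")
  expect_equal(unname(out["fossil", 1]), "L")     # L:3 vs I:2 after inclusion
  expect_equal(unname(out["ref4", 1]), "I")       # references never altered
  expect_equal(unname(out["fossil", 2]), "L")     # single-letter column unchanged
  ## exact tie keeps the observed letter and is logged
  tie <- rbind(ref1 = "I", fossil = "L")
  out2 <- normalize_isobaric(tie, proteomic = "fossil")
  expect_equal(unname(out2["fossil", 1]), "L")
  expect_equal(attr(out2, "isobaric_ties"), 1L)
})

test_that("chain concatenation inserts the R linker and checks the taxon", {
  a1 <- consensus_seq("sloth", rep("X", 1056))
  a2 <- consensus_seq("sloth", rep("X", 1041))
  cc <- concatenate_chains(a1, a2)
  expect_equal(length(cc$seq), 2098)
  expect_equal(cc$seq[1057], "R")
  expect_true(all(cc$seq[-1057] == "X"))
  empty <- concatenate_chains(consensus_seq("t", c("G", "A")),
                              consensus_seq("t", character(0)))
  expect_equal(as.character(empty), "GAR")
  expect_error(concatenate_chains(a1, consensus_seq("other", "G")),
               "taxon mismatch")
})

test_that("variation counts skip undetermined sites and are symmetric", {
  expect_equal(count_variations("AAGR", "ACGK"), 2)
  expect_equal(count_variations("AXG", "ACG"), 0)
  expect_equal(count_variations("A?G-", "ACGG"), 0)
  expect_equal(count_variations("GPAG", "GPAG"), 0)
  expect_error(count_variations("AA", "AAA"), "lengths differ")
  set.seed(71)
  for (rep in 1:10) {
    a <- sample(c("A", "G", "S", "X", "-"), 30, replace = TRUE)
    b <- sample(c("A", "G", "S", "X", "?"), 30, replace = TRUE)
    expect_equal(count_variations(a, b), count_variations(b, a))
    expect_equal(count_variations(a, a), 0)
  }
})

test_that("isobaric harmonisation never increases pairwise variation", {
  set.seed(81)
  for (rep in 1:10) {
    n <- 40
    aln <- rbind(ref1 = sample(c("I", "L", "G", "A"), n, replace = TRUE),
                 ref2 = sample(c("I", "L", "G", "A"), n, replace = TRUE),
                 fos1 = sample(c("I", "L", "G", "X"), n, replace = TRUE),
                 fos2 = sample(c("I", "L", "G", "X"), n, replace = TRUE))
    out <- normalize_isobaric(aln, proteomic = c("fos1", "fos2"))
    for (i in 1:3) for (j in (i + 1):4)
      expect_lte(count_variations(out[i, ], out[j, ]),
                 count_variations(aln[i, ], aln[j, ]))
  }
})

test_that("replicate-confirmed differences require agreement of both specimens", {
  expect_equal(count_confirmed_variations("A", "A", "G"), 1)
  expect_equal(count_confirmed_variations("A", "X", "G"), 0)
  expect_equal(count_confirmed_variations("A", "S", "G"), 0)
  expect_equal(count_confirmed_variations("A", "A", "X"), 0)
  ## confirmed count never exceeds the single-consensus count when the
  ## consensus is restricted to replicated calls
  set.seed(91)
  for (rep in 1:10) {
    n <- 50
    s1 <- sample(c("A", "G", "S", "X"), n, replace = TRUE)
    s2 <- sample(c("A", "G", "S", "X"), n, replace = TRUE)
    other <- sample(c("A", "G", "S"), n, replace = TRUE)
    cons <- ifelse(s1 == s2, s1, "X")   # intersection-supported consensus
    expect_lte(count_confirmed_variations(s1, s2, other),
               count_variations(cons, other))
  }
})
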