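## helpers to build PSM rows concisely
psm_rows <- function(scores, decoy = FALSE, specimen = "sp1",
                     peptide = "GPAGPR", chain = "COL1A1", start = 0L) {
  data.frame(peptide = peptide, modifications = "", score = scores,
             specimen_id = specimen, chain_id = chain, ref_start = start,
             is_decoy = decoy, stringsAsFactors = FALSE)
}

test_that("HFPS is the decoy maximum and requires decoys", {
  psms <- rbind(psm_rows(c(12, 27, 19), decoy = TRUE),
                psm_rows(c(50, 60)))
  expect_equal(hfps(psms), 27)
  expect_equal(hfps(psm_rows(43, decoy = TRUE)), 43)
  expect_error(hfps(psm_rows(c(50, 60))), "decoy")
})

test_that("HFPS filtering keeps strictly greater target scores only", {
  psms <- rbind(psm_rows(c(25, 27, 27.1, 43.2)),
                psm_rows(27, decoy = TRUE))
  kept <- filter_by_hfps(psms, 27)
  expect_equal(kept$score, c(27.1, 43.2))
  expect_true(all(!kept$is_decoy))
  expect_equal(nrow(filter_by_hfps(psms[0, ], 27)), 0L)
  expect_warning(filter_by_hfps(psm_rows(c(10, 20)), 27), "no target")
  ## property: exhaustively, every retained score exceeds the threshold
  set.seed(21)
  for (rep in 1:10) {
    p <- rbind(psm_rows(runif(50, 0, 80)),
               psm_rows(runif(10, 0, 40), decoy = TRUE))
    thr <- hfps(p)
    out <- suppressWarnings(filter_by_hfps(p, thr))
    expect_true(all(out$score > thr))
    expect_true(!any(out$is_decoy))
  }
})

test_that("FDR is 100 * decoys / targets", {
  expect_equal(fdr_percent(rbind(psm_rows(rep(1, 100)),
                                 psm_rows(rep(1, 2), decoy = TRUE))), 2)
  expect_equal(fdr_percent(psm_rows(rep(1, 50))), 0)
  expect_equal(fdr_percent(rbind(psm_rows(rep(1, 98)),
                                 psm_rows(rep(1, 3), decoy = TRUE))),
               100 * 3 / 98)
  expect_error(fdr_percent(psm_rows(1, decoy = TRUE)), "no target")
})

test_that("replicate intersection keys on sequence+chain+position", {
  a <- rbind(psm_rows(60, specimen = "sp1", peptide = "GPAGPR", start = 10),
             psm_rows(55, specimen = "sp1", peptide = "GDRGEK", start = 55))
  b <- psm_rows(40, specimen = "sp2", peptide = "GPAGPR", start = 10)
  out <- replicate_intersection(a, b)
  expect_setequal(unique(out$peptide), "GPAGPR")
  expect_equal(attr(out, "keys"), "GPAGPR|COL1A1|10")
  ## disjoint sets
  expect_equal(nrow(replicate_intersection(
    psm_rows(60, specimen = "sp1", peptide = "GPAGPR"),
    psm_rows(60, specimen = "sp2", peptide = "GDRGEK"))), 0L)
  ## same peptide at a different position is excluded under seq+pos ...
  b2 <- psm_rows(40, specimen = "sp2", peptide = "GPAGPR", start = 13)
  expect_equal(nrow(replicate_intersection(a, b2)), 0L)
  ## ... but kept under the sequence-only key
  expect_gt(nrow(replicate_intersection(a, b2, key = "seq")), 0L)
  ## identical specimen ids are not replicates
  expect_error(replicate_intersection(a, a), "replicate")
})

test_that("replicate intersection is symmetric and a subset of each input", {
  set.seed(31)
  peps <- c("GPAGPR", "GDRGEK", "AAKGER", "GLPGER", "GFPGGR")
  for (rep in 1:10) {
    a <- psm_rows(runif(6, 30, 80), specimen = "sp1",
                  peptide = sample(peps, 6, replace = TRUE),
                  start = sample(c(0, 10, 20), 6, replace = TRUE))
    b <- psm_rows(runif(6, 30, 80), specimen = "sp2",
                  peptide = sample(peps, 6, replace = TRUE),
                  start = sample(c(0, 10, 20), 6, replace = TRUE))
    kab <- sort(attr(replicate_intersection(a, b), "keys"))
    kba <- sort(attr(replicate_intersection(b, a), "keys"))
    expect_identical(kab, kba)
    expect_true(all(kab %in% collagenphylo:::psm_key(a, "seq+pos")))
    expect_true(all(kab %in% collagenphylo:::psm_key(b, "seq+pos")))
  }
})

test_that("coverage is the union of covered positions over the reference", {
  p1 <- psm_rows(60, peptide = paste(rep("G", 10), collapse = ""), start = 0)
  expect_equal(coverage_percent(p1, 20), 50)
  p2 <- rbind(p1, psm_rows(60, peptide = paste(rep("G", 10), collapse = ""),
                           start = 5))
  expect_equal(coverage_percent(p2, 20), 75)
  expect_equal(coverage_percent(p1[0, ], 20), 0)
  expect_error(coverage_percent(p1, 5), "past the reference")
  ## monotone under adding peptides, bounded in [0, 100]
  set.seed(41)
  cov_prev <- 0
  acc <- p1[0, ]
  for (i in 1:15) {
    len <- sample(3:12, 1)
    acc <- rbind(acc, psm_rows(50, peptide = paste(rep("G", len), collapse = ""),
                               start = sample(0:(100 - len), 1)))
    cov <- coverage_percent(acc, 100)
    expect_gte(cov, cov_prev)
    expect_lte(cov, 100)
    cov_prev <- cov
  }
})

test_that("filter_report summarises an analysis like a target-decoy QC table", {
  set.seed(51)
  psms <- degrade_to_specimens(paste(sample(names(AA_MONO_MASS), 300,
                                            replace = TRUE), collapse = ""),
                               simulation_config(seed = 5), taxon = "fossilA",
                               chain_id = "COL1A1", coverage = c(0.7, 0.7))
  sp1 <- psms[psms$specimen_id == "fossilA_sp1", ]
  rep1 <- filter_report(sp1, c(COL1A1 = 300))
  expect_equal(rep1$hfps, max(sp1$score[sp1$is_decoy]))
  expect_equal(rep1$fdr_percent, 100 * sum(sp1$is_decoy) / sum(!sp1$is_decoy))
  expect_lte(rep1$n_unique_sequences, rep1$n_matches)
  expect_gte(rep1$coverage_COL1A1, 0)
  expect_lte(rep1$coverage_COL1A1, 100)
  expect_equal(rep1$coverage_combined, rep1$coverage_COL1A1)
})

test_that("PSM tables round-trip through TSV", {
  psms <- rbind(psm_rows(c(60.5, 44), peptide = "GPAGPR"),
                psm_rows(12, decoy = TRUE, peptide = "RPGAPG"))
  psms$modifications <- c("hydroxylation:1", "", "deamidation:1")
  f <- tempfile(fileext = ".tsv")
  write_psm_table(psms, f)
  back <- read_psm_table(f)
  expect_equal(back$score, psms$score)
  expect_equal(back$modifications, psms$modifications)
  expect_equal(back$is_decoy, psms$is_decoy)
})
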