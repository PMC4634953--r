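small_config <- function(seed = 1, ...) {
  simulation_config(n_taxa = 5, chain_lengths = c(COL1A1 = 120L,
                                                  COL1A2 = 100L),
                    seed = seed, ...)
}

test_that("simulation is deterministic given the master seed", {
  s1 <- simulate_alignment(small_config(seed = 11))
  s2 <- simulate_alignment(small_config(seed = 11))
  s3 <- simulate_alignment(small_config(seed = 12))
  expect_identical(s1$concat, s2$concat)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  expect_false(identical(s1$concat, s3$concat))
  ## concatenation structure: chains joined via a constant R column
  expect_equal(ncol(s1$concat), 120 + 1 + 100)
  expect_true(all(s1$concat[, 121] == "R"))
})

test_that("zero-length branches copy the parent sequence", {
  tree <- ape::read.tree(text = "((A:0,B:0):0.1,(C:0.1,D:0.1):0.05);")
  cfg <- simulation_config(n_taxa = 4, tree = tree,
                           chain_lengths = c(a = 200L, b = 100L), seed = 3)
  sim <- simulate_alignment(cfg)
  expect_identical(sim$concat["A", ], sim$concat["B", ])
  expect_false(identical(sim$concat["A", ], sim$concat["C", ]))
})

test_that("very long branches draw children from the stationary distribution", {
  tree <- ape::read.tree(text = "(A:0.0001,B:20);")
  cfg <- simulation_config(n_taxa = 2, tree = tree, p_inv = 0,
                           chain_lengths = c(a = 3000L, b = 2999L), seed = 5)
  sim <- simulate_alignment(cfg)
  ## composition of the far tip is compatible with the JTT frequencies
  counts <- table(factor(sim$chains[[1]]["B", ],
                         levels = names(AA_MONO_MASS)))
  p <- chisq.test(as.vector(counts), p = sim$model$freq)$p.value
  expect_gt(p, 0.001)
})

test_that("degradation hits the target coverage and yields weak decoys", {
  cfg <- small_config(seed = 21)
  sim <- simulate_alignment(cfg)
  chain <- sim$chains$COL1A1["taxon_02", ]
  psms <- degrade_to_specimens(chain, cfg, taxon = "taxon_02",
                               chain_id = "COL1A1", coverage = c(1, 1),
                               seed = 77)
  ## full coverage, decoys excluded: consensus reconstructs the truth
  sp1 <- psms[psms$specimen_id == "taxon_02_sp1" & !psms$is_decoy, ]
  cs <- assemble_consensus(sp1, length(chain), "taxon_02")
  expect_identical(cs$seq, unname(chain))
  ## decoy bulk sits far below the target bulk
  expect_lt(mean(psms$score[psms$is_decoy]),
            mean(psms$score[!psms$is_decoy]))
  ## PSM table is well-formed and positions in range
  expect_true(all(psms$ref_start + nchar(psms$peptide) <= length(chain)))
  expect_true(all(psms$score >= 0))
})

test_that("PTM annotations on degraded PSMs are consistent with composition", {
  cfg <- small_config(seed = 23)
  sim <- simulate_alignment(cfg)
  psms <- degrade_to_specimens(sim$chains$COL1A1["taxon_03", ], cfg,
                               taxon = "taxon_03", chain_id = "COL1A1",
                               seed = 31)
  tgt <- psms[!psms$is_decoy, ]
  for (i in seq_len(min(40, nrow(tgt)))) {
    counts <- parse_modifications(tgt$modifications[i])
    ch <- strsplit(tgt$peptide[i], "")[[1]]
    if ("carbamidomethyl" %in% names(counts))
      expect_equal(unname(counts["carbamidomethyl"]), sum(ch == "C"))
    if ("hydroxylation" %in% names(counts))
      expect_lte(counts["hydroxylation"], sum(ch %in% c("K", "P")))
    if ("deamidation" %in% names(counts))
      expect_lte(counts["deamidation"], sum(ch %in% c("N", "Q")))
    ## mass arithmetic accepts every emitted modification state
    expect_gt(peptide_mass(tgt$peptide[i], tgt$modifications[i]), 0)
  }
})

test_that("simulated fingerprints are deterministic and trace the peptides", {
  cfg <- small_config(seed = 25)
  sim <- simulate_alignment(cfg)
  seq1 <- sim$concat["taxon_01", ]
  p1 <- simulate_pmf(seq1, cfg, seed = 9)
  p2 <- simulate_pmf(seq1, cfg, seed = 9)
  expect_identical(p1$mz, p2$mz)
  ## zero noise: every peak is a theoretical singly protonated peptide
  cfg0 <- small_config(seed = 25, maldi_noise_peaks = 0L)
  p0 <- simulate_pmf(seq1, cfg0, seed = 9)
  theo <- mz_from_mass(digest_table(paste(seq1, collapse = ""), 1)$mass, 1)
  expect_true(all(vapply(p0$mz, function(x)
    any(abs(theo - x) < 5e-4), logical(1))))
  ## a substitution inside one tryptic peptide shifts only related peaks
  seq2 <- seq1
  seq2[10] <- setdiff(c("F", "G"), seq1[10])[1]
  p3 <- simulate_pmf(seq2, cfg0, seed = 9)
  expect_false(identical(p0$mz, p3$mz))
  shared_all <- shared_peak_count(p0, p3, tol = 1e-4)
  expect_gt(shared_all, 0.7 * min(nrow(p0), nrow(p3)))
})

test_that("coverage masking hits the requested determined fraction", {
  set.seed(61)
  s <- sample(names(AA_MONO_MASS), 2098, replace = TRUE)
  for (cov in c(0.9, 0.6, 0.3)) {
    masked <- mask_to_coverage(s, cov, seed = 5)
    expect_equal(mean(masked != "X"), cov, tolerance = 0.01)
  }
  expect_identical(mask_to_coverage(s, 1, seed = 5), s)
})
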