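## simulate a pair of sequences separated by a known distance
simulate_pair <- function(t, nsites, model, seed) {
  set.seed(seed)
  a <- sample.int(20, nsites, replace = TRUE, prob = model$freq)
  rates <- collagenphylo:::effective_rates(model)
  cls <- ifelse(runif(nsites) < model$p_inv, 0L,
                sample.int(model$k, nsites, replace = TRUE))
  b <- a
  for (cc in seq_len(model$k)) {
    P <- transition_matrix(model, t, rates[cc])
    idx <- which(cls == cc)
    for (s in idx) b[s] <- sample.int(20, 1, prob = P[a[s], ])
  }
  aa <- names(AA_MONO_MASS)
  matrix(aa[c(a, b)], nrow = 2, byrow = TRUE,
         dimnames = list(c("A", "B"), NULL))
}

test_that("branch-length optimization recovers a known divergence", {
  m <- jtt_model(p_inv = 0.2, alpha = 0.5)
  aln <- simulate_pair(0.3, 10000, m, seed = 201)
  tree <- ape::read.tree(text = "(A:0.05,B:0.05);")
  fit <- optimize_branch_lengths(tree, aln, m)
  expect_equal(sum(fit$edge.length), 0.3, tolerance = 0.1)
  ## identical sequences drive the path length to the lower bound
  same <- rbind(A = aln[1, ], B = aln[1, ])
  fit0 <- optimize_branch_lengths(tree, same, m)
  expect_lt(sum(fit0$edge.length), 1e-5)
})

test_that("branch optimization never decreases the likelihood", {
  set.seed(211)
  cfg <- simulation_config(n_taxa = 6, chain_lengths = c(A = 150L, B = 120L),
                           seed = 31)
  sim <- simulate_alignment(cfg)
  m <- sim$model
  start <- sim$tree
  start$edge.length <- rep(0.02, nrow(start$edge))   # deliberately wrong
  ll_prev <- as.numeric(log_likelihood(start, sim$concat, m))
  for (sweeps in 1:3) {
    fit <- optimize_branch_lengths(start, sim$concat, m,
                                   max_sweeps = sweeps)
    ll <- attr(fit, "loglik")
    expect_gte(ll + 1e-9, ll_prev)
    ## cached-message objective agrees with a fresh pruning pass
    expect_equal(ll, as.numeric(log_likelihood(fit, sim$concat, m)),
                 tolerance = 1e-6)
    ll_prev <- ll
  }
})

test_that("model-parameter fitting improves the likelihood and respects bounds", {
  cfg <- simulation_config(n_taxa = 8, chain_lengths = c(A = 600L, B = 500L),
                           alpha = 0.5, p_inv = 0.2, tree_depth = 0.5,
                           seed = 37)
  sim <- simulate_alignment(cfg)
  m0 <- jtt_model(p_inv = 0.05, alpha = 2)
  ll0 <- as.numeric(log_likelihood(sim$tree, sim$concat, m0))
  fit <- optimize_model_params(sim$tree, sim$concat, m0)
  expect_gte(fit$loglik, ll0)
  expect_gte(fit$model$alpha, 0.05); expect_lte(fit$model$alpha, 20)
  expect_gte(fit$model$p_inv, 0);    expect_lte(fit$model$p_inv, 0.8)
})

test_that("NNI search recovers the true 4-taxon topology from a wrong start", {
  cfg <- simulation_config(n_taxa = 4, chain_lengths = c(A = 800L, B = 700L),
                           tree_depth = 0.3, seed = 41)
  sim <- simulate_alignment(cfg)
  truth <- ape::unroot(sim$tree)
  ## build a deliberately wrong topology by swapping two non-sister tips
  wrong <- NULL
  for (j in 2:4) {
    cand <- truth
    i <- match(c("taxon_01", sprintf("taxon_%02d", j)), cand$tip.label)
    cand$tip.label[i] <- cand$tip.label[rev(i)]
    if (rf_distance(cand, truth) > 0) { wrong <- cand; break }
  }
  expect_gt(rf_distance(wrong, truth), 0)
  found <- nni_search(wrong, sim$concat, sim$model)
  expect_equal(rf_distance(found, truth), 0)
  ## starting at the optimum accepts no swap
  again <- nni_search(found, sim$concat, sim$model)
  expect_equal(rf_distance(again, found), 0)
  ## fewer than four taxa: input returned unchanged
  tri <- ape::read.tree(text = "(A:0.1,B:0.1,C:0.1);")
  alntri <- sim$concat[1:3, ]; rownames(alntri) <- c("A", "B", "C")
  expect_equal(rf_distance(nni_search(tri, alntri, sim$model), tri), 0)
})

test_that("NNI reaches the global optimum over all 15 five-taxon topologies", {
  cfg <- simulation_config(n_taxa = 5, chain_lengths = c(A = 700L, B = 600L),
                           tree_depth = 0.3, seed = 43)
  sim <- simulate_alignment(cfg)
  m <- sim$model
  all15 <- phangorn::allTrees(5, tip.label = sim$tree$tip.label)
  lls <- vapply(all15, function(tr) {
    tr$edge.length <- rep(0.05, nrow(tr$edge))
    attr(optimize_branch_lengths(tr, sim$concat, m), "loglik")
  }, numeric(1))
  found <- nni_search(NULL, sim$concat, m)
  expect_equal(attr(found, "loglik"), max(lls), tolerance = 1e-3)
  expect_equal(rf_distance(found, all15[[which.max(lls)]]), 0)
})

test_that("bootstrap supports are reproducible, bounded and strong on clear splits", {
  cfg <- simulation_config(n_taxa = 4, chain_lengths = c(A = 800L, B = 700L),
                           tree_depth = 0.3, seed = 47)
  sim <- simulate_alignment(cfg)
  fit <- ml_tree_search(sim$concat, optimize_model = FALSE,
                        model = sim$model)
  bt1 <- bootstrap_support(sim$concat, sim$model, n_reps = 5, seed = 7,
                           ml_tree = fit$tree)
  bt2 <- bootstrap_support(sim$concat, sim$model, n_reps = 5, seed = 7,
                           ml_tree = fit$tree)
  expect_identical(bt1$node.label, bt2$node.label)
  sup <- as.numeric(bt1$node.label)
  expect_true(all(sup >= 0 & sup <= 100))
  ## one strong split on strongly informative data: full support
  inner <- setdiff(seq_len(bt1$Nnode) + 4L, 5L)  # non-root internal node
  expect_equal(min(sup[inner - 4L]), 100)
})

test_that("outgroup rooting splits the pendant edge and preserves structure", {
  cfg <- simulation_config(n_taxa = 6, chain_lengths = c(A = 100L, B = 80L),
                           seed = 53)
  sim <- simulate_alignment(cfg)
  un <- ape::unroot(sim$tree)
  rooted <- root_at_outgroup(un, sim$outgroup)
  root <- length(rooted$tip.label) + 1L
  kids <- rooted$edge[rooted$edge[, 1] == root, 2]
  og_idx <- match(sim$outgroup, rooted$tip.label)
  expect_true(og_idx %in% kids)
  ## the two root edges are the halves of the original pendant edge
  ce <- rooted$edge.length[rooted$edge[, 1] == root]
  expect_equal(ce[1], ce[2], tolerance = 1e-12)
  og_edge <- un$edge.length[un$edge[, 2] == match(sim$outgroup, un$tip.label)]
  expect_equal(sum(ce), og_edge, tolerance = 1e-12)
  ## rooting/unrooting leaves the bipartition set unchanged
  expect_equal(rf_distance(rooted, un), 0)
  expect_error(root_at_outgroup(un, "nope"), "not among")
})

test_that("NJ starting trees handle missing data and tiny trees", {
  cfg <- simulation_config(n_taxa = 6, chain_lengths = c(A = 200L, B = 150L),
                           seed = 59)
  sim <- simulate_alignment(cfg)
  aln <- sim$concat
  aln[2, 1:250] <- "X"
  tr <- nj_start_tree(aln)
  expect_setequal(tr$tip.label, rownames(aln))
  expect_true(all(tr$edge.length >= 0))
  expect_error(nj_start_tree(aln[1:2, ]), "at least 3")
})
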