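# Independent oracles used by the tests (and by scripts/acceptance.R,
# which sources this file): a brute-force tree-likelihood that sums over
# all internal-node state assignments, and a tiny random-instance
# generator for property-style checks.

# Brute-force log-likelihood by exhaustive enumeration of internal-node
# states. Missing tips (NA codes) contribute a factor of 1 because P rows
# sum to one; everything else is an explicit sum over 20^n_internal
# assignments, so this shares no code path with the pruning algorithm.
oracle_loglik <- function(tree, aln, model) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  inner <- (ntip + 1L):(ntip + tree$Nnode)
  codes <- collagenphylo:::encode_alignment(
    aln[tree$tip.label, , drop = FALSE])
  k <- model$k
  rates <- model$rates / (1 - model$p_inv)
  grid <- as.matrix(expand.grid(rep(list(1:20), length(inner))))
  root <- ntip + 1L
  nsites <- ncol(codes)
  total <- 0
  for (s in seq_len(nsites)) {
    obs <- codes[, s]
    Lc <- numeric(k)
    for (cc in seq_len(k)) {
      f <- model$freq[grid[, match(root, inner)]]
      for (e in seq_len(nrow(tree$edge))) {
        p <- tree$edge[e, 1L]; v <- tree$edge[e, 2L]
        P <- transition_matrix(model, tree$edge.length[e], rates[cc])
        pstate <- grid[, match(p, inner)]
        if (v <= ntip) {
          if (!is.na(obs[v])) f <- f * P[cbind(pstate, obs[v])]
          # missing tip: sum_j P[a, j] = 1, no factor
        } else {
          f <- f * P[cbind(pstate, grid[, match(v, inner)])]
        }
      }
      Lc[cc] <- sum(f)
    }
    d <- unique(obs[!is.na(obs)])
    const_pi <- if (length(d) == 0L) 1 else if (length(d) == 1L)
      model$freq[d] else 0
    L <- model$p_inv * const_pi + (1 - model$p_inv) * mean(Lc)
    total <- total + log(L)
  }
  total
}

# Random tiny instance: tree with 2..max_taxa tips, 1..max_sites sites,
# random branch lengths, random model parameters, residues drawn from the
# stationary frequencies with a sprinkling of missing symbols.
random_tiny_instance <- function(max_taxa = 5L, max_sites = 4L,
                                 missing_prob = 0.2) {
  ntaxa <- sample(2:max_taxa, 1)
  nsites <- sample(1:max_sites, 1)
  tree <- ape::rtree(ntaxa, rooted = ntaxa < 4L,
                     br = function(n) stats::runif(n, 0.01, 1.5))
  model <- jtt_model(p_inv = stats::runif(1, 0, 0.5),
                     alpha = stats::runif(1, 0.2, 2),
                     k = sample(1:4, 1))
  aa <- c(names(AA_MONO_MASS))
  aln <- matrix(sample(aa, ntaxa * nsites, replace = TRUE,
                       prob = model$freq),
                nrow = ntaxa,
                dimnames = list(tree$tip.label, NULL))
  miss <- matrix(stats::runif(ntaxa * nsites) < missing_prob, nrow = ntaxa)
  aln[miss] <- sample(c("X", "?", "-"), sum(miss), replace = TRUE)
  list(tree = tree, aln = aln, model = model)
}

# Numerical-integration oracle for discrete-gamma bin means: conditional
# mean of Gamma(alpha, alpha) within each equal-probability bin, by
# adaptive quadrature.
quadrature_gamma_rates <- function(alpha, k) {
  b <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = alpha,
                     rate = alpha)
  vapply(seq_len(k), function(i) {
    stats::integrate(function(x) x * stats::dgamma(x, alpha, alpha),
                     b[i], b[i + 1], rel.tol = 1e-10)$value * k
  }, numeric(1))
}
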