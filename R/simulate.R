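## Seeded synthetic-data generator: ground-truth trees, collagen-like
## two-chain alignments, degraded duplicate-specimen PSM tables and MALDI
## peak lists with the statistical structure the analysis pipeline
## assumes.

#' Simulation configuration
#'
#' Defaults describe the study conditions the pipeline targets: two
#' collagen chains of 1056 and 1041 aligned residues (concatenated length
#' 2098), per-specimen sequence coverage drawn uniformly from 56-77%, two
#' specimens per fossil taxon, Mascot-like target and decoy score
#' distributions with the decoy bulk well below the targets, collagen PTM
#' rates, and a 700-3700 m/z MALDI window.
#'
#' @param n_taxa Number of taxa on the simulated tree.
#' @param tree Optional fixed \code{phylo} tree (Yule-generated when NULL).
#' @param tree_depth Root-to-tip height in expected substitutions/site
#'   used to scale a generated tree (0.08: collagen-like mammalian
#'   divergence).
#' @param chain_lengths Named lengths of the two chains.
#' @param alpha,p_inv Rate-heterogeneity truth used for simulation.
#' @param n_fossil_taxa Taxa degraded to fossil-style partial data.
#' @param specimens_per_fossil Duplicate specimens per fossil taxon.
#' @param coverage_range Per-specimen target coverage (uniform draw).
#' @param score_target_mean,score_target_sd Target PSM score model.
#' @param score_decoy_mean,score_decoy_sd Decoy PSM score model.
#' @param fdr_target Decoy:target ratio used to size the decoy set.
#' @param hydroxylation_rate Per-eligible-residue K/P hydroxylation
#'   probability.
#' @param deamidation_rate Per-eligible-residue N/Q deamidation
#'   probability.
#' @param maldi_noise_peaks Number of uniform-random noise peaks added to
#'   each fingerprint.
#' @param instrument_range MALDI m/z window.
#' @param seed Master seed; all randomness flows from it.
#' @return A \code{sim_config} list.
#' @export
simulation_config <- function(n_taxa = 8L,
                              tree = NULL,
                              tree_depth = 0.08,
                              chain_lengths = c(COL1A1 = 1056L, COL1A2 = 1041L),
                              alpha = 0.5,
                              p_inv = 0.2,
                              n_fossil_taxa = 2L,
                              specimens_per_fossil = 2L,
                              coverage_range = c(0.56, 0.77),
                              score_target_mean = 60, score_target_sd = 15,
                              score_decoy_mean = 15, score_decoy_sd = 6,
                              fdr_target = 0.02,
                              hydroxylation_rate = 0.4,
                              deamidation_rate = 0.3,
                              maldi_noise_peaks = 25L,
                              instrument_range = c(700, 3700),
                              seed = 1L) {
  stopifnot(length(chain_lengths) == 2L, all(chain_lengths > 0),
            score_decoy_mean < score_target_mean,
            all(coverage_range > 0), all(coverage_range <= 1))
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

## derive a reproducible sub-seed from the master seed (kept < 2^31)
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

## tip of the smaller root clade: a natural outgroup for the simulation
basal_tip <- function(tree) {
  root <- length(tree$tip.label) + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  sizes <- vapply(kids, function(n) {
    if (n <= length(tree$tip.label)) 1L
    else length(ape::extract.clade(tree, n)$tip.label)
  }, integer(1))
  side <- kids[which.min(sizes)]
  if (side <= length(tree$tip.label)) tree$tip.label[side]
  else ape::extract.clade(tree, side)$tip.label[1]
}

## evolve one chain of `nsites` sites down the tree; returns char matrix
evolve_chain <- function(tree, nsites, model, config) {
  pi <- model$freq
  eff <- effective_rates(model)
  rate_class <- ifelse(stats::runif(nsites) < model$p_inv, 0L,
                       sample.int(model$k, nsites, replace = TRUE))
  site_rate <- ifelse(rate_class == 0L, 0, eff[pmax(rate_class, 1L)])
  tree <- ape::reorder.phylo(tree, "cladewise")
  nnode <- length(tree$tip.label) + tree$Nnode
  states <- matrix(NA_integer_, nnode, nsites)
  root <- length(tree$tip.label) + 1L
  states[root, ] <- sample.int(20L, nsites, replace = TRUE, prob = pi)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; v <- tree$edge[e, 2L]
    t <- tree$edge.length[e]
    child <- states[p, ]
    for (r in unique(site_rate)) {
      if (r == 0 || t == 0) next
      P <- transition_matrix(model, t, r)
      idx <- which(site_rate == r)
      for (a in unique(states[p, idx])) {
        ia <- idx[states[p, idx] == a]
        child[ia] <- sample.int(20L, length(ia), replace = TRUE,
                                prob = P[a, ])
      }
    }
    states[v, ] <- child
  }
  tipstates <- states[seq_along(tree$tip.label), , drop = FALSE]
  m <- matrix(AA20[tipstates], nrow = nrow(tipstates),
              dimnames = list(tree$tip.label, NULL))
  m
}

#' Simulate a true tree and two-chain collagen alignment
#'
#' Samples the root sequence from the stationary frequencies and evolves
#' it along the (given or Yule-generated) tree under JTT + I + G, using
#' per-site invariant/gamma rate assignment. Deterministic given the
#' configuration seed.
#'
#' @param config A [simulation_config()].
#' @return List of class \code{collagen_sim}: \code{tree} (true rooted
#'   tree), \code{chains} (list of per-chain character matrices),
#'   \code{concat} (chains joined via an R column; 2098 columns at the
#'   default lengths), \code{outgroup}, \code{model}, \code{config}.
#' @export
simulate_alignment <- function(config = simulation_config()) {
  set.seed(sub_seed(config$seed, 1L))
  model <- jtt_model(p_inv = config$p_inv, alpha = config$alpha)
  tree <- config$tree
  if (is.null(tree)) {
    tree <- ape::rphylo(config$n_taxa, birth = 1, death = 0)
    tree$tip.label <- sprintf("taxon_%02d", seq_len(config$n_taxa))
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length * config$tree_depth / depth
  }
  chains <- lapply(config$chain_lengths, function(n)
    evolve_chain(tree, n, model, config))
  names(chains) <- names(config$chain_lengths)
  concat <- cbind(chains[[1]],
                  matrix("R", nrow(chains[[1]]), 1),
                  chains[[2]])
  colnames(concat) <- NULL
  structure(list(tree = tree, chains = chains, concat = concat,
                 outgroup = basal_tip(tree), model = model,
                 config = config),
            class = "collagen_sim")
}

## retention probability giving the requested expected union coverage
calibrate_retention <- function(cover_counts, target) {
  if (target >= 1) return(1)
  f <- function(p) mean(1 - (1 - p)^cover_counts) - target
  stats::uniroot(f, c(1e-9, 1 - 1e-9), tol = 1e-9)$root
}

## random PTM state and score for retained peptides
decorate_psms <- function(peptides, config, specimen_id, chain_id,
                          decoy = FALSE) {
  n <- nrow(peptides)
  if (n == 0L)
    return(stats::setNames(data.frame(matrix(ncol = length(PSM_COLUMNS),
                                             nrow = 0)), PSM_COLUMNS))
  mods <- character(n)
  for (i in seq_len(n)) {
    ch <- strsplit(peptides$peptide[i], "")[[1]]
    counts <- c(
      carbamidomethyl = sum(ch == "C"),
      hydroxylation = stats::rbinom(1, sum(ch %in% c("K", "P")),
                                    config$hydroxylation_rate),
      deamidation = stats::rbinom(1, sum(ch %in% c("N", "Q")),
                                  config$deamidation_rate))
    mods[i] <- format_modifications(counts)
  }
  score <- if (decoy)
    pmax(0.1, stats::rnorm(n, config$score_decoy_mean, config$score_decoy_sd))
  else
    pmax(1, stats::rnorm(n, config$score_target_mean, config$score_target_sd))
  data.frame(peptide = peptides$peptide, modifications = mods,
             score = score, specimen_id = specimen_id, chain_id = chain_id,
             ref_start = peptides$start, is_decoy = decoy,
             stringsAsFactors = FALSE)
}

#' Degrade a true chain sequence into duplicate-specimen PSM tables
#'
#' Digests the chain (trypsin/P, up to two missed cleavages), retains each
#' peptide by an independent Bernoulli draw whose probability is
#' calibrated so the expected union coverage matches the specimen's
#' target, decorates retained peptides with PTM states and Mascot-like
#' target scores, and adds reversed-sequence decoy PSMs with the (weaker)
#' decoy score model. Specimens are drawn independently.
#'
#' @param sequence Chain sequence (string or character vector) for one
#'   taxon; no indels.
#' @param config A [simulation_config()].
#' @param taxon Taxon label used to derive specimen ids.
#' @param chain_id Chain label recorded in the PSM table.
#' @param coverage Optional numeric vector of per-specimen coverage
#'   targets (defaults drawn from \code{config$coverage_range}).
#' @param seed Seed (defaults derived from the config master seed).
#' @return PSM data.frame for all specimens (targets + decoys).
#' @export
degrade_to_specimens <- function(sequence, config = simulation_config(),
                                 taxon = "fossil", chain_id = "COL1A1",
                                 coverage = NULL, seed = NULL) {
  if (is.null(seed)) seed <- sub_seed(config$seed, 100L)
  set.seed(seed)
  seqstr <- paste(as_residue_vector(sequence), collapse = "")
  dig <- tryptic_digest(seqstr, max_missed = 2L)
  nres <- nchar(seqstr)
  cover_counts <- integer(nres)
  for (i in seq_len(nrow(dig)))
    cover_counts[(dig$start[i] + 1L):dig$end[i]] <-
      cover_counts[(dig$start[i] + 1L):dig$end[i]] + 1L
  rev_dig <- tryptic_digest(paste(rev(strsplit(seqstr, "")[[1]]),
                                  collapse = ""), max_missed = 2L)
  out <- list()
  for (s in seq_len(config$specimens_per_fossil)) {
    target <- if (!is.null(coverage)) coverage[s]
              else stats::runif(1, config$coverage_range[1],
                                config$coverage_range[2])
    p <- calibrate_retention(cover_counts, target)
    keep <- stats::runif(nrow(dig)) < p
    tgt <- decorate_psms(dig[keep, , drop = FALSE], config,
                         specimen_id = sprintf("%s_sp%d", taxon, s),
                         chain_id = chain_id)
    n_dec <- max(3L, round(config$fdr_target * nrow(tgt)))
    di <- sample.int(nrow(rev_dig), min(n_dec, nrow(rev_dig)))
    dec <- decorate_psms(rev_dig[di, , drop = FALSE], config,
                         specimen_id = sprintf("%s_sp%d", taxon, s),
                         chain_id = chain_id, decoy = TRUE)
    out[[s]] <- rbind(tgt, dec)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Simulate a MALDI peptide-mass fingerprint
#'
#' Peptides (trypsin/P, up to one missed cleavage) whose singly protonated
#' monoisotopic m/z falls inside the instrument window become peaks with
#' log-normal intensities; a configurable number of uniform-random noise
#' peaks is added. PTMs are not applied, so identical sequences give
#' identical peak m/z sets.
#'
#' @param sequence Protein sequence (string or character vector).
#' @param config A [simulation_config()].
#' @param seed Seed for intensities and noise (defaults derived from the
#'   config master seed).
#' @return A \code{peaklist}.
#' @export
simulate_pmf <- function(sequence, config = simulation_config(),
                         seed = NULL) {
  if (is.null(seed)) seed <- sub_seed(config$seed, 200L)
  set.seed(seed)
  seqstr <- paste(as_residue_vector(sequence), collapse = "")
  dig <- tryptic_digest(seqstr, max_missed = 1L)
  mz <- mz_from_mass(vapply(dig$peptide, peptide_mass, numeric(1),
                            USE.NAMES = FALSE), 1L)
  mz <- sort(unique(round(mz, 4)))
  mz <- mz[mz >= config$instrument_range[1] & mz <= config$instrument_range[2]]
  int <- stats::rlnorm(length(mz), meanlog = log(1000), sdlog = 1)
  n_noise <- config$maldi_noise_peaks
  if (n_noise > 0L) {
    mz <- c(mz, stats::runif(n_noise, config$instrument_range[1],
                             config$instrument_range[2]))
    int <- c(int, stats::rlnorm(n_noise, meanlog = log(100), sdlog = 0.7))
  }
  peaklist(mz, int, config$instrument_range)
}

#' Mask a sequence down to a target coverage with X blocks
#'
#' Replaces random contiguous blocks (geometric lengths, mean
#' \code{mean_block}) with \code{X} until the determined fraction reaches
#' the target coverage. Emulates the patchy site recovery of ancient
#' protein sequencing.
#'
#' @param sequence String or character vector.
#' @param coverage Target determined fraction in (0, 1].
#' @param seed Integer seed.
#' @param mean_block Mean masked-block length in residues.
#' @return Character vector with X at masked sites.
#' @export
mask_to_coverage <- function(sequence, coverage, seed = 1L,
                             mean_block = 25) {
  stopifnot(coverage > 0, coverage <= 1)
  set.seed(seed)
  s <- as_residue_vector(sequence)
  n <- length(s)
  target_masked <- round((1 - coverage) * n)
  masked <- logical(n)
  while (sum(masked) < target_masked) {
    len <- 1L + stats::rgeom(1, 1 / mean_block)
    start <- sample.int(n, 1)
    idx <- start:min(n, start + len - 1L)
    masked[idx] <- TRUE
  }
  extra <- sum(masked) - target_masked
  if (extra > 0) {                       # trim overshoot deterministically
    on <- which(masked)
    masked[on[seq_len(extra)]] <- FALSE
  }
  s[masked] <- "X"
  s
}
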