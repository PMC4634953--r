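## End-to-end orchestration: synthetic dataset emission, and the full
## filter -> intersect -> assemble -> normalize -> concatenate -> compare
## -> ML tree pipeline with a reproducible run manifest.

stage_msg <- function(...) message("[collagenphylo] ", ...)

write_manifest <- function(out_dir, config, seed, timings, files) {
  manifest <- list(
    package = "collagenphylo",
    version = as.character(utils::packageVersion("collagenphylo")),
    seed = seed,
    config = unclass(config),
    stage_seconds = timings,
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Emit a complete synthetic dataset to a directory
#'
#' Simulates the true tree and alignment, degrades the fossil taxa into
#' duplicate-specimen PSM tables, simulates MALDI fingerprints for every
#' taxon, and writes everything in the pipeline's input formats (Newick,
#' FASTA, TSV, two-column peak lists) together with a run manifest
#' carrying content digests.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the simulation object and file paths.
#' @export
run_simulate <- function(config = simulation_config(), out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir)
  t0 <- proc.time()[["elapsed"]]
  sim <- simulate_alignment(config)
  fossil <- setdiff(sim$tree$tip.label, sim$outgroup)[
    seq_len(config$n_fossil_taxa)]
  files <- character(0)
  f <- file.path(out_dir, "true_tree.nwk")
  ape::write.tree(sim$tree, f); files <- c(files, f)
  f <- file.path(out_dir, "alignment_concat.fasta")
  write_alignment_fasta(sim$concat, f); files <- c(files, f)
  for (ch in names(sim$chains)) {
    f <- file.path(out_dir, sprintf("alignment_%s.fasta", ch))
    write_alignment_fasta(sim$chains[[ch]], f); files <- c(files, f)
  }
  for (i in seq_along(fossil)) {
    tax <- fossil[i]
    psms <- do.call(rbind, lapply(seq_along(sim$chains), function(j) {
      degrade_to_specimens(sim$chains[[j]][tax, ], config, taxon = tax,
                           chain_id = names(sim$chains)[j],
                           seed = sub_seed(config$seed, 100L + 10L * i + j))
    }))
    f <- file.path(out_dir, sprintf("psms_%s.tsv", tax))
    write_psm_table(psms, f); files <- c(files, f)
  }
  for (tax in sim$tree$tip.label) {
    pl <- simulate_pmf(sim$concat[tax, ], config,
                       seed = sub_seed(config$seed,
                                       200L + match(tax, sim$tree$tip.label)))
    f <- file.path(out_dir, sprintf("pmf_%s.txt", tax))
    write_peaklist(pl, f); files <- c(files, f)
  }
  timings <- list(simulate = proc.time()[["elapsed"]] - t0)
  cfg <- config; cfg$tree <- NULL     # trees are written, not serialised
  mf <- write_manifest(out_dir, cfg, config$seed, timings, files)
  stage_msg("synthetic dataset written to ", out_dir,
            " (", length(files), " files)")
  invisible(list(sim = sim, fossil_taxa = fossil,
                 files = c(files, mf), out_dir = out_dir))
}

#' Run the full analysis pipeline
#'
#' Reproduces the analysis order of the collagen palaeoproteomic workflow:
#' per-specimen HFPS filtering with a target-decoy quality report,
#' intersection of duplicate specimens per fossil taxon, per-chain
#' consensus assembly, isobaric I/L harmonisation against the reference
#' alignment, chain concatenation, pairwise variation and MALDI
#' shared-peak matrices, and a JTT + I + G maximum-likelihood tree with
#' bootstrap support rooted at the configured outgroup.
#'
#' @param psm_tables Named list (fossil taxon -> PSM data.frame or TSV
#'   path) holding both specimens and both chains per taxon.
#' @param peaklists Named list (taxon -> \code{peaklist} or file path);
#'   optional (NULL skips the fingerprint comparison).
#' @param reference_chains Named list of per-chain character matrices (or
#'   FASTA paths) of database-derived reference taxa, e.g.
#'   \code{list(COL1A1 = ..., COL1A2 = ...)}.
#' @param outgroup Tip label used to root the final tree.
#' @param chain_mode \code{"concat"} (both chains joined via R) or
#'   \code{"a2-only"} (alpha-2 block alone).
#' @param isobaric Apply I/L harmonisation (default TRUE).
#' @param intersect_key Identity key for the both-specimens rule
#'   (\code{"seq+pos"} or \code{"seq"}).
#' @param bootstrap_reps Bootstrap replicates (0 to skip).
#' @param top_n,tolerance_da Fingerprint comparison parameters.
#' @param seed Seed for the stochastic steps (bootstrap).
#' @param out_dir Optional output directory for the report bundle.
#' @return List of class \code{collagen_run}: \code{filter_reports},
#'   \code{consensus} (per-taxon concatenated \code{consensus_seq}),
#'   \code{alignment} (references + fossil consensus), \code{variations},
#'   \code{confirmed}, \code{shared_peaks}, \code{tree} (rooted, with
#'   support), \code{model}, \code{loglik}.
#' @export
run_full <- function(psm_tables, peaklists = NULL, reference_chains,
                     outgroup, chain_mode = c("concat", "a2-only"),
                     isobaric = TRUE, intersect_key = c("seq+pos", "seq"),
                     bootstrap_reps = 100L, top_n = 100L,
                     tolerance_da = 0.2, seed = 1L, out_dir = NULL) {
  chain_mode <- match.arg(chain_mode)
  intersect_key <- match.arg(intersect_key)
  timings <- list()
  tick <- function() proc.time()[["elapsed"]]

  ## --- load inputs ----------------------------------------------------
  is_path <- function(x) is.character(x) && !is.matrix(x) && length(x) == 1L
  psm_tables <- lapply(psm_tables, function(x)
    if (is_path(x)) read_psm_table(x) else x)
  reference_chains <- lapply(reference_chains, function(x)
    if (is_path(x)) read_alignment_fasta(x) else x)
  if (!is.null(peaklists))
    peaklists <- lapply(peaklists, function(x)
      if (is_path(x)) read_peaklist(x) else x)
  chains <- names(reference_chains)
  chain_len <- vapply(reference_chains, ncol, integer(1))

  ## --- stage 1: per-specimen filtering --------------------------------
  t0 <- tick()
  stage_msg("stage 1: HFPS filtering")
  filtered <- list(); reports <- list()
  for (tax in names(psm_tables)) {
    tab <- psm_tables[[tax]]
    specs <- unique(tab$specimen_id[!tab$is_decoy])
    if (length(specs) < 2L)
      stop("taxon '", tax, "' has ", length(specs), " specimen(s); the ",
           "both-specimens rule requires duplicate specimens")
    for (sp in specs) {
      sub <- tab[tab$specimen_id == sp, , drop = FALSE]
      reports[[sp]] <- filter_report(sub, chain_len)
      filtered[[sp]] <- filter_by_hfps(sub)
    }
  }
  filter_reports <- do.call(rbind, reports)
  rownames(filter_reports) <- NULL
  timings$filter <- tick() - t0

  ## --- stage 2-4: intersect, assemble, concatenate --------------------
  t0 <- tick()
  stage_msg("stage 2: replicate intersection and consensus assembly")
  fossil_taxa <- names(psm_tables)
  consensus <- list(); union_consensus <- list(); specimen_seqs <- list()
  for (tax in fossil_taxa) {
    specs <- unique(psm_tables[[tax]]$specimen_id[!psm_tables[[tax]]$is_decoy])
    per_chain <- list(); per_chain_union <- list(); per_chain_spec <- list()
    for (ch in chains) {
      a <- filtered[[specs[1]]]
      b <- filtered[[specs[2]]]
      a <- a[a$chain_id == ch, , drop = FALSE]
      b <- b[b$chain_id == ch, , drop = FALSE]
      inter <- replicate_intersection(a, b, key = intersect_key)
      per_chain[[ch]] <- assemble_consensus(inter, chain_len[[ch]], tax)
      ## either-specimen consensus: basis of the variation counts, whose
      ## replicate-confirmed subset is reported alongside
      per_chain_union[[ch]] <- assemble_consensus(rbind(a, b),
                                                  chain_len[[ch]], tax)
      per_chain_spec[[ch]] <- list(
        assemble_consensus(a, chain_len[[ch]], tax),
        assemble_consensus(b, chain_len[[ch]], tax))
    }
    consensus[[tax]] <- concatenate_chains(per_chain[[1]], per_chain[[2]])
    union_consensus[[tax]] <- concatenate_chains(per_chain_union[[1]],
                                                 per_chain_union[[2]])
    specimen_seqs[[tax]] <- list(
      concatenate_chains(per_chain_spec[[1]][[1]], per_chain_spec[[2]][[1]]),
      concatenate_chains(per_chain_spec[[1]][[2]], per_chain_spec[[2]][[2]]))
  }
  ref_concat <- cbind(reference_chains[[1]],
                      matrix("R", nrow(reference_chains[[1]]), 1),
                      reference_chains[[2]])
  colnames(ref_concat) <- NULL
  aln <- rbind(ref_concat,
               do.call(rbind, lapply(consensus, function(cs)
                 matrix(cs$seq, nrow = 1))))
  rownames(aln) <- c(rownames(ref_concat), names(consensus))
  if (isobaric) aln <- normalize_isobaric(aln, proteomic = fossil_taxa)
  timings$assemble <- tick() - t0

  ## --- stage 5: comparison matrices -----------------------------------
  t0 <- tick()
  stage_msg("stage 3: variation and shared-peak matrices")
  ## variation counts use the either-specimen consensus so that the
  ## replicate-confirmed counts are a subset of them; the specimen-level
  ## rows are harmonised jointly so I/L winners agree across all three
  aln_var <- aln
  for (tax in fossil_taxa)
    aln_var[tax, ] <- union_consensus[[tax]]$seq
  spec_rows <- do.call(rbind, lapply(fossil_taxa, function(tax)
    rbind(specimen_seqs[[tax]][[1]]$seq, specimen_seqs[[tax]][[2]]$seq)))
  rownames(spec_rows) <- paste0(rep(fossil_taxa, each = 2), "__sp",
                                rep(1:2, length(fossil_taxa)))
  big <- rbind(aln_var, spec_rows)
  if (isobaric)
    big <- normalize_isobaric(big, proteomic = c(fossil_taxa,
                                                 rownames(spec_rows)))
  aln_var <- big[rownames(aln_var), , drop = FALSE]
  for (tax in fossil_taxa) {
    specimen_seqs[[tax]][[1]]$seq <- unname(big[paste0(tax, "__sp1"), ])
    specimen_seqs[[tax]][[2]]$seq <- unname(big[paste0(tax, "__sp2"), ])
  }
  variations <- variation_matrix(aln_var)
  confirmed <- matrix(NA_integer_, length(fossil_taxa), nrow(aln),
                      dimnames = list(fossil_taxa, rownames(aln)))
  for (tax in fossil_taxa) for (other in rownames(aln_var)) {
    if (other == tax) next
    confirmed[tax, other] <- count_confirmed_variations(
      specimen_seqs[[tax]][[1]], specimen_seqs[[tax]][[2]], aln_var[other, ])
  }
  shared_peaks <- if (!is.null(peaklists))
    pairwise_shared_matrix(peaklists, n = top_n, tol = tolerance_da)
  timings$compare <- tick() - t0

  ## --- stage 6: maximum likelihood ------------------------------------
  t0 <- tick()
  stage_msg("stage 4: maximum-likelihood tree (", chain_mode, ")")
  phy_aln <- switch(chain_mode,
    "concat" = aln,
    "a2-only" = aln[, (chain_len[[1]] + 2L):ncol(aln), drop = FALSE])
  fit <- ml_tree_search(phy_aln)
  tree <- fit$tree
  if (bootstrap_reps > 0L)
    tree <- bootstrap_support(phy_aln, fit$model, n_reps = bootstrap_reps,
                              seed = seed, ml_tree = tree)
  rooted <- root_at_outgroup(tree, outgroup)
  timings$phylo <- tick() - t0

  res <- structure(list(filter_reports = filter_reports,
                        consensus = consensus,
                        specimen_seqs = specimen_seqs,
                        alignment = aln,
                        variations = variations,
                        confirmed = confirmed,
                        shared_peaks = shared_peaks,
                        tree = rooted,
                        unrooted_tree = tree,
                        model = fit$model,
                        loglik = fit$loglik,
                        seed = seed,
                        timings = timings),
                   class = "collagen_run")
  if (!is.null(out_dir)) write_run_bundle(res, out_dir)
  res
}

## write the report bundle (TSV/FASTA/Newick + manifest) for a run
write_run_bundle <- function(res, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir)
  files <- character(0)
  wtsv <- function(x, name, rn = TRUE) {
    f <- file.path(out_dir, name)
    utils::write.table(x, f, sep = "\t", quote = FALSE, row.names = rn,
                       col.names = NA)
    files <<- c(files, f)
  }
  f <- file.path(out_dir, "filter_report.tsv")
  utils::write.table(res$filter_reports, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, f)
  wtsv(res$variations, "variations.tsv")
  wtsv(res$confirmed, "confirmed_variations.tsv")
  if (!is.null(res$shared_peaks)) wtsv(res$shared_peaks, "shared_peaks.tsv")
  f <- file.path(out_dir, "consensus.fasta")
  write_alignment_fasta(lapply(res$consensus, function(cs) cs$seq), f)
  files <- c(files, f)
  f <- file.path(out_dir, "alignment.fasta")
  write_alignment_fasta(res$alignment, f)
  files <- c(files, f)
  f <- file.path(out_dir, "ml_tree.nwk")
  ape::write.tree(res$tree, f)
  files <- c(files, f)
  mf <- write_manifest(out_dir, list(seed = res$seed), res$seed,
                       res$timings, files)
  invisible(c(files, mf))
}

#' @export
print.collagen_run <- function(x, ...) {
  cat("collagen palaeoproteomics run\n")
  cat("  specimens filtered :", nrow(x$filter_reports), "\n")
  cat("  fossil consensus   :", paste(names(x$consensus), collapse = ", "), "\n")
  cat("  alignment          :", nrow(x$alignment), "taxa x",
      ncol(x$alignment), "sites\n")
  cat("  log-likelihood     :", format(x$loglik, digits = 10), "\n")
  invisible(x)
}
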