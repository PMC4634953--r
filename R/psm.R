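## Target-decoy quality control for peptide-spectrum matches:
## highest-false-positive-score (HFPS) thresholding, FDR summary,
## duplicate-specimen intersection and coverage.

#' Highest false-positive score of an analysis
#'
#' The maximum search-engine score among decoy PSMs. Used as the
#' per-analysis filtering threshold: only target matches scoring strictly
#' above the best decoy are retained, so that (by construction) the
#' retained set contains no match as weak as the strongest known false
#' positive.
#'
#' @param psms PSM data.frame (see [read_psm_table()]).
#' @return The highest decoy score (numeric scalar).
#' @export
hfps <- function(psms) {
  dec <- psms$score[psms$is_decoy]
  if (!length(dec))
    stop("no decoy PSMs present: supply a decoy search or pass an explicit ",
         "threshold to filter_by_hfps()")
  max(dec)
}

#' Filter target PSMs by a score threshold
#'
#' Keeps non-decoy PSMs whose score is strictly greater than
#' \code{threshold} (the HFPS rule uses "greater than", not ">=").
#' Input order is preserved.
#'
#' @param psms PSM data.frame.
#' @param threshold Score threshold, typically [hfps()].
#' @return Filtered PSM data.frame (decoys removed).
#' @export
filter_by_hfps <- function(psms, threshold = hfps(psms)) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  out <- psms[!psms$is_decoy & psms$score > threshold, , drop = FALSE]
  if (nrow(psms) > 0L && nrow(out) == 0L)
    warning("no target PSMs exceed the threshold (", threshold, ")")
  rownames(out) <- NULL
  out
}

#' Decoy-based false discovery rate (percent)
#'
#' \code{100 * n_decoys / n_targets} over all PSMs supplied (i.e. the set
#' reported above the search engine's significance cut).
#'
#' @param psms PSM data.frame.
#' @return FDR in percent.
#' @export
fdr_percent <- function(psms) {
  n_t <- sum(!psms$is_decoy)
  n_d <- sum(psms$is_decoy)
  if (n_t == 0L) stop("FDR undefined: no target PSMs")
  100 * n_d / n_t
}

## identity key for the both-specimens rule
psm_key <- function(psms, key = c("seq+pos", "seq")) {
  key <- match.arg(key)
  if (key == "seq+pos")
    paste(psms$peptide, psms$chain_id, psms$ref_start, sep = "|")
  else
    paste(psms$peptide, psms$chain_id, sep = "|")
}

#' Intersection of peptide matches across duplicate specimens
#'
#' Retains only matches observed in both specimens of the same (extinct)
#' taxon. The identity key defaults to (stripped peptide sequence, chain,
#' reference position); modification state is deliberately ignored because
#' collagen PTMs are variable between specimens. Pass \code{key = "seq"} to
#' drop the position from the key.
#'
#' @param filtered_a,filtered_b HFPS-filtered PSM tables from the two
#'   specimens.
#' @param key \code{"seq+pos"} (default) or \code{"seq"}.
#' @return The rows of \code{filtered_a} (plus unmatched-state rows of
#'   \code{filtered_b}) whose key occurs in both specimens; attribute
#'   \code{keys} holds the shared key set.
#' @export
replicate_intersection <- function(filtered_a, filtered_b,
                                   key = c("seq+pos", "seq")) {
  key <- match.arg(key)
  ida <- unique(filtered_a$specimen_id)
  idb <- unique(filtered_b$specimen_id)
  if (length(intersect(ida, idb)))
    stop("the two PSM sets share specimen_id(s) (",
         paste(intersect(ida, idb), collapse = ", "),
         "): not true replicate specimens")
  ka <- psm_key(filtered_a, key)
  kb <- psm_key(filtered_b, key)
  shared <- intersect(ka, kb)
  out <- rbind(filtered_a[ka %in% shared, , drop = FALSE],
               filtered_b[kb %in% shared, , drop = FALSE])
  rownames(out) <- NULL
  attr(out, "keys") <- shared
  out
}

## 0-based half-open residue intervals covered by peptides
covered_positions <- function(psms, reference_length) {
  ends <- psms$ref_start + nchar(psms$peptide)
  if (any(ends > reference_length))
    stop("peptide extends past the reference end (length ",
         reference_length, ")")
  if (nrow(psms) == 0L) return(integer(0))
  sort(unique(unlist(Map(function(s, e) seq.int(s, e - 1L),
                         psms$ref_start, ends))))
}

#' Sequence coverage of a reference chain (percent)
#'
#' 100 x |union of residue positions covered by the peptides| / reference
#' length.
#'
#' @param psms PSM data.frame (targets; positions 0-based).
#' @param reference_length Length of the chain's reference alignment.
#' @return Coverage in percent.
#' @export
coverage_percent <- function(psms, reference_length) {
  if (reference_length <= 0) stop("reference_length must be positive")
  100 * length(covered_positions(psms, reference_length)) / reference_length
}

#' Per-analysis quality report
#'
#' Summarises one specimen's search in the style of a target-decoy QC
#' table: FDR, HFPS threshold, total score, match and unique-sequence
#' counts, and per-chain plus combined coverage of the filtered matches.
#'
#' @param psms Unfiltered PSM table for one specimen (targets + decoys).
#' @param reference_lengths Named vector of chain reference lengths, e.g.
#'   \code{c(COL1A1 = 1056, COL1A2 = 1041)}.
#' @return One-row data.frame.
#' @export
filter_report <- function(psms, reference_lengths) {
  thr <- hfps(psms)
  kept <- filter_by_hfps(psms, thr)
  cov <- vapply(names(reference_lengths), function(ch) {
    coverage_percent(kept[kept$chain_id == ch, , drop = FALSE],
                     reference_lengths[[ch]])
  }, numeric(1))
  combined <- 100 *
    sum(vapply(names(reference_lengths), function(ch) {
      length(covered_positions(kept[kept$chain_id == ch, , drop = FALSE],
                               reference_lengths[[ch]]))
    }, numeric(1))) / sum(reference_lengths)
  out <- data.frame(
    specimen_id = if (nrow(psms)) psms$specimen_id[!psms$is_decoy][1] else NA,
    fdr_percent = fdr_percent(psms),
    hfps = thr,
    total_score = sum(kept$score),
    n_matches = nrow(kept),
    n_unique_sequences = length(unique(kept$peptide)),
    coverage_combined = combined,
    stringsAsFactors = FALSE)
  for (ch in names(cov)) out[[paste0("coverage_", ch)]] <- cov[[ch]]
  out
}
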