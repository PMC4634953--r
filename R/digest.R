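## In-silico tryptic digestion and peptide mass arithmetic.

#' Monoisotopic residue masses
#'
#' Named vector of monoisotopic masses (Da) for the 20 standard amino-acid
#' residues (i.e. the mass contributed inside a peptide chain, water
#' excluded), in the order used by the JTT substitution matrix.
#'
#' @format Named numeric vector of length 20.
#' @export
AA_MONO_MASS <- c(
  A = 71.037114, R = 156.101111, N = 114.042927, D = 115.026943,
  C = 103.009185, Q = 128.058578, E = 129.042593, G = 57.021464,
  H = 137.058912, I = 113.084064, L = 113.084064, K = 128.094963,
  M = 131.040485, F = 147.068414, P = 97.052764, S = 87.032028,
  T = 101.047678, W = 186.079313, Y = 163.063329, V = 99.068414
)

## monoisotopic constants
MASS_WATER  <- 18.0105646
MASS_PROTON <- 1.00727646

#' Post-translational modification mass deltas
#'
#' Full-precision monoisotopic deltas for the modifications considered in
#' collagen palaeoproteomics: fixed carbamidomethylation of cysteine,
#' variable oxidation (hydroxylation) of K/P (optionally M), and variable
#' deamidation of N/Q. Rounded two-decimal values (+57.02, +15.99, +0.98)
#' are commonly printed; full precision is used internally so that error
#' does not accumulate over long peptides.
#'
#' @format Named numeric vector (Da).
#' @export
MOD_DELTAS <- c(
  carbamidomethyl = 57.021464,
  hydroxylation   = 15.994915,
  deamidation     = 0.984016
)

## residues eligible for each modification; M-oxidation is optional because
## the error-tolerant search applied oxidation to K/P while the decoy search
## additionally allowed M (see vignette).
mod_eligible <- function(include_met_ox = FALSE) {
  ox <- if (include_met_ox) c("K", "P", "M") else c("K", "P")
  list(carbamidomethyl = "C", hydroxylation = ox, deamidation = c("N", "Q"))
}

check_aa_sequence <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop(what, " must be a single character string")
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% names(AA_MONO_MASS))
  if (length(bad))
    stop(sprintf("non-standard residue '%s' at position %d of %s",
                 chars[bad[1]], bad[1], what))
  chars
}

#' In-silico tryptic digestion (trypsin/P rule)
#'
#' Cleaves a protein sequence after every K or R, including when the next
#' residue is proline (the trypsin/P convention used for collagen, whose
#' abundant -K-P- and -R-P- motifs would otherwise suppress cleavage).
#' Peptides with up to \code{max_missed} internal missed cleavage sites are
#' enumerated; the C-terminal peptide is emitted even without a trailing
#' K/R.
#'
#' @param sequence Protein sequence (20 standard one-letter codes only).
#' @param max_missed Maximum number of internal missed cleavages (>= 0).
#' @return A data.frame with columns \code{peptide}, \code{start} (0-based),
#'   \code{end} (exclusive), \code{missed}. The 0-missed rows tile the
#'   input exactly.
#' @examples
#' tryptic_digest("GAKGPR", 0)   # GAK, GPR
#' tryptic_digest("GAKPGR", 0)   # GAK, PGR  (cleavage before P allowed)
#' @export
tryptic_digest <- function(sequence, max_missed = 0L) {
  chars <- check_aa_sequence(sequence)
  if (!is.numeric(max_missed) || length(max_missed) != 1L || max_missed < 0)
    stop("max_missed must be a single non-negative integer")
  max_missed <- as.integer(max_missed)
  n <- length(chars)
  ## cut points: after each K/R, plus sequence end
  cuts <- which(chars %in% c("K", "R"))
  bounds <- unique(c(0L, cuts, n))        # 0-based segment boundaries
  nseg <- length(bounds) - 1L
  out <- vector("list", 0L)
  for (i in seq_len(nseg)) {
    for (m in 0:max_missed) {
      j <- i + m
      if (j > nseg) break
      s <- bounds[i]; e <- bounds[j + 1L]
      out[[length(out) + 1L]] <- list(
        peptide = paste(chars[(s + 1L):e], collapse = ""),
        start = s, end = e, missed = m)
    }
  }
  df <- do.call(rbind.data.frame, c(out, list(stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  df
}

#' Parse a modification-count string
#'
#' Modifications travel through PSM tables as a compact string such as
#' \code{"hydroxylation:2;deamidation:1"}. An empty string or \code{NA}
#' means unmodified.
#'
#' @param mods Modification string (or named numeric vector, returned as-is).
#' @return Named numeric vector of modification counts.
#' @export
parse_modifications <- function(mods) {
  if (is.numeric(mods)) {
    if (is.null(names(mods))) stop("numeric mods must be named")
    return(mods)
  }
  if (is.null(mods) || length(mods) == 0L || is.na(mods) || !nzchar(mods))
    return(numeric(0))
  parts <- strsplit(mods, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  counts <- vapply(kv, function(p) as.numeric(p[2]), numeric(1))
  names(counts) <- vapply(kv, `[`, character(1), 1L)
  unknown <- setdiff(names(counts), names(MOD_DELTAS))
  if (length(unknown))
    stop("unknown modification(s): ", paste(unknown, collapse = ", "))
  counts
}

format_modifications <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) return("")
  paste(sprintf("%s:%d", names(counts), as.integer(counts)), collapse = ";")
}

#' Monoisotopic peptide mass with modifications
#'
#' Sum of residue masses plus one water, plus the mass deltas of the applied
#' modifications. Modification counts are validated against the number of
#' eligible residues in the peptide.
#'
#' @param peptide Peptide sequence (standard letters).
#' @param mods Modification string or named count vector
#'   (see [parse_modifications()]); default unmodified.
#' @param include_met_ox Logical; whether methionine counts as eligible for
#'   the +15.99 Da oxidation (used in decoy-style searches).
#' @return Monoisotopic mass in Da.
#' @examples
#' peptide_mass("G")                              # 75.03203
#' peptide_mass("GPAGPR", "hydroxylation:1")
#' @export
peptide_mass <- function(peptide, mods = "", include_met_ox = FALSE) {
  chars <- check_aa_sequence(peptide, "peptide")
  counts <- parse_modifications(mods)
  elig <- mod_eligible(include_met_ox)
  for (m in names(counts)) {
    n_elig <- sum(chars %in% elig[[m]])
    if (counts[m] > n_elig)
      stop(sprintf("%d x %s requested but only %d eligible residue(s) in '%s'",
                   counts[m], m, n_elig, peptide))
    if (counts[m] < 0) stop("negative modification count")
  }
  sum(AA_MONO_MASS[chars]) + MASS_WATER + sum(MOD_DELTAS[names(counts)] * counts)
}

#' m/z of a peptide ion
#'
#' \code{(mass + charge * proton) / charge}. MALDI ions are singly
#' protonated; LC-MS/MS precursors are typically 2+ or 3+.
#'
#' @param mass Neutral monoisotopic mass (Da), > 0 allowed to be 0 for the
#'   degenerate proton case.
#' @param charge Positive integer charge state.
#' @return m/z value.
#' @export
mz_from_mass <- function(mass, charge = 1L) {
  if (!is.numeric(mass) || any(mass < 0)) stop("mass must be non-negative")
  if (!is.numeric(charge) || any(charge < 1)) stop("charge must be >= 1")
  (mass + charge * MASS_PROTON) / charge
}

#' Digest a protein and tabulate peptide masses
#'
#' Convenience wrapper: digest, then compute the unmodified monoisotopic
#' mass of every peptide. Written as TSV by [write_digest_tsv()].
#'
#' @inheritParams tryptic_digest
#' @return data.frame with columns peptide, start, end, missed, mass.
#' @export
digest_table <- function(sequence, max_missed = 0L) {
  df <- tryptic_digest(sequence, max_missed)
  df$mass <- vapply(df$peptide, peptide_mass, numeric(1), USE.NAMES = FALSE)
  df
}

#' @rdname digest_table
#' @param digest A data.frame from [digest_table()].
#' @param file Output path.
#' @export
write_digest_tsv <- function(digest, file) {
  utils::write.table(digest, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
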