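## File I/O: FASTA alignments, PSM tables, MALDI peak lists.

#' Read an amino-acid alignment from FASTA
#'
#' Returns the alignment as an upper-case character matrix (rows = taxa,
#' columns = sites). The alphabet is not restricted here: partial ancient
#' sequences use \code{X} (unknown residue), \code{?} (unknown at an indel
#' site of other taxa) and \code{-} (gap); all three are treated as fully
#' missing by the likelihood machinery.
#'
#' @param file Path to a FASTA file.
#' @return Character matrix with taxon rownames.
#' @export
read_alignment_fasta <- function(file) {
  x <- ape::read.FASTA(file, type = "AA")
  m <- toupper(as.character(as.matrix(x)))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(names(x)))
  m
}

#' Write an amino-acid alignment to FASTA
#'
#' @param aln Character matrix (rows = taxa) or named list/vector of
#'   equal-length sequence strings.
#' @param file Output path.
#' @export
write_alignment_fasta <- function(aln, file) {
  if (is.matrix(aln)) {
    seqs <- apply(aln, 1, paste, collapse = "")
  } else {
    seqs <- vapply(aln, paste, character(1), collapse = "")
  }
  con <- file(file, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    writeLines(seqs[[nm]], con)
  }
  invisible(file)
}

PSM_COLUMNS <- c("peptide", "modifications", "score", "specimen_id",
                 "chain_id", "ref_start", "is_decoy")

#' Read / write a PSM table
#'
#' Tab-separated with a header line; columns \code{peptide},
#' \code{modifications} (see [parse_modifications()]), \code{score},
#' \code{specimen_id}, \code{chain_id}, \code{ref_start} (0-based position
#' of the peptide in the chain's reference alignment) and \code{is_decoy}
#' (TRUE/FALSE).
#'
#' @param file Path to a TSV file.
#' @return data.frame of peptide-spectrum matches.
#' @export
read_psm_table <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = c(modifications = "character"))
  missing_cols <- setdiff(PSM_COLUMNS, names(df))
  if (length(missing_cols))
    stop("PSM table ", file, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  df$is_decoy <- as.logical(df$is_decoy)
  df$modifications[is.na(df$modifications)] <- ""
  validate_psm(df)
  df
}

#' @rdname read_psm_table
#' @param psms PSM data.frame.
#' @export
write_psm_table <- function(psms, file) {
  utils::write.table(psms[, PSM_COLUMNS], file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

validate_psm <- function(psms) {
  if (any(psms$score < 0)) stop("PSM scores must be non-negative")
  if (any(psms$ref_start < 0)) stop("ref_start must be >= 0")
  invisible(psms)
}

#' Read / write a MALDI peak list
#'
#' Two-column whitespace- or tab-delimited text (m/z, intensity). Peaks are
#' sorted ascending by m/z; peaks outside the instrument range are dropped
#' with a warning.
#'
#' @param file Path to a peak-list file.
#' @param instrument_range Numeric length-2 m/z window (default the MALDI
#'   acquisition window 700-3700).
#' @return A \code{peaklist} object (data.frame mz/intensity with an
#'   \code{instrument_range} attribute).
#' @export
read_peaklist <- function(file, instrument_range = c(700, 3700)) {
  df <- utils::read.table(file, header = FALSE,
                          col.names = c("mz", "intensity"))
  peaklist(df$mz, df$intensity, instrument_range)
}

#' @rdname read_peaklist
#' @param pl A \code{peaklist}.
#' @export
write_peaklist <- function(pl, file) {
  utils::write.table(format(as.data.frame(pl), digits = 10), file,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
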