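## Assembly of partial aligned consensus sequences from filtered peptide
## matches, isobaric (I/L) harmonisation, chain concatenation and pairwise
## variation counts.

## amino-acid alphabet in JTT order
AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

is_determined <- function(x) x %in% AA20

#' Construct a consensus-sequence object
#'
#' @param taxon Taxon label.
#' @param seq Character vector of single letters over the alphabet
#'   {20 amino acids, X, ?, -}.
#' @param support Integer vector of per-site supporting-peptide counts
#'   (NA where not applicable).
#' @return Object of class \code{consensus_seq}.
#' @export
consensus_seq <- function(taxon, seq, support = rep(NA_integer_, length(seq))) {
  if (length(seq) != length(support))
    stop("seq and support lengths differ")
  structure(list(taxon = taxon, seq = seq, support = support),
            class = "consensus_seq")
}

#' @export
print.consensus_seq <- function(x, ...) {
  det <- sum(is_determined(x$seq))
  cat(sprintf("consensus_seq '%s': %d sites, %d determined (%.1f%%)\n",
              x$taxon, length(x$seq), det, 100 * det / length(x$seq)))
  invisible(x)
}

#' @export
as.character.consensus_seq <- function(x, ...) paste(x$seq, collapse = "")

#' Assemble a partial consensus sequence from peptide matches
#'
#' Each aligned site covered by at least one peptide receives the residue
#' its peptides imply; uncovered sites are \code{X}. When peptides disagree
#' at a site, the residue with the greatest summed PSM score wins; an exact
#' score tie yields \code{X}. Conflicting sites are recorded in the
#' \code{conflicts} attribute.
#'
#' @param matches PSM-style data.frame with columns \code{peptide},
#'   \code{score}, \code{ref_start} (0-based).
#' @param alignment_length Length of the chain's reference alignment.
#' @param taxon Taxon label for the result.
#' @return A \code{consensus_seq} of length \code{alignment_length} with
#'   per-site support counts.
#' @export
assemble_consensus <- function(matches, alignment_length, taxon = "consensus") {
  seq <- rep("X", alignment_length)
  support <- integer(alignment_length)
  conflicts <- integer(0)
  if (nrow(matches) > 0L) {
    ends <- matches$ref_start + nchar(matches$peptide)
    if (any(matches$ref_start < 0) || any(ends > alignment_length))
      stop("peptide match outside [0, alignment_length)")
    pos <- unlist(Map(function(s, e) seq.int(s, e - 1L),
                      matches$ref_start, ends)) + 1L
    res <- unlist(strsplit(matches$peptide, ""))
    sc <- rep(matches$score, nchar(matches$peptide))
    tab <- tapply(sc, list(pos = pos, res = res), sum)
    cnt <- tapply(rep(1L, length(pos)), pos, sum)
    support[as.integer(names(cnt))] <- as.integer(cnt)
    for (p in rownames(tab)) {
      w <- stats::setNames(tab[p, ], colnames(tab))
      w <- w[!is.na(w)]
      i <- as.integer(p)
      if (length(w) == 1L) {
        seq[i] <- names(w)
      } else {
        conflicts <- c(conflicts, i)
        best <- which(w == max(w))
        if (length(best) == 1L) seq[i] <- names(w)[best]
        else seq[i] <- "X"        # unresolvable tie
      }
    }
    if (length(conflicts))
      warning(length(conflicts), " site(s) with conflicting residue calls",
              " resolved by summed score (ties -> X)")
  }
  out <- consensus_seq(taxon, seq, support)
  attr(out, "conflicts") <- conflicts
  out
}

#' Harmonise isobaric leucine/isoleucine calls across an alignment
#'
#' I and L have identical residue mass and cannot be distinguished by the
#' mass-spectrometry workflow. At every column where both letters occur,
#' I/L calls in the proteomics-derived sequences are replaced by the more
#' abundant of the two across all sequences in that column; database-derived
#' reference sequences are never altered. Exact ties keep the observed
#' letter and are recorded in the \code{isobaric_ties} attribute.
#'
#' @param aln Character matrix (rows = taxa, with rownames).
#' @param proteomic Character vector of row names whose sequences are
#'   proteomics-derived (eligible for replacement).
#' @return The matrix with harmonised I/L calls.
#' @export
normalize_isobaric <- function(aln, proteomic) {
  stopifnot(is.matrix(aln), all(proteomic %in% rownames(aln)))
  ties <- integer(0)
  prot <- rownames(aln) %in% proteomic
  for (j in seq_len(ncol(aln))) {
    col <- aln[, j]
    nI <- sum(col == "I"); nL <- sum(col == "L")
    if (nI > 0L && nL > 0L) {
      if (nI == nL) { ties <- c(ties, j); next }
      winner <- if (nL > nI) "L" else "I"
      il <- prot & col %in% c("I", "L")
      aln[il, j] <- winner
    }
  }
  attr(aln, "isobaric_ties") <- ties
  aln
}

#' Concatenate the two collagen chains of one taxon
#'
#' Joins the alpha-1 and alpha-2 consensus sequences via a single \code{R}
#' residue (the linker used when building the concatenated character
#' matrix), so the result length is \code{len(a1) + len(a2) + 1} - with the
#' default chain lengths 1056 and 1041, the canonical 2098.
#'
#' @param a1,a2 \code{consensus_seq} objects for the same taxon.
#' @return A \code{consensus_seq} for the concatenated molecule.
#' @export
concatenate_chains <- function(a1, a2) {
  if (!identical(a1$taxon, a2$taxon))
    stop("taxon mismatch: '", a1$taxon, "' vs '", a2$taxon, "'")
  consensus_seq(a1$taxon,
                c(a1$seq, "R", a2$seq),
                c(a1$support, NA_integer_, a2$support))
}

as_residue_vector <- function(x) {
  if (inherits(x, "consensus_seq")) x$seq
  else if (is.character(x) && length(x) == 1L) strsplit(x, "")[[1]]
  else as.character(x)
}

#' Count amino-acid differences between two aligned sequences
#'
#' Number of columns where both residues are determined (not X/?/-) and
#' differ. Symmetric; zero on self-comparison.
#'
#' @param seq_a,seq_b \code{consensus_seq} objects, strings or character
#'   vectors of equal aligned length.
#' @return Integer count.
#' @export
count_variations <- function(seq_a, seq_b) {
  a <- as_residue_vector(seq_a); b <- as_residue_vector(seq_b)
  if (length(a) != length(b)) stop("aligned lengths differ")
  sum(is_determined(a) & is_determined(b) & a != b)
}

#' Count replicate-confirmed amino-acid differences
#'
#' A difference between a fossil taxon and a comparison sequence counts as
#' confirmed only when both duplicate specimens of the fossil taxon show
#' the same determined residue and that residue differs from the
#' comparison taxon's determined residue.
#'
#' @param specimen1,specimen2 Specimen-level sequences of the fossil taxon.
#' @param other The comparison taxon's sequence.
#' @return Integer count of confirmed differences.
#' @export
count_confirmed_variations <- function(specimen1, specimen2, other) {
  s1 <- as_residue_vector(specimen1)
  s2 <- as_residue_vector(specimen2)
  b <- as_residue_vector(other)
  if (length(s1) != length(s2) || length(s1) != length(b))
    stop("aligned lengths differ")
  sum(is_determined(s1) & s1 == s2 & is_determined(b) & s1 != b)
}

#' Pairwise variation-count matrix
#'
#' [count_variations()] over all pairs of a set of aligned sequences.
#'
#' @param aln Character matrix (rows = taxa).
#' @return Symmetric integer matrix.
#' @export
variation_matrix <- function(aln) {
  k <- nrow(aln)
  m <- matrix(0L, k, k, dimnames = list(rownames(aln), rownames(aln)))
  if (k >= 2L) for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
    m[i, j] <- m[j, i] <- count_variations(aln[i, ], aln[j, ])
  m
}
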