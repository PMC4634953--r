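## Missing-data-aware Felsenstein pruning under JTT + I + G.
##
## Alignments are character matrices over {20 AA, X, ?, -}; X, ? and - are
## all fully missing in the likelihood (their tip partials are all ones).
## Site patterns are compressed once and carry resampling weights, which
## is also how the bootstrap avoids re-reading the alignment.

MISSING_SYMBOLS <- c("X", "?", "-", ".", "*")

#' Encode an alignment as integer states
#'
#' @param aln Character matrix (rows = taxa).
#' @return Integer matrix (1..20, NA for missing symbols).
#' @keywords internal
encode_alignment <- function(aln) {
  v <- toupper(aln)
  codes <- match(v, AA20)
  bad <- which(is.na(codes) & !(v %in% MISSING_SYMBOLS))
  if (length(bad))
    stop("unknown residue symbol '", v[bad[1]], "' in alignment")
  matrix(codes, nrow = nrow(aln), dimnames = dimnames(aln))
}

#' Compress alignment columns into site patterns
#'
#' @param aln Character matrix (rows = taxa, rownames required).
#' @param freq Stationary frequencies (for the invariant-site term).
#' @return List: \code{codes} (taxa x n_patterns), \code{weights},
#'   \code{const_pi} (stationary probability of the compatible constant
#'   state, 0 when the pattern is variable), \code{site_pattern} (pattern
#'   index of each original site), \code{taxa}.
#' @keywords internal
compress_patterns <- function(aln, freq = JTT_FREQ) {
  if (is.null(rownames(aln))) stop("alignment must have taxon rownames")
  if (ncol(aln) == 0L) stop("empty alignment")
  codes <- encode_alignment(aln)
  key <- apply(codes, 2, paste, collapse = ",")
  uk <- unique(key)
  idx <- match(key, uk)
  first <- match(uk, key)
  pcodes <- codes[, first, drop = FALSE]
  weights <- as.numeric(tabulate(idx, nbins = length(uk)))
  const_pi <- apply(pcodes, 2, function(col) {
    d <- unique(col[!is.na(col)])
    if (length(d) == 0L) 1
    else if (length(d) == 1L) freq[d]
    else 0
  })
  list(codes = pcodes, weights = weights, const_pi = const_pi,
       site_pattern = idx, taxa = rownames(aln))
}

## tip partial-likelihood matrix (20 x n_patterns)
tip_partial <- function(codes_row) {
  npat <- length(codes_row)
  m <- matrix(0, 20, npat)
  obs <- which(!is.na(codes_row))
  m[cbind(codes_row[obs], obs)] <- 1
  m[, is.na(codes_row)] <- 1
  m
}

## column maxima of a 20 x n matrix (fast path, no apply)
col_max <- function(m) m[cbind(max.col(t(m), ties.method = "first"),
                               seq_len(ncol(m)))]

## rescale a scaled message (list m, lg) to avoid underflow
rescale_msg <- function(msg) {
  s <- col_max(msg$m)
  s[s <= 0] <- 1
  msg$m <- msg$m / rep(s, each = 20L)
  msg$lg <- msg$lg + log(s)
  msg
}

## per-category effective rates under +I (gamma rates / (1 - p_inv))
effective_rates <- function(model) model$rates / (1 - model$p_inv)

## per-category log site likelihoods: n_patterns x k matrix
category_site_loglik <- function(tree, pat, model) {
  tree <- ape::reorder.phylo(tree, "postorder")
  edge <- tree$edge
  el <- tree$edge.length
  if (is.null(el)) stop("tree has no branch lengths")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  tipidx <- match(tree$tip.label, pat$taxa)
  if (anyNA(tipidx)) stop("tree tips missing from alignment: ",
                          paste(tree$tip.label[is.na(tipidx)], collapse = ", "))
  npat <- ncol(pat$codes)
  rates <- effective_rates(model)
  out <- matrix(NA_real_, npat, model$k)
  tips <- lapply(seq_len(ntip), function(i) tip_partial(pat$codes[tipidx[i], ]))
  for (cc in seq_len(model$k)) {
    msgs <- vector("list", nnode)
    lgs <- vector("list", nnode)
    for (e in seq_len(nrow(edge))) {
      p <- edge[e, 1L]; v <- edge[e, 2L]
      P <- transition_matrix(model, el[e], rates[cc])
      if (v <= ntip) {
        contrib <- P %*% tips[[v]]
        clg <- 0
      } else {
        contrib <- P %*% msgs[[v]]
        clg <- lgs[[v]]
      }
      if (is.null(msgs[[p]])) {
        msgs[[p]] <- contrib
        lgs[[p]] <- clg
      } else {
        msgs[[p]] <- msgs[[p]] * contrib
        lgs[[p]] <- lgs[[p]] + clg
      }
      ## rescale as we accumulate to keep partials in range
      s <- col_max(msgs[[p]])
      s[s <= 0] <- 1
      msgs[[p]] <- msgs[[p]] / rep(s, each = 20L)
      lgs[[p]] <- lgs[[p]] + log(s)
    }
    root <- ntip + 1L
    L <- colSums(model$freq * msgs[[root]])
    out[, cc] <- log(L) + lgs[[root]]
  }
  out
}

## combine per-category log likelihoods with the invariant-site class
combine_site_loglik <- function(logLc, pat, model) {
  k <- ncol(logLc)
  m <- do.call(pmax, as.data.frame(logLc))
  mix <- (1 - model$p_inv) * rowMeans(exp(logLc - m))
  b <- m + log(mix)
  if (model$p_inv > 0) {
    a <- ifelse(pat$const_pi > 0, log(model$p_inv * pat$const_pi), -Inf)
    hi <- pmax(a, b); lo <- pmin(a, b)
    site <- hi + log1p(exp(lo - hi))
    site[!is.finite(hi)] <- -Inf
  } else {
    site <- b
  }
  site
}

#' Log-likelihood of an alignment on a tree
#'
#' Felsenstein pruning under the supplied reversible model with invariant
#' sites and discrete-gamma rate heterogeneity. Missing symbols (X, ?, -)
#' contribute all-ones tip partials, so a fully missing column adds
#' exactly zero to the total. The per-site likelihood is
#' \deqn{L_s = p_{inv} \pi(x_s) [\mathrm{constant}] +
#'       (1-p_{inv}) \frac{1}{k}\sum_c L_s(r_c/(1-p_{inv}))}
#'
#' @param tree An \code{ape} \code{phylo} tree with branch lengths; its
#'   tips must occur in the alignment.
#' @param alignment Character matrix (rows = taxa) or a compressed pattern
#'   object from \code{compress_patterns}.
#' @param model A \code{subst_model}.
#' @return Total log-likelihood (numeric scalar); per-site values in the
#'   \code{site_loglik} attribute (per pattern, with weights).
#' @export
log_likelihood <- function(tree, alignment, model) {
  pat <- if (is.matrix(alignment)) compress_patterns(alignment, model$freq)
         else alignment
  logLc <- category_site_loglik(tree, pat, model)
  site <- combine_site_loglik(logLc, pat, model)
  total <- sum(pat$weights * site)
  attr(total, "site_loglik") <- site
  attr(total, "weights") <- pat$weights
  total
}
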