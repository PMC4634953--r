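## JTT + I + G substitution model: published exchangeabilities and
## frequencies, discrete-gamma rate heterogeneity, and transition-matrix
## computation via symmetric eigendecomposition.

## Published Jones-Taylor-Thornton (1992) amino-acid exchangeabilities,
## lower triangle (column-major) in the residue order ARNDCQEGHILKMFPSTWYV.
JTT_LOWER <- c(
  58, 54, 81, 56, 57, 105, 179, 27, 36, 30, 35, 54, 15, 194, 378, 475, 9,
  11, 298, 45, 16, 113, 310, 29, 137, 328, 22, 38, 646, 44, 5, 74, 101, 64,
  126, 20, 17, 528, 34, 86, 58, 81, 391, 47, 12, 263, 30, 10, 15, 503, 232,
  8, 70, 16, 10, 49, 767, 130, 112, 11, 7, 26, 15, 4, 15, 59, 38, 4, 46,
  31, 9, 5, 59, 69, 17, 23, 7, 31, 78, 14, 223, 42, 115, 209, 62, 323, 26,
  597, 9, 72, 292, 43, 4, 164, 53, 51, 18, 24, 20, 119, 26, 12, 9, 181, 18,
  5, 18, 30, 32, 10, 7, 45, 23, 6, 6, 27, 14, 5, 24, 201, 33, 55, 8, 47,
  16, 56, 45, 33, 40, 115, 73, 46, 8, 573, 11, 229, 21, 479, 89, 10, 40,
  245, 9, 32, 961, 14, 388, 248, 102, 59, 25, 52, 24, 180, 65, 4, 21, 47,
  103, 10, 8, 14, 43, 16, 29, 226, 24, 18, 323, 17, 92, 12, 53, 536, 62,
  285, 118, 6, 10, 23, 477, 35, 63, 38, 12, 21, 112, 71, 25, 16)

## Published JTT stationary amino-acid frequencies (same residue order).
JTT_FREQ <- c(
  0.076748, 0.051691, 0.042645, 0.051544, 0.019803, 0.040752, 0.061830,
  0.073152, 0.022944, 0.053761, 0.091904, 0.058676, 0.023826, 0.040126,
  0.050901, 0.068765, 0.058565, 0.014261, 0.032102, 0.066005)

#' The JTT exchangeability matrix
#'
#' Symmetric 20x20 matrix of published JTT exchangeabilities (zero
#' diagonal), residues ordered \code{ARNDCQEGHILKMFPSTWYV}.
#'
#' @return Numeric 20x20 matrix with residue dimnames.
#' @export
jtt_exchangeabilities <- function() {
  S <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
  S[lower.tri(S)] <- JTT_LOWER
  S <- S + t(S)
  S
}

#' Construct a JTT + I + G substitution model
#'
#' Builds the reversible rate matrix Q = S diag(pi), with the diagonal set
#' so rows sum to zero and the whole matrix scaled so the mean
#' substitution rate at stationarity is 1 (branch lengths are then
#' expected substitutions per site). The gamma rate categories are
#' equal-probability mean-of-bin discretisations; under +I they are
#' divided by (1 - p_inv) so the model's overall mean rate stays 1.
#'
#' @param p_inv Proportion of invariant sites in [0, 1).
#' @param alpha Gamma shape parameter (> 0).
#' @param k Number of discrete gamma categories (default 4).
#' @param frequencies Stationary frequencies; defaults to the published JTT
#'   frequencies (set to observed frequencies for a +F variant).
#' @return Object of class \code{subst_model}.
#' @export
jtt_model <- function(p_inv = 0, alpha = 1, k = 4L,
                      frequencies = NULL) {
  S <- jtt_exchangeabilities()
  pi <- if (is.null(frequencies)) JTT_FREQ else frequencies
  subst_model(S, pi, p_inv = p_inv, alpha = alpha, k = k)
}

#' @rdname jtt_model
#' @param S Symmetric non-negative 20x20 exchangeability matrix.
#' @param frequencies20 Stationary frequencies (length 20, positive).
#' @export
subst_model <- function(S, frequencies20, p_inv = 0, alpha = 1, k = 4L) {
  stopifnot(is.matrix(S), nrow(S) == 20, ncol(S) == 20,
            isTRUE(all.equal(S, t(S))), all(S >= 0),
            length(frequencies20) == 20, all(frequencies20 > 0))
  pi <- frequencies20 / sum(frequencies20)
  Q <- S %*% diag(pi)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))            # mean rate at stationarity
  Q <- Q / mu
  ## symmetric form diag(pi)^1/2 Q diag(pi)^-1/2 has a real spectrum
  sp <- sqrt(pi)
  B <- (sp * Q) %*% diag(1 / sp)      # row-scale then column-scale
  B <- (B + t(B)) / 2                 # kill round-off asymmetry
  eig <- eigen(B, symmetric = TRUE)
  C1 <- eig$vectors / sp              # diag(1/sqrt(pi)) V   (row scaling)
  C2 <- t(eig$vectors) %*% diag(sp)   # t(V) diag(sqrt(pi))
  m <- structure(list(S = S, freq = pi, Q = Q,
                      eig = list(values = eig$values, C1 = C1, C2 = C2)),
                 class = "subst_model")
  set_model_params(m, p_inv = p_inv, alpha = alpha, k = k)
}

#' Update the rate-heterogeneity parameters of a model
#'
#' Cheap: the eigendecomposition of Q is reused; only the gamma category
#' rates are recomputed.
#'
#' @param model A \code{subst_model}.
#' @inheritParams jtt_model
#' @return The updated model.
#' @export
set_model_params <- function(model, p_inv = model$p_inv,
                             alpha = model$alpha, k = model$k) {
  if (p_inv < 0 || p_inv >= 1) stop("p_inv must be in [0, 1)")
  model$p_inv <- p_inv
  model$alpha <- alpha
  model$k <- as.integer(k)
  g <- discrete_gamma_rates(alpha, k)
  model$rates <- g$rates
  model
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("subst_model: 20-state reversible; p_inv = %.4g, alpha = %.4g, %d gamma categories\n",
              x$p_inv, x$alpha, x$k))
  invisible(x)
}

#' Discrete-gamma rate categories (mean-of-bin)
#'
#' Splits the Gamma(shape = alpha, rate = alpha) distribution (mean 1)
#' into \code{k} equal-probability bins and uses each bin's conditional
#' mean as the category rate, so the category rates average exactly 1.
#'
#' @param alpha Gamma shape (> 0).
#' @param k Number of categories (>= 1).
#' @return List with \code{rates} (length k) and \code{probs} (all 1/k).
#' @export
discrete_gamma_rates <- function(alpha, k = 4L) {
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be positive")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k == 1L) return(list(rates = 1, probs = 1))
  b <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = alpha,
                     rate = alpha)
  ## E[X; X in bin] / (1/k), using the incomplete-gamma identity
  ## E[X 1{X<b}] = P(Gamma(alpha+1, alpha) < b) for mean-1 gamma
  cdf1 <- stats::pgamma(b, shape = alpha + 1, rate = alpha)
  rates <- k * diff(cdf1)
  rates <- rates / mean(rates)        # exact unit mean
  list(rates = rates, probs = rep(1 / k, k))
}

#' Transition probability matrix P(t) = exp(Q t r)
#'
#' @param model A \code{subst_model}.
#' @param t Branch length (expected substitutions per site at rate 1).
#' @param rate Rate multiplier (e.g. a gamma category rate).
#' @return Row-stochastic 20x20 matrix.
#' @export
transition_matrix <- function(model, t, rate = 1) {
  if (t < 0) stop("branch length must be >= 0")
  P <- model$eig$C1 %*% (exp(model$eig$values * (t * rate)) * model$eig$C2)
  P[P < 0] <- 0                        # clip eigen round-off
  dimnames(P) <- list(AA20, AA20)
  P
}
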