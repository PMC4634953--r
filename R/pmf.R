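## MALDI peptide-mass-fingerprint comparison: top-n peak selection and
## tolerance-based one-to-one shared-peak counting.

#' Construct a MALDI peak list
#'
#' @param mz Numeric vector of m/z values.
#' @param intensity Non-negative intensities, same length.
#' @param instrument_range m/z acquisition window; peaks outside it are
#'   dropped with a warning.
#' @return A \code{peaklist}: data.frame (mz, intensity) sorted ascending
#'   by m/z with an \code{instrument_range} attribute.
#' @export
peaklist <- function(mz, intensity, instrument_range = c(700, 3700)) {
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  keep <- mz >= instrument_range[1] & mz <= instrument_range[2]
  if (any(!keep))
    warning(sum(!keep), " peak(s) outside the instrument range dropped")
  o <- order(mz[keep])
  out <- data.frame(mz = mz[keep][o], intensity = intensity[keep][o])
  attr(out, "instrument_range") <- instrument_range
  class(out) <- c("peaklist", "data.frame")
  out
}

#' Most intense peaks of a fingerprint
#'
#' Selects the \code{n} highest-intensity peaks (all peaks, with a warning,
#' if fewer are available) and returns them re-sorted by m/z. Intensity
#' ties at the cutoff are broken deterministically in favour of the lower
#' m/z.
#'
#' @param pl A \code{peaklist}.
#' @param n Number of peaks to keep (default 100).
#' @return A \code{peaklist} of at most \code{n} peaks.
#' @export
top_n_peaks <- function(pl, n = 100L) {
  if (n < 1) stop("n must be >= 1")
  if (nrow(pl) == 0L) stop("empty peak list")
  if (nrow(pl) < n) {
    warning("only ", nrow(pl), " peaks available (n = ", n, ")")
    n <- nrow(pl)
  }
  o <- order(-pl$intensity, pl$mz)
  peaklist(pl$mz[o[seq_len(n)]], pl$intensity[o[seq_len(n)]],
           attr(pl, "instrument_range"))
}

#' Shared peaks between two fingerprints
#'
#' Size of a one-to-one matching between the two peak lists in which
#' matched peaks differ by at most \code{tol}. Pairs are matched greedily
#' by ascending m/z distance, so no peak can be counted twice and the
#' statistic is symmetric in its arguments.
#'
#' @param a,b \code{peaklist} objects (typically [top_n_peaks()] output).
#' @param tol Match tolerance. Interpreted in Da when \code{ppm = FALSE}
#'   (default 0.2 Da, a conventional externally calibrated PMF window), or
#'   in parts-per-million of the mean pair m/z when \code{ppm = TRUE}.
#' @param ppm Logical; use relative (ppm) tolerance.
#' @return Integer count of shared peaks.
#' @export
shared_peak_count <- function(a, b, tol = 0.2, ppm = FALSE) {
  if (tol <= 0) stop("tol must be positive")
  if (nrow(a) == 0L || nrow(b) == 0L) return(0L)
  d <- abs(outer(a$mz, b$mz, "-"))
  lim <- if (ppm) outer(a$mz, b$mz, function(x, y) (x + y) / 2 * tol * 1e-6)
         else tol
  ok <- which(d <= lim, arr.ind = TRUE)
  if (!nrow(ok)) return(0L)
  ## greedy one-to-one by ascending distance; deterministic tie-break on m/z
  o <- order(d[ok], a$mz[ok[, 1]], b$mz[ok[, 2]])
  ok <- ok[o, , drop = FALSE]
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  count <- 0L
  for (i in seq_len(nrow(ok))) {
    ia <- ok[i, 1]; ib <- ok[i, 2]
    if (!used_a[ia] && !used_b[ib]) {
      used_a[ia] <- TRUE; used_b[ib] <- TRUE
      count <- count + 1L
    }
  }
  count
}

#' Pairwise shared-peak matrix
#'
#' Applies [top_n_peaks()] to every fingerprint and counts shared peaks for
#' all unordered pairs. The diagonal holds \code{min(n, peaks available)},
#' i.e. the self-comparison count.
#'
#' @param peaklists Named list of \code{peaklist} objects (>= 1 taxa).
#' @param n Top-peak count passed to [top_n_peaks()].
#' @param tol,ppm Matching tolerance, see [shared_peak_count()].
#' @return Symmetric integer matrix with taxon dimnames.
#' @export
pairwise_shared_matrix <- function(peaklists, n = 100L, tol = 0.2,
                                   ppm = FALSE) {
  if (is.null(names(peaklists)) || anyDuplicated(names(peaklists)))
    stop("peaklists must be a uniquely named list")
  tops <- lapply(peaklists, function(pl)
    suppressWarnings(top_n_peaks(pl, n)))
  k <- length(tops)
  m <- matrix(0L, k, k, dimnames = list(names(tops), names(tops)))
  diag(m) <- vapply(tops, nrow, integer(1))
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      m[i, j] <- m[j, i] <- shared_peak_count(tops[[i]], tops[[j]], tol, ppm)
    }
  }
  m
}
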