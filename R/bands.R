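#' Frequency band scheme
#'
#' The analysis bands used throughout the feature battery.  The default
#' follows the conventional neonatal scheme delta 1-4, theta 4-7, alpha
#' 7-13, beta 13-30 Hz; `scheme = "narrow"` selects the alternative
#' delta 0.5-3 / theta 4-7 / alpha 8-12 / beta 13-30 Hz convention.  Range
#' EEG is computed on 1-20 Hz and fractal dimension on 1-30 Hz in either
#' scheme.  Band interiors must be ordered and non-overlapping; membership
#' of a frequency bin f in band (lo, hi) is `lo < f <= hi`.
#'
#' @param scheme `"default"` or `"narrow"`, or ignored when explicit band
#'   edges are supplied.
#' @param delta,theta,alpha,beta numeric length-2 `(lo, hi)` in Hz.
#' @param reeg_band,fd_band bands for range-EEG and fractal dimension.
#' @return list of class `band_scheme`.
#' @export
band_scheme <- function(scheme = c("default", "narrow"),
                        delta = NULL, theta = NULL, alpha = NULL,
                        beta = NULL, reeg_band = c(1, 20),
                        fd_band = c(1, 30)) {
  scheme <- match.arg(scheme)
  base <- if (scheme == "default")
    list(delta = c(1, 4), theta = c(4, 7), alpha = c(7, 13),
         beta = c(13, 30))
  else
    list(delta = c(0.5, 3), theta = c(4, 7), alpha = c(8, 12),
         beta = c(13, 30))
  if (!is.null(delta)) base$delta <- delta
  if (!is.null(theta)) base$theta <- theta
  if (!is.null(alpha)) base$alpha <- alpha
  if (!is.null(beta))  base$beta  <- beta
  edges <- do.call(rbind, base)
  if (any(edges[, 2] <= edges[, 1]) ||
      any(diff(as.vector(t(edges))) < -1e-9))
    stop("bands must be ordered with non-overlapping interiors")
  structure(c(base, list(reeg_band = reeg_band, fd_band = fd_band)),
            class = "band_scheme")
}

BAND_NAMES <- c("delta", "theta", "alpha", "beta")

band_bins <- function(freqs, band) which(freqs > band[1] & freqs <= band[2])
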