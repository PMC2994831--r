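#' Canonical double-gamma hemodynamic response function
#'
#' Samples the canonical HRF — the difference of two gamma densities with the
#' conventional parameters (response peak at 6 s, undershoot peak at 16 s,
#' dispersions of 1 s, undershoot-to-peak ratio 1/6) — on a regular grid and
#' rescales it to unit peak amplitude.
#'
#' @param tr_seconds sampling interval in seconds (the repetition time).
#' @param duration_seconds length of the sampled kernel in seconds.
#' @return numeric vector of `duration_seconds / tr_seconds` samples taken at
#'   t = 0, tr, 2 tr, ...; the maximum value is 1.
#' @examples
#' h <- canonical_hrf(2, 32)
#' plot(seq(0, by = 2, length.out = length(h)), h, type = "b")
#' @export
canonical_hrf <- function(tr_seconds, duration_seconds = 32) {
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    stop("'tr_seconds' must be a positive scalar")
  if (!is.numeric(duration_seconds) || length(duration_seconds) != 1L ||
      duration_seconds <= 0)
    stop("'duration_seconds' must be a positive scalar")
  t <- seq(0, duration_seconds - tr_seconds / 2, by = tr_seconds)
  h <- hrf_density(t)
  h / max(h)
}

# Unnormalized double-gamma HRF evaluated at times t (seconds).
# Shape/rate parameterization: peak delay 6 s, undershoot delay 16 s,
# dispersion 1 s each, undershoot ratio 1/6.
hrf_density <- function(t) {
  stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
}
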