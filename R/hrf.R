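#' Canonical haemodynamic response function
#'
#' Double-gamma impulse response: a gamma response peaking about 5 s after
#' the event minus a later undershoot (response delay 6 s, undershoot delay
#' 16 s, unit dispersions, undershoot ratio 1/6), sampled on a regular grid
#' and rescaled to unit peak amplitude.
#'
#' @param sample_dt Sampling interval in seconds (0 < sample_dt <= 2).
#' @param length Kernel support in seconds (default 32; the kernel has
#'   decayed to well under 1 percent of its peak by then).
#' @return Numeric vector of kernel values at `seq(0, length, by = sample_dt)`,
#'   with attribute `"time"` holding the sample times.
#' @examples
#' h <- canonical_hrf(0.1)
#' attr(h, "time")[which.max(h)]  # peak near 5 s
#' @export
canonical_hrf <- function(sample_dt, length = 32) {
  stopifnot(is.numeric(sample_dt), length(sample_dt) == 1L,
            sample_dt > 0, sample_dt <= 2)
  tt <- seq(0, length, by = sample_dt)
  h <- .double_gamma(tt)
  h <- h / max(h)
  attr(h, "time") <- tt
  h
}

.double_gamma <- function(t) {
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- stats::dgamma(t[pos], shape = 6, rate = 1) -
    stats::dgamma(t[pos], shape = 16, rate = 1) / 6
  out
}

#' Temporal-derivative basis kernel
#'
#' Shift-difference derivative of the canonical kernel: the canonical
#' response minus the same response delayed by 1 s, divided by the 1 s
#' shift.  The kernel has a positive lobe followed by a negative lobe and
#' integrates to approximately zero.
#'
#' The kernel is then multiplied by `max_shift * slope / 2` (= 2.759 for
#' the default sigmoidal latency transform, see [latency_transform()]).
#' For a response shifted by a small delta the least-squares
#' derivative-to-canonical beta ratio is then `-2 * delta /
#' (max_shift * slope)`, exactly the value the sigmoid maps back to
#' `delta`: this scaling makes latency recovery first-order unbiased and
#' is the pairing convention the transform's constants are calibrated
#' for.
#'
#' @param canonical Kernel returned by [canonical_hrf()].
#' @param sample_dt Sampling interval used for `canonical`, in seconds.
#' @param max_shift,slope Constants of the latency transform the basis
#'   is paired with (defaults 1.78 s and 3.1).
#' @return Numeric vector on the same grid, attribute `"time"` as for
#'   [canonical_hrf()].
#' @export
hrf_derivative <- function(canonical, sample_dt, max_shift = 1.78,
                           slope = 3.1) {
  tt <- attr(canonical, "time")
  if (is.null(tt)) tt <- (seq_along(canonical) - 1) * sample_dt
  pk <- max(.double_gamma(tt))
  h <- .double_gamma(tt) / pk
  hlag <- .double_gamma(tt - 1) / pk
  d <- (h - hlag) / 1.0
  d <- d * (max_shift * slope / 2)
  attr(d, "time") <- tt
  d
}

#' HRF basis pair (canonical + temporal derivative)
#'
#' @param sample_dt Sampling interval in seconds.
#' @param length Kernel support in seconds.
#' @return Object of class `hrf_basis`: list with elements `canonical`,
#'   `derivative`, `time`, `sample_dt`, `length`.
#' @export
hrf_basis <- function(sample_dt, length = 32) {
  h <- canonical_hrf(sample_dt, length)
  d <- hrf_derivative(h, sample_dt)
  structure(list(canonical = as.numeric(h), derivative = as.numeric(d),
                 time = attr(h, "time"), sample_dt = sample_dt,
                 length = length),
            class = "hrf_basis")
}

#' @export
print.hrf_basis <- function(x, ...) {
  cat(sprintf("HRF basis: canonical + 1 s shift-difference derivative\n"))
  cat(sprintf("  sample_dt = %g s, support = %g s, peak at %.2f s\n",
              x$sample_dt, x$length, x$time[which.max(x$canonical)]))
  invisible(x)
}
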