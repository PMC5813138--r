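#' Sigmoidal BOLD latency transform
#'
#' Parameters of the bounded sigmoidal map from the
#' derivative-to-canonical beta ratio to onset latency in seconds:
#'
#'   latency = 2 * max_shift / (1 + exp(slope * beta2 / beta1)) - max_shift
#'
#' with `max_shift = 1.78` s and `slope = 3.1`.  The output lies strictly
#' inside (-1.78, +1.78) for finite ratios, equals 0 at ratio 0, and is
#' monotone decreasing in the ratio: a positive ratio means the response
#' leads the canonical shape (negative latency, earlier onset).
#'
#' @param max_shift Saturation bound in seconds (default 1.78).
#' @param slope Sigmoid slope (default 3.1).
#' @param stability_threshold Minimum |t| of the canonical beta for a
#'   voxel's ratio to be considered stable (default 1.65, one-sided
#'   p ~= 0.05); used by [latency_map()].
#' @return Object of class `latency_transform`.
#' @export
latency_transform <- function(max_shift = 1.78, slope = 3.1,
                              stability_threshold = 1.65) {
  stopifnot(max_shift > 0, slope > 0, stability_threshold >= 0)
  structure(list(max_shift = max_shift, slope = slope,
                 stability_threshold = stability_threshold),
            class = "latency_transform")
}

#' BOLD latency from a pair of beta estimates
#'
#' Vectorised evaluation of the sigmoidal transform.  `beta1 = 0` (or
#' non-finite input) yields `NA`, never infinity; the transform depends
#' only on the ratio, so deactivations (negative `beta1`) are mapped
#' as-is.
#'
#' @param beta1 Canonical-HRF beta estimate(s).
#' @param beta2 Temporal-derivative beta estimate(s).
#' @param transform A [latency_transform()].
#' @return Latency in seconds, same length as the inputs.
#' @examples
#' latency_from_betas(1, 0)   # 0
#' latency_from_betas(1, 1)   # -1.6265
#' @export
latency_from_betas <- function(beta1, beta2, transform = latency_transform()) {
  r <- beta2 / beta1
  out <- 2 * transform$max_shift / (1 + exp(transform$slope * r)) -
    transform$max_shift
  out[!is.finite(beta1) | !is.finite(beta2) | beta1 == 0] <- NA_real_
  # exp overflow for very large ratios: the limit is the (open) bound
  big <- is.finite(r) & beta1 != 0 & !is.finite(exp(transform$slope * r))
  out[big] <- -transform$max_shift
  out
}

#' Voxelwise latency map for one condition
#'
#' Applies [latency_from_betas()] to a fitted condition's basis pair,
#' keeping only voxels whose canonical beta is stable
#' (|beta1 / se1| >= `stability_threshold`).  Invalid voxels are `NA`,
#' never 0.
#'
#' @param fit A `bold_glm`.
#' @param condition Condition label.
#' @param transform A [latency_transform()].
#' @return Object of class `latency_map`: list with `values` (vector, or
#'   3-D array when the fit has spatial dims; `NA` where invalid),
#'   `valid_mask` (logical, same shape), `condition`, `transform`.
#' @export
latency_map <- function(fit, condition, transform = latency_transform()) {
  stopifnot(inherits(fit, "bold_glm"))
  cb <- condition_betas(fit, condition)
  tstat <- cb$beta1 / cb$se1
  valid <- fit$mask & is.finite(tstat) &
    abs(tstat) >= transform$stability_threshold
  vals <- rep(NA_real_, length(cb$beta1))
  vals[valid] <- latency_from_betas(cb$beta1[valid], cb$beta2[valid],
                                    transform)
  valid <- valid & !is.na(vals)
  if (!is.null(fit$dims)) {
    vals <- array(vals, dim = fit$dims)
    valid <- array(valid, dim = fit$dims)
  }
  structure(list(values = vals, valid_mask = valid, condition = condition,
                 transform = transform),
            class = "latency_map")
}

#' @export
print.latency_map <- function(x, ...) {
  v <- x$values[x$valid_mask]
  cat(sprintf("Latency map (%s): %d valid voxels", x$condition, length(v)))
  if (length(v))
    cat(sprintf(", mean %.3f s, range [%.3f, %.3f] s", mean(v),
                min(v), max(v)))
  cat("\n")
  invisible(x)
}

#' Write a latency map as NIfTI (NaN-coded invalid voxels)
#' @param map A [latency_map()] result with spatial dims.
#' @param path Output file.
#' @export
write_latency_map <- function(map, path) {
  stopifnot(is.array(map$values))
  RNifti::writeNifti(RNifti::asNifti(map$values), path)
  invisible(path)
}
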