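#' Fit the prewhitened GLM to one run
#'
#' Two-stage estimation in the SPM style: ordinary least squares first,
#' then a single AR(1) coefficient pooled over in-mask voxels (lag-1
#' autocorrelation of the OLS residuals), then generalised least squares
#' by AR(1) prewhitening of both data and design.  Each voxel's time
#' series is scaled to percent signal change (divided by its temporal
#' mean, times 100) before fitting, so betas are in percent-signal units.
#'
#' Voxels with zero temporal mean or zero variance are masked out (betas
#' `NA` there), not an error.
#'
#' @param run A `bold_run` (from [simulate_run()] or [read_bold_run()]),
#'   or a volumes x voxels numeric matrix.
#' @param design A [build_design()] result with rows matching the run.
#' @param mask Optional logical vector/array selecting voxels to fit.
#' @param keep_residuals Store the whitened residual matrix (volumes x
#'   in-mask voxels) for diagnostics?  Off by default to save memory.
#' @param ar1_rho Optional fixed AR(1) coefficient, bypassing the pooled
#'   estimate (0 reduces GLS to OLS exactly).
#' @return Object of class `bold_glm`: `beta` and `beta_se`
#'   (regressors x voxels, `NA` outside the mask), `ar1_rho`,
#'   `residual_var`, `dof`, `mask` (logical), `design`, `dims` (spatial
#'   dims, or `NULL` for matrix input), `n_runs = 1`.
#' @export
fit_glm <- function(run, design, mask = NULL, keep_residuals = FALSE,
                    ar1_rho = NULL) {
  stopifnot(inherits(design, "design_matrix"))
  dims <- NULL
  if (inherits(run, "bold_run")) {
    dims <- dim(run$data)[1:3]
    nv <- dim(run$data)[4]
    Y <- matrix(run$data, nrow = prod(dims), ncol = nv)
    Y <- t(Y)                      # volumes x voxels
  } else {
    Y <- as.matrix(run)
    nv <- nrow(Y)
  }
  X <- design$matrix
  if (nrow(X) != nv) stop("design rows must equal run volumes")
  V <- ncol(Y)
  mu <- colMeans(Y)
  vr <- apply(Y, 2, stats::var)
  ok <- is.finite(mu) & mu > 0 & vr > 0
  if (!is.null(mask)) ok <- ok & as.logical(mask)
  if (!any(ok)) stop("no usable voxels")

  Yp <- sweep(Y[, ok, drop = FALSE], 2, mu[ok], "/") * 100

  if (is.null(ar1_rho)) {
    qx <- qr(X)
    B0 <- qr.coef(qx, Yp)
    R0 <- Yp - X %*% B0
    # pooled AR(1): lag-1 autocorrelation averaged over voxels
    num <- colSums(R0[-1, , drop = FALSE] * R0[-nv, , drop = FALSE])
    den <- colSums(R0^2)
    usable <- den > .Machine$double.eps * nv
    rho <- if (any(usable)) mean(num[usable] / den[usable]) else 0
    rho <- max(min(rho, 0.95), -0.95)
  } else {
    rho <- ar1_rho
    stopifnot(abs(rho) < 1)
  }

  W <- function(M) {
    M2 <- M
    M2[1, ] <- sqrt(1 - rho^2) * M[1, ]
    M2[-1, ] <- M[-1, , drop = FALSE] - rho * M[-nv, , drop = FALSE]
    M2
  }
  Xw <- W(X); Yw <- W(Yp)
  qw <- qr(Xw)
  B <- qr.coef(qw, Yw)
  Rw <- Yw - Xw %*% B
  p <- qw$rank
  dof <- nv - p
  s2 <- colSums(Rw^2) / dof
  XtXinv <- chol2inv(qr.R(qw))
  se <- sqrt(outer(diag(XtXinv), s2))

  beta <- matrix(NA_real_, ncol(X), V,
                 dimnames = list(colnames(X), NULL))
  beta_se <- beta; resvar <- rep(NA_real_, V)
  beta[, ok] <- B
  beta_se[, ok] <- se
  resvar[ok] <- s2

  out <- structure(list(beta = beta, beta_se = beta_se, ar1_rho = rho,
                        residual_var = resvar, dof = dof, mask = ok,
                        design = design, dims = dims, n_runs = 1L),
                   class = "bold_glm")
  if (keep_residuals) attr(out, "resid") <- Rw
  out
}

#' @export
print.bold_glm <- function(x, ...) {
  cat(sprintf("BOLD GLM fit: %d regressors x %d voxels (%d in mask)\n",
              nrow(x$beta), ncol(x$beta), sum(x$mask)))
  cat(sprintf("  pooled AR(1) rho = %.3f, dof = %g, runs combined = %d\n",
              x$ar1_rho, x$dof, x$n_runs))
  invisible(x)
}

#' @export
coef.bold_glm <- function(object, ...) object$beta

#' @export
residuals.bold_glm <- function(object, ...) {
  r <- attr(object, "resid")
  if (is.null(r))
    stop("refit with keep_residuals = TRUE to retain residuals")
  r
}

#' @export
summary.bold_glm <- function(object, ...) {
  b <- rowMeans(object$beta[, object$mask, drop = FALSE])
  s <- rowMeans(object$beta_se[, object$mask, drop = FALSE])
  out <- data.frame(regressor = rownames(object$beta),
                    mean_beta = b, mean_se = s, row.names = NULL)
  class(out) <- c("summary.bold_glm", "data.frame")
  out
}

#' Combine per-run fits into a subject-level fit
#'
#' Unweighted mean of the per-run beta maps over the regressors the runs
#' share (equal session weighting); degrees of freedom are summed and the
#' standard errors propagated as for a mean of independent estimates.
#'
#' @param fits List of `bold_glm` objects for one subject's retained runs.
#' @return A `bold_glm` with `n_runs = length(fits)`.
#' @export
combine_runs <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "bold_glm")))
  if (length(fits) == 1L) return(fits[[1]])
  common <- Reduce(intersect, lapply(fits, function(f) rownames(f$beta)))
  if (!length(common)) stop("runs share no regressors")
  k <- length(fits)
  B <- Reduce(`+`, lapply(fits, function(f) f$beta[common, , drop = FALSE])) / k
  SE <- sqrt(Reduce(`+`, lapply(fits, function(f)
    f$beta_se[common, , drop = FALSE]^2))) / k
  mask <- Reduce(`&`, lapply(fits, function(f) f$mask))
  B[, !mask] <- NA_real_; SE[, !mask] <- NA_real_
  structure(list(beta = B, beta_se = SE,
                 ar1_rho = mean(vapply(fits, `[[`, 0, "ar1_rho")),
                 residual_var = Reduce(`+`, lapply(fits, `[[`, "residual_var")) / k,
                 dof = sum(vapply(fits, `[[`, 0, "dof")),
                 mask = mask, design = fits[[1]]$design,
                 dims = fits[[1]]$dims, n_runs = k),
            class = "bold_glm")
}

#' Beta and SE maps for one condition's basis pair
#'
#' @param fit A `bold_glm`.
#' @param condition Condition label present in the fit's design.
#' @return List with vectors `beta1`, `beta2`, `se1` (canonical beta,
#'   derivative beta, canonical SE) over all voxels.
#' @export
condition_betas <- function(fit, condition) {
  rn <- rownames(fit$beta)
  c1 <- condition; c2 <- paste0(condition, "_deriv")
  if (!(c1 %in% rn) || !(c2 %in% rn))
    stop("condition '", condition, "' not present in fit")
  list(beta1 = fit$beta[c1, ], beta2 = fit$beta[c2, ],
       se1 = fit$beta_se[c1, ])
}

#' Write beta maps of a fit as NIfTI
#'
#' One 3-D volume per regressor; only meaningful for fits of `bold_run`
#' input (spatial dims known).
#'
#' @param fit A `bold_glm` with `dims` set.
#' @param dir Output directory.
#' @param prefix File prefix.
#' @export
write_beta_maps <- function(fit, dir, prefix = "beta") {
  stopifnot(!is.null(fit$dims))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rn in rownames(fit$beta)) {
    a <- array(fit$beta[rn, ], dim = fit$dims)
    RNifti::writeNifti(RNifti::asNifti(a),
                       file.path(dir, paste0(prefix, "_", rn, ".nii")))
  }
  invisible(dir)
}
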