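#' Discrete-cosine high-pass basis
#'
#' DCT regressors spanning fluctuations slower than `cutoff` seconds;
#' the number of functions is `floor(2 * n * tr / cutoff)` (the constant
#' term is kept separate in the design).
#'
#' @param n Number of volumes.
#' @param tr Repetition time in seconds.
#' @param cutoff High-pass cutoff in seconds (default 128).
#' @return Matrix n x K (K possibly 0) with columns `hp1..hpK`.
#' @export
dct_basis <- function(n, tr, cutoff = 128) {
  K <- floor(2 * n * tr / cutoff)
  if (K < 1) return(matrix(0, n, 0))
  t0 <- seq_len(n) - 1
  X <- sapply(seq_len(K), function(k) cos(pi * k * (2 * t0 + 1) / (2 * n)))
  X <- matrix(X, nrow = n)
  colnames(X) <- paste0("hp", seq_len(K))
  X
}

#' Build the event-related design matrix
#'
#' Impulse regressors for cues (pooled), each correct-target condition and
#' error trials (missed or incorrect targets pooled), each convolved with
#' the canonical HRF and its temporal derivative on an oversampled grid
#' (dt = tr/16) and sampled at volume acquisition times.  Optional
#' reaction-time parametric modulators: per condition, impulses of height
#' RT in seconds mean-centred within condition within run, convolved with
#' the canonical kernel only.  Nuisance block: six motion parameters, the
#' 128 s discrete-cosine high-pass set, and a constant.
#'
#' Condition column pairs with no events, and zero-variance modulator
#' columns, are dropped (recorded in `$dropped`).  A run with no correct
#' target at all is an error.
#'
#' @param events An [event_table()].
#' @param n_volumes Number of acquired volumes.
#' @param tr Repetition time, seconds.
#' @param motion Optional volumes x 6 motion matrix.
#' @param include_modulators Add per-condition RT modulators?
#' @param hp_cutoff High-pass cutoff in seconds (default 128).
#' @param basis Optional precomputed [hrf_basis()] at `tr/16` sampling.
#' @return Object of class `design_matrix`: list with `matrix`,
#'   `column_names`, `basis_pairs` (condition -> c(canonical, derivative)
#'   column indices), `modulator_columns`, `nuisance_columns`, `dropped`,
#'   `tr`.
#' @export
build_design <- function(events, n_volumes, tr, motion = NULL,
                         include_modulators = FALSE, hp_cutoff = 128,
                         basis = NULL) {
  stopifnot(inherits(events, "data.frame"), n_volumes >= 2, tr > 0)
  os <- 16L; dt <- tr / os; ng <- n_volumes * os
  if (is.null(basis)) basis <- hrf_basis(dt)
  stopifnot(abs(basis$sample_dt - dt) < 1e-12)
  keep <- seq(1L, ng, by = os)
  if (max(events$onset) >= n_volumes * tr)
    stop("events extend beyond the run")

  tgt <- events$trial_type %in% event_conditions()
  correct <- tgt & !is.na(events$accuracy) & events$accuracy == 1
  errors <- tgt & !is.na(events$accuracy) & events$accuracy == 0
  if (!any(correct))
    stop("no correct target responses in this run; design is unusable")

  stick <- function(onsets, heights = 1) {
    s <- numeric(ng)
    j <- round(onsets / dt) + 1L
    ok <- j >= 1L & j <= ng
    s[j[ok]] <- s[j[ok]] + rep_len(heights, length(onsets))[ok]
    s
  }
  conv_pair <- function(s) {
    cbind(.conv_sample(s, basis$canonical)[keep],
          .conv_sample(s, basis$derivative)[keep])
  }

  cols <- list(); pairs <- list(); mods <- list(); dropped <- character(0)
  add_pair <- function(name, onsets) {
    if (!length(onsets)) { dropped <<- c(dropped, name); return(invisible()) }
    xy <- conv_pair(stick(onsets))
    cols[[name]] <<- xy[, 1]; cols[[paste0(name, "_deriv")]] <<- xy[, 2]
    pairs[[name]] <<- c(paste0(name, ""), paste0(name, "_deriv"))
  }
  add_pair("cue", events$onset[events$trial_type == "cue"])
  for (cnd in event_conditions())
    add_pair(cnd, events$onset[correct & events$trial_type == cnd])
  add_pair("error_trials", events$onset[errors])

  if (include_modulators) {
    for (cnd in event_conditions()) {
      i <- which(correct & events$trial_type == cnd)
      if (!length(i)) next
      rt_s <- events$response_time[i] / 1000
      h <- rt_s - mean(rt_s)
      if (all(abs(h) < 1e-12)) {
        dropped <- c(dropped, paste0(cnd, "_rt")); next
      }
      m <- .conv_sample(stick(events$onset[i], h), basis$canonical)[keep]
      cols[[paste0(cnd, "_rt")]] <- m
      mods[[cnd]] <- paste0(cnd, "_rt")
    }
  }

  X <- do.call(cbind, cols)
  nuis <- NULL
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    stopifnot(nrow(motion) == n_volumes, ncol(motion) == 6)
    colnames(motion) <- paste0("motion", 1:6)
    nuis <- motion
  }
  hp <- dct_basis(n_volumes, tr, hp_cutoff)
  nuis <- cbind(nuis, hp, constant = rep(1, n_volumes))
  Xfull <- cbind(X, nuis)
  colnames(Xfull) <- c(names(cols), colnames(nuis))

  qrX <- qr(Xfull)
  if (qrX$rank < ncol(Xfull))
    stop("design matrix is rank deficient after dropping empty columns")

  cn <- colnames(Xfull)
  structure(list(
    matrix = Xfull, column_names = cn,
    basis_pairs = lapply(pairs, function(p) match(p, cn)),
    modulator_columns = lapply(mods, function(m) match(m, cn)),
    nuisance_columns = match(colnames(nuis), cn),
    dropped = dropped, tr = tr, n_volumes = n_volumes),
    class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("Design matrix: %d volumes x %d regressors (TR %g s)\n",
              nrow(x$matrix), ncol(x$matrix), x$tr))
  cat("  basis pairs:", paste(names(x$basis_pairs), collapse = ", "), "\n")
  if (length(x$modulator_columns))
    cat("  RT modulators:", paste(names(x$modulator_columns), collapse = ", "), "\n")
  if (length(x$dropped))
    cat("  dropped (empty):", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Write a design matrix as TSV
#' @param design A [build_design()] result.
#' @param path Output file.
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(design$matrix, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
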