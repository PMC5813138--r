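#' Mean of a statistic map over each ROI
#'
#' Unweighted mean over the valid (non-`NA`) in-mask voxels of each
#' region; a region with no valid voxel yields `NA`.
#'
#' @param map 3-D numeric array (e.g. a beta map or [latency_map()]
#'   `$values`), or a plain vector matching the label array length.
#' @param masks A [make_roi_masks()] result on the same grid.
#' @return Named numeric vector, one value per region.
#' @export
extract_roi_means <- function(map, masks) {
  stopifnot(inherits(masks, "roi_mask_set"))
  if (is.array(map) && !all(dim(map) == masks$grid_shape))
    stop("map and masks are on different grids")
  v <- as.numeric(map)
  if (length(v) != prod(masks$grid_shape))
    stop("map and masks are on different grids")
  lab <- as.integer(masks$labels)
  out <- vapply(seq_along(masks$names), function(i) {
    x <- v[lab == i]
    x <- x[!is.na(x)]
    if (length(x)) mean(x) else NA_real_
  }, numeric(1))
  names(out) <- masks$names
  out
}

#' Behavioural RT contrasts for one subject
#'
#' From the correct target trials pooled over the subject's retained
#' runs: the executive effect (mean of the easy- and hard-incongruent
#' condition mean RTs minus the congruent mean RT) and the conflict
#' effect (hard minus easy incongruent mean RT), both in milliseconds.
#'
#' @param events_list List of [event_table()]s (one per retained run), or
#'   a single event table.
#' @return List: `executive_effect`, `conflict_effect`, `condition_means`
#'   (named, ms).  A condition with no correct trial gives `NA` contrasts
#'   involving it, with a `"reason"` attribute.
#' @export
behavioral_contrasts <- function(events_list) {
  if (inherits(events_list, "data.frame")) events_list <- list(events_list)
  ev <- do.call(rbind, lapply(events_list, as.data.frame))
  ok <- ev$trial_type %in% event_conditions() &
    !is.na(ev$accuracy) & ev$accuracy == 1
  m <- vapply(event_conditions(), function(cnd) {
    x <- ev$response_time[ok & ev$trial_type == cnd]
    if (length(x)) mean(x) else NA_real_
  }, numeric(1))
  out <- list(
    executive_effect = mean(m[c("easy_incongruent", "hard_incongruent")]) -
      m["congruent"],
    conflict_effect = m["hard_incongruent"] - m["easy_incongruent"],
    condition_means = m)
  out$executive_effect <- unname(out$executive_effect)
  out$conflict_effect <- unname(out$conflict_effect)
  if (anyNA(m))
    attr(out, "reason") <- paste("no correct trials in:",
                                 paste(names(m)[is.na(m)], collapse = ", "))
  out
}

#' Subject-level ROI summary of magnitude and latency
#'
#' For one subject's (combined) fit: the ROI mean of the canonical beta
#' map (BOLD magnitude, percent signal) and the ROI mean of the
#' stability-masked voxelwise latency map (seconds), for every condition.
#'
#' @param fit A `bold_glm` with spatial dims.
#' @param masks A [make_roi_masks()] result.
#' @param transform A [latency_transform()].
#' @param conditions Conditions to summarise (default the three targets).
#' @return data.frame: roi, condition, bold_magnitude, bold_latency.
#' @export
summarize_subject <- function(fit, masks, transform = latency_transform(),
                              conditions = event_conditions()) {
  stopifnot(!is.null(fit$dims))
  rows <- list()
  for (cnd in conditions) {
    cb <- condition_betas(fit, cnd)
    magmap <- array(ifelse(fit$mask, cb$beta1, NA_real_), dim = fit$dims)
    lm_ <- latency_map(fit, cnd, transform)
    rows[[cnd]] <- data.frame(
      roi = masks$names, condition = cnd,
      bold_magnitude = unname(extract_roi_means(magmap, masks)),
      bold_latency = unname(extract_roi_means(lm_$values, masks)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble the long-format ROI summary table
#'
#' Binds per-subject summaries into the subject x group x roi x condition
#' table (long format, one row per measure) that feeds the group
#' statistics.
#'
#' @param per_subject Named list (by subject id) of [summarize_subject()]
#'   results, or of data.frames with the same columns.
#' @param groups Named character vector mapping subject id to
#'   `"control"`/`"patient"`.
#' @return data.frame with columns subject, group, roi, condition,
#'   measure (`"bold_magnitude"`/`"bold_latency"`), value.
#' @export
roi_summary_table <- function(per_subject, groups) {
  rows <- lapply(names(per_subject), function(s) {
    d <- per_subject[[s]]
    long <- rbind(
      data.frame(subject = s, group = unname(groups[s]), roi = d$roi,
                 condition = d$condition, measure = "bold_magnitude",
                 value = d$bold_magnitude, stringsAsFactors = FALSE),
      data.frame(subject = s, group = unname(groups[s]), roi = d$roi,
                 condition = d$condition, measure = "bold_latency",
                 value = d$bold_latency, stringsAsFactors = FALSE))
    long
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read the long-format summary TSV
#' @param table A [roi_summary_table()] result.
#' @param path File path.
#' @export
write_summary_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_tsv
#' @export
read_summary_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
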