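# --- individual-level screening verdicts ----------------------------------

#' Per-subject underestimation verdict
#'
#' Aggregates per-stride posterior-predictive inferences of one model to
#' subject level. A subject is flagged as consistently underestimated
#' when more than `ratio_threshold` of all pooled predictive samples fall
#' below the actual value AND the majority of its strides have a negative
#' mean Delta (predicted - actual).
#'
#' @param inferences [predict_strides()] output (one or many subjects).
#' @param ratio_threshold pooled-sample threshold (default 0.75).
#' @return data.frame, one row per subject: `subject_id`, `actual`,
#'   `n_strides`, `underestimation_count` (strides with mean Delta < 0),
#'   `underestimation_ratio` (pooled fraction of predictive samples below
#'   actual), `pred_mean_delta`, `pred_sd`, `consistent_underestimation`.
#' @export
subject_verdict <- function(inferences, ratio_threshold = 0.75) {
  stopifnot(nrow(inferences) >= 1)
  sp <- split(inferences, inferences$subject_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(
      subject_id = d$subject_id[1],
      actual = mean(d$actual),
      n_strides = nrow(d),
      underestimation_count = sum(d$delta_mean < 0),
      underestimation_ratio = mean(d$frac_below),
      pred_mean_delta = mean(d$delta_mean),
      pred_sd = mean(d$pred_sd))
  }))
  out$consistent_underestimation <-
    out$underestimation_ratio > ratio_threshold &
    out$underestimation_count > out$n_strides / 2
  rownames(out) <- NULL
  out[order(out$actual), ]
}

#' Grouped Delta distributions
#'
#' Per-group histograms of the per-stride mean prediction error, with
#' heights normalized within each group so that differently sized groups
#' are comparable, plus a summary table.
#'
#' @param inferences [predict_strides()] output.
#' @param grouping vector (same length as rows of `inferences`) assigning
#'   each stride to a group, e.g. the train/validation/test category.
#' @param breaks histogram breaks passed to [hist()] (default 20 bins
#'   over the pooled range).
#' @return list with `summary` (group, n, mean/sd of Delta) and `bins`
#'   (group, mid, density with per-group maximum height 1). Empty groups
#'   are omitted with a message.
#' @export
delta_histograms <- function(inferences, grouping, breaks = NULL) {
  grouping <- as.character(grouping)
  stopifnot(length(grouping) == nrow(inferences))
  keep <- !is.na(inferences$delta_mean)
  groups <- split(inferences$delta_mean[keep], grouping[keep])
  empty <- setdiff(unique(grouping), names(groups))
  if (length(empty))
    message("omitting empty group(s): ", paste(empty, collapse = ", "))
  if (is.null(breaks)) {
    rng <- range(unlist(groups))
    breaks <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = 21)
  }
  bins <- do.call(rbind, lapply(names(groups), function(g) {
    h <- graphics::hist(groups[[g]], breaks = breaks, plot = FALSE)
    dens <- if (max(h$counts) > 0) h$counts / max(h$counts) else h$counts
    data.frame(group = g, mid = h$mids, density = dens)
  }))
  summary <- do.call(rbind, lapply(names(groups), function(g)
    data.frame(group = g, n = length(groups[[g]]),
               delta_mean = mean(groups[[g]]),
               delta_sd = stats::sd(groups[[g]]))))
  list(summary = summary, bins = bins)
}
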