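# Hit selection: rank units on a per-unit metric and call "high"/"low"
# hits by robust median +/- k*SD thresholds recomputed per dataset.

#' Default SD multiples per metric
#'
#' The top threshold is median + 2 SD for every metric; the bottom
#' threshold is median - 0.5 SD for spread area, median - 1 SD for
#' roundness and median - 2 SD for the differentiated-cell percentage.
#'
#' @param metric Metric name.
#' @return `c(k_top, k_bottom)`.
#' @export
default_hit_k <- function(metric) {
  switch(metric,
         pct_pos = c(2, -2),
         avg_spread_area_pos = c(2, -0.5),
         mean_roundness_pos = c(2, -1),
         c(2, -2))
}

#' Call high/low hits on a unit metric
#'
#' Cutoffs are `median + k_top * SD` and `median + k_bottom * SD` over the
#' units with a defined metric value (SD is the sample standard deviation);
#' a unit is `high` iff its value strictly exceeds the top cutoff, `low`
#' iff strictly below the bottom cutoff, `mid` otherwise, and `excluded`
#' when the metric is undefined (e.g. shape metrics on units without
#' positive cells). Excluded units do not enter the median/SD.
#'
#' @param units Unit summary data.frame (from [summarize_units()]).
#' @param metric Column to rank on.
#' @param k_top,k_bottom SD multiples (defaults per [default_hit_k()]).
#' @param min_units Minimum number of units with a defined value.
#' @return A data.frame of class `hit_table`: the unit key columns, `value`
#'   and `label`, with attributes `metric`, `top_cutoff`, `bottom_cutoff`
#'   and `n_class`.
#' @export
select_hits <- function(units, metric,
                        k_top = default_hit_k(metric)[1],
                        k_bottom = default_hit_k(metric)[2],
                        min_units = 10) {
  if (!metric %in% names(units)) stopf("metric '%s' not in unit table", metric)
  if (k_top <= k_bottom) stopf("k_top must exceed k_bottom")
  v <- units[[metric]]
  ok <- is.finite(v)
  if (sum(ok) < min_units) {
    stopf("only %d units with a defined '%s' (need >= %d)",
          sum(ok), metric, min_units)
  }
  med <- stats::median(v[ok])
  sdev <- stats::sd(v[ok])
  if (sdev == 0) {
    warnf("select_hits: all '%s' values identical; no hits called", metric)
  }
  top <- med + k_top * sdev
  bottom <- med + k_bottom * sdev
  label <- rep("mid", nrow(units))
  label[!ok] <- "excluded"
  label[ok & v > top] <- "high"
  label[ok & v < bottom] <- "low"
  keep <- setdiff(names(units), c("value", "label"))
  out <- units[keep]
  out$value <- v
  out$label <- label
  structure(out, metric = metric, top_cutoff = top, bottom_cutoff = bottom,
            k_top = k_top, k_bottom = k_bottom,
            n_class = table(factor(label, c("high", "mid", "low", "excluded"))),
            class = c("hit_table", "data.frame"))
}

#' @export
print.hit_table <- function(x, ...) {
  n <- attr(x, "n_class")
  cat(sprintf("hit_table on '%s': top > %.4g, bottom < %.4g\n",
              attr(x, "metric"), attr(x, "top_cutoff"),
              attr(x, "bottom_cutoff")))
  cat(sprintf("  high %d, mid %d, low %d, excluded %d\n",
              n[["high"]], n[["mid"]], n[["low"]], n[["excluded"]]))
  invisible(x)
}

#' Build a binary design label table from hit calls
#'
#' Takes the `high` calls of one hit table and the `low` calls of another
#' (usually the same table) and joins duplicate units by `design_id`: a
#' design is `high`/`low` if either duplicate qualifies; a design that
#' qualifies for both classes is excluded with a warning.
#'
#' @param hits_high `hit_table` supplying the `high` calls (must carry a
#'   `design_id` column).
#' @param hits_low `hit_table` supplying the `low` calls over the same unit
#'   universe (defaults to `hits_high`).
#' @return A data.frame `design_id`, `label` restricted to hit designs;
#'   excluded conflicts are recorded in attribute `conflicts`.
#' @export
make_labels <- function(hits_high, hits_low = hits_high) {
  if (is.null(hits_high$design_id) || is.null(hits_low$design_id)) {
    stopf("hit tables must carry design_id")
  }
  high_ids <- unique(hits_high$design_id[hits_high$label == "high"])
  low_ids <- unique(hits_low$design_id[hits_low$label == "low"])
  conflict <- intersect(high_ids, low_ids)
  if (length(conflict)) {
    warnf("make_labels: %d design(s) qualify as both high and low; excluded",
          length(conflict))
    high_ids <- setdiff(high_ids, conflict)
    low_ids <- setdiff(low_ids, conflict)
  }
  out <- quick_df(list(
    design_id = c(high_ids, low_ids),
    label = c(rep("high", length(high_ids)), rep("low", length(low_ids)))))
  out <- out[order(out$design_id), , drop = FALSE]
  row.names(out) <- NULL
  attr(out, "conflicts") <- conflict
  out
}
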