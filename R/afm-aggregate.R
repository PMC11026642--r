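#' Aggregate per-curve results up the measurement hierarchy
#'
#' AFM sessions on tissue repeat indentations at each point, sample
#' several points per region and several regions per animal. Averaging
#' proceeds level by level — replicates to point, points to region,
#' regions to sample — and the group summary reports mean and standard
#' error with the animal (sample) as the unit of replication. Flagged
#' curves are excluded and counted in the QC report; a point, region or
#' sample whose curves are all flagged is dropped with a warning.
#'
#' @param results Tibble of per-curve rows (e.g. from
#'   [analyze_curve_batch()]) with hierarchy columns and a logical
#'   `flagged` column (absent = nothing flagged).
#' @param values Character vector of measurement columns to aggregate.
#' @param sample_col Name of the sample (animal) column; `NULL` when the
#'   batch is a single sample.
#' @param group_cols Grouping factors carried to the top level (e.g.
#'   `c("age", "volume")`); may be empty.
#' @return An `ecm_aggregate` list of tibbles `point`, `region`, `sample`,
#'   `group`, plus `qc` (curve counts). `tidy()` returns the group table.
#' @export
aggregate_hierarchy <- function(results,
                                values = c("E_Pa", "hysteresis_ratio",
                                           "F_adh_nN"),
                                sample_col = "sample_id",
                                group_cols = c("age", "volume")) {
  values <- intersect(values, names(results))
  if (!length(values)) abort("no measurement columns found to aggregate")
  if (!is.null(sample_col) && !sample_col %in% names(results))
    sample_col <- NULL
  group_cols <- intersect(group_cols, names(results))
  hier <- c(group_cols, sample_col, intersect(c("region", "point"),
                                              names(results)))

  n_total <- nrow(results)
  if ("flagged" %in% names(results)) {
    kept <- results[!results$flagged, ]
  } else kept <- results
  n_flagged <- n_total - nrow(kept)
  if (nrow(kept) == 0L) abort("all curves flagged; nothing to aggregate")
  dropped <- dplyr::anti_join(
    dplyr::distinct(results[hier]), dplyr::distinct(kept[hier]), by = hier)
  if (nrow(dropped))
    warn(sprintf("%d hierarchy unit(s) had only flagged curves and were dropped",
                 nrow(dropped)))

  mean_over <- function(d, by) {
    dplyr::summarise(dplyr::group_by(d, dplyr::across(dplyr::all_of(by))),
                     dplyr::across(dplyr::all_of(values),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
  }
  by_point <- mean_over(kept, hier)
  by_region <- mean_over(by_point, setdiff(hier, "point"))
  by_sample <- mean_over(by_region, setdiff(hier, c("point", "region")))

  grp <- dplyr::group_by(by_sample, dplyr::across(dplyr::all_of(group_cols)))
  by_group <- dplyr::summarise(
    grp,
    n = dplyr::n(),
    dplyr::across(dplyr::all_of(values),
                  list(mean = ~ mean(.x, na.rm = TRUE),
                       se = ~ if (dplyr::n() > 1)
                         sd(.x, na.rm = TRUE) / sqrt(dplyr::n())
                       else NA_real_),
                  .names = "{.col}_{.fn}"),
    .groups = "drop")

  structure(list(point = by_point, region = by_region, sample = by_sample,
                 group = by_group,
                 qc = list(n_curves = n_total, n_flagged = n_flagged,
                           n_units_dropped = nrow(dropped))),
            class = "ecm_aggregate")
}

#' @export
print.ecm_aggregate <- function(x, ...) {
  cat(sprintf("<ecm_aggregate> %d curves (%d flagged), %d samples, %d group(s)\n",
              x$qc$n_curves, x$qc$n_flagged, nrow(x$sample), nrow(x$group)))
  print(x$group)
  invisible(x)
}

#' @describeIn aggregate_hierarchy Group-level means and SEs as a tibble.
#' @param x An `ecm_aggregate`.
#' @param level Which level to return: `"group"`, `"sample"`, `"region"`
#'   or `"point"`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ecm_aggregate <- function(x, level = c("group", "sample", "region",
                                            "point"), ...) {
  level <- match.arg(level)
  x[[level]]
}
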