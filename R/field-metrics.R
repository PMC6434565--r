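# Field-data utilities: veliger larval density from aliquot counts and tow
# volumes, and paired comparisons of larval count series.
#
# A plankton tow concentrates ~190 L of filtered water into a 15 ml sample;
# veligers are counted in 500 ul aliquots under cross-polarised light. The
# per-sample total scales the mean aliquot count by sample volume / aliquot
# volume; density per litre divides by the filtered volume.

#' Veliger density from aliquot counts
#'
#' `per_sample = mean(aliquot_counts) * sample_volume_ml / aliquot_volume_ml`;
#' `per_liter = per_sample / filtered_volume_l`.
#'
#' @param aliquot_counts Non-negative veliger counts, one per aliquot
#'   (typically three).
#' @param aliquot_volume_ml Volume counted per aliquot (default 0.5 ml =
#'   500 ul).
#' @param sample_volume_ml Concentrated sample volume (default 15 ml).
#' @param filtered_volume_l Water volume filtered by the tow (default 190 L).
#' @return One-row tibble: `per_sample`, `per_liter`.
#' @export
veliger_density <- function(aliquot_counts, aliquot_volume_ml = 0.5,
                            sample_volume_ml = 15, filtered_volume_l = 190) {
  if (length(aliquot_counts) < 1) abort("need at least one aliquot count")
  if (any(aliquot_counts < 0)) abort("aliquot counts must be non-negative")
  if (aliquot_volume_ml <= 0 || sample_volume_ml <= 0) {
    abort("volumes must be positive")
  }
  if (filtered_volume_l <= 0) abort("filtered volume must be positive")
  per_sample <- mean(aliquot_counts) * sample_volume_ml / aliquot_volume_ml
  tibble(per_sample = per_sample, per_liter = per_sample / filtered_volume_l)
}

#' Density estimates for a table of tows
#'
#' Applies [veliger_density()] per row and, when several replicate tows
#' share a site/date, summarises the replicate densities as mean +/- SE
#' (standard error across replicates, the reporting convention for tow
#' series; within-tow aliquot spread stays in the per-row table).
#'
#' @param tows Tibble with list-column or comma-separated `aliquot_counts`
#'   (or numeric columns `aliquot1`, `aliquot2`, ...), plus optional
#'   `aliquot_volume_ml`, `sample_volume_ml`, `filtered_volume_l` columns
#'   overriding the defaults.
#' @param by Character vector of grouping columns for the replicate summary
#'   (default `c("site", "date")` intersected with available columns).
#' @return List with `per_tow` (row-wise densities) and `summary` (mean,
#'   `se`, `n` per group; `se` is `NA` for singleton groups).
#' @export
density_table <- function(tows, by = c("site", "date")) {
  counts <- extract_aliquots(tows)
  vol <- function(nm, default) {
    if (nm %in% names(tows)) tows[[nm]] else rep(default, nrow(tows))
  }
  av <- vol("aliquot_volume_ml", 0.5)
  sv <- vol("sample_volume_ml", 15)
  fv <- vol("filtered_volume_l", 190)
  per_tow <- purrr::map_dfr(seq_len(nrow(tows)), function(i) {
    veliger_density(counts[[i]], aliquot_volume_ml = av[i],
                    sample_volume_ml = sv[i], filtered_volume_l = fv[i])
  })
  per_tow <- dplyr::bind_cols(
    tows[, intersect(names(tows), c("site", "date", "replicate")), drop = FALSE],
    per_tow
  )
  by <- intersect(by, names(per_tow))
  summary <- if (length(by) > 0) {
    per_tow |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::summarise(
        mean_per_liter = mean(.data$per_liter),
        se = if (dplyr::n() > 1) sd(.data$per_liter) / sqrt(dplyr::n()) else NA_real_,
        n = dplyr::n(),
        .groups = "drop"
      )
  } else {
    tibble(
      mean_per_liter = mean(per_tow$per_liter),
      se = if (nrow(per_tow) > 1) sd(per_tow$per_liter) / sqrt(nrow(per_tow)) else NA_real_,
      n = nrow(per_tow)
    )
  }
  list(per_tow = per_tow, summary = summary)
}

extract_aliquots <- function(tows) {
  if ("aliquot_counts" %in% names(tows)) {
    if (is.list(tows$aliquot_counts)) return(tows$aliquot_counts)
    return(lapply(strsplit(as.character(tows$aliquot_counts), "[,;]"),
                  function(v) as.numeric(trimws(v))))
  }
  ac <- grep("^aliquot[0-9]+$", names(tows), value = TRUE)
  if (length(ac) == 0) abort("no aliquot count columns found")
  lapply(seq_len(nrow(tows)), function(i) as.numeric(unlist(tows[i, ac])))
}

#' Compare two larval count series
#'
#' Paired (default) or two-sample Student's t-test, two-sided.
#'
#' @param series_a,series_b Numeric count series (equal length when paired).
#' @param paired Pair observations by position (default `TRUE`).
#' @return An `htest` (from [stats::t.test()]).
#' @export
compare_counts <- function(series_a, series_b, paired = TRUE) {
  if (paired && length(series_a) != length(series_b)) {
    abort("paired comparison needs equal-length series")
  }
  if (length(series_a) < 2 || length(series_b) < 2) abort("need n >= 2 per series")
  if (paired && sd(series_a - series_b) == 0) {
    if (all(series_a == series_b)) {
      # identical series: no evidence of a shift
      return(structure(
        list(statistic = c(t = 0), parameter = c(df = length(series_a) - 1),
             p.value = 1, method = "Paired t-test (degenerate: identical series)",
             estimate = c(`mean difference` = 0),
             data.name = "series_a vs series_b"),
        class = "htest"
      ))
    }
    abort("zero variance of paired differences: t-test degenerate")
  }
  t.test(series_a, series_b, paired = paired)
}
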