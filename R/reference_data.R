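#' Published climate ranges of the Yunnan climate sub-areas
#'
#' The study area (Yunnan province, southwest China) was regionalized into
#' four primary regions by annual accumulated temperature -- C (cold
#' temperate), M (cool temperate), W (warm plateau) and H (tropical) -- and
#' 13 sub-areas by four further climate/terrain factors. This table holds
#' the published factor ranges of every sub-area: the accumulated
#' temperature interval of its primary region plus the sub-area's annual
#' precipitation, relative humidity, mean annual temperature and mean
#' altitude ranges. It drives threshold-mode zonation (the accumulated
#' temperature intervals are disjoint across regions) and the default
#' climate boxes of the synthetic town generator.
#'
#' @return A tibble with one row per sub-area: `region_label`,
#'   `subarea_label`, and `<factor>_lo` / `<factor>_hi` bounds for
#'   `acc_temp` (degree C day), `precip` (mm), `rh` (percent), `mat`
#'   (degree C) and `alt` (m).
#' @seealso [region_temperature_intervals()], [subarea_scenarios()]
#' @export
subarea_climate_ranges <- function() {
  tibble(
    region_label = rep(c("C", "M", "W", "H"), c(2L, 3L, 4L, 4L)),
    subarea_label = c("C-I", "C-II", "M-I", "M-II", "M-III",
                      "W-I", "W-II", "W-III", "W-IV",
                      "H-I", "H-II", "H-III", "H-IV"),
    acc_temp_lo = rep(c(1489, 3280, 4348, 6302), c(2L, 3L, 4L, 4L)),
    acc_temp_hi = rep(c(3215, 4344, 6281, 8287), c(2L, 3L, 4L, 4L)),
    precip_lo = c(636, 900, 690, 874, 1152, 1166, 713, 920, 796,
                  1504, 716, 893, 1090),
    precip_hi = c(898, 1200, 932, 1135, 1585, 1594, 1015, 1240, 1037,
                  2253, 983, 1266, 1708),
    rh_lo = c(65, 65, 74, 65, 73, 72, 63, 63, 75, 77, 63, 72, 71),
    rh_hi = c(77, 85, 84, 76, 81, 85, 76, 82, 85, 87, 75, 83, 86),
    mat_lo = c(1, 6, 6, 8, 10, 13, 11, 11, 12, 16, 16, 15, 16),
    mat_hi = c(10, 10, 13, 13, 13, 19, 18, 19, 16, 23, 19, 22, 22),
    alt_lo = c(2614, 2582, 1452, 2243, 2066, 1181, 1305, 1012, 613,
               334, 1231, 450, 579),
    alt_hi = c(4069, 3328, 2978, 3021, 2634, 2224, 2383, 2645, 1646,
               1770, 1740, 1903, 1634)
  )
}

#' Accumulated temperature intervals of the primary regions
#'
#' One row per primary region with its published annual accumulated
#' temperature interval (degree C day). Intervals are disjoint and ordered
#' C < M < W < H, so threshold-mode primary division is unambiguous.
#'
#' @return A tibble with columns `region_label`, `lower`, `upper`.
#' @export
region_temperature_intervals <- function() {
  distinct(
    subarea_climate_ranges()[, c("region_label", "acc_temp_lo", "acc_temp_hi")]
  ) |>
    rename(lower = "acc_temp_lo", upper = "acc_temp_hi")
}

#' Published monitoring-sample stage counts per stratum
#'
#' Final-year (2017) succession-outcome tallies of the eligible monitoring
#' plots for each of the 13 climate sub-areas and each of the 4 primary
#' regions, as published for the Yunnan monitoring system: plots still in
#' the grassland stage, plots that reached only the shrub stage, and plots
#' that reached the forest stage. These counts are the inputs of the
#' Natural Succession Index and serve as a fixed regression surface for
#' the index computation.
#'
#' Region rows are reported as published; for the W and H regions they do
#' not equal the column sums of their sub-area rows (an inconsistency in
#' the source), so each row is used individually, never re-derived by
#' summation.
#'
#' @param stratum optional character vector of stratum labels (e.g.
#'   `"C-I"`, `"H"`) to subset to.
#' @return A tibble with columns `stratum`, `level` ("region" or
#'   "subarea"), `n_grassland`, `n_shrub`, `n_forest`, `N`.
#' @examples
#' reference_stage_counts("C-I") # 9 grassland, 20 shrub, 6 forest, N = 35
#' @export
reference_stage_counts <- function(stratum = NULL) {
  counts <- tibble(
    stratum = c("C", "M", "W", "H",
                "C-I", "C-II", "M-I", "M-II", "M-III",
                "W-I", "W-II", "W-III", "W-IV",
                "H-I", "H-II", "H-III", "H-IV"),
    level = rep(c("region", "subarea"), c(4L, 13L)),
    n_grassland = c(21, 32, 120, 75,
                    9, 12, 13, 15, 4, 32, 48, 62, 3, 26, 18, 18, 21),
    n_shrub = c(29, 19, 138, 40,
                20, 9, 9, 8, 2, 34, 94, 71, 8, 20, 18, 22, 19),
    n_forest = c(21, 44, 399, 373,
                 6, 15, 9, 26, 9, 100, 60, 135, 10, 142, 12, 55, 117)
  )
  counts$N <- counts$n_grassland + counts$n_shrub + counts$n_forest
  if (!is.null(stratum)) {
    unknown <- setdiff(stratum, counts$stratum)
    if (length(unknown)) {
      stop_nsindex("nsindex_domain_error",
                   paste0("Unknown stratum label(s): ",
                          paste(unknown, collapse = ", ")))
    }
    counts <- counts[match(stratum, counts$stratum), ]
  }
  counts
}
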