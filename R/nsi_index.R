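# The Natural Succession Index: a habitat-quality-weighted fraction of
# monitoring samples per stratum, P = (sum_x Q_x * n_x) / N, with habitat
# quality Q the exact reciprocal of landscape-matrix resistance
# (grassland 30, shrub 5, forest 1 by default). P = 1 means every sample
# reached the forest stage; the all-grassland floor is 1/30.

#' Habitat quality from landscape resistance
#'
#' Habitat quality is the exact reciprocal of the resistance of a
#' land-cover type to ecological flow (circuit-theory sense). No rounding
#' is applied here: a grassland resistance of 30 yields quality 1/30, not
#' the 4-decimal display value 0.0333 -- the distinction is observable in
#' the 4th decimal of index values.
#'
#' @param resistance positive numeric vector of resistance values.
#' @return `1 / resistance`.
#' @export
habitat_quality <- function(resistance) {
  if (!is.numeric(resistance) || any(!is.finite(resistance)) ||
      any(resistance <= 0)) {
    stop_nsindex("nsindex_domain_error", "resistance must be > 0 and finite")
  }
  1 / resistance
}

#' Default resistance/quality table per seral stage
#'
#' Literature resistance values: grassland 30, shrub 5, forest 1, giving
#' qualities 1/30, 0.2 and 1, strictly increasing along the succession
#' chain. Alternative resistance sets may be supplied to every function
#' that takes a `quality` argument.
#'
#' @param resistance named numeric vector over the three stages.
#' @return Tibble `stage`, `resistance`, `quality`.
#' @export
habitat_quality_table <- function(resistance = c(grassland = 30, shrub = 5,
                                                 forest = 1)) {
  if (!setequal(names(resistance), seral_stages())) {
    stop_nsindex("nsindex_config_error",
                 "resistance must be named over grassland/shrub/forest")
  }
  resistance <- resistance[seral_stages()]
  tibble(stage = seral_stages(),
         resistance = unname(resistance),
         quality = habitat_quality(unname(resistance)))
}

quality_vector <- function(quality) {
  if (is.data.frame(quality)) {
    stats::setNames(quality$quality, quality$stage)[seral_stages()]
  } else {
    quality[seral_stages()]
  }
}

#' Compute the Natural Succession Index
#'
#' `P = (Q_grassland * n_grassland + Q_shrub * n_shrub + Q_forest *
#' n_forest) / N` with `N` the total number of samples in the stratum.
#' Computed with exact reciprocals; rounding (4 decimals, half up) is a
#' display concern, see [round_half_up()].
#'
#' @param n_grassland,n_shrub,n_forest stage counts (vectorized).
#' @param quality a [habitat_quality_table()] or named quality vector.
#' @return Exact index value(s) in `[min(quality), 1]`; `NA` with a
#'   warning where `N = 0` (the index is undefined, not zero).
#' @examples
#' compute_nsi(9, 20, 6)     # 0.29428..., displays as 0.2943
#' compute_nsi(0, 0, 12)     # 1: every sample reached forest
#' @export
compute_nsi <- function(n_grassland, n_shrub, n_forest,
                        quality = habitat_quality_table()) {
  q <- quality_vector(quality)
  counts <- cbind(n_grassland, n_shrub, n_forest)
  if (any(counts < 0, na.rm = TRUE)) {
    stop_nsindex("nsindex_domain_error", "stage counts must be >= 0")
  }
  n_total <- rowSums(counts)
  p <- as.vector(counts %*% unname(q)) / n_total
  if (any(n_total == 0, na.rm = TRUE)) {
    warn("N = 0: the Natural Succession Index is undefined; returning NA.")
    p[n_total == 0] <- NA_real_
  }
  p
}

#' Stage percentages of a stratum
#'
#' `100 * n / N`, rounded half-up to 2 decimals. Rows therefore sum to
#' 100 only up to rounding (within 0.02).
#'
#' @param n stage count(s).
#' @param n_total stratum total `N`.
#' @return Percentage(s), 2 decimals.
#' @export
stage_percentages <- function(n, n_total) {
  round_half_up(100 * n / n_total, 2)
}

#' Index table per stratum with ordering
#'
#' Builds the per-sub-area index table (counts, percentages to 2
#' decimals, exact and display-rounded index) and, optionally, pooled
#' rows per primary region obtained by summing the sub-area counts
#' (pooled P is then the count-weighted mean of the sub-area P values).
#' Sub-area rows are ordered by descending exact (unrounded) index, ties
#' broken lexicographically by label; region rows precede them.
#'
#' @param counts tibble with `subarea_label`, `n_grassland`, `n_shrub`,
#'   `n_forest` (e.g. from [summarize_subareas()]).
#' @param quality a [habitat_quality_table()] or named quality vector.
#' @param include_regions add pooled rows per region (label prefix before
#'   `"-"`).
#' @return Tibble `stratum`, `level`, counts, `pct_*`, `N`, `nsi`
#'   (exact), `nsi_display` (4 decimals, half-up).
#' @export
nsi_table <- function(counts, quality = habitat_quality_table(),
                      include_regions = TRUE) {
  need <- c("subarea_label", "n_grassland", "n_shrub", "n_forest")
  require_columns(names(counts), need, "stage counts")
  sub_rows <- tibble(
    stratum = counts$subarea_label, level = "subarea",
    n_grassland = counts$n_grassland, n_shrub = counts$n_shrub,
    n_forest = counts$n_forest
  )
  rows <- sub_rows
  if (include_regions) {
    reg <- sub_rows |>
      mutate(stratum = sub("-.*$", "", .data$stratum), level = "region") |>
      group_by(.data$stratum, .data$level) |>
      summarise(across(all_of(c("n_grassland", "n_shrub", "n_forest")), sum),
                .groups = "drop")
    rows <- bind_rows(reg, sub_rows)
  }
  rows <- rows |>
    mutate(
      N = .data$n_grassland + .data$n_shrub + .data$n_forest,
      pct_grassland = stage_percentages(.data$n_grassland, .data$N),
      pct_shrub = stage_percentages(.data$n_shrub, .data$N),
      pct_forest = stage_percentages(.data$n_forest, .data$N),
      nsi = compute_nsi(.data$n_grassland, .data$n_shrub, .data$n_forest,
                        quality),
      nsi_display = round_half_up(.data$nsi, 4)
    )
  rows |>
    mutate(level = factor(.data$level, levels = c("region", "subarea"))) |>
    arrange(.data$level, desc(.data$nsi), .data$stratum) |>
    mutate(level = as.character(.data$level))
}
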