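# Seeded synthetic-data generator emulating the monitoring system: towns
# drawn uniformly within published per-sub-area climate boxes, and plot
# series produced by a latent annual grassland -> shrub -> forest chain
# observed only at the 5-year monitoring grid. The annual chain observed
# at a coarser grid reproduces exactly the interval-censoring structure
# the duration estimator must handle.

#' Default sub-area scenarios
#'
#' One scenario per sub-area: its climate box (from
#' [subarea_climate_ranges()]), a favorability `theta` in (0, 1), the
#' annual transition probabilities derived from `theta`, and the number
#' of plots. Defaults follow the study conditions: `theta` is set to the
#' sub-area's observed index value (strictly ordered across sub-areas and
#' spanning the observed range) and `n_plots` to the sub-area's published
#' sample size (totalling 1311). Transition probabilities follow
#' [transition_rates()], calibrated so the expected outcome mix of a
#' scenario resembles the observed mix of a sub-area with that index
#' value (expected index approximately equal to `theta` over the
#' observed range).
#'
#' @param theta optional numeric vector (length 13, (0, 1)) overriding
#'   the favorabilities, in the row order of [subarea_climate_ranges()].
#' @param n_plots optional integer vector or scalar overriding plots per
#'   scenario.
#' @return Tibble: `subarea_label`, `region_label`, climate-box bounds,
#'   `theta`, `p_grass_to_shrub`, `p_shrub_to_forest`, `n_plots`.
#' @export
subarea_scenarios <- function(theta = NULL, n_plots = NULL) {
  boxes <- subarea_climate_ranges()
  default_theta <- c(
    "C-I" = 0.2943, "C-II" = 0.4778, "M-I" = 0.3624, "M-II" = 0.5735,
    "M-III" = 0.6356, "W-I" = 0.6498, "W-II" = 0.3980, "W-III" = 0.5644,
    "W-IV" = 0.5571, "H-I" = 0.7812, "H-II" = 0.3375, "H-III" = 0.6316,
    "H-IV" = 0.7739
  )
  default_n <- c(
    "C-I" = 35L, "C-II" = 36L, "M-I" = 31L, "M-II" = 49L, "M-III" = 15L,
    "W-I" = 166L, "W-II" = 202L, "W-III" = 268L, "W-IV" = 21L,
    "H-I" = 188L, "H-II" = 48L, "H-III" = 95L, "H-IV" = 157L
  )
  theta <- theta %||% unname(default_theta[boxes$subarea_label])
  n_plots <- n_plots %||% unname(default_n[boxes$subarea_label])
  if (length(theta) != nrow(boxes) || any(theta <= 0) || any(theta >= 1)) {
    stop_nsindex("nsindex_config_error",
                 "theta must have one value in (0, 1) per sub-area")
  }
  n_plots <- rep_len(as.integer(n_plots), nrow(boxes))
  boxes |>
    mutate(
      theta = theta,
      p_grass_to_shrub = transition_rates(theta)$p_grass_to_shrub,
      p_shrub_to_forest = transition_rates(theta)$p_shrub_to_forest,
      n_plots = n_plots
    )
}

#' Annual transition probabilities from favorability
#'
#' `p_grass_to_shrub = 0.017 + 0.056 theta` and
#' `p_shrub_to_forest = 0.004 exp(4.6 theta)`: both strictly increasing,
#' in (0, 1) for `theta` in (0, 1). The coefficients reflect the pattern
#' in the monitoring data that grassland-exit rates vary modestly across
#' climates while the shrub-to-forest rate varies by an order of
#' magnitude between the least and most favorable sub-areas; under the
#' 30-year absorbing chain the expected index of a scenario then
#' approximates its `theta` across the observed range.
#'
#' @param theta favorability in (0, 1).
#' @return List with `p_grass_to_shrub` and `p_shrub_to_forest`, both
#'   strictly increasing in `theta`.
#' @export
transition_rates <- function(theta) {
  list(p_grass_to_shrub = 0.017 + 0.056 * theta,
       p_shrub_to_forest = 0.004 * exp(4.6 * theta))
}

#' Generate synthetic town climate records
#'
#' Each factor is drawn uniformly within the scenario's climate box
#' (uniform rather than normal so generated towns respect the published
#' ranges exactly, making threshold-mode zonation a closed-loop test).
#' Town ids encode their generating sub-area for truth tracking.
#'
#' @param scenarios tibble from [subarea_scenarios()].
#' @param towns_per_subarea towns generated per scenario.
#' @param seed integer seed (mandatory: reproducibility is part of the
#'   contract).
#' @return Validated town tibble with an extra `true_subarea` column
#'   (dropped by [write_town_records()]).
#' @export
generate_towns <- function(scenarios, towns_per_subarea = 5, seed) {
  if (nrow(scenarios) == 0) {
    stop_nsindex("nsindex_domain_error", "scenario list is empty")
  }
  if (missing(seed)) {
    stop_nsindex("nsindex_config_error", "a seed is required")
  }
  set.seed(seed)
  pieces <- lapply(seq_len(nrow(scenarios)), function(i) {
    sc <- scenarios[i, ]
    n <- towns_per_subarea
    tibble(
      town_id = sprintf("%s-town%03d", sc$subarea_label, seq_len(n)),
      accumulated_temperature = runif(n, sc$acc_temp_lo, sc$acc_temp_hi),
      annual_precipitation = runif(n, sc$precip_lo, sc$precip_hi),
      relative_humidity = runif(n, sc$rh_lo, sc$rh_hi),
      mean_annual_temperature = runif(n, sc$mat_lo, sc$mat_hi),
      mean_altitude = runif(n, sc$alt_lo, sc$alt_hi),
      true_subarea = sc$subarea_label
    )
  })
  validate_town_records(bind_rows(pieces))
}

# latent geometric transition year: support {1, 2, ...}; Inf when p = 0
draw_transition_year <- function(n, p) {
  if (p <= 0) rep(Inf, n) else rgeom(n, p) + 1
}

#' Generate synthetic plot series
#'
#' Every plot starts in grassland. A latent annual chain applies
#' grassland -> shrub with `p_grass_to_shrub` and shrub -> forest with
#' `p_shrub_to_forest` each year; the state is recorded only at the
#' observation-grid years, so transitions are interval-censored exactly
#' as in the monitoring design. All eligibility flags are `TRUE`.
#'
#' @param scenarios tibble from [subarea_scenarios()].
#' @param seed integer seed (mandatory).
#' @param years observation grid (default 1987 to 2017 every 5 years).
#' @param towns optional town tibble from [generate_towns()]; plots are
#'   spread round-robin over the towns of their generating sub-area.
#'   Without it, each sub-area gets a single placeholder town id.
#' @return Validated long plot tibble. The latent truth (exact transition
#'   years per plot) is attached as the `"truth"` attribute for
#'   closed-loop testing.
#' @export
generate_plots <- function(scenarios, seed, years = seq(1987, 2017, by = 5),
                           towns = NULL) {
  if (nrow(scenarios) == 0) {
    stop_nsindex("nsindex_domain_error", "scenario list is empty")
  }
  if (missing(seed)) {
    stop_nsindex("nsindex_config_error", "a seed is required")
  }
  set.seed(seed)
  offsets <- years - min(years)
  pieces <- vector("list", nrow(scenarios))
  truths <- vector("list", nrow(scenarios))
  for (i in seq_len(nrow(scenarios))) {
    sc <- scenarios[i, ]
    n <- sc$n_plots
    t_shrub <- draw_transition_year(n, sc$p_grass_to_shrub)
    t_forest <- t_shrub + draw_transition_year(n, sc$p_shrub_to_forest)
    plot_ids <- sprintf("%s-plot%04d", sc$subarea_label, seq_len(n))
    town_ids <- if (is.null(towns)) {
      rep(paste0(sc$subarea_label, "-town001"), n)
    } else {
      pool <- towns$town_id[towns$true_subarea == sc$subarea_label]
      if (!length(pool)) {
        stop_nsindex("nsindex_integrity_error",
                     paste0("No towns generated for sub-area ",
                            sc$subarea_label))
      }
      pool[(seq_len(n) - 1L) %% length(pool) + 1L]
    }
    grid <- expand.grid(idx = seq_len(n), offset = offsets)
    stage_num <- 1L + (t_shrub[grid$idx] <= grid$offset) +
      (t_forest[grid$idx] <= grid$offset)
    pieces[[i]] <- tibble(
      plot_id = plot_ids[grid$idx],
      town_id = town_ids[grid$idx],
      year = grid$offset + min(years),
      stage = factor(seral_stages()[stage_num], levels = seral_stages(),
                     ordered = TRUE),
      initial_grassland = TRUE, disturbance_cleared = TRUE,
      disaster_free = TRUE, protected = TRUE
    )
    truths[[i]] <- tibble(
      plot_id = plot_ids, subarea_label = sc$subarea_label,
      theta = sc$theta, t_shrub = t_shrub, t_forest = t_forest
    )
  }
  out <- validate_plot_series(bind_rows(pieces),
                              interval = unique(diff(years)))
  attr(out, "truth") <- bind_rows(truths)
  out
}

#' Closed-form outcome probabilities of the latent chain
#'
#' For the two-step absorbing chain (grassland -> shrub -> forest with
#' annual probabilities `p_gs`, `p_sf`) observed after `years` annual
#' steps: still grassland with probability `(1 - p_gs)^years`; forest if
#' the shrub entry year `k` and a subsequent shrub -> forest transition
#' both fit within the horizon,
#' `sum_k (1 - p_gs)^(k-1) p_gs (1 - (1 - p_sf)^(years - k))`;
#' shrub otherwise. Serves as the analytic reference for the simulator.
#'
#' @param p_gs,p_sf annual transition probabilities in `[0, 1]`.
#' @param years horizon in years (default 30).
#' @return Named numeric vector `grassland`, `shrub`, `forest`
#'   (sums to 1).
#' @export
outcome_probabilities <- function(p_gs, p_sf, years = 30) {
  stopifnot(p_gs >= 0, p_gs <= 1, p_sf >= 0, p_sf <= 1, years >= 1)
  p_grass <- (1 - p_gs)^years
  k <- seq_len(max(years - 1, 0))
  p_forest <- if (length(k) == 0 || p_gs == 0) 0 else {
    sum((1 - p_gs)^(k - 1) * p_gs * (1 - (1 - p_sf)^(years - k)))
  }
  c(grassland = p_grass, shrub = 1 - p_grass - p_forest, forest = p_forest)
}
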