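# Succession-outcome classification and interval-censored stage durations.
#
# With observations every 5 years, a stage transition is only known to lie
# between the last observation in the old stage and the first observation
# in the new stage. Point estimates come from a configurable estimator
# (interval midpoint by default, unbiased under a uniform transition time
# within the bracketing interval); brackets are always reported alongside.

#' Succession outcomes
#'
#' @return Character vector of the three outcomes, in order of increasing
#'   succession progress: `non_succession` (still grassland at the final
#'   observation), `hard_succession` (reached only shrub),
#'   `accessible_succession` (reached forest).
#' @export
succession_outcomes <- function() {
  c("non_succession", "hard_succession", "accessible_succession")
}

# per-plot stage sequence bookkeeping shared by classify/durations
plot_sequence_checks <- function(plots, on_nonmonotone) {
  plots <- validate_plot_series(plots, interval = NULL)
  seqs <- plots |>
    group_by(.data$plot_id) |>
    summarise(
      town_id = first(.data$town_id),
      first_stage = as.character(first(.data$stage)),
      final_stage = as.character(last(.data$stage)),
      monotone = all(diff(as.integer(.data$stage)) >= 0),
      .groups = "drop"
    )
  not_grass <- seqs$plot_id[seqs$first_stage != "grassland"]
  if (length(not_grass)) {
    stop_nsindex("nsindex_validation_error",
                 paste0("Plot(s) not starting in the grassland stage ",
                        "(run filter_eligible first): ",
                        paste(not_grass, collapse = ", ")))
  }
  bad <- seqs$plot_id[!seqs$monotone]
  if (length(bad)) {
    msg <- paste0("Non-monotone stage sequence (succession runs one way, ",
                  "grassland -> shrub -> forest) for plot(s): ",
                  paste(bad, collapse = ", "))
    if (on_nonmonotone == "error") {
      stop_nsindex("nsindex_validation_error", msg)
    }
    warn(paste0(msg, "; using the final observed stage."))
  }
  seqs
}

#' Classify plots into succession outcomes
#'
#' The outcome of an eligible (grassland-start) plot is determined solely
#' by its final-year observation: still grassland -> `non_succession`;
#' shrub -> `hard_succession`; forest -> `accessible_succession`.
#'
#' @param plots validated long plot tibble (eligible plots).
#' @param on_nonmonotone `"error"` (default) rejects stage regressions
#'   such as shrub -> grassland; `"warn"` keeps the plot and classifies by
#'   its final stage, which is all the outcome depends on.
#' @return Tibble `plot_id`, `town_id`, `outcome` (factor over
#'   [succession_outcomes()]).
#' @export
classify_plots <- function(plots, on_nonmonotone = c("error", "warn")) {
  on_nonmonotone <- match.arg(on_nonmonotone)
  seqs <- plot_sequence_checks(plots, on_nonmonotone)
  map <- stats::setNames(succession_outcomes(), seral_stages())
  tibble(
    plot_id = seqs$plot_id,
    town_id = seqs$town_id,
    outcome = factor(unname(map[seqs$final_stage]),
                     levels = succession_outcomes())
  )
}

#' Interval-censored stage durations per plot
#'
#' All times are years since the first observation of the plot. For each
#' transition the bracketing interval `(lower, upper]` spans the last
#' observation in the old stage to the first observation in the new
#' stage; the point estimate is the interval midpoint, the first
#' observation in the new stage, or the last observation in the old
#' stage, per `estimator`. `time_to_forest` is the time of the
#' shrub-to-forest transition since the series start; the grassland
#' duration is the grassland-to-shrub transition time; the shrub duration
#' is their difference. Transitions never observed are right-censored
#' (`upper = Inf`, point `NA`): the lower bound is the final observation
#' time for transitions out of the current stage, and the observed time
#' already spent in shrub for an unfinished shrub stage. `forest_tenure`
#' is the time spent in forest by the final observation, derived from the
#' `time_to_forest` point estimate.
#'
#' @param plots validated long plot tibble (eligible plots).
#' @param estimator point-estimate rule for transition times.
#' @param on_nonmonotone see [classify_plots()].
#' @return One row per plot with `<duration>_lower`, `<duration>_upper`,
#'   `<duration>_point`, `<duration>_censored` for `grassland`, `shrub`
#'   and `time_to_forest`, plus `forest_tenure`.
#' @export
stage_durations <- function(plots,
                            estimator = c("midpoint", "first_observation",
                                          "last_previous"),
                            on_nonmonotone = c("error", "warn")) {
  estimator <- match.arg(estimator)
  on_nonmonotone <- match.arg(on_nonmonotone)
  plot_sequence_checks(plots, on_nonmonotone)
  plots <- validate_plot_series(plots, interval = NULL)

  marks <- plots |>
    group_by(.data$plot_id) |>
    summarise(
      t_final = max(.data$year) - min(.data$year),
      last_grass = max(.data$year[.data$stage == "grassland"]) -
        min(.data$year),
      first_nongrass = if (any(.data$stage != "grassland"))
        min(.data$year[.data$stage != "grassland"]) - min(.data$year)
      else NA_real_,
      first_forest = if (any(.data$stage == "forest"))
        min(.data$year[.data$stage == "forest"]) - min(.data$year)
      else NA_real_,
      last_preforest = if (any(.data$stage == "forest"))
        max(.data$year[.data$stage != "forest"]) - min(.data$year)
      else NA_real_,
      .groups = "drop"
    )

  point_of <- function(lower, upper) {
    switch(estimator,
           midpoint = (lower + upper) / 2,
           first_observation = upper,
           last_previous = lower)
  }

  left_shrub <- !is.na(marks$first_nongrass)   # left grassland at some point
  reached_forest <- !is.na(marks$first_forest)

  out <- tibble(plot_id = marks$plot_id)

  # grassland duration = time of the G -> S transition
  out$grassland_lower <- ifelse(left_shrub, marks$last_grass, marks$t_final)
  out$grassland_upper <- ifelse(left_shrub, marks$first_nongrass, Inf)
  out$grassland_point <- ifelse(
    left_shrub, point_of(out$grassland_lower, out$grassland_upper), NA_real_
  )
  out$grassland_censored <- !left_shrub

  # time to forest = time of the S -> F transition since series start
  out$time_to_forest_lower <- ifelse(reached_forest, marks$last_preforest,
                                     marks$t_final)
  out$time_to_forest_upper <- ifelse(reached_forest, marks$first_forest, Inf)
  out$time_to_forest_point <- ifelse(
    reached_forest,
    point_of(out$time_to_forest_lower, out$time_to_forest_upper), NA_real_
  )
  out$time_to_forest_censored <- !reached_forest

  # shrub duration = difference of the two transition times
  out$shrub_lower <- dplyr::case_when(
    reached_forest ~ pmax(0, marks$last_preforest - marks$first_nongrass),
    left_shrub ~ marks$t_final - marks$first_nongrass,
    .default = NA_real_
  )
  out$shrub_upper <- dplyr::case_when(
    reached_forest ~ marks$first_forest - marks$last_grass,
    left_shrub ~ Inf,
    .default = NA_real_
  )
  out$shrub_point <- ifelse(
    reached_forest, out$time_to_forest_point - out$grassland_point, NA_real_
  )
  out$shrub_censored <- !reached_forest

  out$forest_tenure <- ifelse(reached_forest,
                              marks$t_final - out$time_to_forest_point,
                              NA_real_)
  out
}

#' Summarize outcomes and durations per sub-area
#'
#' Produces the per-sub-area stage counts (the inputs of the Natural
#' Succession Index), mean point-estimate durations over uncensored plots
#' only, the mean forest tenure, and its base-10 logarithm -- the log of
#' the mean, not the mean of logs, matching the convention used when
#' relating the index to time spent in the forest stage.
#'
#' @param outcomes tibble from [classify_plots()].
#' @param durations tibble from [stage_durations()].
#' @param plot_subareas tibble with `plot_id` and `subarea_label`, e.g.
#'   from [assign_plots()].
#' @param subareas optional vector of all expected sub-area labels;
#'   labels with zero plots are excluded from the summary with a warning.
#' @return One row per sub-area: `subarea_label`, `n_grassland`,
#'   `n_shrub`, `n_forest`, `N`, `mean_grassland`, `mean_shrub`,
#'   `mean_time_to_forest`, `mean_forest_tenure`, `log10_forest_tenure`.
#' @export
summarize_subareas <- function(outcomes, durations, plot_subareas,
                               subareas = NULL) {
  missing <- setdiff(outcomes$plot_id, plot_subareas$plot_id)
  if (length(missing)) {
    stop_nsindex("nsindex_integrity_error",
                 paste0("Plot(s) without a sub-area assignment: ",
                        paste(missing, collapse = ", ")))
  }
  joined <- outcomes |>
    left_join(plot_subareas[, c("plot_id", "subarea_label")], by = "plot_id") |>
    left_join(durations, by = "plot_id")
  if (!is.null(subareas)) {
    empty <- setdiff(subareas, joined$subarea_label)
    if (length(empty)) {
      warn(paste0("Sub-area(s) with zero plots excluded from summary: ",
                  paste(empty, collapse = ", ")))
    }
  }
  mean_or_na <- function(x) if (any(is.finite(x))) mean(x[is.finite(x)])
                            else NA_real_
  joined |>
    group_by(.data$subarea_label) |>
    summarise(
      n_grassland = sum(.data$outcome == "non_succession"),
      n_shrub = sum(.data$outcome == "hard_succession"),
      n_forest = sum(.data$outcome == "accessible_succession"),
      N = n(),
      mean_grassland = mean_or_na(
        .data$grassland_point[!.data$grassland_censored]),
      mean_shrub = mean_or_na(.data$shrub_point[!.data$shrub_censored]),
      mean_time_to_forest = mean_or_na(
        .data$time_to_forest_point[!.data$time_to_forest_censored]),
      mean_forest_tenure = mean_or_na(.data$forest_tenure),
      .groups = "drop"
    ) |>
    mutate(log10_forest_tenure = ifelse(.data$mean_forest_tenure > 0,
                                        log10(.data$mean_forest_tenure),
                                        NA_real_))
}

#' Rank correlation between sub-area index and forest-stage time
#'
#' Spearman rank correlation with the sub-area as the unit, chosen
#' because the substantive claim is an ordering: sub-areas with a higher
#' Natural Succession Index accumulate more time in the forest stage.
#'
#' @param nsi numeric vector of sub-area index values.
#' @param log_forest_tenure numeric vector (same length/order), typically
#'   `log10_forest_tenure` from [summarize_subareas()]; any monotone
#'   transform of tenure gives the same rank correlation.
#' @return Spearman's rho, or `NA` with a warning if either input is
#'   constant (the correlation is undefined).
#' @export
nsi_time_correlation <- function(nsi, log_forest_tenure) {
  ok <- is.finite(nsi) & is.finite(log_forest_tenure)
  nsi <- nsi[ok]
  log_forest_tenure <- log_forest_tenure[ok]
  if (length(nsi) < 3) {
    stop_nsindex("nsindex_domain_error",
                 "At least 3 sub-areas with both quantities are required.")
  }
  if (sd(nsi) == 0 || sd(log_forest_tenure) == 0) {
    warn("Constant input: rank correlation is undefined.")
    return(NA_real_)
  }
  cor(nsi, log_forest_tenure, method = "spearman")
}
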