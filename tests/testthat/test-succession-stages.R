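# Outcome classification, interval-censored durations and the sub-area
# summary.

test_that("outcome is determined by the final observation", {
  plots <- make_plots(list(
    stay  = "GGGGGGG",   # never left grassland
    hard  = "GGSSSSS",   # reached shrub only
    reach = "GSSFFFF"    # entered forest
  ))
  got <- classify_plots(plots)
  expect_equal(
    as.character(got$outcome[match(c("stay", "hard", "reach"), got$plot_id)]),
    c("non_succession", "hard_succession", "accessible_succession")
  )
})

test_that("stage regressions are rejected by default, tolerated on request", {
  plots <- make_plots(list(back = "GSSGGSS", ok = "GGSSSFF"))
  expect_error(classify_plots(plots), "back",
               class = "nsindex_validation_error")
  expect_warning(got <- classify_plots(plots, on_nonmonotone = "warn"),
                 "final")
  expect_equal(as.character(got$outcome[got$plot_id == "back"]),
               "hard_succession")
})

test_that("plots not starting in grassland are rejected", {
  expect_error(classify_plots(make_plot("P1", "SSFFFFF")),
               class = "nsindex_validation_error")
})

test_that("midpoint durations match the hand-enumerated bracketing", {
  # years 0,5,...,30: last grassland at 10, first shrub at 15,
  # last shrub at 20, first forest at 25
  d <- stage_durations(make_plot("P1", "GGGSSFF"))
  expect_equal(d$grassland_lower, 10)
  expect_equal(d$grassland_upper, 15)
  expect_equal(d$grassland_point, 12.5)
  expect_equal(d$time_to_forest_point, 22.5)
  expect_equal(d$forest_tenure, 30 - 22.5)
  expect_equal(d$shrub_point, 10)
  expect_false(any(d$grassland_censored, d$shrub_censored,
                   d$time_to_forest_censored))
})

test_that("an all-grassland series is right-censored everywhere", {
  d <- stage_durations(make_plot("P1", "GGGGGGG"))
  expect_true(all(d$grassland_censored, d$shrub_censored,
                  d$time_to_forest_censored))
  expect_equal(d$grassland_lower, 30)
  expect_equal(d$grassland_upper, Inf)
  expect_true(is.na(d$grassland_point))
  expect_true(is.na(d$forest_tenure))
})

test_that("shrub duration is censored from its observed entry when forest is unreached", {
  d <- stage_durations(make_plot("P1", "GGSSSSS"))
  expect_false(d$grassland_censored)
  expect_true(d$shrub_censored)
  expect_equal(d$shrub_lower, 30 - 10) # in shrub since first seen at year 10
  expect_equal(d$shrub_upper, Inf)
})

test_that("alternative estimators bracket the same transition", {
  p <- make_plot("P1", "GFFFFFF")
  first <- stage_durations(p, estimator = "first_observation")
  expect_equal(first$time_to_forest_point, 5)
  last <- stage_durations(p, estimator = "last_previous")
  expect_equal(last$time_to_forest_point, 0)
  mid <- stage_durations(p)
  expect_equal(mid$time_to_forest_point, 2.5)
})

test_that("point estimates stay within their brackets on simulated series", {
  plots <- generate_plots(subarea_scenarios(n_plots = 60)[c(1, 7, 13), ],
                          seed = 31)
  truth <- attr(plots, "truth")
  d <- stage_durations(plots)
  ok <- !d$grassland_censored
  expect_true(all(d$grassland_lower[ok] <= d$grassland_point[ok] &
                    d$grassland_point[ok] <= d$grassland_upper[ok]))
  okf <- !d$time_to_forest_censored
  expect_true(all(d$time_to_forest_lower[okf] <= d$time_to_forest_point[okf] &
                    d$time_to_forest_point[okf] <= d$time_to_forest_upper[okf]))
  # latent truth lies in the half-open bracket (lower, upper]
  tr <- truth[match(d$plot_id, truth$plot_id), ]
  expect_true(all(tr$t_shrub[ok] > d$grassland_lower[ok] &
                    tr$t_shrub[ok] <= d$grassland_upper[ok]))
  expect_true(all(tr$t_forest[okf] > d$time_to_forest_lower[okf] &
                    tr$t_forest[okf] <= d$time_to_forest_upper[okf]))
  # classification and censoring agree: forest-final <=> uncensored
  out <- classify_plots(plots)
  expect_equal(out$outcome == "accessible_succession",
               !d$time_to_forest_censored[match(out$plot_id, d$plot_id)],
               ignore_attr = TRUE)
})

test_that("finer observation grids shrink the brackets", {
  scen <- subarea_scenarios(n_plots = 40)[5, ]
  coarse <- generate_plots(scen, seed = 17, years = seq(0, 30, by = 5))
  fine <- generate_plots(scen, seed = 17, years = seq(0, 30, by = 1))
  # same seed => same latent transition times
  expect_equal(attr(coarse, "truth"), attr(fine, "truth"))
  dc <- stage_durations(coarse)
  df <- stage_durations(fine)
  okc <- !dc$grassland_censored & !df$grassland_censored
  width_c <- dc$grassland_upper[okc] - dc$grassland_lower[okc]
  width_f <- df$grassland_upper[okc] - df$grassland_lower[okc]
  expect_true(all(width_f <= width_c))
  expect_equal(unique(width_f), 1)
})

test_that("sub-area summary counts outcomes and averages uncensored durations", {
  plots <- make_plots(list(a = "GGGGGGG", b = "GGSSSSS", c = "GSSFFFF"))
  outcomes <- classify_plots(plots)
  durations <- stage_durations(plots)
  map <- tibble::tibble(plot_id = c("a", "b", "c"),
                        subarea_label = "H-I")
  got <- summarize_subareas(outcomes, durations, map)
  expect_equal(got$n_grassland, 1)
  expect_equal(got$n_shrub, 1)
  expect_equal(got$n_forest, 1)
  expect_equal(got$N, 3)
  # uncensored grassland durations: b in (5,10] -> 7.5, c in (0,5] -> 2.5
  expect_equal(got$mean_grassland, mean(c(7.5, 2.5)))
  # only c reaches forest: transition in (10,15], tenure 30 - 12.5
  expect_equal(got$mean_forest_tenure, 17.5)
  expect_equal(got$log10_forest_tenure, log10(17.5))
})

test_that("summary means equal a hand-computed average over simulated truth", {
  plots <- generate_plots(subarea_scenarios(n_plots = 100)[8, ], seed = 41)
  outcomes <- classify_plots(plots)
  durations <- stage_durations(plots)
  map <- tibble::tibble(plot_id = unique(plots$plot_id),
                        subarea_label = "M-II")
  got <- summarize_subareas(outcomes, durations, map)
  # independent arithmetic oracle: loop over each plot's observed series
  per_plot <- split(plots, plots$plot_id)
  mids <- vapply(per_plot, function(p) {
    p <- p[order(p$year), ]
    y <- p$year - min(p$year)
    s <- as.character(p$stage)
    if (all(s == "grassland")) return(NA_real_)
    (max(y[s == "grassland"]) + min(y[s != "grassland"])) / 2
  }, numeric(1))
  expect_equal(got$mean_grassland, mean(mids, na.rm = TRUE))
  expect_equal(got$N, 100)
  expect_equal(got$n_grassland + got$n_shrub + got$n_forest, got$N)
})

test_that("empty sub-areas are reported and unmapped plots rejected", {
  plots <- make_plots(list(a = "GGSSSFF"))
  outcomes <- classify_plots(plots)
  durations <- stage_durations(plots)
  expect_error(
    summarize_subareas(outcomes, durations,
                       tibble::tibble(plot_id = "zz", subarea_label = "C-I")),
    class = "nsindex_integrity_error"
  )
  expect_warning(
    summarize_subareas(outcomes, durations,
                       tibble::tibble(plot_id = "a", subarea_label = "C-I"),
                       subareas = c("C-I", "C-II")),
    "C-II"
  )
})

test_that("rank correlation reflects co-monotonicity and rejects tiny input", {
  expect_equal(nsi_time_correlation(c(0.2, 0.5, 0.8), c(1, 2, 3)), 1)
  expect_equal(nsi_time_correlation(c(0.2, 0.5, 0.8), c(3, 2, 1)), -1)
  expect_warning(got <- nsi_time_correlation(c(0.5, 0.5, 0.5), c(1, 2, 3)),
                 "undefined")
  expect_true(is.na(got))
  expect_error(nsi_time_correlation(c(0.1, 0.2), c(1, 2)),
               class = "nsindex_domain_error")
})
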