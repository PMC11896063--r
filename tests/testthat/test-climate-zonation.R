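# Two-stage regionalization: threshold assignment, clustering, labelling
# determinism and plot inheritance.

test_that("threshold mode reproduces the published temperature intervals", {
  cfg <- zonation_config(mode = "threshold")
  iv <- region_temperature_intervals()
  # every value inside a printed interval maps to that region, including
  # both endpoints
  probe <- dplyr::bind_rows(lapply(seq_len(nrow(iv)), function(i) {
    tibble::tibble(
      region = iv$region_label[i],
      at = c(iv$lower[i], iv$upper[i],
             seq(iv$lower[i], iv$upper[i], length.out = 9))
    )
  }))
  towns <- make_towns(nrow(probe), acc_temp = probe$at)
  got <- primary_division(towns, cfg)
  expect_equal(got$region_label, probe$region)
})

test_that("threshold mode sends specific temperatures to C and H", {
  cfg <- zonation_config(mode = "threshold")
  towns <- make_towns(2, acc_temp = c(2000, 7000))
  expect_equal(primary_division(towns, cfg)$region_label, c("C", "H"))
})

test_that("out-of-interval temperatures go to the nearest region with warning", {
  cfg <- zonation_config(mode = "threshold")
  towns <- make_towns(3, acc_temp = c(1000, 3240, 9000)) # below, gap, above
  expect_warning(got <- primary_division(towns, cfg), "nearest")
  expect_equal(got$region_label, c("C", "C", "H")) # 3240 is 25 from C, 40 from M
  towns2 <- make_towns(1, acc_temp = 3250) # 35 from C, 30 from M
  expect_warning(got2 <- primary_division(towns2, cfg))
  expect_equal(got2$region_label, "M")
})

test_that("clustering four distinct temperatures into k=4 gives ordered singletons", {
  towns <- make_towns(4, acc_temp = c(6400, 1500, 4400, 3300)) # shuffled
  got <- primary_division(towns, zonation_config())
  expect_equal(got$region_label, c("H", "C", "W", "M"))
})

test_that("region labels are invariant under row permutation", {
  set.seed(11)
  towns <- make_towns(20, acc_temp = runif(20, 1500, 8000))
  base <- primary_division(towns, zonation_config())
  perm <- sample(nrow(towns))
  shuffled <- primary_division(towns[perm, ], zonation_config())
  expect_equal(shuffled$region_label[order(perm)], base$region_label)
})

test_that("primary clustering needs at least k towns", {
  expect_error(primary_division(make_towns(3), zonation_config(primary_k = 4)),
               class = "nsindex_config_error")
})

test_that("secondary division with k=1 labels every town <region>-I", {
  towns <- make_towns(5, acc_temp = rep(5000, 5))
  got <- secondary_division(towns, "W", k = 1)
  expect_equal(got$subarea_label, rep("W-I", 5))
})

test_that("secondary labels are deterministic under the tie-break chain", {
  # two singleton clusters: equal size, so ascending mean precipitation
  # decides; the wetter town gets the later numeral only if drier first
  towns <- make_towns(2, acc_temp = c(5000, 5000))
  towns$annual_precipitation <- c(1200, 700)
  got <- secondary_division(towns, "W", k = 2)
  expect_equal(got$subarea_label, c("W-II", "W-I"))
})

test_that("secondary division recovers two well-separated factor boxes", {
  set.seed(23)
  n <- 4
  box_a <- tibble::tibble(
    town_id = sprintf("A%02d", 1:n),
    accumulated_temperature = runif(n, 4348, 6281),
    annual_precipitation = runif(n, 700, 750),
    relative_humidity = runif(n, 63, 66),
    mean_annual_temperature = runif(n, 11, 12),
    mean_altitude = runif(n, 2300, 2400)
  )
  box_b <- tibble::tibble(
    town_id = sprintf("B%02d", 1:n),
    accumulated_temperature = runif(n, 4348, 6281),
    annual_precipitation = runif(n, 1500, 1594),
    relative_humidity = runif(n, 83, 85),
    mean_annual_temperature = runif(n, 18, 19),
    mean_altitude = runif(n, 1181, 1300)
  )
  towns <- dplyr::bind_rows(box_a, box_b)
  got <- secondary_division(towns, "W", k = 2)
  # oracle: exhaustive 2-partition minimizing within-group sum of squares
  # on the z-scored 4-factor vectors
  x <- scale(as.matrix(towns[, c("annual_precipitation", "relative_humidity",
                                 "mean_annual_temperature", "mean_altitude")]))
  wss <- function(idx) {
    sum(apply(x[idx, , drop = FALSE], 2, function(v) sum((v - mean(v))^2)))
  }
  best <- NULL
  best_val <- Inf
  for (mask in 1:(2^(2 * n - 1) - 1)) {
    idx <- as.logical(bitwAnd(mask, 2^(0:(2 * n - 1))))
    if (!any(idx) || all(idx)) next
    val <- wss(which(idx)) + wss(which(!idx))
    if (val < best_val) {
      best_val <- val
      best <- idx
    }
  }
  expect_equal(split(towns$town_id, got$subarea_label) |>
                 lapply(sort) |> unname() |> (\(x) x[order(sapply(x, "[", 1))])(),
               split(towns$town_id, best) |>
                 lapply(sort) |> unname() |> (\(x) x[order(sapply(x, "[", 1))])())
  # and the generating boxes are exactly recovered
  expect_equal(length(unique(got$subarea_label[1:n])), 1L)
  expect_equal(length(unique(got$subarea_label[(n + 1):(2 * n)])), 1L)
})

test_that("full zonation yields a partition with region-prefixed labels", {
  set.seed(5)
  scen <- subarea_scenarios()
  towns <- generate_towns(scen, towns_per_subarea = 4, seed = 9)
  got <- climate_zonation(towns[, -ncol(towns)],
                          zonation_config(mode = "threshold"))
  expect_equal(nrow(got), nrow(towns))
  expect_equal(anyDuplicated(got$town_id), 0L)
  expect_true(all(sub("-.*$", "", got$subarea_label) == got$region_label))
  # partition: within each region the sub-area label sets cover its towns
  split_regions <- split(got$subarea_label, got$region_label)
  expect_equal(sort(names(split_regions)), c("C", "H", "M", "W"))
  expect_equal(lengths(lapply(split_regions, unique))[c("C", "M", "W", "H")],
               c(C = 2L, M = 3L, W = 4L, H = 4L))
})

test_that("secondary k above the town count is a configuration error", {
  expect_error(secondary_division(make_towns(2), "C", k = 3),
               class = "nsindex_config_error")
})

test_that("plots inherit their town's sub-area; orphans are integrity errors", {
  assignment <- tibble::tibble(
    town_id = c("T01", "T02", "T03"),
    region_label = c("H", "H", "W"),
    subarea_label = c("H-I", "H-I", "W-II")
  )
  plots <- dplyr::bind_rows(
    make_plots(setNames(rep("GGSSSFF", 4), paste0("P", 1:4)), town_id = "T01"),
    make_plots(setNames(rep("GGGGGGG", 3), paste0("P", 5:7)), town_id = "T02"),
    make_plots(setNames(rep("GSSFFFF", 3), paste0("P", 8:10)), town_id = "T03")
  )
  got <- assign_plots(plots, assignment)
  expect_equal(nrow(got), 10L)
  expect_equal(got$subarea_label[got$plot_id == "P1"], "H-I")
  expect_equal(got$subarea_label[got$plot_id == "P9"], "W-II")

  orphan <- make_plot("PX", "GSF", town_id = "T99")
  expect_error(assign_plots(dplyr::bind_rows(plots, orphan), assignment),
               "PX", class = "nsindex_integrity_error")
})
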