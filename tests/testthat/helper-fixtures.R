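# Fixtures built in code: tiny town and plot collections used across tests.

make_towns <- function(n = 4,
                       acc_temp = c(1500, 3300, 4400, 6400)[seq_len(n)]) {
  tibble::tibble(
    town_id = sprintf("T%02d", seq_len(n)),
    accumulated_temperature = acc_temp,
    annual_precipitation = seq(700, by = 50, length.out = n),
    relative_humidity = 60 + (seq_len(n) * 2) %% 35,
    mean_annual_temperature = seq(5, by = 2, length.out = n),
    mean_altitude = seq(800, by = 100, length.out = n)
  )
}

# a plot series from a stage-letter string, e.g. "GGGSSFF"
make_plot <- function(plot_id, stages, town_id = "T01",
                      years = seq(1987, by = 5, length.out = nchar(stages)),
                      flags = c(TRUE, TRUE, TRUE, TRUE)) {
  code <- c(G = "grassland", S = "shrub", F = "forest")
  tibble::tibble(
    plot_id = plot_id,
    town_id = town_id,
    year = years,
    stage = factor(unname(code[strsplit(stages, "")[[1]]]),
                   levels = nsindex::seral_stages(), ordered = TRUE),
    initial_grassland = flags[1],
    disturbance_cleared = flags[2],
    disaster_free = flags[3],
    protected = flags[4]
  )
}

make_plots <- function(specs, town_id = "T01") {
  dplyr::bind_rows(lapply(names(specs), function(id) {
    make_plot(id, specs[[id]], town_id = town_id)
  }))
}

reference_subarea_counts <- function() {
  rc <- nsindex::reference_stage_counts()
  rc[rc$level == "subarea", ]
}
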