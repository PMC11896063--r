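# Two-stage climate regionalization: towns are first partitioned into
# four primary regions on annual accumulated temperature, then each region
# is subdivided on the remaining four climate/terrain factors.

#' Zonation configuration
#'
#' @param primary_k number of primary regions (default 4).
#' @param secondary_k named integer vector, clusters per primary region
#'   (default `c(C = 2, M = 3, W = 4, H = 4)`, i.e. 13 sub-areas).
#' @param linkage agglomeration method passed to [stats::hclust()].
#'   Ward linkage on Euclidean distances of z-scored factors is the
#'   conventional choice for climate regionalization.
#' @param standardize z-score the four secondary factors within each
#'   region before clustering.
#' @param mode `"cluster"` runs hierarchical clustering; `"threshold"`
#'   assigns primary regions from the published accumulated temperature
#'   intervals (see [region_temperature_intervals()]), which makes the
#'   primary division bit-exact and independent of clustering choices.
#' @return A list of class `nsindex_zonation_config`.
#' @export
zonation_config <- function(primary_k = 4L,
                            secondary_k = c(C = 2L, M = 3L, W = 4L, H = 4L),
                            linkage = "ward.D2",
                            standardize = TRUE,
                            mode = c("cluster", "threshold")) {
  mode <- match.arg(mode)
  if (!is_scalar_number(primary_k) || primary_k < 1) {
    stop_nsindex("nsindex_config_error", "primary_k must be >= 1")
  }
  if (length(secondary_k) && (is.null(names(secondary_k)) ||
                              any(secondary_k < 1))) {
    stop_nsindex("nsindex_config_error",
                 "secondary_k must be a named vector of counts >= 1")
  }
  structure(
    list(primary_k = as.integer(primary_k),
         secondary_k = secondary_k,
         linkage = linkage,
         standardize = isTRUE(standardize),
         mode = mode),
    class = "nsindex_zonation_config"
  )
}

secondary_factor_fields <- function() {
  c("annual_precipitation", "relative_humidity",
    "mean_annual_temperature", "mean_altitude")
}

primary_region_labels <- function(k) {
  if (k <= 4L) c("C", "M", "W", "H")[seq_len(k)] else paste0("R", seq_len(k))
}

#' Primary division of towns by accumulated temperature
#'
#' In cluster mode, towns are grouped by 1-D agglomerative clustering on
#' annual accumulated temperature and the groups are labelled C, M, W, H
#' in ascending order of group-mean accumulated temperature (coldest to
#' hottest). In threshold mode, each town is assigned to the published
#' accumulated temperature interval containing its value; values falling
#' outside every interval go to the nearest interval with a warning.
#'
#' @param towns validated town tibble.
#' @param config a [zonation_config()].
#' @return Tibble `town_id`, `region_label`.
#' @export
primary_division <- function(towns, config = zonation_config()) {
  towns <- validate_town_records(towns)
  at <- towns$accumulated_temperature
  if (config$mode == "threshold") {
    iv <- region_temperature_intervals()
    idx <- vapply(at, function(v) {
      inside <- which(v >= iv$lower & v <= iv$upper)
      if (length(inside)) inside[1] else NA_integer_
    }, integer(1))
    outside <- which(is.na(idx))
    if (length(outside)) {
      idx[outside] <- vapply(at[outside], function(v) {
        which.min(pmax(iv$lower - v, 0, v - iv$upper))
      }, integer(1))
      warn(paste0("Accumulated temperature outside all published intervals ",
                  "for town(s) ", paste(towns$town_id[outside], collapse = ", "),
                  "; assigned to nearest interval."))
    }
    return(tibble(town_id = towns$town_id,
                  region_label = iv$region_label[idx]))
  }
  k <- config$primary_k
  if (nrow(towns) < k) {
    stop_nsindex("nsindex_config_error",
                 paste0("primary_k = ", k, " exceeds number of towns (",
                        nrow(towns), ")"))
  }
  hc <- hclust(dist(at), method = config$linkage)
  grp <- cutree(hc, k = k)
  means <- tapply(at, grp, mean)
  labels <- primary_region_labels(k)
  relabel <- stats::setNames(labels, names(sort(means)))
  tibble(town_id = towns$town_id,
         region_label = unname(relabel[as.character(grp)]))
}

#' Secondary division of one region's towns
#'
#' Agglomerative clustering on the four secondary factors (annual
#' precipitation, relative humidity, mean annual temperature, mean
#' altitude), z-scored within the region when `config$standardize` is
#' `TRUE`. Clusters are relabelled I, II, ... by descending cluster size,
#' ties broken by ascending mean precipitation, then by ascending minimum
#' `town_id` -- a fully deterministic convention (published sub-area
#' numbering follows no recoverable rule).
#'
#' @param towns town tibble, all belonging to one primary region.
#' @param region_label the region's label, used as sub-area prefix.
#' @param k number of sub-areas for this region.
#' @param config a [zonation_config()].
#' @return Tibble `town_id`, `subarea_label` (e.g. `"W-III"`).
#' @export
secondary_division <- function(towns, region_label, k,
                               config = zonation_config()) {
  towns <- validate_town_records(towns)
  if (!is_scalar_number(k) || k < 1 || k > nrow(towns)) {
    stop_nsindex("nsindex_config_error",
                 paste0("secondary k for region ", region_label,
                        " must be between 1 and the number of its towns (",
                        nrow(towns), "), got ", k))
  }
  k <- as.integer(k)
  if (k == 1L) {
    grp <- rep(1L, nrow(towns))
  } else {
    x <- as.matrix(towns[, secondary_factor_fields()])
    if (config$standardize) {
      x <- scale(x)
      x[, attr(x, "scaled:scale") == 0] <- 0  # constant factor carries no signal
    }
    hc <- hclust(dist(x), method = config$linkage)
    grp <- cutree(hc, k = k)
  }
  ord <- order(
    -tabulate(grp, nbins = k),
    tapply(towns$annual_precipitation, factor(grp, levels = seq_len(k)), mean),
    tapply(towns$town_id, factor(grp, levels = seq_len(k)), min)
  )
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  tibble(town_id = towns$town_id,
         subarea_label = paste0(region_label, "-", roman_label(relabel[grp])))
}

#' Full two-stage climate zonation
#'
#' Runs [primary_division()] and then [secondary_division()] within each
#' region, with per-region cluster counts from `config$secondary_k`
#' (regions absent from that map default to a single sub-area).
#'
#' @param towns validated town tibble.
#' @param config a [zonation_config()].
#' @return Tibble `town_id`, `region_label`, `subarea_label`; one row per
#'   town, sub-area prefix equal to the region label.
#' @export
climate_zonation <- function(towns, config = zonation_config()) {
  primary <- primary_division(towns, config)
  pieces <- lapply(sort(unique(primary$region_label)), function(region) {
    ids <- primary$town_id[primary$region_label == region]
    k <- config$secondary_k[[region]] %||% 1L
    sub <- secondary_division(towns[match(ids, towns$town_id), ],
                              region, k, config)
    sub$region_label <- region
    sub
  })
  out <- bind_rows(pieces)[, c("town_id", "region_label", "subarea_label")]
  out[match(towns$town_id, out$town_id), ]
}

#' Assign plots to sub-areas through their towns
#'
#' Pure inheritance: a plot belongs to the sub-area of its town. No
#' spatial computation is involved.
#'
#' @param plots validated long plot tibble.
#' @param assignment zonation tibble with `town_id` and `subarea_label`
#'   (and optionally `region_label`).
#' @return Tibble `plot_id`, `town_id`, `subarea_label` (plus
#'   `region_label` when available), one row per plot.
#' @export
assign_plots <- function(plots, assignment) {
  plot_towns <- distinct(plots[, c("plot_id", "town_id")])
  orphans <- setdiff(plot_towns$town_id, assignment$town_id)
  if (length(orphans)) {
    bad_plots <- plot_towns$plot_id[plot_towns$town_id %in% orphans]
    stop_nsindex("nsindex_integrity_error",
                 paste0("Plot(s) in town(s) absent from the assignment: ",
                        paste(bad_plots, collapse = ", ")))
  }
  keep <- intersect(c("town_id", "region_label", "subarea_label"),
                    names(assignment))
  left_join(plot_towns, assignment[, keep], by = "town_id")
}
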