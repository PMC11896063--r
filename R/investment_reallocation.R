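# Restoration-budget re-balancing around the mean index K:
# I = In * (1 + (K - Px) / K). Sub-areas whose index exceeds K are
# investment-surplus (budget shrinks); below K, investment-deficient
# (budget grows). With equal baselines the total budget is conserved,
# since the adjustments sum to zero around the mean.

#' Mean-index threshold K
#'
#' Unweighted arithmetic mean of the sub-area index values (exact,
#' unrounded values by default). K partitions sub-areas into investment
#' surplus (`Px > K`) and deficit (`Px < K`).
#'
#' @param p numeric vector of sub-area index values in (0, 1].
#' @return The mean, K.
#' @export
mean_threshold <- function(p) {
  if (length(p) == 0) {
    stop_nsindex("nsindex_domain_error",
                 "Cannot take the mean index of an empty collection.")
  }
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop_nsindex("nsindex_domain_error", "index values must lie in (0, 1]")
  }
  mean(p)
}

#' Re-balance restoration budgets around K
#'
#' Applies `I = In * (1 + (K - Px) / K)` row-wise. Negative adjusted
#' budgets (which arise when `Px > 2K`) are reported with a warning, not
#' clamped: clamping would silently break the budget-conservation
#' identity that holds under equal baselines.
#'
#' @param baselines named numeric vector, baseline budget `In` per
#'   sub-area (currency units, `>= 0`).
#' @param nsi named numeric vector, index `Px` per sub-area. Key sets of
#'   `baselines` and `nsi` must be identical.
#' @param k threshold; defaults to [mean_threshold()] of `nsi`.
#' @return Tibble `subarea_label`, `nsi`, `baseline`, `adjusted`,
#'   `status` (`"surplus"`, `"deficit"` or `"neutral"`), with a `totals`
#'   attribute holding the summed baseline and adjusted budgets.
#' @export
reallocate <- function(baselines, nsi, k = mean_threshold(nsi)) {
  if (is.null(names(baselines)) || is.null(names(nsi)) ||
      !setequal(names(baselines), names(nsi))) {
    missing_p <- setdiff(names(baselines), names(nsi))
    stop_nsindex(
      "nsindex_integrity_error",
      if (length(missing_p)) {
        paste0("No index value for budgeted sub-area(s): ",
               paste(missing_p, collapse = ", "))
      } else {
        "baselines and nsi must be named over identical sub-area sets"
      }
    )
  }
  if (!is_scalar_number(k) || k <= 0) {
    stop_nsindex("nsindex_domain_error", "K must be a positive number")
  }
  if (any(baselines < 0)) {
    stop_nsindex("nsindex_domain_error", "baseline budgets must be >= 0")
  }
  labels <- names(baselines)
  px <- unname(nsi[labels])
  adj <- unname(baselines) * (1 + (k - px) / k)
  plan <- tibble(
    subarea_label = labels,
    nsi = px,
    baseline = unname(baselines),
    adjusted = adj,
    status = dplyr::case_when(px > k ~ "surplus",
                              px < k ~ "deficit",
                              .default = "neutral")
  )
  if (any(adj < 0)) {
    warn(paste0("Negative adjusted budget for sub-area(s) ",
                paste(labels[adj < 0], collapse = ", "),
                " (index above 2K); reported unclamped."))
  }
  attr(plan, "totals") <- c(baseline = sum(plan$baseline),
                            adjusted = sum(plan$adjusted))
  plan
}
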