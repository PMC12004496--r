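#' Published trade-off indices per grassland and litter level
#'
#' The twelve study-reported TPCP-MBCP trade-off indices (one per
#' grassland-by-litter cell). The underlying replicate data were not
#' deposited, so these values cannot be recomputed; they serve as fixtures
#' for feasibility checks (every index must lie in the attainable range
#' \[0, 1/sqrt(2)\]) and for qualitative comparison, not as recovery
#' targets.
#'
#' @return A tibble: `grassland`, `litter`, `index`.
#' @export
reported_tradeoff_indices <- function() {
  readr::read_csv(
    system.file("extdata", "reported_tradeoff_indices.csv",
                package = "cptradeoff", mustWork = TRUE),
    show_col_types = FALSE, progress = FALSE
  )
}

#' Published peak treatment means
#'
#' The study-reported peak treatment means per grassland: biomass, tissue
#' carbon content, the derived plant pools, and profile MBC/MBCP (which
#' peak at T2 in the fenced meadow and T3 elsewhere). These are the worked
#' example for the pool formulas and the anchors of the synthetic
#' generator's defaults.
#'
#' @return A tibble: `grassland`, `litter`, `variable`, `value`, `unit`.
#' @export
reported_peak_means <- function() {
  readr::read_csv(
    system.file("extdata", "reported_peak_means.csv",
                package = "cptradeoff", mustWork = TRUE),
    show_col_types = FALSE, progress = FALSE
  )
}
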