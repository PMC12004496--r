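#' @importFrom broom tidy glance
#' @export
broom::tidy

#' @export
broom::glance

#' Tidy the pairwise comparisons of a Tukey HSD result
#'
#' @param x A `tukey_hsd` object.
#' @param ... Unused.
#' @return A tibble with one row per group pair (`level_i`, `level_j`,
#'   `mean_diff`, `q_stat`, `p_adj`).
#' @method tidy tukey_hsd
#' @export
tidy.tukey_hsd <- function(x, ...) {
  x$pairs
}

#' Tidy per-grassland group statistics
#'
#' Returns the Tukey pairwise comparisons across all grasslands, the
#' per-term detail of the analysis; the one-row-per-grassland ANOVA
#' summary is available through [glance.group_stats()].
#'
#' @param x A `group_stats` object from [group_statistics()].
#' @param ... Unused.
#' @return A tibble of pairwise comparisons with significance letters.
#' @method tidy group_stats
#' @export
tidy.group_stats <- function(x, ...) {
  dplyr::left_join(x$tukey, x$letters,
                   by = c("grassland", "level_i" = "litter"))
}

#' One-row-per-grassland ANOVA summary
#'
#' @param x A `group_stats` object from [group_statistics()].
#' @param ... Unused.
#' @return A tibble with `grassland`, `f_stat`, degrees of freedom,
#'   `p_value` and the distributional diagnostics.
#' @method glance group_stats
#' @export
glance.group_stats <- function(x, ...) {
  dplyr::left_join(x$anova, x$checks, by = "grassland")
}
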