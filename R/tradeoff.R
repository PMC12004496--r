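#' Min-max standardization of pool benefits
#'
#' Rescales observed pool values to relative benefits in \[0, 1\] by the
#' affine map `(x - min) / (max - min)`. The map is order-preserving and
#' sends the minimum to 0 and the maximum to 1. A degenerate scale (all
#' values equal) is an error: there is no 0/0 convention.
#'
#' @param values Numeric vector of observed pool values (>= 2 values).
#' @param scope_label Optional label naming the standardization scope, used
#'   in the degenerate-scale error message.
#' @return Numeric vector of standardized benefits in \[0, 1\].
#' @export
#' @examples
#' standardize(c(2, 4, 6))
standardize <- function(values, scope_label = NULL) {
  if (length(values) < 2) abort("Need at least 2 values to standardize.")
  lo <- min(values)
  hi <- max(values)
  if (hi == lo) {
    abort(paste0(
      "Degenerate standardization scale (all values equal)",
      if (!is.null(scope_label)) paste0(" in scope ", scope_label), "."
    ))
  }
  (values - lo) / (hi - lo)
}

#' Trade-off index between two standardized benefits
#'
#' The trade-off between two services is the root-mean-square deviation of
#' their standardized benefits from their common mean,
#' `sqrt(((a - m)^2 + (b - m)^2) / (n - 1))` with `m = (a + b)/2` and
#' `n = 2`, which equals `|a - b| / sqrt(2)`: geometrically, the
#' perpendicular distance from the point `(a, b)` to the 1:1 line. It is
#' symmetric, zero iff the benefits coincide, and at most `1/sqrt(2)`.
#'
#' @param a_std,b_std Standardized benefits in \[0, 1\]. Vectorized.
#' @return Trade-off index in \[0, 1/sqrt(2)\].
#' @export
#' @examples
#' tradeoff_index(1, 0) # maximal imbalance, 1/sqrt(2)
#' tradeoff_index(0.6, 0.2)
tradeoff_index <- function(a_std, b_std) {
  if (any(a_std < 0 | a_std > 1) || any(b_std < 0 | b_std > 1)) {
    abort("Standardized benefits must lie in [0, 1].")
  }
  m <- (a_std + b_std) / 2
  n <- 2
  sqrt(((a_std - m)^2 + (b_std - m)^2) / (n - 1))
}

#' Trade-off propensity relative to the 1:1 line
#'
#' Classifies which pool the trade-off favors. With the plant benefit on
#' the y axis and the microbial benefit on the x axis, a point above the
#' 1:1 line (plant benefit larger) favors TPCP and a point below favors
#' MBCP; points within `tol` of the line are neutral.
#'
#' @param tpcp_std Standardized total plant pool benefit, in \[0, 1\].
#' @param mbcp_std Standardized microbial pool benefit, in \[0, 1\].
#' @param tol Neutrality tolerance, >= 0. The default `1e-12` treats only
#'   exact ties (to rounding) as neutral.
#' @return Character vector over `{"TPCP", "MBCP", "neutral"}`.
#' @export
#' @examples
#' propensity(0.8, 0.2)
propensity <- function(tpcp_std, mbcp_std, tol = 1e-12) {
  if (any(tpcp_std < 0 | tpcp_std > 1) || any(mbcp_std < 0 | mbcp_std > 1)) {
    abort("Standardized benefits must lie in [0, 1].")
  }
  if (any(tol < 0)) abort("`tol` must be non-negative.")
  d <- tpcp_std - mbcp_std
  dplyr::case_when(d > tol ~ "TPCP", d < -tol ~ "MBCP", TRUE ~ "neutral")
}

#' Trade-off table per grassland and litter treatment
#'
#' Standardizes the total plant pool (TPCP) and microbial pool (MBCP)
#' across all treatment-by-replicate observations within a scope, then
#' computes one trade-off index and propensity per grassland-by-litter
#' cell.
#'
#' Two under-determined choices are exposed as arguments:
#'
#' * `scope`: each pool's min-max bounds come either from that grassland's
#'   observations alone (`"per_grassland"`, default; each grassland's
#'   treatment ranking stands on its own) or from the pooled data
#'   (`"global"`, for cross-grassland comparison).
#' * `aggregation`: `"mean_then_index"` (default) standardizes replicate
#'   observations, averages them within each treatment, and computes the
#'   index on the treatment-mean benefits; `"index_then_mean"` computes a
#'   per-replicate index first and averages those (propensity then follows
#'   the mean signed difference).
#'
#' @param pools A pools tibble from [derive_pools()] (columns `grassland`,
#'   `litter`, `tpcp_g_m2`, `mbcp`).
#' @param scope `"per_grassland"` or `"global"`.
#' @param aggregation `"mean_then_index"` or `"index_then_mean"`.
#' @param tol Neutrality tolerance passed to [propensity()].
#' @return A tibble of class `tradeoff_tbl`: one row per grassland-litter
#'   cell with `tpcp_std`, `mbcp_std`, `index`, `propensity`, `scope` and
#'   `aggregation`.
#' @export
tradeoff_table <- function(pools,
                           scope = c("per_grassland", "global"),
                           aggregation = c("mean_then_index", "index_then_mean"),
                           tol = 1e-12) {
  scope <- match.arg(scope)
  aggregation <- match.arg(aggregation)
  needed <- c("grassland", "litter", "tpcp_g_m2", "mbcp")
  missing_cols <- setdiff(needed, names(pools))
  if (length(missing_cols) > 0) {
    abort(paste0("`pools` is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }

  std_within <- function(df, label) {
    dplyr::mutate(
      df,
      tpcp_std = standardize(.data$tpcp_g_m2, scope_label = label),
      mbcp_std = standardize(.data$mbcp, scope_label = label)
    )
  }
  std <- if (scope == "global") {
    std_within(pools, "global")
  } else {
    pools |>
      dplyr::group_by(.data$grassland) |>
      dplyr::group_modify(~ std_within(.x, paste0("grassland=", .y$grassland))) |>
      dplyr::ungroup()
  }

  if (aggregation == "mean_then_index") {
    out <- std |>
      dplyr::group_by(.data$grassland, .data$litter) |>
      dplyr::summarise(
        tpcp_std = mean(.data$tpcp_std),
        mbcp_std = mean(.data$mbcp_std),
        .groups = "drop"
      ) |>
      dplyr::mutate(
        index = tradeoff_index(.data$tpcp_std, .data$mbcp_std),
        propensity = propensity(.data$tpcp_std, .data$mbcp_std, tol = tol)
      )
  } else {
    out <- std |>
      dplyr::group_by(.data$grassland, .data$litter) |>
      dplyr::summarise(
        index = mean(tradeoff_index(.data$tpcp_std, .data$mbcp_std)),
        tpcp_std = mean(.data$tpcp_std),
        mbcp_std = mean(.data$mbcp_std),
        .groups = "drop"
      ) |>
      dplyr::mutate(
        propensity = propensity(.data$tpcp_std, .data$mbcp_std, tol = tol)
      ) |>
      dplyr::relocate("tpcp_std", "mbcp_std", .before = "index")
  }

  out <- dplyr::mutate(out, scope = scope, aggregation = aggregation)
  class(out) <- c("tradeoff_tbl", class(out))
  out
}
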