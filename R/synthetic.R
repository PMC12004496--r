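#' Default treatment-cell means for the synthetic generator
#'
#' One row per grassland-by-litter cell with the mean of every measured
#' variable. The peak-treatment values anchor each grassland: aboveground
#' and root biomass, tissue carbon contents and (for the grazed meadows)
#' profile MBC peak at the full litter dose T3, while the fenced meadow's
#' MBC rises to its peak at T2 and falls back at T3. Non-peak levels scale
#' the anchor linearly from 70% (T0) to 100% (peak), an illustrative
#' monotone dose response, not the study's data. Profile MBC is split over
#' the three 10-cm layers as 50/30/20% (microbial biomass declines with
#' depth) and bulk density increases with depth (1.1, 1.2, 1.3 g/cm3),
#' constant across treatments.
#'
#' @return A tibble with columns `grassland`, `litter`, `agb_g_m2`,
#'   `rb_g_m2`, `apc_mg_g`, `rc_mg_g`, `mbc_0_10_mg_kg`, `mbc_10_20_mg_kg`,
#'   `mbc_20_30_mg_kg`, `bd_0_10`, `bd_10_20`, `bd_20_30`.
#' @export
default_cell_means <- function() {
  ramp <- c(T0 = 0.7, T1 = 0.8, T2 = 0.9, T3 = 1.0)
  # fenced MBC peaks at T2, declines at T3
  mbc_ramp <- list(
    fenced = c(T0 = 0.70, T1 = 0.85, T2 = 1.00, T3 = 0.90),
    light = ramp,
    moderate = ramp
  )
  anchors <- tibble(
    grassland = GRASSLAND_LEVELS,
    agb = c(213.35, 124.01, 102.54),
    rb = c(118.52, 138.51, 98.40),
    apc = c(368.43, 407.07, 412.94),
    rc = c(300.05, 249.23, 270.77),
    mbc = c(1005.14, 889.68, 966.02)
  )
  layer_frac <- c(0.5, 0.3, 0.2)
  bd <- c(1.1, 1.2, 1.3)

  purrr::map_dfr(seq_len(nrow(anchors)), function(i) {
    a <- anchors[i, ]
    purrr::map_dfr(LITTER_LEVELS, function(lv) {
      r <- ramp[[lv]]
      mbc_total <- a$mbc * mbc_ramp[[a$grassland]][[lv]]
      tibble(
        grassland = a$grassland, litter = lv,
        agb_g_m2 = a$agb * r, rb_g_m2 = a$rb * r,
        apc_mg_g = a$apc * r, rc_mg_g = a$rc * r,
        mbc_0_10_mg_kg = mbc_total * layer_frac[1],
        mbc_10_20_mg_kg = mbc_total * layer_frac[2],
        mbc_20_30_mg_kg = mbc_total * layer_frac[3],
        bd_0_10 = bd[1], bd_10_20 = bd[2], bd_20_30 = bd[3]
      )
    })
  })
}

#' Configuration for the synthetic plot-table generator
#'
#' Describes a factorial grazing-by-litter field design: which grasslands
#' and litter levels to simulate, the per-cell variable means, the
#' replicate count, the noise level and the seed. The default emulates the
#' full 3 grassland x 4 litter x 4 replicate layout.
#'
#' @param grasslands Subset of `c("fenced", "light", "moderate")`.
#' @param litter_levels Subset of `c("T0", "T1", "T2", "T3")`.
#' @param n_replicates Replicates per cell, integer >= 2.
#' @param cell_means Cell-mean table as from [default_cell_means()]; must
#'   contain every requested grassland-litter cell with a complete mean
#'   vector.
#' @param noise_cv Coefficient of variation of the additive replicate
#'   noise, >= 0; either a single number applied to every variable or a
#'   named vector over variable columns. Default 0.1.
#' @param shared_plot_cv CV of an optional shared plot-level multiplicative
#'   factor applied to both biomass variables, inducing a realistic
#'   aboveground-root correlation. Default 0 (independent noise).
#' @param seed Integer seed; generation is fully reproducible from it.
#' @param layer_plan Soil layer plan; see [default_layer_plan()].
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(grasslands = GRASSLAND_LEVELS,
                             litter_levels = LITTER_LEVELS,
                             n_replicates = 4,
                             cell_means = default_cell_means(),
                             noise_cv = 0.1,
                             shared_plot_cv = 0,
                             seed = 1L,
                             layer_plan = default_layer_plan()) {
  grasslands <- match.arg(grasslands, GRASSLAND_LEVELS, several.ok = TRUE)
  litter_levels <- match.arg(litter_levels, LITTER_LEVELS, several.ok = TRUE)
  if (n_replicates < 2 || n_replicates != round(n_replicates)) {
    abort("`n_replicates` must be an integer >= 2.")
  }
  if (any(noise_cv < 0) || any(shared_plot_cv < 0)) {
    abort("`noise_cv` and `shared_plot_cv` must be non-negative.")
  }
  layer_plan <- validate_layer_plan(layer_plan)
  var_cols <- c("agb_g_m2", "rb_g_m2", "apc_mg_g", "rc_mg_g",
                layer_column_names(layer_plan, "mbc"),
                layer_column_names(layer_plan, "bd"))
  missing_cols <- setdiff(c("grassland", "litter", var_cols), names(cell_means))
  if (length(missing_cols) > 0) {
    abort(paste0("`cell_means` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  wanted <- expand.grid(grassland = grasslands, litter = litter_levels,
                        stringsAsFactors = FALSE)
  have <- paste(cell_means$grassland, cell_means$litter)
  absent <- !paste(wanted$grassland, wanted$litter) %in% have
  if (any(absent)) {
    abort(paste0("`cell_means` lacks requested cell(s): ",
                 paste(paste(wanted$grassland, wanted$litter)[absent],
                       collapse = "; ")))
  }
  if (any(is.na(cell_means[var_cols])) || any(cell_means[var_cols] < 0)) {
    abort("`cell_means` must be complete and non-negative.")
  }
  if (is.null(names(noise_cv))) {
    if (length(noise_cv) != 1) abort("Unnamed `noise_cv` must be a single number.")
    noise_cv <- stats::setNames(rep(noise_cv, length(var_cols)), var_cols)
  } else {
    unknown <- setdiff(names(noise_cv), var_cols)
    if (length(unknown) > 0) {
      abort(paste0("Unknown `noise_cv` name(s): ", paste(unknown, collapse = ", ")))
    }
    full <- stats::setNames(rep(0, length(var_cols)), var_cols)
    full[names(noise_cv)] <- noise_cv
    noise_cv <- full
  }

  structure(list(
    grasslands = grasslands, litter_levels = litter_levels,
    n_replicates = as.integer(n_replicates),
    cell_means = cell_means[have %in% paste(wanted$grassland, wanted$litter), ],
    noise_cv = noise_cv, shared_plot_cv = shared_plot_cv,
    seed = as.integer(seed), layer_plan = layer_plan,
    var_cols = var_cols
  ), class = "synthetic_config")
}

# truncated-at-zero normal draws: resample negatives so the realized
# distribution is conditionally non-negative; bias is negligible when
# cv <= 0.1 (the mean sits >= 10 sd from zero)
rnorm_trunc0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- which(x < 0)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < 0)
  }
  x
}

#' Generate a synthetic plot table
#'
#' Draws `n_replicates` plot records per requested grassland-by-litter
#' cell. Each variable is drawn independently from a truncated-at-zero
#' normal with the configured cell mean and `sd = mean * noise_cv`;
#' an optional shared plot-level factor couples the two biomass draws.
#' Two calls with the same config (and seed) return identical tables.
#'
#' @param config A [synthetic_config()].
#' @return A tibble with the same schema that [read_plot_table()] accepts,
#'   already validated (factors on canonical levels).
#' @export
generate_plots <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    abort("`config` must be built with synthetic_config().")
  }
  cm <- config$cell_means
  withr::with_seed(config$seed, {
    rows <- purrr::map_dfr(seq_len(nrow(cm)), function(i) {
      cell <- cm[i, ]
      draws <- purrr::map(config$var_cols, function(v) {
        rnorm_trunc0(config$n_replicates, cell[[v]],
                     cell[[v]] * config$noise_cv[[v]])
      })
      names(draws) <- config$var_cols
      out <- tibble(
        grassland = cell$grassland, litter = cell$litter,
        replicate = seq_len(config$n_replicates)
      )
      out <- dplyr::bind_cols(out, as_tibble(draws))
      if (config$shared_plot_cv > 0) {
        f <- rnorm_trunc0(config$n_replicates, 1, config$shared_plot_cv)
        out$agb_g_m2 <- out$agb_g_m2 * f
        out$rb_g_m2 <- out$rb_g_m2 * f
      }
      out
    })
    validate_plot_table(rows, config$layer_plan)
  })
}

#' Ground truth implied by a synthetic configuration
#'
#' Applies the carbon-pool formulas to the configured cell means
#' (noise-free) to obtain the expected per-cell pools, and the trade-off
#' machinery to those expected pools to obtain the expected index and
#' propensity per cell. Serves as the recovery target for pipeline tests:
#' with small noise and many replicates, estimates from [generate_plots()]
#' data converge to these values.
#'
#' @param config A [synthetic_config()].
#' @inheritParams derive_pools
#' @param scope,aggregation Passed to [tradeoff_table()].
#' @return A list with `pools` (expected cell-mean pools tibble) and
#'   `tradeoffs` (expected [tradeoff_table()] of the noise-free means).
#' @export
ground_truth <- function(config,
                         unit_mode = c("literal", "si"),
                         bd_unit = c("g_cm3", "g_m3"),
                         scope = c("per_grassland", "global"),
                         aggregation = c("mean_then_index", "index_then_mean")) {
  if (!inherits(config, "synthetic_config")) {
    abort("`config` must be built with synthetic_config().")
  }
  scope <- match.arg(scope)
  aggregation <- match.arg(aggregation)
  mean_table <- dplyr::mutate(config$cell_means, replicate = 1L,
                              .after = "litter")
  mean_table <- validate_plot_table(mean_table, config$layer_plan)
  pools <- derive_pools(mean_table, unit_mode = unit_mode, bd_unit = bd_unit,
                        layer_plan = config$layer_plan)

  # noise-free means: both aggregation modes coincide (one value per cell);
  # a pool with identical expected values across cells has no trade-off
  # scale — flag it and pin the benefit at the midpoint so the expected
  # index is 0 and the propensity neutral
  std_or_mid <- function(v, label) {
    if (max(v) == min(v)) {
      warn(paste0("Degenerate ground-truth standardization (", label,
                  "): all expected values equal; benefit fixed at 0.5."))
      rep(0.5, length(v))
    } else {
      standardize(v, scope_label = label)
    }
  }
  std_group <- function(df, label) {
    dplyr::mutate(
      df,
      tpcp_std = std_or_mid(.data$tpcp_g_m2, paste0("TPCP, ", label)),
      mbcp_std = std_or_mid(.data$mbcp, paste0("MBCP, ", label))
    )
  }
  std <- if (scope == "global") {
    std_group(pools, "global")
  } else {
    pools |>
      dplyr::group_by(.data$grassland) |>
      dplyr::group_modify(~ std_group(.x, paste0("grassland=", .y$grassland))) |>
      dplyr::ungroup()
  }
  trade <- std |>
    dplyr::transmute(
      grassland = .data$grassland, litter = .data$litter,
      tpcp_std = .data$tpcp_std, mbcp_std = .data$mbcp_std,
      index = tradeoff_index(.data$tpcp_std, .data$mbcp_std),
      propensity = propensity(.data$tpcp_std, .data$mbcp_std),
      scope = scope, aggregation = aggregation
    )
  class(trade) <- c("tradeoff_tbl", class(trade))
  list(pools = dplyr::select(pools, -"replicate"), tradeoffs = trade)
}

#' Read a synthetic-generator configuration from a YAML or JSON file
#'
#' Accepts a key-value file whose top-level keys are the arguments of
#' [synthetic_config()] (scalar or vector values; `cell_means` may be a
#' list of row records). Unknown keys are an error.
#'
#' @param path Path to a `.yml`/`.yaml` or `.json` file.
#' @return A [synthetic_config()].
#' @export
synthetic_config_from_file <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) abort("Package `yaml` required.")
    yaml::read_yaml(path)
  } else if (ext == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE)) abort("Package `jsonlite` required.")
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    abort("Config file must be .yaml/.yml or .json.")
  }
  allowed <- setdiff(names(formals(synthetic_config)), "layer_plan")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  if (!is.null(raw$cell_means)) raw$cell_means <- as_tibble(raw$cell_means)
  if (!is.null(raw$noise_cv) && !is.null(names(raw$noise_cv))) {
    raw$noise_cv <- unlist(raw$noise_cv)
  }
  do.call(synthetic_config, raw)
}
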