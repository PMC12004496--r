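#' Default soil sampling layer plan
#'
#' The profile is sampled in three contiguous 10-cm layers from the surface
#' down to 30 cm, matching the standard auger protocol for alpine meadow
#' soils. Layer bounds drive both the expected input column names
#' (`mbc_0_10_mg_kg`, `bd_0_10`, ...) and the per-layer pool summation.
#'
#' @param depth_cm Total profile depth in cm. Must be divisible by
#'   `layer_cm`.
#' @param layer_cm Thickness of each layer in cm.
#' @return A tibble with columns `top_cm` and `bottom_cm`, one row per layer,
#'   ordered from the surface downwards.
#' @export
#' @examples
#' default_layer_plan()
default_layer_plan <- function(depth_cm = 30, layer_cm = 10) {
  if (depth_cm <= 0 || layer_cm <= 0 || depth_cm %% layer_cm != 0) {
    abort("`depth_cm` must be a positive multiple of `layer_cm`.")
  }
  tops <- seq(0, depth_cm - layer_cm, by = layer_cm)
  tibble(top_cm = tops, bottom_cm = tops + layer_cm)
}

# column names implied by a layer plan, e.g. mbc_0_10_mg_kg / bd_0_10
layer_column_names <- function(layer_plan, what = c("mbc", "bd")) {
  what <- match.arg(what)
  stem <- paste0(what, "_", layer_plan$top_cm, "_", layer_plan$bottom_cm)
  if (what == "mbc") paste0(stem, "_mg_kg") else stem
}

validate_layer_plan <- function(layer_plan) {
  if (nrow(layer_plan) == 0) abort("Layer plan must contain at least one layer.")
  if (any(layer_plan$bottom_cm <= layer_plan$top_cm)) {
    abort("Each layer must have bottom_cm > top_cm.")
  }
  ord <- order(layer_plan$top_cm)
  lp <- layer_plan[ord, ]
  if (nrow(lp) > 1 && any(lp$top_cm[-1] != lp$bottom_cm[-nrow(lp)])) {
    abort("Layers must be contiguous and non-overlapping.")
  }
  lp
}

#' Canonicalize litter-treatment labels
#'
#' Field sheets and figures label the four glucose-addition levels
#' inconsistently: the control appears as `T0`, `F0`, `L0`, `M0` or `CK`,
#' and each addition level carries an optional grassland prefix (`F1`, `L2`,
#' `M3`, ...). The grassland letter is redundant with the grassland column,
#' so all synonyms collapse onto the canonical `T0`-`T3` coding. The mapping
#' is idempotent: canonical labels pass through unchanged.
#'
#' @param x Character vector of raw treatment labels.
#' @return Character vector of canonical labels (`"T0"` ... `"T3"`).
#' @export
#' @examples
#' normalize_litter(c("CK", "L2", "T3", "f1"))
normalize_litter <- function(x) {
  raw <- trimws(toupper(as.character(x)))
  out <- ifelse(raw == "CK", "T0", sub("^[TFLM]([0-3])$", "T\\1", raw))
  bad <- !out %in% LITTER_LEVELS
  if (any(bad)) {
    abort(paste0(
      "Unknown litter treatment label(s): ",
      paste(unique(raw[bad]), collapse = ", "),
      ". Expected T0-T3, F/L/M-prefixed synonyms, or CK."
    ))
  }
  out
}

# grassland synonyms: fenced/ungrazed/F, light(ly)/L, moderate(ly)/M
normalize_grassland <- function(x) {
  raw <- trimws(tolower(as.character(x)))
  map <- c(
    fenced = "fenced", ungrazed = "fenced", f = "fenced",
    light = "light", lightly = "light", l = "light",
    moderate = "moderate", moderately = "moderate", m = "moderate"
  )
  out <- unname(map[raw])
  bad <- is.na(out)
  if (any(bad)) {
    abort(paste0(
      "Unknown grassland label(s): ", paste(unique(raw[bad]), collapse = ", "),
      ". Expected fenced/ungrazed, light(ly) or moderate(ly)."
    ))
  }
  out
}

#' Read and validate a plot-level measurement table
#'
#' Reads a CSV of per-replicate plot measurements (design factors, plant
#' biomass, tissue carbon content, per-layer soil microbial biomass carbon
#' and bulk density), validates every row, and canonicalizes treatment and
#' grassland labels. Rows with missing cells are rejected rather than
#' imputed, and every violated constraint is reported with its row index.
#'
#' Required columns (case-insensitive): `grassland`, `litter`, `replicate`,
#' `agb_g_m2`, `rb_g_m2`, `apc_mg_g`, `rc_mg_g`, plus one
#' `mbc_<top>_<bottom>_mg_kg` and one `bd_<top>_<bottom>` column per layer
#' of `layer_plan`.
#'
#' @param path Path to a CSV file.
#' @param layer_plan Soil layer plan; see [default_layer_plan()].
#' @return A tibble of validated plot records, one row per replicate plot,
#'   with `grassland` and `litter` as factors on their canonical levels and
#'   the original row order preserved.
#' @export
read_plot_table <- function(path, layer_plan = default_layer_plan()) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  layer_plan <- validate_layer_plan(layer_plan)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(raw) <- tolower(names(raw))

  required <- c(
    "grassland", "litter", "replicate",
    "agb_g_m2", "rb_g_m2", "apc_mg_g", "rc_mg_g",
    layer_column_names(layer_plan, "mbc"),
    layer_column_names(layer_plan, "bd")
  )
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Input table is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  raw <- raw[required]
  validate_plot_table(raw, layer_plan)
}

# row-level validation shared by read_plot_table and generate_plots
validate_plot_table <- function(df, layer_plan = default_layer_plan()) {
  layer_plan <- validate_layer_plan(layer_plan)
  mbc_cols <- layer_column_names(layer_plan, "mbc")
  bd_cols <- layer_column_names(layer_plan, "bd")
  num_cols <- c("replicate", "agb_g_m2", "rb_g_m2", "apc_mg_g", "rc_mg_g",
                mbc_cols, bd_cols)

  for (col in num_cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vnum <- as.numeric(v))
      newly_na <- which(is.na(vnum) & !is.na(v))
      if (length(newly_na) > 0) {
        abort(paste0(
          "Column `", col, "` has unparseable numeric value at row(s): ",
          paste(head(newly_na, 5), collapse = ", ")
        ))
      }
      df[[col]] <- vnum
    }
  }

  incomplete <- which(!stats::complete.cases(df))
  if (length(incomplete) > 0) {
    abort(paste0(
      "Row(s) with missing cells rejected (no imputation): ",
      paste(head(incomplete, 10), collapse = ", ")
    ))
  }

  check_range <- function(col, lo, hi = Inf, strict_lo = FALSE) {
    v <- df[[col]]
    bad <- if (strict_lo) which(v <= lo) else which(v < lo | v > hi)
    if (length(bad) > 0) {
      abort(paste0(
        "Column `", col, "` out of range at row(s): ",
        paste(head(bad, 5), collapse = ", "),
        if (strict_lo) paste0(" (must be > ", lo, ")")
        else paste0(" (must be in [", lo, ", ", hi, "])")
      ))
    }
  }
  check_range("agb_g_m2", 0)
  check_range("rb_g_m2", 0)
  check_range("apc_mg_g", 0, 1000)
  check_range("rc_mg_g", 0, 1000)
  for (col in mbc_cols) check_range(col, 0)
  for (col in bd_cols) check_range(col, 0, strict_lo = TRUE)
  if (any(df$replicate <= 0 | df$replicate != round(df$replicate))) {
    abort("Column `replicate` must contain positive integer IDs.")
  }

  df$grassland <- factor(normalize_grassland(df$grassland), levels = GRASSLAND_LEVELS)
  df$litter <- factor(normalize_litter(df$litter), levels = LITTER_LEVELS)
  as_tibble(df)
}

#' Write a result table to CSV
#'
#' Writes any of the pipeline's result tibbles with a deterministic column
#' order and numbers formatted to 6 significant digits, so that writing and
#' re-reading round-trips values to that precision and repeated runs are
#' byte-identical.
#'
#' @param records A data frame (possibly empty; an empty frame yields a
#'   header-only CSV).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  if (!is.data.frame(records)) abort("`records` must be a data frame.")
  out <- as_tibble(records)
  out <- dplyr::mutate(out, dplyr::across(
    dplyr::where(is.numeric),
    ~ as.numeric(signif(.x, 6))
  ))
  out <- dplyr::mutate(out, dplyr::across(dplyr::where(is.factor), as.character))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
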