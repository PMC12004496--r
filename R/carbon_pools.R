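#' Carbon pool from biomass and tissue carbon content
#'
#' A plant carbon pool (g C/m2) is the product of dry biomass (g/m2) and
#' tissue carbon content (mg C/g dry mass), divided by 1000 to convert mg
#' to g. Applies to both the aboveground community pool (APCP) and the root
#' pool (RCP).
#'
#' @param biomass Dry biomass, g/m2, non-negative. Vectorized.
#' @param carbon_content Tissue carbon content, mg/g, in \[0, 1000\].
#' @return Carbon pool, g C/m2.
#' @export
#' @examples
#' compute_pool(213.35, 368.43) # fenced meadow aboveground pool at peak litter
compute_pool <- function(biomass, carbon_content) {
  if (any(biomass < 0)) abort("`biomass` must be non-negative.")
  if (any(carbon_content < 0 | carbon_content > 1000)) {
    abort("`carbon_content` must lie in [0, 1000] mg/g.")
  }
  biomass * carbon_content / 1000
}

#' Total plant community carbon pool
#'
#' The total plant community carbon pool (TPCP) is the exact sum of the
#' aboveground community pool and the root pool.
#'
#' @param apcp Aboveground plant community carbon pool, g/m2, non-negative.
#' @param rcp Root carbon pool, g/m2, non-negative.
#' @return TPCP, g/m2.
#' @export
total_plant_pool <- function(apcp, rcp) {
  if (any(apcp < 0) || any(rcp < 0)) abort("Pools must be non-negative.")
  apcp + rcp
}

#' Soil bulk density from the ring-knife method
#'
#' Bulk density is oven-dry soil mass divided by the sampling ring volume.
#' The quotient carries whatever unit pair is supplied (g and cm3 give
#' g/cm3).
#'
#' @param dry_soil_mass Oven-dry soil mass, non-negative.
#' @param ring_volume Ring (core) volume, strictly positive.
#' @return Bulk density, mass per volume.
#' @export
bulk_density <- function(dry_soil_mass, ring_volume) {
  if (any(ring_volume <= 0)) abort("`ring_volume` must be strictly positive.")
  if (any(dry_soil_mass < 0)) abort("`dry_soil_mass` must be non-negative.")
  dry_soil_mass / ring_volume
}

#' Microbial biomass carbon from chloroform fumigation-extraction
#'
#' MBC is the fumigation C flush (fumigated minus unfumigated extractable
#' C) divided by the extraction efficiency factor kEC. Negative flushes are
#' physically meaningless (the unfumigated extract cannot exceed the
#' fumigated one except by measurement error) and are clamped to zero with
#' a warning.
#'
#' @param c_fumigated Extractable C of the fumigated portion, mg/kg.
#' @param c_unfumigated Extractable C of the unfumigated portion, mg/kg.
#' @param kec Extraction efficiency factor, in (0, 1\]. Default 0.45.
#' @return MBC, mg/kg soil.
#' @export
#' @examples
#' mbc_from_fumigation(145, 100) # flush of 45 -> 100 mg/kg at kEC = 0.45
mbc_from_fumigation <- function(c_fumigated, c_unfumigated, kec = 0.45) {
  if (any(kec <= 0) || any(kec > 1)) abort("`kec` must lie in (0, 1].")
  flush <- c_fumigated - c_unfumigated
  if (any(flush < 0)) {
    warn("Negative fumigation flush clamped to 0 (check extract pairing).")
    flush <- pmax(flush, 0)
  }
  flush / kec
}

#' Per-layer microbial biomass carbon pool
#'
#' Converts a layer's MBC concentration (mg/kg soil) into an areal pool
#' using bulk density and layer thickness. Two unit conventions are
#' supported:
#'
#' * `"literal"` (default): `MBC x BD x H x 10`, the published field
#'   formula applied verbatim on the supplied numbers. Its scale depends on
#'   the BD unit convention of the data source.
#' * `"si"`: the dimensionally consistent areal stock in g C/m2 with BD in
#'   g/cm3: `MBC x BD x H / 100` (a 1 m2 column of thickness H cm at BD
#'   g/cm3 holds `10 x BD x H` kg of soil).
#'
#' The two modes differ by a constant factor of 1000 when BD is supplied in
#' g/cm3 in both, so rankings, standardized benefits and trade-off indices
#' are identical under either mode.
#'
#' @param mbc Microbial biomass carbon, mg/kg, non-negative.
#' @param bd Bulk density, non-negative; see `bd_unit`.
#' @param h Layer thickness, cm, non-negative.
#' @param unit_mode `"literal"` or `"si"`.
#' @param bd_unit Unit in which `bd` is supplied: `"g_cm3"` (default) or
#'   `"g_m3"`. Under `"si"` the value is converted to g/cm3 first; under
#'   `"literal"` it enters the formula as given.
#' @return Layer pool (g/m2 under `"si"`).
#' @export
mbcp_layer <- function(mbc, bd, h,
                       unit_mode = c("literal", "si"),
                       bd_unit = c("g_cm3", "g_m3")) {
  unit_mode <- match.arg(unit_mode)
  bd_unit <- match.arg(bd_unit)
  if (any(mbc < 0) || any(bd < 0) || any(h < 0)) {
    abort("`mbc`, `bd` and `h` must be non-negative.")
  }
  if (unit_mode == "literal") {
    mbc * bd * h * 10
  } else {
    bd_g_cm3 <- if (bd_unit == "g_m3") bd / 1e6 else bd
    mbc * bd_g_cm3 * h / 100
  }
}

#' Profile microbial biomass carbon pool
#'
#' The 0-to-full-depth microbial pool is the sum of the per-layer pools.
#' Splitting any layer into sublayers with the same MBC and bulk density
#' leaves the total unchanged.
#'
#' @param layers A data frame with columns `top_cm`, `bottom_cm`, `mbc`,
#'   `bd` (one row per layer, contiguous and non-overlapping).
#' @inheritParams mbcp_layer
#' @return Profile pool (scalar).
#' @export
mbcp_profile <- function(layers, unit_mode = c("literal", "si"),
                         bd_unit = c("g_cm3", "g_m3")) {
  unit_mode <- match.arg(unit_mode)
  bd_unit <- match.arg(bd_unit)
  if (!is.data.frame(layers) || nrow(layers) == 0) {
    abort("`layers` must be a non-empty data frame of soil layers.")
  }
  plan <- validate_layer_plan(layers[c("top_cm", "bottom_cm")])
  h <- layers$bottom_cm - layers$top_cm
  sum(mbcp_layer(layers$mbc, layers$bd, h, unit_mode, bd_unit))
}

#' Derive all carbon pools for a table of plot records
#'
#' Applies the pool formulas to every validated plot record: APCP from
#' aboveground biomass and carbon content, RCP from root biomass and root
#' carbon content, TPCP as their exact sum, and MBCP as the layer-summed
#' microbial pool. Also reports the thickness-weighted profile-mean MBC
#' concentration.
#'
#' @param plots A plot table as returned by [read_plot_table()] or
#'   [generate_plots()].
#' @inheritParams mbcp_layer
#' @param layer_plan Soil layer plan matching the table's layer columns;
#'   by default inferred from the `mbc_<top>_<bottom>_mg_kg` column names.
#' @return A tibble with one row per plot: `grassland`, `litter`,
#'   `replicate`, `apcp_g_m2`, `rcp_g_m2`, `tpcp_g_m2`, `mbc_mg_kg`
#'   (profile mean) and `mbcp`.
#' @export
derive_pools <- function(plots,
                         unit_mode = c("literal", "si"),
                         bd_unit = c("g_cm3", "g_m3"),
                         layer_plan = NULL) {
  unit_mode <- match.arg(unit_mode)
  bd_unit <- match.arg(bd_unit)
  if (is.null(layer_plan)) layer_plan <- infer_layer_plan(plots)
  layer_plan <- validate_layer_plan(layer_plan)
  mbc_cols <- layer_column_names(layer_plan, "mbc")
  bd_cols <- layer_column_names(layer_plan, "bd")
  missing_cols <- setdiff(c(mbc_cols, bd_cols), names(plots))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing layer column(s): ", paste(missing_cols, collapse = ", ")))
  }

  h <- layer_plan$bottom_cm - layer_plan$top_cm
  mbc_mat <- as.matrix(plots[mbc_cols])
  bd_mat <- as.matrix(plots[bd_cols])
  layer_pools <- mbcp_layer(
    mbc = as.vector(mbc_mat),
    bd = as.vector(bd_mat),
    h = rep(h, each = nrow(plots)),
    unit_mode = unit_mode, bd_unit = bd_unit
  )
  mbcp <- rowSums(matrix(layer_pools, nrow = nrow(plots)))
  mbc_profile <- as.vector(mbc_mat %*% h) / sum(h)

  apcp <- compute_pool(plots$agb_g_m2, plots$apc_mg_g)
  rcp <- compute_pool(plots$rb_g_m2, plots$rc_mg_g)
  tibble(
    grassland = plots$grassland,
    litter = plots$litter,
    replicate = plots$replicate,
    apcp_g_m2 = apcp,
    rcp_g_m2 = rcp,
    tpcp_g_m2 = total_plant_pool(apcp, rcp),
    mbc_mg_kg = mbc_profile,
    mbcp = mbcp
  )
}

# recover the layer plan from mbc_<top>_<bottom>_mg_kg column names
infer_layer_plan <- function(plots) {
  m <- regmatches(names(plots), regexec("^mbc_([0-9]+)_([0-9]+)_mg_kg$", names(plots)))
  hits <- m[lengths(m) == 3]
  if (length(hits) == 0) {
    abort("No `mbc_<top>_<bottom>_mg_kg` columns found; supply `layer_plan`.")
  }
  plan <- tibble(
    top_cm = as.numeric(vapply(hits, `[`, "", 2)),
    bottom_cm = as.numeric(vapply(hits, `[`, "", 3))
  )
  plan[order(plan$top_cm), ]
}
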