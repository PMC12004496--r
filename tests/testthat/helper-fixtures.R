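# shared fixtures built in code

# minimal valid plot table (wide schema, three 10-cm layers)
make_plot_tbl <- function(n = 3, grassland = "fenced", litter = c("T0", "L2", "CK")) {
  tibble::tibble(
    grassland = rep_len(grassland, n),
    litter = rep_len(litter, n),
    replicate = seq_len(n),
    agb_g_m2 = 100 + 10 * seq_len(n),
    rb_g_m2 = 50 + 5 * seq_len(n),
    apc_mg_g = 350,
    rc_mg_g = 280,
    mbc_0_10_mg_kg = 500,
    mbc_10_20_mg_kg = 300,
    mbc_20_30_mg_kg = 200,
    bd_0_10 = 1.1, bd_10_20 = 1.2, bd_20_30 = 1.3
  )
}

write_plot_csv <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path)
  path
}

# independent geometric oracle: distance from point (a, b) to the line
# y = x by the point-to-line formula with normal vector (1, -1)
perp_dist_1to1 <- function(a, b) abs(a - b) / sqrt(1^2 + (-1)^2)

# pools tibble with designed per-treatment standardized benefits.
# a_std/b_std: designed TPCP/MBCP standardized means per litter level
# (each must span [0, 1]); replicated exactly (no noise).
make_designed_pools <- function(a_std, b_std, n_rep = 2, grassland = "fenced") {
  stopifnot(length(a_std) == length(b_std), length(a_std) <= 4)
  lev <- c("T0", "T1", "T2", "T3")[seq_along(a_std)]
  tpcp <- 60 + 60 * a_std
  mbcp <- 1000 + 1000 * b_std
  tibble::tibble(
    grassland = factor(rep(grassland, length(lev) * n_rep),
                       levels = c("fenced", "light", "moderate")),
    litter = factor(rep(lev, each = n_rep), levels = c("T0", "T1", "T2", "T3")),
    replicate = rep(seq_len(n_rep), times = length(lev)),
    apcp_g_m2 = rep(tpcp, each = n_rep) / 2,
    rcp_g_m2 = rep(tpcp, each = n_rep) / 2,
    tpcp_g_m2 = rep(tpcp, each = n_rep),
    mbc_mg_kg = rep(mbcp, each = n_rep) / 300,
    mbcp = rep(mbcp, each = n_rep)
  )
}

# synthetic config whose ground-truth standardized benefits are the
# designed vectors (single grassland, literal unit mode, bd = 1):
# tpcp = agb * apc / 1000 with rb = 0; mbcp = 100 * sum(layer mbc).
# Replicate noise of the given cv rides on one variable per pool (agb and
# the surface-layer mbc) so each pool's observations have exactly that cv;
# both pools share the same relative mean structure (min near 0), keeping
# the min-max compression of the standardized scale uniform.
designed_separation_config <- function(a_std, b_std, n_replicates = 30,
                                       noise_cv = 0.05, seed = 1L) {
  lev <- c("T0", "T1", "T2", "T3")[seq_along(a_std)]
  tpcp <- 120 * (a_std + 0.01)
  mbcp <- 2000 * (b_std + 0.01)
  cm <- tibble::tibble(
    grassland = "fenced", litter = lev,
    agb_g_m2 = 2 * tpcp, rb_g_m2 = 0,
    apc_mg_g = 500, rc_mg_g = 500,
    mbc_0_10_mg_kg = mbcp / 100,
    mbc_10_20_mg_kg = 0,
    mbc_20_30_mg_kg = 0,
    bd_0_10 = 1, bd_10_20 = 1, bd_20_30 = 1
  )
  synthetic_config(
    grasslands = "fenced", litter_levels = lev,
    n_replicates = n_replicates, cell_means = cm,
    noise_cv = c(agb_g_m2 = noise_cv, mbc_0_10_mg_kg = noise_cv),
    seed = seed
  )
}
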