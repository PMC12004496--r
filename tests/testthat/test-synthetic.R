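test_that("generation is deterministic in the seed", {
  cfg <- synthetic_config(seed = 123)
  expect_identical(generate_plots(cfg), generate_plots(cfg))
  cfg2 <- synthetic_config(seed = 124)
  expect_false(identical(generate_plots(cfg), generate_plots(cfg2)))
})

test_that("zero noise reproduces the cell means exactly", {
  cfg <- synthetic_config(n_replicates = 3, noise_cv = 0, seed = 1)
  p <- generate_plots(cfg)
  expect_equal(nrow(p), 3 * 4 * 3)
  joined <- dplyr::left_join(
    p, cfg$cell_means,
    by = c("grassland", "litter"), suffix = c("", ".mean")
  )
  for (v in c("agb_g_m2", "rb_g_m2", "apc_mg_g", "mbc_0_10_mg_kg")) {
    expect_equal(joined[[v]], joined[[paste0(v, ".mean")]])
  }
})

test_that("large samples concentrate around the configured means", {
  cfg <- synthetic_config(grasslands = "fenced", n_replicates = 200,
                          noise_cv = 0.1, seed = 777)
  p <- generate_plots(cfg)
  sm <- p |>
    dplyr::group_by(litter) |>
    dplyr::summarise(dplyr::across(
      c("agb_g_m2", "rb_g_m2", "apc_mg_g", "rc_mg_g", "mbc_0_10_mg_kg"),
      list(m = mean, se = ~ sd(.x) / sqrt(dplyr::n()))
    ), .groups = "drop") |>
    dplyr::left_join(cfg$cell_means, by = "litter")
  zs <- c()
  for (v in c("agb_g_m2", "rb_g_m2", "apc_mg_g", "rc_mg_g", "mbc_0_10_mg_kg")) {
    zs <- c(zs, abs(sm[[paste0(v, "_m")]] - sm[[v]]) / sm[[paste0(v, "_se")]])
  }
  # law of large numbers: every cell mean within 3 SE, the bulk within 2
  expect_true(all(zs < 3))
  expect_gte(mean(zs < 2), 0.9)
})

test_that("the shared plot-level factor induces biomass correlation", {
  base <- synthetic_config(grasslands = "fenced", litter_levels = "T3",
                           n_replicates = 200, noise_cv = 0.05, seed = 5)
  coupled <- synthetic_config(grasslands = "fenced", litter_levels = "T3",
                              n_replicates = 200, noise_cv = 0.05,
                              shared_plot_cv = 0.3, seed = 5)
  r0 <- cor(generate_plots(base)$agb_g_m2, generate_plots(base)$rb_g_m2)
  r1 <- cor(generate_plots(coupled)$agb_g_m2, generate_plots(coupled)$rb_g_m2)
  expect_lt(abs(r0), 0.3)
  expect_gt(r1, 0.8)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_replicates = 1), ">= 2")
  expect_error(synthetic_config(noise_cv = -0.1), "non-negative")
  cm <- default_cell_means()
  expect_error(
    synthetic_config(cell_means = cm[cm$litter != "T2", ]),
    "lacks requested cell"
  )
  expect_error(synthetic_config(noise_cv = c(bogus_var = 0.1)), "Unknown")
})

test_that("ground truth applies the pool formulas to the cell means", {
  cfg <- synthetic_config()
  gt <- ground_truth(cfg)
  fen_t3 <- dplyr::filter(gt$pools, grassland == "fenced", litter == "T3")
  expect_equal(fen_t3$apcp_g_m2, 213.35 * 368.43 / 1000)
  expect_equal(gt$pools$tpcp_g_m2, gt$pools$apcp_g_m2 + gt$pools$rcp_g_m2)
  expect_equal(nrow(gt$tradeoffs), 12)
  expect_true(all(gt$tradeoffs$index >= 0 & gt$tradeoffs$index <= 1 / sqrt(2)))
})

test_that("identical cells yield a flagged neutral ground truth", {
  cm <- default_cell_means()
  flat <- cm[cm$grassland == "fenced", ]
  flat[, -(1:2)] <- flat[rep(1, 4), -(1:2)]
  cfg <- synthetic_config(grasslands = "fenced", cell_means = flat)
  expect_warning(gt <- ground_truth(cfg), "Degenerate ground-truth")
  expect_equal(gt$tradeoffs$index, rep(0, 4))
  expect_equal(gt$tradeoffs$propensity, rep("neutral", 4))
})

test_that("estimated trade-off indices converge to ground truth as noise
           shrinks", {
  # The min-max bounds are taken over replicate observations, so the
  # sample range - and with it the compression of the standardized scale -
  # grows with the replicate count: the estimator is consistent in the
  # small-noise limit, not the large-n limit. Accordingly the error is
  # driven down by the noise cv at fixed n.
  a <- c(0.0, 0.2, 1.0, 0.6)
  b <- c(0.1, 0.0, 0.7, 1.0)
  truth <- abs(a - b) / sqrt(2)
  med_err <- vapply(c(0.10, 0.05, 0.01), function(cv) {
    errs <- vapply(1:6, function(s) {
      cfg <- designed_separation_config(a, b, n_replicates = 30,
                                        noise_cv = cv, seed = 1000 + s)
      est <- tradeoff_table(derive_pools(generate_plots(cfg)))$index
      median(abs(est - truth))
    }, 0)
    median(errs)
  }, 0)
  expect_true(all(diff(med_err) < 0))
  expect_lt(med_err[3], 0.005)
})

test_that("configs round-trip through YAML and JSON files", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c(
    "grasslands: [fenced, light]",
    "litter_levels: [T0, T3]",
    "n_replicates: 3",
    "noise_cv: 0.05",
    "seed: 42"
  ), yml)
  cfg <- synthetic_config_from_file(yml)
  expect_equal(cfg$grasslands, c("fenced", "light"))
  expect_equal(cfg$n_replicates, 3L)
  expect_equal(cfg$seed, 42L)

  jsn <- tempfile(fileext = ".json")
  writeLines('{"grasslands": "moderate", "n_replicates": 4, "seed": 7}', jsn)
  cfg2 <- synthetic_config_from_file(jsn)
  expect_equal(cfg2$grasslands, "moderate")
  expect_equal(cfg2$litter_levels, c("T0", "T1", "T2", "T3"))

  writeLines("bogus_key: 1", yml)
  expect_error(synthetic_config_from_file(yml), "Unknown config key")
})
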