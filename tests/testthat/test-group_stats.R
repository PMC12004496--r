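test_that("one-way ANOVA matches the hand-computed F", {
  d <- data.frame(
    y = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
    g = rep(c("a", "b", "c"), each = 3)
  )
  # SSB = 6 on 2 df, SSW = 6 on 6 df -> F = 3 exactly
  res <- one_way_anova(d, "y", "g")
  expect_equal(res$f_stat, 3)
  expect_equal(res$df_between, 2)
  expect_equal(res$df_within, 6)
  expect_equal(res$p_value, pf(3, 2, 6, lower.tail = FALSE))
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  withr::with_seed(21, {
    for (i in 1:10) {
      d <- data.frame(
        y = c(rnorm(6, 0), rnorm(9, 0.8)),
        g = rep(c("a", "b"), c(6, 9))
      )
      f <- one_way_anova(d, "y", "g")$f_stat
      t2 <- stats::t.test(y ~ g, data = d, var.equal = TRUE)$statistic^2
      expect_equal(f, unname(t2))
    }
  })
})

test_that("ANOVA F is invariant under common affine transformation", {
  withr::with_seed(31, {
    d <- data.frame(y = rnorm(20, 5), g = rep(letters[1:4], each = 5))
    f0 <- one_way_anova(d, "y", "g")$f_stat
    d$y <- 13.7 * d$y - 250
    expect_equal(one_way_anova(d, "y", "g")$f_stat, f0)
  })
})

test_that("ANOVA preconditions are enforced", {
  expect_error(one_way_anova(data.frame(y = 1:4, g = "a"), "y", "g"), "2 groups")
  expect_error(
    one_way_anova(data.frame(y = 1:3, g = c("a", "a", "b")), "y", "g"),
    "at least 2 observations"
  )
  expect_error(
    one_way_anova(data.frame(y = rep(1, 8), g = rep(c("a", "b"), 4)), "y", "g"),
    "identical"
  )
})

test_that("well-separated groups get distinct letters, overlapping ones share", {
  withr::with_seed(41, {
    far <- data.frame(
      y = c(rnorm(5, 0, 1), rnorm(5, 100, 1)),
      g = rep(c("lo", "hi"), each = 5)
    )
    tk <- tukey_hsd(far, "y", "g")
    expect_equal(unname(tk$letters[c("hi", "lo")]), c("a", "b"))

    near <- data.frame(
      y = rnorm(24, 50, 1),
      g = rep(letters[1:4], each = 6)
    )
    tk2 <- tukey_hsd(near, "y", "g")
    expect_equal(unname(tk2$letters), rep("a", 4))
  })
})

test_that("letters encode exactly the Tukey significance pattern", {
  # shared letter <=> p_adj >= alpha, checked pair-by-pair on random
  # instances spanning null and strongly structured group means
  withr::with_seed(51, {
    for (i in 1:60) {
      k <- sample(3:6, 1)
      n_per <- sample(3:7, k, replace = TRUE)
      mu <- sample(c(0, 0, 1, 3, 10), k, replace = TRUE)
      d <- data.frame(
        y = rnorm(sum(n_per), rep(mu, n_per), 1),
        g = rep(paste0("g", seq_len(k)), n_per)
      )
      tk <- tukey_hsd(d, "y", "g", alpha = 0.05)
      shares <- function(i, j) {
        any(strsplit(tk$letters[[i]], "")[[1]] %in%
              strsplit(tk$letters[[j]], "")[[1]])
      }
      for (r in seq_len(nrow(tk$pairs))) {
        expect_equal(
          shares(tk$pairs$level_i[r], tk$pairs$level_j[r]),
          tk$pairs$p_adj[r] >= 0.05
        )
      }
    }
  })
})

test_that("letter assignment agrees with the reference multcomp display", {
  withr::with_seed(61, {
    for (i in 1:10) {
      d <- data.frame(
        y = rnorm(30, rep(sample(c(0, 1, 4, 8), 5, replace = TRUE), each = 6), 2),
        g = factor(rep(paste0("g", 1:5), each = 6))
      )
      if (length(unique(round(tapply(d$y, d$g, mean), 6))) < 2) next
      tk <- tukey_hsd(d, "y", "g", alpha = 0.05)
      fit <- stats::aov(y ~ g, data = d)
      ref <- multcomp::cld(multcomp::glht(fit, linfct = multcomp::mcp(g = "Tukey")),
                           level = 0.05)$mcletters$Letters
      # letter identities may differ; the sharing pattern must agree
      shares <- function(lt, i, j) {
        any(strsplit(lt[[i]], "")[[1]] %in% strsplit(lt[[j]], "")[[1]])
      }
      for (a in 1:4) {
        for (b in (a + 1):5) {
          la <- paste0("g", a); lb <- paste0("g", b)
          expect_equal(shares(tk$letters, la, lb), shares(ref, la, lb))
        }
      }
    }
  })
})

test_that("Tukey adjusted p-values dominate unadjusted pairwise t-tests", {
  withr::with_seed(71, {
    d <- data.frame(
      y = rnorm(24, rep(c(0, 0.5, 1, 2), each = 6)),
      g = rep(letters[1:4], each = 6)
    )
    tk <- tukey_hsd(d, "y", "g")
    mse <- anova(stats::aov(y ~ g, data = d))$`Mean Sq`[2]
    for (r in seq_len(nrow(tk$pairs))) {
      yi <- d$y[d$g == tk$pairs$level_i[r]]
      yj <- d$y[d$g == tk$pairs$level_j[r]]
      se <- sqrt(mse * (1 / length(yi) + 1 / length(yj)))
      t_p <- 2 * pt(abs(mean(yi) - mean(yj)) / se, df = 20, lower.tail = FALSE)
      expect_gte(tk$pairs$p_adj[r] + 1e-10, t_p)
    }
  })
})

test_that("per-grassland statistics assemble ANOVA, Tukey and diagnostics", {
  cfg <- synthetic_config(n_replicates = 4, noise_cv = 0.08, seed = 13)
  pools <- derive_pools(generate_plots(cfg))
  gs <- group_statistics(pools, "tpcp_g_m2")
  expect_s3_class(gs, "group_stats")
  expect_equal(nrow(gs$anova), 3)
  expect_equal(gs$anova$df_between, rep(3, 3))
  expect_equal(gs$anova$df_within, rep(12, 3))
  expect_equal(nrow(gs$tukey), 3 * choose(4, 2))
  expect_equal(nrow(gs$letters), 12)
  expect_true(all(c("shapiro_w", "levene_f") %in% names(gs$checks)))
  # broom-style accessors
  expect_equal(nrow(glance(gs)), 3)
  expect_true("letter" %in% names(tidy(gs)))
})

test_that("treatment summary reports designed means, counts and letters", {
  cfg <- synthetic_config(grasslands = "fenced", n_replicates = 5,
                          noise_cv = 1e-4, seed = 3)
  pools <- derive_pools(generate_plots(cfg))
  sm <- treatment_summary(pools, "tpcp_g_m2")
  gt <- ground_truth(cfg)
  expect_equal(sm$mean, gt$pools$tpcp_g_m2, tolerance = 1e-3)
  expect_equal(sm$n, rep(5, 4))
  # near-noise-free: the largest mean is significantly largest, letter "a"
  expect_equal(sm$letter[which.max(sm$mean)], "a")
})

test_that("a single litter level skips the ANOVA with a warning", {
  cfg <- synthetic_config(grasslands = "fenced", litter_levels = "T3",
                          n_replicates = 4, noise_cv = 0.05, seed = 9)
  pools <- derive_pools(generate_plots(cfg))
  expect_warning(sm <- treatment_summary(pools, "tpcp_g_m2"), "single litter")
  expect_true(is.na(sm$letter))
  expect_equal(sm$n, 4)
})
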