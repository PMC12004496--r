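#' One-way ANOVA across treatment groups
#'
#' Classical fixed-effects one-way analysis of variance of a response
#' against a single grouping factor, `F = MS_between / MS_within`, fitted
#' with [stats::aov()].
#'
#' @param data A data frame.
#' @param response Name of the numeric response column (string).
#' @param group Name of the grouping column (string).
#' @return A one-row tibble: `response`, `f_stat`, `df_between`,
#'   `df_within`, `p_value`.
#' @export
#' @examples
#' d <- data.frame(y = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
#'                 g = rep(c("a", "b", "c"), each = 3))
#' one_way_anova(d, "y", "g") # F = 3 on (2, 6) df
one_way_anova <- function(data, response, group) {
  y <- data[[response]]
  g <- droplevels(factor(data[[group]]))
  if (nlevels(g) < 2) abort("Need at least 2 groups for ANOVA.")
  if (any(table(g) < 2)) abort("Every group needs at least 2 observations.")
  if (isTRUE(all(y == y[1]))) {
    abort("Degenerate response: all values identical (zero variance).")
  }
  fit <- aov(y ~ g)
  tab <- anova(fit)
  tibble(
    response = response,
    f_stat = tab$`F value`[1],
    df_between = tab$Df[1],
    df_within = tab$Df[2],
    p_value = tab$`Pr(>F)`[1]
  )
}

#' Tukey HSD multiple comparisons with compact letter display
#'
#' All pairwise group comparisons by the Tukey-Kramer method (studentized
#' range distribution, valid under unequal group sizes) on top of the
#' one-way ANOVA fit, plus a compact letter display in which groups sharing
#' a letter do not differ significantly at `alpha`. Letters are assigned in
#' descending order of group means, so `"a"` always marks the largest
#' group, the convention used in ecology figures.
#'
#' @inheritParams one_way_anova
#' @param alpha Significance level in (0, 1), default 0.05.
#' @return A list of class `tukey_hsd` with elements `pairs` (tibble:
#'   `level_i`, `level_j`, `mean_diff`, `q_stat`, `p_adj`), `letters`
#'   (named character vector, one entry per group level) and `alpha`.
#' @export
tukey_hsd <- function(data, response, group, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  y <- data[[response]]
  g <- droplevels(factor(data[[group]]))
  if (nlevels(g) < 2) abort("Need at least 2 groups for Tukey HSD.")
  fit <- aov(y ~ g)
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$g
  cmp <- strsplit(rownames(tk), "-", fixed = TRUE)

  mse <- anova(fit)$`Mean Sq`[2]
  n_by <- table(g)
  lev_i <- vapply(cmp, `[`, "", 1)
  lev_j <- vapply(cmp, `[`, "", 2)
  se_q <- sqrt(mse / 2 * (1 / n_by[lev_i] + 1 / n_by[lev_j]))
  pairs <- tibble(
    level_i = lev_i,
    level_j = lev_j,
    mean_diff = unname(tk[, "diff"]),
    q_stat = unname(abs(tk[, "diff"]) / se_q),
    p_adj = unname(tk[, "p adj"])
  )

  means <- tapply(y, g, mean)
  sig <- matrix(FALSE, nlevels(g), nlevels(g),
                dimnames = list(levels(g), levels(g)))
  for (k in seq_len(nrow(pairs))) {
    if (pairs$p_adj[k] < alpha) {
      sig[pairs$level_i[k], pairs$level_j[k]] <- TRUE
      sig[pairs$level_j[k], pairs$level_i[k]] <- TRUE
    }
  }
  letters <- cld_letters(sig, means)

  structure(list(pairs = pairs, letters = letters, alpha = alpha),
            class = "tukey_hsd")
}

# Insert-absorb compact letter display.
# sig: symmetric logical matrix of significant pairs (dimnames = levels);
# means: named group means, used only to order letters ('a' = largest mean).
# Guarantees: every non-significant pair shares >= 1 letter (connection),
# no significant pair shares any (separation).
cld_letters <- function(sig, means) {
  lev <- rownames(sig)
  sets <- list(lev) # start: one letter covering everything
  for (i in seq_along(lev)) {
    for (j in seq_along(lev)) {
      if (j <= i || !sig[i, j]) next
      for (k in rev(seq_along(sets))) {
        s <- sets[[k]]
        if (all(c(lev[i], lev[j]) %in% s)) {
          # duplicate the offending set, removing one member from each copy
          sets[[k]] <- setdiff(s, lev[i])
          sets[[length(sets) + 1]] <- setdiff(s, lev[j])
        }
      }
      sets <- sets[lengths(sets) > 0]
      sets <- absorb_sets(sets)
    }
  }
  # order letters by the largest mean each set contains, descending
  set_top <- vapply(sets, function(s) max(means[s]), 0)
  sets <- sets[order(-set_top)]
  vapply(lev, function(l) {
    paste0(letters[which(vapply(sets, function(s) l %in% s, TRUE))], collapse = "")
  }, "")
}

# drop sets that are subsets of (or equal to) another retained set
absorb_sets <- function(sets) {
  keep <- rep(TRUE, length(sets))
  for (a in seq_along(sets)) {
    for (b in seq_along(sets)) {
      if (a == b || !keep[a] || !keep[b]) next
      if (all(sets[[a]] %in% sets[[b]]) &&
          (length(sets[[a]]) < length(sets[[b]]) || a > b)) {
        keep[a] <- FALSE
      }
    }
  }
  sets[keep]
}

#' Per-grassland group statistics for a pool response
#'
#' For each grassland, runs the one-way ANOVA of a pool response across
#' litter levels, Tukey HSD multiple comparisons with a compact letter
#' display, and distributional diagnostics (Shapiro-Wilk normality of
#' residuals, Levene homogeneity of variance). The diagnostics are reported
#' but never gate the ANOVA.
#'
#' @param pools A pools tibble from [derive_pools()].
#' @param response Pool column to analyse, e.g. `"tpcp_g_m2"` or `"mbcp"`.
#' @param alpha Significance level for letters, default 0.05.
#' @return An object of class `group_stats`: a list with tibbles `anova`
#'   (one row per grassland), `tukey` (all pairs per grassland), `letters`
#'   (grassland x litter), and `checks` (Shapiro and Levene statistics per
#'   grassland). Use [tidy()] / [glance()] to extract tibbles.
#' @export
group_statistics <- function(pools, response, alpha = 0.05) {
  if (!response %in% names(pools)) {
    abort(paste0("`pools` has no column `", response, "`."))
  }
  by_grass <- split(pools, droplevels(factor(pools$grassland)))

  res <- purrr::map(names(by_grass), function(gname) {
    d <- by_grass[[gname]]
    d$litter <- droplevels(factor(d$litter))
    if (nlevels(d$litter) < 2) {
      warn(paste0("Grassland ", gname,
                  ": single litter level present; ANOVA skipped."))
      return(list(
        anova = NULL, tukey = NULL,
        letters = tibble(grassland = gname,
                         litter = levels(d$litter), letter = NA_character_),
        checks = NULL
      ))
    }
    an <- one_way_anova(d, response, "litter") |>
      dplyr::mutate(grassland = gname, .before = 1)
    tk <- tukey_hsd(d, response, "litter", alpha = alpha)
    fit <- aov(d[[response]] ~ d$litter)
    shap <- shapiro.test(stats::residuals(fit))
    lev <- car::leveneTest(d[[response]] ~ d$litter)
    list(
      anova = an,
      tukey = dplyr::mutate(tk$pairs, grassland = gname, .before = 1),
      letters = tibble(grassland = gname,
                       litter = names(tk$letters),
                       letter = unname(tk$letters)),
      checks = tibble(
        grassland = gname,
        shapiro_w = unname(shap$statistic),
        shapiro_p = shap$p.value,
        levene_f = lev$`F value`[1],
        levene_p = lev$`Pr(>F)`[1]
      )
    )
  })

  structure(list(
    response = response,
    alpha = alpha,
    anova = dplyr::bind_rows(purrr::map(res, "anova")),
    tukey = dplyr::bind_rows(purrr::map(res, "tukey")),
    letters = dplyr::bind_rows(purrr::map(res, "letters")),
    checks = dplyr::bind_rows(purrr::map(res, "checks"))
  ), class = "group_stats")
}

#' Treatment-level summary with significance letters
#'
#' Mean, standard deviation and replicate count of a pool response per
#' grassland-by-litter cell, annotated with the Tukey compact letter
#' display from [group_statistics()]. Grasslands with a single litter level
#' get `NA` letters (ANOVA is skipped with a warning).
#'
#' @inheritParams group_statistics
#' @return A tibble: `grassland`, `litter`, `mean`, `sd`, `n`, `letter`.
#' @export
treatment_summary <- function(pools, response, alpha = 0.05) {
  gs <- group_statistics(pools, response, alpha = alpha)
  pools |>
    dplyr::group_by(.data$grassland, .data$litter) |>
    dplyr::summarise(
      mean = mean(.data[[response]]),
      sd = sd(.data[[response]]),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      dplyr::mutate(gs$letters,
                    grassland = factor(.data$grassland, levels = GRASSLAND_LEVELS),
                    litter = factor(.data$litter, levels = LITTER_LEVELS)),
      by = c("grassland", "litter")
    )
}

#' @export
print.tukey_hsd <- function(x, ...) {
  cat("Tukey HSD (alpha = ", x$alpha, ")\n", sep = "")
  print(x$pairs)
  cat("Letters: ", paste(names(x$letters), x$letters, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
print.group_stats <- function(x, ...) {
  cat("Group statistics for response `", x$response, "`\n", sep = "")
  print(x$anova)
  invisible(x)
}
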