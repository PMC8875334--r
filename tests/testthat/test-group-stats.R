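# Outlier removal, rank and parametric group tests, regression layer.

test_that("robust outlier flagging catches gross outliers and spares nulls", {
  expect_error(rout_outliers(c(1, 2, 3)), "at least 5")
  expect_error(rout_outliers(rnorm(10), Q = 0.5), "Q must be")

  r <- rout_outliers(c(seq(0.1, 1.0, by = 0.1), 50.0))
  expect_equal(r$flagged, 11L)
  expect_equal(r$kept, seq(0.1, 1.0, by = 0.1))

  same <- rout_outliers(rep(3.7, 8))
  expect_length(same$flagged, 0L)
  expect_equal(same$kept, rep(3.7, 8))

  set.seed(71)
  flags <- replicate(50, length(rout_outliers(rnorm(100), Q = 0.01)$flagged))
  expect_lte(mean(flags), 0.5)   # well under 2% of n = 100
})

test_that("Kruskal-Wallis exact p equals exhaustive label permutation", {
  v <- c(1, 2, 3, 10, 11, 12)
  g <- rep(c("a", "b"), each = 3)
  res <- kruskal_dunn(v, g, method = "exact")
  # independent oracle: every permutation of the values against fixed labels
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(x) length(unique(x)) == 6L), ]
  h0 <- suppressWarnings(kruskal.test(v, factor(g))$statistic)
  hp <- apply(perms, 1, function(ix)
    suppressWarnings(kruskal.test(v[ix], factor(g))$statistic))
  expect_equal(res$p_value, mean(hp >= h0 - 1e-12))
  expect_equal(res$p_value, 0.1)

  # three unbalanced groups, ties present
  v2 <- c(1, 1, 2, 5, 6, 6, 9, 9)
  g2 <- c("a", "a", "a", "b", "b", "c", "c", "c")
  res2 <- kruskal_dunn(v2, g2, method = "exact")
  arr <- trophoquant:::label_arrangements(c(3L, 2L, 3L))
  h0b <- trophoquant:::kw_statistic(v2, factor(g2))
  hpb <- vapply(arr, function(a) {
    gl <- integer(8); for (i in 1:3) gl[a[[i]]] <- i
    trophoquant:::kw_statistic(v2, factor(gl))
  }, 0)
  expect_equal(res2$p_value, mean(hpb >= h0b - 1e-12))
  expect_equal(nrow(res2$pairwise), 3L)
  expect_true(all(res2$pairwise$p_adjusted >= res2$pairwise$p_raw))
})

test_that("rank tests have power against a 3-SD shift", {
  set.seed(72)
  hits <- replicate(100, {
    y <- c(rnorm(30), rnorm(30), rnorm(30, mean = 3))
    g <- rep(1:3, each = 30)
    kruskal_dunn(y, g, method = "asymptotic")$p_value <= 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("ANOVA/Tukey handles degenerate inputs and is selective", {
  res <- anova_tukey(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(anova_tukey(c(1, 1, 2, 2), c("a", "a", "b", "b")),
               "zero within-group variance")
  expect_error(anova_tukey(1:5, c("a", "a", "a", "a", "b")), "n >= 2")

  set.seed(73)
  sel <- replicate(100, {
    y <- c(rnorm(15), rnorm(15), rnorm(15, mean = 2.5))
    g <- factor(rep(c("a", "b", "c"), each = 15))
    pw <- anova_tukey(y, g)$pairwise
    only_c <- all(pw$p_adjusted[grepl("c", pw$comparison)] <= 0.05) &&
      pw$p_adjusted[pw$comparison == "b-a"] > 0.05
    only_c
  })
  expect_gte(mean(sel), 0.75)
})

test_that("site-adjusted linear model recovers effects and handles rank issues", {
  # intercept-only: estimated mean equals the sample mean exactly
  y <- c(4.2, 5.1, 3.8, 4.6)
  m <- suppressMessages(fit_site_adjusted_linear(y, rep("normal", 4),
                                                 rep("site_A", 4)))
  expect_equal(m$estimated_means$estimate[1], mean(y))

  set.seed(74)
  ok_site <- ok_grp <- logical(100)
  grp_est <- numeric(100)
  for (i in 1:100) {
    g <- factor(rep(c("normal", "PE"), each = 30), levels = c("normal", "PE"))
    s <- factor(sample(c("site_A", "site_B"), 60, replace = TRUE))
    y <- 150 + 10 * (g == "PE") + rnorm(60, sd = 8)   # site effect 0
    fit <- fit_site_adjusted_linear(y, g, s)
    fe <- fit$fixed_effects
    site_row <- fe[grepl("site", fe$term), ]
    ok_site[i] <- abs(site_row$estimate) < 3 * site_row$se
    grp_est[i] <- fe$estimate[fe$term == "groupPE"]
  }
  expect_gte(mean(ok_site), 0.95)
  expect_lt(abs(mean(grp_est) - 10), 2)

  # constant site is dropped and leaves estimates at the no-site fit
  g <- factor(rep(c("normal", "PE"), each = 10), levels = c("normal", "PE"))
  y <- rnorm(20)
  expect_message(f1 <- fit_site_adjusted_linear(y, g, rep("site_A", 20)),
                 "single level")
  f2 <- suppressMessages(fit_site_adjusted_linear(y, g, rep("site_A", 20)))
  expect_equal(coef(f2)[["groupPE"]], unname(coef(lm(y ~ g))[2]))

  # collinear covariate: error names the offending term
  s_dup <- factor(ifelse(g == "PE", "site_B", "site_A"))
  expect_error(fit_site_adjusted_linear(y, g, s_dup), "collinear")
})

test_that("density-band mixed model recovers fixed effects without bias", {
  est <- mixed_recovery_study(n_sims = 40, seed = 75)
  expect_lt(abs(mean(est) - 8), 2)
})

test_that("mixed model near-zero subject variance stays near zero", {
  set.seed(76)
  small <- replicate(20, {
    n <- 30
    df <- data.frame(value = rnorm(2 * n, sd = 5),
                     subject = rep(seq_len(n), each = 2),
                     group = rep(c("A", "B"), each = n),
                     site = "site_A",
                     band = rep(c("low", "high"), n))
    fit <- suppressMessages(fit_density_band_mixed(df, interaction = FALSE))
    fit$random_intercept_var <= 5   # vs residual variance 25
  })
  expect_gte(mean(small), 0.9)
})

test_that("mixed model degenerate inputs take the documented paths", {
  # duplicate observations per subject match the deduplicated fixed fit
  set.seed(77)
  n <- 20
  base <- data.frame(value = rnorm(n, 100, 5),
                     subject = seq_len(n),
                     group = rep(c("A", "B"), each = n / 2),
                     site = rep(c("site_A", "site_B"), n / 2),
                     band = "low")
  dup <- rbind(base, base)
  fit_dup <- suppressWarnings(suppressMessages(fit_density_band_mixed(dup)))
  fit_lm <- lm(value ~ group + site, data = base)
  fe <- fit_dup$fixed_effects
  expect_equal(fe$estimate[fe$term == "groupB"], unname(coef(fit_lm)["groupB"]),
               tolerance = 1e-6)

  # one band per subject: random intercept inestimable, warned fallback
  expect_warning(suppressMessages(fit_density_band_mixed(base)),
                 "falling back")
})

test_that("mixed model estimates are invariant to subject relabeling and order", {
  set.seed(78)
  n <- 16
  df <- data.frame(value = rnorm(2 * n, 100, 5) +
                     rep(rnorm(n, sd = 4), each = 2),
                   subject = rep(sprintf("s%02d", seq_len(n)), each = 2),
                   group = rep(c("A", "B"), each = n),
                   site = "site_A",
                   band = rep(c("low", "high"), n))
  f1 <- suppressMessages(fit_density_band_mixed(df))
  df2 <- df[sample(nrow(df)), ]
  df2$subject <- paste0("x_", df2$subject)
  f2 <- suppressMessages(fit_density_band_mixed(df2))
  expect_equal(f1$fixed_effects$estimate, f2$fixed_effects$estimate,
               tolerance = 1e-8)
  expect_equal(f1$estimated_means$estimate, f2$estimated_means$estimate,
               tolerance = 1e-8)
})
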