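test_that("two-way ANOVA reproduces the hand sums-of-squares oracle", {
  df <- balanced_toy()
  fit <- two_way_anova(df, "y")
  oracle <- hand_anova(df)
  expect_equal(fit$table$sumsq, oracle$ss, tolerance = 1e-8)
  expect_equal(fit$table$f, oracle$f, tolerance = 1e-8)
  expect_equal(fit$error_ss, oracle$sse, tolerance = 1e-8)
  # SS decomposition is exact on the balanced design
  expect_equal(sum(fit$table$sumsq) + fit$error_ss,
               sum((df$y - mean(df$y))^2), tolerance = 1e-8)
  # partial eta-squared identity via F
  eta_f <- fit$table$f * fit$table$df /
    (fit$table$f * fit$table$df + fit$error_df)
  expect_equal(fit$table$partial_eta_sq, eta_f, tolerance = 1e-10)
})

test_that("a factor with no effect yields an F of zero", {
  df <- expand.grid(stage = c("i", "p", "m"), age_group = c(3, 4, 5),
                    rep = 1:3)
  # outcome depends on stage only; replicate noise is repeated identically
  # across age groups, so the age sums of squares are exactly zero while
  # the error term stays positive
  set.seed(2)
  eps <- rnorm(9)
  df$y <- 2 * as.numeric(factor(df$stage)) +
    eps[as.integer(interaction(df$stage, df$rep))]
  fit <- two_way_anova(df, "y")
  f_age <- fit$table$f[fit$table$effect == "age_group"]
  expect_lt(abs(f_age), 1e-10)
  f_int <- fit$table$f[grepl(":", fit$table$effect)]
  expect_lt(abs(f_int), 1e-10)
})

test_that("empty design cells fall back to main effects with a flag", {
  df <- balanced_toy()
  df <- df[!(df$stage == "m" & df$age_group == 3), ]
  fit <- two_way_anova(df, "y")
  expect_true("empty_cells_main_effects_only" %in% fit$flags)
  expect_false(any(grepl(":", fit$table$effect)))
})

test_that("LSD comparisons use the pooled error term", {
  df <- balanced_toy(reps = 6)
  an <- two_way_anova(df, "y")
  out <- lsd_posthoc(df, "y", "stage", anova = an)
  mse <- an$error_ss / an$error_df
  m <- tapply(df$y, df$stage, mean)
  n <- tapply(df$y, df$stage, length)
  t_hand <- (m[["i"]] - m[["p"]]) / sqrt(mse * (1 / n[["i"]] + 1 / n[["p"]]))
  row <- out[out$level_1 == "i" & out$level_2 == "p", ]
  expect_equal(row$t, unname(t_hand), tolerance = 1e-10)
  expect_equal(row$df, an$error_df)
  # identical groups: t = 0, p = 1
  df2 <- data.frame(g = rep(c("a", "b"), each = 5), y = rep(1:5, 2))
  out2 <- lsd_posthoc(df2, "y", "g")
  expect_equal(out2$t, 0)
  expect_equal(out2$p, 1)
  # only contrasts against a separated third group are significant
  df3 <- data.frame(g = rep(c("a", "b", "c"), each = 6),
                    y = c(rnorm(12, 0, 0.01), rnorm(6, 5, 0.01)))
  out3 <- lsd_posthoc(df3, "y", "g")
  expect_gt(out3$p[out3$level_1 == "a" & out3$level_2 == "b"], 0.05)
  expect_lt(max(out3$p[out3$level_2 == "c"]), 1e-6)
})

test_that("stepwise selection recovers an exact single-predictor model", {
  set.seed(10)
  df <- tibble::tibble(x1 = rnorm(60))
  for (j in 2:6) df[[paste0("x", j)]] <- rnorm(60)
  df$y <- 3 * df$x1
  sw <- suppressWarnings(
    stepwise_regression(df, "y", paste0("x", 1:6)))
  expect_equal(sw$selected, "x1")
  expect_equal(unname(coef(sw$fit)[["x1"]]), 3, tolerance = 1e-9)
  expect_equal(sw$r_squared, 1, tolerance = 1e-12)
})

test_that("stepwise recovers the printed flight-height coefficients exactly", {
  coh <- generate_regression_cohort(80, noise_sd = 0, seed = 31)
  cand <- setdiff(names(coh), "flight_height_mm")
  sw <- suppressWarnings(
    stepwise_regression(coh, "flight_height_mm", cand))
  eq <- flight_height_equation()
  expect_setequal(sw$selected, eq$term[-1])
  est <- setNames(sw$terms$estimate, sw$terms$term)
  for (i in seq_len(nrow(eq))) {
    expect_lt(abs(est[[eq$term[i]]] - eq$estimate[i]), 1e-6)
  }
})

test_that("stepwise selects the true model under calibrated noise", {
  eq <- flight_height_equation()
  hits <- sapply(1:12, function(s) {
    coh <- generate_regression_cohort(500, r_squared = 0.64, seed = 900 + s)
    sw <- stepwise_regression(coh, "flight_height_mm",
                              setdiff(names(coh), "flight_height_mm"))
    c(all_true = setequal(intersect(sw$selected, eq$term[-1]), eq$term[-1]),
      no_decoy = !any(grepl("^decoy", sw$selected)))
  })
  expect_gte(mean(hits["all_true", ]), 0.9)
  expect_gte(mean(hits["no_decoy", ]), 0.8)
})

test_that("stepwise with one candidate reduces to ordinary least squares", {
  set.seed(12)
  df <- tibble::tibble(x = rnorm(40), y = 1.5 + 0.2 * rnorm(40))
  sw <- stepwise_regression(df, "y", "x", p_enter = 1, p_remove = 1)
  ols <- lm(y ~ x, data = df)
  expect_equal(unname(coef(sw$fit)), unname(coef(ols)), tolerance = 1e-10)
  # standardized beta identity
  bx <- sw$terms$beta[sw$terms$term == "x"]
  expect_equal(bx, unname(coef(ols)[["x"]]) * sd(df$x) / sd(df$y),
               tolerance = 1e-10)
})

test_that("an intercept-only outcome is flagged", {
  set.seed(13)
  df <- tibble::tibble(x = rnorm(40), y = rnorm(40))
  sw <- stepwise_regression(df, "y", "x", p_enter = 1e-6)
  expect_true("intercept_only" %in% sw$flags)
})

test_that("collinearity diagnostics and Durbin-Watson follow their formulas", {
  n <- 40
  x1 <- rep(c(-1, 1), n / 2); x2 <- rep(c(-1, -1, 1, 1), n / 4)
  df <- tibble::tibble(x1 = x1, x2 = x2)
  cd <- collinearity_diagnostics(df, c("x1", "x2"))
  expect_equal(cd$vif, c(1, 1), tolerance = 1e-10)
  df$x3 <- df$x1 + df$x2
  cd2 <- collinearity_diagnostics(df, c("x1", "x2", "x3"))
  expect_true(any(is.infinite(cd2$vif)))
  expect_true("perfectly_collinear" %in% cd2$flag)
  # alternating residuals: DW = 4 (n - 1) / n
  e <- rep(c(1, -1), 20)
  expect_equal(durbin_watson(e), 4 * 39 / 40, tolerance = 1e-12)
  expect_error(durbin_watson(1), "at least 2")
  # iid residuals concentrate near 2, and match the lmtest oracle
  dws <- sapply(1:10, function(s) {
    set.seed(200 + s)
    durbin_watson(rnorm(1000))
  })
  expect_gte(mean(dws > 1.8 & dws < 2.2), 0.9)
  set.seed(3)
  df4 <- tibble::tibble(x = rnorm(50), y = rnorm(50))
  fit <- lm(y ~ x, data = df4)
  expect_equal(durbin_watson(resid(fit)),
               unname(lmtest::dwtest(fit)$statistic), tolerance = 1e-10)
})

test_that("group-level differences are detectable in sampled cohorts", {
  # metric values drawn from the per-age distributions: the age effect is
  # overwhelming relative to the dispersions
  specs <- group_specs_age()
  specs <- specs[specs$metric == "hip_max_angvel_pushing_rad_s", ]
  hits <- sapply(1:15, function(s) {
    set.seed(300 + s)
    df <- do.call(rbind, lapply(seq_len(nrow(specs)), function(i) {
      data.frame(age_group = specs$age_group[i],
                 stage = sample(c("primary", "mature"), 30, replace = TRUE),
                 y = rnorm(30, specs$mean[i], specs$sd[i]))
    }))
    fit <- two_way_anova(df, "y", factors = c("stage", "age_group"))
    fit$table$p[fit$table$effect == "age_group"] < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("tidy and glance methods return the documented shapes", {
  df <- balanced_toy()
  an <- two_way_anova(df, "y")
  expect_s3_class(tidy(an), "tbl_df")
  expect_true(all(c("effect", "f", "p", "partial_eta_sq") %in%
                    names(tidy(an))))
  expect_equal(nrow(glance(an)), 1)
  coh <- generate_regression_cohort(60, noise_sd = 5, seed = 2)
  sw <- stepwise_regression(coh, "flight_height_mm",
                            setdiff(names(coh), "flight_height_mm"))
  expect_true(all(c("term", "estimate", "beta", "vif") %in% names(tidy(sw))))
  expect_true(all(c("r.squared", "durbin_watson") %in% names(glance(sw))))
})
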