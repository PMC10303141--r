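test_that("size and OD normalization are plain homogeneous divisions", {
  expect_equal(normalize_to_size(1000, 100), 10)
  expect_equal(normalize_to_size(2000, 200), 10)
  expect_equal(normalize_to_od(5000, 1), 5000)
  expect_equal(normalize_to_od(5000, 2), 2500)
  expect_error(normalize_to_size(10, 0), class = "platesensor_normalize_error")
  expect_error(normalize_to_od(10, -1), class = "platesensor_normalize_error")
})

test_that("size-normalized dilution-series signal is stable down to 70% size", {
  g <- simulate_dilution_series(
    tibble::tibble(strain = "wt", ratio = 1.05),
    n_steps = 3, noise = noise_model(cv = 0.02, channel_cv = 0.005, seed = 8)
  )
  d <- dplyr::filter(plate_ratios(g, 380, 470), .data$size_px >= 0.7 * 680)
  rflu <- normalize_to_size(d$I_den, d$perimeter_px)
  # area-linear intensity over perimeter ~ sqrt(area): not constant, but the
  # ratio of extremes over 100..72.9% area stays within the observed stability
  expect_lt(sd(rflu) / mean(rflu), 0.20)
  ratio_cv <- sd(d$ratio) / mean(d$ratio)
  expect_lt(ratio_cv, 0.03)
})

test_that("Hill fits recover generator parameters", {
  doses <- c(0, 0.005, 0.01, 0.025, 0.05, 0.1, 0.25, 0.5, 1, 2.5, 5)
  truth <- tfb_model(F0 = 5e3, Fmax = 1.95e5, K = 0.1, n = 1.5)
  fit <- fit_hill(doses, hill_response(doses, truth))
  expect_true(fit$converged)
  expect_lt(abs(fit$F0 - truth$F0) / truth$F0, 1e-3)
  expect_lt(abs(fit$Fmax - truth$Fmax) / truth$Fmax, 1e-3)
  expect_lt(abs(fit$K - truth$K) / truth$K, 1e-3)
  expect_lt(abs(fit$n - truth$n) / truth$n, 1e-3)

  # flat, empty-vector-like responses
  flat <- fit_hill(doses, rep(5e3, length(doses)))
  expect_lt(flat$Fmax, 0.02 * 5e3)
  lin <- fit_linear(doses, rep(5e3, length(doses)))
  expect_equal(lin$slope, 0, tolerance = 1e-9)

  # stochastic recovery at generator noise
  lay <- tibble::tibble(
    well = well_labels(96)[1:44], strain = "high",
    dose = rep(doses, each = 4), role = "sample"
  )
  g <- simulate_tfb_plate(lay,
    models = list(high = tfb_model()),
    noise = noise_model(cv = 0.05, channel_cv = 0.005, seed = 13)
  )
  fit2 <- fit_hill(g$dose, g$intensity)
  expect_lt(abs(fit2$K - 0.1) / 0.1, 0.2)

  expect_error(fit_hill(c(0, 1, 1, 1), c(1, 2, 2, 2)), class = "platesensor_fit_error")
})

test_that("linear fits agree with the normal-equations oracle", {
  set.seed(51)
  for (i in 1:5) {
    x <- runif(10, 0, 5)
    y <- runif(10, 0, 10)
    fit <- fit_linear(x, y)
    # closed-form OLS
    slope <- (mean(x * y) - mean(x) * mean(y)) / (mean(x^2) - mean(x)^2)
    intercept <- mean(y) - slope * mean(x)
    expect_equal(fit$slope, slope, tolerance = 1e-10)
    expect_equal(fit$intercept, intercept, tolerance = 1e-10)
  }
  exact <- fit_linear(1:5, 2 * (1:5) + 3)
  expect_equal(exact$r_squared, 1, tolerance = 1e-12)
})

test_that("fold changes reproduce the printed group-mean examples", {
  weak <- fold_change_from_means(1.19e5, 1.22e4, 6.62e4, 8.59e3)
  expect_equal(round(weak$fold, 2), 1.80)
  strong <- fold_change_from_means(7.46e5, 8.74e4, 6.62e4, 8.59e3)
  expect_lt(abs(strong$fold - 11.30) / 11.30, 0.005)

  x <- c(10, 11, 12)
  expect_equal(fold_change(x, x)$fold, 1)
  # linear in the group mean
  expect_equal(fold_change(3 * x, x)$fold, 3 * fold_change(x, x)$fold)
  expect_error(fold_change(x, c(-1, 0, -2)), class = "platesensor_fit_error")
})

test_that("one-way ANOVA matches an explicit sum-of-squares oracle", {
  # hand-computable 3 x 5 example
  groups <- list(a = c(6, 8, 4, 5, 3), b = c(8, 12, 9, 11, 6), c = c(13, 9, 11, 8, 12))
  df <- tibble::tibble(
    value = unlist(groups),
    group = rep(names(groups), times = lengths(groups))
  )
  grand <- mean(df$value)
  ss_between <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 1))
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  f_oracle <- (ss_between / 2) / (ss_within / 12)
  p_oracle <- pf(f_oracle, 2, 12, lower.tail = FALSE)

  res <- one_way_anova(df)
  expect_equal(res$f, f_oracle, tolerance = 1e-10)
  expect_equal(res$p, p_oracle, tolerance = 1e-10)

  # invariances
  df2 <- dplyr::mutate(df, value = value + 100)
  expect_equal(one_way_anova(df2)$f, res$f, tolerance = 1e-10)
  df3 <- dplyr::mutate(df, value = value * 7)
  expect_equal(one_way_anova(df3)$f, res$f, tolerance = 1e-10)

  same <- tibble::tibble(value = rep(c(1, 2, 3), 3), group = rep(c("a", "b", "c"), each = 3))
  # identical groups: F = 0, p = 1
  expect_equal(one_way_anova(same)[, c("f", "p")], tibble::tibble(f = 0, p = 1))
  degenerate <- tibble::tibble(value = rep(c(1, 2), each = 3), group = rep(c("a", "b"), each = 3))
  res_d <- one_way_anova(degenerate)
  expect_true(res_d$infinite_f)
  expect_equal(res_d$p, 0)
})

test_that("ANOVA p agrees with a permutation oracle", {
  set.seed(52)
  df <- tibble::tibble(
    value = c(rnorm(6), rnorm(6, 1)),
    group = rep(c("a", "b"), each = 6)
  )
  obs <- one_way_anova(df)
  n_perm <- 4000
  f_perm <- replicate(n_perm, {
    one_way_anova(tibble::tibble(value = sample(df$value), group = df$group))$f
  })
  p_mc <- (1 + sum(f_perm >= obs$f)) / (n_perm + 1)
  se <- sqrt(p_mc * (1 - p_mc) / n_perm)
  expect_lt(abs(obs$p - p_mc), 4 * se + 0.01)
})

test_that("Tukey HSD reduces to the pooled t-test for two groups", {
  set.seed(53)
  df <- tibble::tibble(
    value = c(rnorm(8), rnorm(8, 0.8)),
    group = rep(c("a", "b"), each = 8)
  )
  tk <- tukey_hsd(df)
  tt <- stats::t.test(value ~ group, data = df, var.equal = TRUE)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-8)

  same <- tibble::tibble(value = rep(c(1, 2, 3), 2), group = rep(c("a", "b"), each = 3))
  tk_same <- tukey_hsd(same)
  expect_equal(tk_same$p_adj, 1)
  expect_false(any(tk_same$significant))
})

test_that("Tukey-adjusted p values dominate unadjusted pairwise t-tests", {
  set.seed(54)
  df <- tibble::tibble(
    value = c(rnorm(6), rnorm(6, 0.5), rnorm(6, 1.5)),
    group = rep(c("a", "b", "c"), each = 6)
  )
  tk <- tukey_hsd(df)
  # on shared-variance pooled tests the Tukey adjustment is conservative
  fit <- stats::aov(value ~ group, data = df)
  mse <- summary(fit)[[1]]$`Mean Sq`[2]
  for (i in seq_len(nrow(tk))) {
    m <- tapply(df$value, df$group, mean)
    se <- sqrt(mse * (1 / 6 + 1 / 6))
    t_stat <- abs(m[tk$group_2[i]] - m[tk$group_1[i]]) / se
    p_unadj <- 2 * pt(t_stat, df = 15, lower.tail = FALSE)
    expect_gte(tk$p_adj[i] + 1e-12, unname(p_unadj))
  }
})

test_that("a three-strain screening plate separates all groups at the * tier", {
  layout <- three_strain_layout()
  models <- list(
    background = tfb_model(F0 = 6.62e4, Fmax = 0),
    weak = tfb_model(F0 = 1.19e5, Fmax = 0),
    strong = tfb_model(F0 = 7.46e5, Fmax = 0)
  )
  layout$dose <- 0
  g <- simulate_tfb_plate(layout,
    models = models,
    excitation_nm = 480, emission_nm = 530,
    noise = noise_model(cv = 0.05, channel_cv = 0.005, seed = 9)
  )
  samples <- dplyr::filter(tibble::as_tibble(g), role == "sample")
  cmp <- compare_groups(samples, value = "intensity", group = "strain")
  expect_equal(nrow(cmp$pairwise), 3)
  expect_true(all(cmp$pairwise$p_adj <= 0.001))
  expect_true(all(cmp$pairwise$tier == "*"))
  expect_lt(cmp$anova$p, 1e-10)
})

test_that("significance tiers mirror the figure annotation scheme", {
  expect_equal(
    significance_tier(c(0.2, 0.0005, 0.01)),
    c("n.s.", "*", "0.001 < p <= 0.05")
  )
})
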