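#' Normalize colony fluorescence to colony size
#'
#' Relative fluorescence (RFLU) of an agar-grown colony: raw intensity divided
#' by the colony perimeter (the growth proxy used for arrayed colonies; use
#' [normalize_to_od()] for liquid cultures).
#'
#' @param intensity Fluorescence intensities (FLU); vectorized.
#' @param perimeter_px Colony perimeters (pixels), `> 0`.
#' @return RFLU values.
#' @export
#' @examples
#' normalize_to_size(1000, 100)
normalize_to_size <- function(intensity, perimeter_px) {
  if (any(!is.finite(perimeter_px)) || any(perimeter_px <= 0)) {
    abort("`perimeter_px` must be positive.", class = "platesensor_normalize_error")
  }
  intensity / perimeter_px
}

#' Normalize fluorescence to optical density
#'
#' RFLU for liquid cultures: intensity divided by OD600.
#'
#' @param intensity Fluorescence intensities (FLU); vectorized.
#' @param od600 Optical densities at 600 nm, `> 0`.
#' @return RFLU values.
#' @export
normalize_to_od <- function(intensity, od600) {
  if (any(!is.finite(od600)) || any(od600 <= 0)) {
    abort("`od600` must be positive.", class = "platesensor_normalize_error")
  }
  intensity / od600
}

#' Fit a Hill dose-response curve
#'
#' Bounded nonlinear least squares of `F(c) = F0 + Fmax * c^n / (K^n + c^n)`
#' (Levenberg-Marquardt). Initialization is data-driven: `F0` from the
#' zero-dose responses, `Fmax` from the top of the curve, `K` from the dose
#' nearest the half-rise, `n = 1`. Bounds: `F0, Fmax >= 0`,
#' `K` within `[min positive dose / 10, max dose * 10]`, `n` in `(0, 6]`.
#' A non-converged fit is returned with `converged = FALSE` rather than
#' raised.
#'
#' @param doses Inducer concentrations (>= 4 distinct values including 0).
#' @param responses Positive responses (RFLU), same length.
#' @return A `hill_fit` with `F0`, `Fmax`, `K`, `n`, `rss`, `converged` and the
#'   data; supports [predict()], [tidy()], [glance()], [autoplot()].
#' @export
fit_hill <- function(doses, responses) {
  if (length(doses) != length(responses)) {
    abort("doses and responses must have equal length.", class = "platesensor_fit_error")
  }
  if (length(unique(doses)) < 4 || !any(doses == 0)) {
    abort("Need >= 4 distinct doses including 0.", class = "platesensor_fit_error")
  }
  df <- tibble(dose = doses, resp = responses)
  f0_init <- mean(df$resp[df$dose == 0])
  top <- mean(df$resp[df$dose == max(df$dose)])
  fmax_init <- max(top - f0_init, 1e-8)
  half <- f0_init + fmax_init / 2
  pos <- df[df$dose > 0, ]
  k_init <- pos$dose[which.min(abs(pos$resp - half))]
  k_lo <- min(pos$dose) / 10
  k_hi <- max(df$dose) * 10
  k_init <- min(max(k_init, k_lo), k_hi)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      resp ~ F0 + Fmax * ifelse(dose == 0, 0, dose^n / (K^n + dose^n)),
      data = df,
      start = list(F0 = f0_init, Fmax = fmax_init, K = k_init, n = 1),
      lower = c(0, 0, k_lo, 1e-3),
      upper = c(Inf, Inf, k_hi, 6),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(structure(
      list(
        F0 = f0_init, Fmax = fmax_init, K = k_init, n = 1,
        rss = sum((df$resp - f0_init)^2), converged = FALSE, data = df
      ),
      class = "hill_fit"
    ))
  }
  cf <- coef(fit)
  structure(
    list(
      F0 = unname(cf["F0"]), Fmax = unname(cf["Fmax"]),
      K = unname(cf["K"]), n = unname(cf["n"]),
      rss = sum(stats::residuals(fit)^2),
      converged = fit$convInfo$isConv %||% TRUE,
      data = df
    ),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(
    "<hill_fit> F0 = ", format(x$F0, digits = 4), ", Fmax = ", format(x$Fmax, digits = 4),
    ", K = ", format(x$K, digits = 4), ", n = ", format(x$n, digits = 3),
    " (rss = ", format(x$rss, digits = 3), ", converged: ", x$converged, ")\n",
    sep = ""
  )
  invisible(x)
}

#' @export
predict.hill_fit <- function(object, dose = NULL, ...) {
  dose <- dose %||% object$data$dose
  hill_response(dose, object)
}

#' @exportS3Method generics::tidy
tidy.hill_fit <- function(x, ...) {
  tibble(
    term = c("F0", "Fmax", "K", "n"),
    estimate = c(x$F0, x$Fmax, x$K, x$n)
  )
}

#' @exportS3Method generics::glance
glance.hill_fit <- function(x, ...) {
  tibble(rss = x$rss, converged = x$converged, n_obs = nrow(x$data))
}

#' @exportS3Method ggplot2::autoplot
autoplot.hill_fit <- function(object, ...) {
  pos <- object$data$dose[object$data$dose > 0]
  grid_doses <- c(0, exp(seq(log(min(pos)), log(max(pos)), length.out = 100)))
  curve <- tibble(dose = grid_doses, resp = predict(object, grid_doses))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$dose, y = .data$resp)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve) +
    ggplot2::labs(x = "dose", y = "RFLU") +
    ggplot2::theme_minimal()
}

#' Linear dose-response fit
#'
#' OLS line used for reporter-free (empty vector) strains whose response has
#' no dose dependence to speak of.
#'
#' @param doses,responses Numeric vectors (>= 2 distinct doses).
#' @return A one-row tibble `slope, intercept, r_squared`.
#' @export
fit_linear <- function(doses, responses) {
  if (length(unique(doses)) < 2) {
    abort("Need >= 2 distinct doses.", class = "platesensor_fit_error")
  }
  fit <- lm(responses ~ doses)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((responses - mean(responses))^2)
  tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  )
}

#' Fold change between a group and a reference group
#'
#' `fold = mean(group) / mean(reference)`. The uncertainty is first-order
#' error propagation of the two group standard deviations:
#' `sd_fold = fold * sqrt((sd_g / mean_g)^2 + (sd_r / mean_r)^2)`.
#'
#' @param group_values,reference_values Numeric vectors of per-colony values.
#' @return A one-row tibble `fold, sd_fold`.
#' @export
#' @examples
#' fold_change(c(10, 12, 11), c(5, 6, 5.5))
fold_change <- function(group_values, reference_values) {
  fold_change_from_means(
    mean(group_values), sd(group_values),
    mean(reference_values), sd(reference_values)
  )
}

#' Fold change from summary statistics
#'
#' Same computation as [fold_change()] but starting from reported group means
#' and standard deviations.
#'
#' @param mean_g,sd_g Group mean and sd.
#' @param mean_r,sd_r Reference mean and sd.
#' @return A one-row tibble `fold, sd_fold`.
#' @export
fold_change_from_means <- function(mean_g, sd_g, mean_r, sd_r) {
  if (!is.finite(mean_r) || mean_r <= 0) {
    abort("Reference mean must be positive.", class = "platesensor_fit_error")
  }
  fold <- mean_g / mean_r
  tibble(
    fold = fold,
    sd_fold = abs(fold) * sqrt((sd_g / mean_g)^2 + (sd_r / mean_r)^2)
  )
}

check_groups <- function(data, value, group) {
  df <- tibble(
    value = data[[value]],
    group = as.character(data[[group]])
  )
  df <- df[is.finite(df$value), ]
  counts <- table(df$group)
  if (length(counts) < 2 || any(counts < 2)) {
    abort("Need >= 2 groups with >= 2 values each.", class = "platesensor_stats_error")
  }
  df
}

#' One-way analysis of variance
#'
#' Classical between/within mean-square F with `(k - 1, N - k)` degrees of
#' freedom. Degenerate inputs are resolved explicitly: with zero within-group
#' variance, equal group means give `F = 0, p = 1` and unequal means give
#' `F = Inf, p = 0` (flagged via `infinite_f`).
#'
#' @param data A data frame.
#' @param value,group Column names (strings) of the response and the grouping
#'   factor.
#' @return A one-row tibble `f, p, df_between, df_within, infinite_f`.
#' @export
one_way_anova <- function(data, value = "value", group = "group") {
  df <- check_groups(data, value, group)
  k <- length(unique(df$group))
  n <- nrow(df)
  within_var <- stats::ave(df$value, df$group, FUN = function(x) x - mean(x))
  ss_within <- sum(within_var^2)
  means_equal <- length(unique(tapply(df$value, df$group, mean))) == 1
  if (ss_within == 0) {
    if (means_equal) {
      return(tibble(f = 0, p = 1, df_between = k - 1, df_within = n - k, infinite_f = FALSE))
    }
    return(tibble(f = Inf, p = 0, df_between = k - 1, df_within = n - k, infinite_f = TRUE))
  }
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  tibble(
    f = tab$`F value`[1], p = tab$`Pr(>F)`[1],
    df_between = tab$Df[1], df_within = tab$Df[2],
    infinite_f = FALSE
  )
}

#' Significance tier labels
#'
#' Maps adjusted p values onto the annotation tiers used on screening figures:
#' `n.s.` for p > 0.05, `*` for p <= 0.001, and an explicit intermediate tier
#' `0.001 < p <= 0.05`.
#'
#' @param p Numeric p values.
#' @return Character labels.
#' @export
significance_tier <- function(p) {
  dplyr::case_when(
    p > 0.05 ~ "n.s.",
    p <= 0.001 ~ "*",
    TRUE ~ "0.001 < p <= 0.05"
  )
}

#' Tukey's honestly-significant-difference test
#'
#' All pairwise group comparisons after a one-way ANOVA, using the studentized
#' range distribution (Tukey-Kramer for unbalanced groups). Pairs are
#' significant at the 0.05 threshold.
#'
#' @inheritParams one_way_anova
#' @return A tibble with `C(k, 2)` rows: `group_1, group_2, diff, lwr, upr,
#'   p_adj, significant, tier`.
#' @export
tukey_hsd <- function(data, value = "value", group = "group") {
  df <- check_groups(data, value, group)
  groups <- sort(unique(df$group))
  within_var <- stats::ave(df$value, df$group, FUN = function(x) x - mean(x))
  if (sum(within_var^2) == 0) {
    pairs <- utils::combn(groups, 2)
    means <- tapply(df$value, df$group, mean)
    diffs <- means[pairs[2, ]] - means[pairs[1, ]]
    p <- ifelse(diffs == 0, 1, 0)
    return(tibble(
      group_1 = pairs[1, ], group_2 = pairs[2, ],
      diff = unname(diffs), lwr = unname(diffs), upr = unname(diffs),
      p_adj = p, significant = p < 0.05, tier = significance_tier(p)
    ))
  }
  df$group <- factor(df$group, levels = groups)
  fit <- stats::aov(value ~ group, data = df)
  tk <- stats::TukeyHSD(fit)$group
  labels <- strsplit(rownames(tk), "-", fixed = TRUE)
  tibble(
    group_1 = vapply(labels, `[`, "", 2),
    group_2 = vapply(labels, `[`, "", 1),
    diff = unname(tk[, "diff"]),
    lwr = unname(tk[, "lwr"]),
    upr = unname(tk[, "upr"]),
    p_adj = unname(tk[, "p adj"]),
    significant = unname(tk[, "p adj"]) < 0.05,
    tier = significance_tier(unname(tk[, "p adj"]))
  )
}

#' Full group comparison for screening decisions
#'
#' Per-group summary statistics, one-way ANOVA and Tukey HSD pairwise table in
#' one object, as used to decide which reporter constructs are separable on a
#' plate.
#'
#' @inheritParams one_way_anova
#' @return A `group_comparison`: list with `groups` (label, mean, sd, n),
#'   `anova` and `pairwise` tibbles.
#' @export
compare_groups <- function(data, value = "value", group = "group") {
  df <- check_groups(data, value, group)
  stats_tbl <- dplyr::summarise(
    dplyr::group_by(df, .data$group),
    mean = mean(.data$value), sd = sd(.data$value), n = dplyr::n(),
    .groups = "drop"
  )
  structure(
    list(
      groups = stats_tbl,
      anova = one_way_anova(df),
      pairwise = tukey_hsd(df)
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n")
  print(x$groups)
  cat(sprintf(
    "ANOVA: F(%d, %d) = %.4g, p = %.3g\n",
    x$anova$df_between, x$anova$df_within, x$anova$f, x$anova$p
  ))
  print(x$pairwise)
  invisible(x)
}
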