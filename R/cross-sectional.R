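#' Per-test Bonferroni threshold
#'
#' `alpha / m` for a family of `m` comparisons.  The two families used in
#' the reports are the 18 group-comparison tests (per-test threshold
#' 0.00278 at alpha = .05) and the 54 feature-outcome regressions
#' (18 features x 3 outcomes; per-test threshold 0.00092).
#'
#' @param alpha Family-wise significance level.
#' @param m Number of comparisons in the family (>= 1).
#' @return The per-test threshold `alpha/m`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 54)
bonferroni_threshold <- function(alpha = 0.05, m = 1) {
  if (length(m) != 1 || is.na(m) || m < 1) {
    stop("family size m must be a single integer >= 1")
  }
  alpha / m
}

#' Compare network features between groups
#'
#' Welch two-sample t test of each feature between the two groups, with a
#' Bonferroni significance flag at `alpha/m`.  The groups are independent
#' samples, so the two-sample (not paired) test applies; Welch's form
#' drops the equal-variance assumption and coincides with the pooled test
#' for balanced equal-variance data.
#'
#' @param features Feature tibble (one row per participant) containing a
#'   group column and the feature columns; typically from
#'   [cohort_features()].
#' @param feature_names Features to test (default all 18).
#' @param group_col Name of the group column (two levels).
#' @param alpha Family-wise level.
#' @param m Family size for the Bonferroni flag (default the number of
#'   features tested).
#' @return A tibble with one row per feature: group means/SDs and ns,
#'   `t`, `p`, `degenerate` (zero variance in both groups) and
#'   `significant` (`p < alpha/m`); the `m` used is recorded in the
#'   `bonferroni_m` attribute.
#' @export
compare_groups <- function(features, feature_names = persnet_features(),
                           group_col = "group", alpha = 0.05,
                           m = length(feature_names)) {
  g <- features[[group_col]]
  lev <- sort(unique(as.character(g)))
  if (length(lev) != 2) stop("group column must have exactly two levels")
  thr <- bonferroni_threshold(alpha, m)
  rows <- purrr::map(feature_names, function(f) {
    x <- features[[f]][g == lev[1]]
    y <- features[[f]][g == lev[2]]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    degenerate <- (length(x) < 2 || length(y) < 2) ||
      (sd(x) == 0 && sd(y) == 0)
    if (degenerate) {
      tt <- list(statistic = NA_real_, p.value = NA_real_)
    } else {
      tt <- t.test(x, y)
    }
    out <- tibble::tibble(
      feature = f,
      n_1 = length(x), mean_1 = mean(x), sd_1 = sd(x),
      n_2 = length(y), mean_2 = mean(y), sd_2 = sd(y),
      t = unname(tt$statistic), p = tt$p.value,
      degenerate = degenerate,
      significant = !is.na(tt$p.value) && tt$p.value < thr
    )
    names(out) <- sub("_1$", paste0("_", lev[1]), names(out))
    names(out) <- sub("_2$", paste0("_", lev[2]), names(out))
    out
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "bonferroni_m") <- m
  attr(out, "threshold") <- thr
  out
}

# Shared OLS engine: outcome ~ focal + covariates on complete cases.
# Returns the focal coefficient with normal-theory 95% Wald CI and p.
ols_focal <- function(data, focal, outcome, covariates, conf = 0.95) {
  cols <- c(outcome, focal, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("column(s) not found: ", paste(missing_cols, collapse = ", "))
  }
  d <- data[cols]
  d <- d[complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  form <- stats::reformulate(c(focal, covariates), response = outcome)
  mm <- model.matrix(form, data = d)
  if (n < ncol(mm) + 5) {
    stop("too few complete cases (", n, ") for ", ncol(mm),
         " parameters in ", focal, " -> ", outcome)
  }
  fit <- lm(form, data = d)
  if (anyNA(coef(fit))) {
    stop("rank-deficient design; collinear column(s): ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  # the focal term can expand to one coefficient only (numeric focal)
  est <- sm[focal, "Estimate"]
  se <- sm[focal, "Std. Error"]
  df <- fit$df.residual
  z <- qt(1 - (1 - conf) / 2, df)
  list(fit = fit, n = n, beta = est, se = se,
       ci_low = est - z * se, ci_high = est + z * se,
       p = sm[focal, "Pr(>|t|)"])
}

#' Covariate-adjusted association of one network feature with one outcome
#'
#' Ordinary least squares of the outcome on the feature plus covariates,
#' on complete cases, returning the feature coefficient with its 95%
#' normal-theory confidence interval and p-value.  Percentage-type
#' features should be supplied on the 0-1 proportion scale
#' ([features_regression_scale()]) so the coefficient measures the
#' outcome shift for a 0-to-1 sweep of the feature.  pwMS models
#' conventionally adjust for age, disease duration, employment and
#' income; control models drop disease duration (not applicable).
#'
#' @param data Analysis tibble: one row per participant with the feature,
#'   outcome and covariate columns.
#' @param feature,outcome Column names.
#' @param covariates Character vector of covariate column names.
#' @return A one-row tibble (`feature`, `outcome`, `n`, `beta`, `ci_low`,
#'   `ci_high`, `p`, `covariates`).
#' @export
feature_outcome_regression <- function(data, feature, outcome,
                                       covariates = c("age",
                                                      "disease_duration",
                                                      "employment_bin",
                                                      "income_bracket")) {
  res <- ols_focal(data, feature, outcome, covariates)
  tibble::tibble(feature = feature, outcome = outcome, n = res$n,
                 beta = res$beta, ci_low = res$ci_low,
                 ci_high = res$ci_high, p = res$p,
                 covariates = paste(covariates, collapse = "+"))
}

#' Run the full feature-outcome regression battery
#'
#' One covariate-adjusted regression per (feature, outcome) pair — the
#' 18 x 3 = 54-model battery for pwMS, or 18 x 1 for the control arm —
#' with a Bonferroni flag over the whole battery.
#'
#' @inheritParams feature_outcome_regression
#' @param features,outcomes Character vectors of column names.
#' @param alpha Family-wise level for the Bonferroni flag.
#' @param m Family size (default `length(features) * length(outcomes)`).
#' @return A tibble of association results with a `significant` column.
#' @export
regression_battery <- function(data, features = persnet_features(),
                               outcomes = c("pdds", "msrs_r", "promis_pf"),
                               covariates = c("age", "disease_duration",
                                              "employment_bin",
                                              "income_bracket"),
                               alpha = 0.05,
                               m = length(features) * length(outcomes)) {
  grid <- expand.grid(feature = features, outcome = outcomes,
                      stringsAsFactors = FALSE)
  out <- purrr::map2_dfr(grid$feature, grid$outcome, function(f, oc) {
    feature_outcome_regression(data, f, oc, covariates)
  })
  out$significant <- out$p < bonferroni_threshold(alpha, m)
  attr(out, "bonferroni_m") <- m
  out
}

#' Moderation of a feature-outcome association by MS diagnosis
#'
#' Joint model over both groups with a feature x diagnosis interaction:
#' `outcome ~ feature * is_pwms + covariates`.  The interaction
#' coefficient tests whether having an MS diagnosis changes the strength
#' or direction of the association; group-specific simple slopes are
#' derived from the coefficients (`slope_control = b_feature`,
#' `slope_pwms = b_feature + b_interaction`) with delta-method standard
#' errors.  The feature's 25th/50th/75th percentiles are reported as
#' display anchors for plotting.
#'
#' @param data Analysis tibble over both groups, with a `group` column
#'   (`"pwms"`/`"control"`), the feature, outcome and covariates.
#' @param feature Feature column name (regression scale).
#' @param outcome Outcome column (default PROMIS Physical Function, the
#'   outcome defined for both groups).
#' @param covariates Covariates applicable to both groups (default age,
#'   employment, income — disease duration is undefined for controls).
#' @return A list of class `moderation_result`: `interaction` (one-row
#'   tibble with beta/CI/p), `slopes` (tibble with one row per group),
#'   `anchors` (named 25/50/75 percentiles), `n`, `feature`, `outcome`.
#' @export
moderation_analysis <- function(data, feature, outcome = "promis_pf",
                                covariates = c("age", "employment_bin",
                                               "income_bracket")) {
  if (!"group" %in% names(data)) stop("data must have a group column")
  groups <- unique(as.character(data$group))
  if (!setequal(groups, c("pwms", "control"))) {
    stop("moderation analysis needs both groups (pwms and control)")
  }
  d <- data[c(outcome, feature, "group", covariates)]
  d <- d[complete.cases(d), , drop = FALSE]
  d$is_pwms <- as.numeric(d$group == "pwms")
  if (any(tapply(d[[feature]], d$group, sd) == 0)) {
    stop("feature is constant within a group")
  }
  form <- as.formula(paste(outcome, "~", feature, "* is_pwms +",
                           paste(covariates, collapse = "+")))
  fit <- lm(form, data = d)
  if (anyNA(coef(fit))) {
    stop("rank-deficient design; collinear column(s): ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  V <- vcov(fit)
  cf <- coef(fit)
  int_name <- paste0(feature, ":is_pwms")
  df <- fit$df.residual
  z <- qt(0.975, df)
  term_row <- function(est, se, term) {
    est <- unname(est)
    se <- unname(se)
    tibble::tibble(term = term, beta = est, se = se,
                   ci_low = est - z * se, ci_high = est + z * se,
                   p = 2 * pt(-abs(est / se), df))
  }
  interaction <- term_row(cf[int_name], sqrt(V[int_name, int_name]),
                          "interaction")
  s_con <- cf[feature]
  se_con <- sqrt(V[feature, feature])
  s_pw <- cf[feature] + cf[int_name]
  se_pw <- sqrt(V[feature, feature] + V[int_name, int_name] +
                  2 * V[feature, int_name])
  slopes <- dplyr::bind_rows(
    dplyr::mutate(term_row(s_pw, se_pw, "slope"), group = "pwms"),
    dplyr::mutate(term_row(s_con, se_con, "slope"), group = "control")
  )
  structure(
    list(feature = feature, outcome = outcome, n = nrow(d),
         interaction = interaction, slopes = slopes,
         anchors = quantile(d[[feature]], c(0.25, 0.5, 0.75)),
         fit = fit),
    class = "moderation_result"
  )
}

#' @export
print.moderation_result <- function(x, ...) {
  cat(sprintf("<moderation_result> %s -> %s (n=%d)\n", x$feature, x$outcome,
              x$n))
  cat(sprintf("  interaction beta %.3f [%.3f, %.3f], p=%.3g\n",
              x$interaction$beta, x$interaction$ci_low, x$interaction$ci_high,
              x$interaction$p))
  for (i in seq_len(nrow(x$slopes))) {
    s <- x$slopes[i, ]
    cat(sprintf("  slope (%s) %.3f [%.3f, %.3f], p=%.3g\n", s$group, s$beta,
                s$ci_low, s$ci_high, s$p))
  }
  cat(sprintf("  feature quartile anchors: %s\n",
              paste(signif(x$anchors, 3), collapse = " / ")))
  invisible(x)
}
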