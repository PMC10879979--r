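#' Calibrate a truncated negative-binomial size distribution
#'
#' Network sizes are drawn from a negative binomial truncated to
#' `[1, max]`.  Truncation shifts the mean, so the raw `mu` is solved by
#' root finding such that the *truncated* distribution has exactly the
#' target mean; dispersion `theta` is matched to the target variance of
#' the untruncated fit (`theta = mean^2 / (var - mean)`).
#'
#' @param mean_target,sd_target Target mean and SD of network size.
#' @param max Upper truncation (default 25 alters).
#' @return List with `mu`, `theta`, `max` and the probability vector
#'   `pmf` over sizes `1..max`.
#' @export
calibrate_size_dist <- function(mean_target, sd_target, max = 25L) {
  stopifnot(mean_target > 1, mean_target < max,
            sd_target^2 > mean_target)
  theta <- mean_target^2 / (sd_target^2 - mean_target)
  k <- seq_len(max)
  tmean <- function(mu) {
    p <- dnbinom(k, size = theta, mu = mu)
    sum(k * p) / sum(p) - mean_target
  }
  mu <- uniroot(tmean, c(1, max))$root
  p <- dnbinom(k, size = theta, mu = mu)
  list(mu = mu, theta = theta, max = max, pmf = p / sum(p))
}

# beta shape parameters from a mean/sd target
beta_shapes <- function(mean, sd) {
  stopifnot(mean > 0, mean < 1, sd^2 < mean * (1 - mean))
  nu <- mean * (1 - mean) / sd^2 - 1
  c(a = mean * nu, b = (1 - mean) * nu)
}

# per-group default profile; values follow the descriptive moments of the
# pandemic cross-sectional tables (see the methods vignette)
default_profile <- function(group = c("pwms", "control"),
                            preset = c("cross_sectional", "longitudinal")) {
  group <- match.arg(group)
  preset <- match.arg(preset)
  if (group == "pwms") {
    size <- if (preset == "cross_sectional") c(6.79, 4.24) else c(8.02, 5.70)
    density <- if (preset == "cross_sectional") c(0.76, 0.25) else c(0.74, 0.25)
    kin_prob <- if (preset == "cross_sectional") 0.56 else 0.46
    contact_probs <- if (preset == "cross_sectional") {
      c(daily = 0.84, weekly = 0.07, monthly = 0.06, less = 0.03)
    } else {
      c(daily = 0.765, weekly = 0.10, monthly = 0.09, less = 0.045)
    }
    list(
      size_mean = size[1], size_sd = size[2], size_max = 25L,
      density_mean = density[1], density_sd = density[2],
      kin_prob = kin_prob,
      contact_probs = contact_probs,
      behavior_probs = c(drinks = 0.124, smokes = 0.089,
                         nonexerciser = 0.353, bad_diet = 0.230),
      neg_influence_model = c(intercept = -1.341, drinks = 0.9, smokes = 0.9,
                              nonexerciser = 0.9, bad_diet = 0.9),
      distance_prob = 0.32,
      years_known_shape = 2, years_known_scale = 10,
      alter_age_sd = 13, alter_age_center_sd = 6,
      sex_probs = c(man = 0.32, woman = 0.65, other_unknown = 0.03),
      race_probs = c(african_american = 0.03,
                     native_hawaiian_pacific_islander = 0.005, asian = 0.01,
                     white = 0.935, multiracial = 0.01, other = 0.01),
      age_mean = 50.7, age_sd = 12.1,
      woman_prob = 0.82,
      nhw_prob = 0.92,
      income_probs = c(0.076, 0.087, 0.100, 0.095, 0.081, 0.078, 0.082,
                       0.087, 0.312),
      employment_prob = 0.537,
      education_probs = c(0.01, 0.062, 0.137, 0.099, 0.324, 0.368),
      married_prob = 0.70, lives_alone_prob = 0.15,
      disease_duration_shape = 2.25, disease_duration_scale = 6.67
    )
  } else {
    size <- if (preset == "cross_sectional") c(6.78, 3.90) else c(8.18, 4.05)
    density <- if (preset == "cross_sectional") c(0.72, 0.24) else c(0.69, 0.24)
    kin_prob <- if (preset == "cross_sectional") 0.51 else 0.48
    contact_probs <- if (preset == "cross_sectional") {
      c(daily = 0.82, weekly = 0.08, monthly = 0.06, less = 0.04)
    } else {
      c(daily = 0.70, weekly = 0.14, monthly = 0.11, less = 0.05)
    }
    list(
      size_mean = size[1], size_sd = size[2], size_max = 25L,
      density_mean = density[1], density_sd = density[2],
      kin_prob = kin_prob,
      contact_probs = contact_probs,
      behavior_probs = c(drinks = 0.166, smokes = 0.072,
                         nonexerciser = 0.391, bad_diet = 0.228),
      neg_influence_model = c(intercept = -1.341, drinks = 0.9, smokes = 0.9,
                              nonexerciser = 0.9, bad_diet = 0.9),
      distance_prob = 0.39,
      years_known_shape = 2, years_known_scale = 8,
      alter_age_sd = 12, alter_age_center_sd = 6,
      sex_probs = c(man = 0.35, woman = 0.62, other_unknown = 0.03),
      race_probs = c(african_american = 0.01,
                     native_hawaiian_pacific_islander = 0.005, asian = 0.01,
                     white = 0.955, multiracial = 0.01, other = 0.01),
      age_mean = 44.4, age_sd = 12.1,
      woman_prob = 0.77,
      nhw_prob = 0.96,
      income_probs = c(0.031, 0.047, 0.063, 0.089, 0.101, 0.079, 0.107,
                       0.094, 0.388),
      employment_prob = 0.779,
      education_probs = c(0.005, 0.028, 0.085, 0.056, 0.353, 0.473),
      married_prob = 0.67, lives_alone_prob = 0.15,
      disease_duration_shape = NULL, disease_duration_scale = NULL
    )
  }
}

default_outcome_model <- function() {
  list(
    # covariate coefficients per outcome; intercepts are solved at
    # configuration time so each outcome hits its target population mean
    coefficients = list(
      msrs_r = c(age = 0.08, disease_duration = 0.09, employment_bin = -1.8,
                 income_bracket = -0.35),
      promis_pf_pwms = c(age = -0.18, disease_duration = -0.15,
                         employment_bin = 4, income_bracket = 0.7),
      promis_pf_control = c(age = -0.12, employment_bin = 3,
                            income_bracket = 0.5),
      pdds_latent = c(age = 0.035, disease_duration = 0.05,
                      employment_bin = -0.9, income_bracket = -0.12)
    ),
    residual_sd = c(msrs_r = 5.1, promis_pf_pwms = 10.1,
                    promis_pf_control = 8.5, pdds_latent = 1.8),
    target_mean = c(msrs_r = 7.55, promis_pf_pwms = 46.4,
                    promis_pf_control = 56.3),
    # right-skewed gait-disability distribution over steps 0..8
    # (population mean ~1.9); latent score is cut at these cumulative
    # probabilities
    pdds_probs = c(0.35, 0.20, 0.13, 0.10, 0.08, 0.06, 0.05, 0.02, 0.01)
  )
}

default_contraction <- function() {
  list(
    # weak alters: contacted less than weekly AND non-kin
    dropout_weak = 0.80,
    # background dropout for the remaining alters; kin are protected by
    # the retention boost (their rate is dropout_other * (1 - kin_boost))
    dropout_other = 0.165,
    kin_boost = 0.5,
    tie_removal = 0
  )
}

#' Generator configuration for synthetic cohorts
#'
#' Bundles every distributional assumption of the synthetic-cohort
#' generator: network size (truncated negative binomial) and per-network
#' tie density (beta), alter attribute distributions (kin, contact
#' frequency, demographics, health-behavior flags, and a logistic model
#' generating the perceived negative-health-influence flag from the
#' behavior flags), participant covariates, outcome models (linear for
#' MSRS-R and PROMIS Physical Function; a thresholded latent score for
#' the ordinal PDDS), configurable feature effects, and the pandemic
#' contraction operator.  Defaults are calibrated once to the descriptive
#' moments of the published pandemic cohorts (see the methods vignette);
#' the `"longitudinal"` preset instead matches the prepandemic baseline
#' of the longitudinal subcohorts.
#'
#' @param n_pwms,n_controls Cohort sizes.
#' @param preset `"cross_sectional"` (pandemic moments) or
#'   `"longitudinal"` (prepandemic baseline moments).
#' @param effects Named list of feature effects on the outcomes, on the
#'   regression (0-1 proportion) scale: elements `msrs_r`,
#'   `promis_pf_pwms`, `promis_pf_control`, `pdds_latent`, each a named
#'   numeric vector over feature names.  `NULL` uses the defaults (the
#'   published negative-influence estimates); `"null"` sets every effect
#'   to zero.
#' @param pwms,control Named lists overriding entries of the group
#'   profiles (see the vignette for all knobs).
#' @param contraction Named list overriding the contraction defaults
#'   (`dropout_weak`, `dropout_other`, `kin_boost`, `tie_removal`).
#' @param seed Default seed stored in the config (can be overridden at
#'   [simulate_cohort()] time).
#' @return A list of class `persnet_config`.
#' @export
#' @examples
#' cfg <- generator_config(n_pwms = 50, n_controls = 0, seed = 1)
#' cohort <- simulate_cohort(cfg)
generator_config <- function(n_pwms = 713, n_controls = 1250,
                             preset = c("cross_sectional", "longitudinal"),
                             effects = NULL, pwms = list(), control = list(),
                             contraction = list(), seed = NULL) {
  preset <- match.arg(preset)
  prof_pw <- utils::modifyList(default_profile("pwms", preset), pwms)
  prof_co <- utils::modifyList(default_profile("control", preset), control)
  for (prof in list(prof_pw, prof_co)) {
    stopifnot(prof$size_mean >= 1, prof$size_mean <= prof$size_max,
              all(prof$behavior_probs >= 0 & prof$behavior_probs <= 1),
              prof$kin_prob >= 0, prof$kin_prob <= 1)
  }
  if (identical(effects, "null")) {
    effects <- list(msrs_r = numeric(), promis_pf_pwms = numeric(),
                    promis_pf_control = numeric(), pdds_latent = numeric())
  } else if (is.null(effects)) {
    effects <- list(
      msrs_r = c(pct_negative_influence = 2.181),
      promis_pf_pwms = c(pct_negative_influence = -0.650),
      promis_pf_control = c(pct_negative_influence = -5.707),
      pdds_latent = numeric()
    )
  }
  bad <- setdiff(unlist(lapply(effects, names)), persnet_features())
  if (length(bad)) stop("unknown feature(s) in effects: ",
                        paste(bad, collapse = ", "))
  outcome <- default_outcome_model()
  contraction <- utils::modifyList(default_contraction(), contraction)
  stopifnot(contraction$dropout_weak >= 0, contraction$dropout_weak <= 1,
            contraction$dropout_other >= 0, contraction$dropout_other <= 1,
            contraction$kin_boost >= 0, contraction$kin_boost <= 1,
            contraction$tie_removal >= 0, contraction$tie_removal <= 1)
  structure(
    list(n_pwms = n_pwms, n_controls = n_controls, preset = preset,
         profiles = list(pwms = prof_pw, control = prof_co),
         effects = effects, outcome = outcome, contraction = contraction,
         seed = seed),
    class = "persnet_config"
  )
}

#' @export
print.persnet_config <- function(x, ...) {
  cat(sprintf("<persnet_config> %s preset: %d pwMS, %d controls\n",
              x$preset, x$n_pwms, x$n_controls))
  eff <- purrr::compact(purrr::map(x$effects, function(e) e[e != 0]))
  if (length(unlist(eff)) == 0) {
    cat("  feature effects: none (null model)\n")
  } else {
    for (oc in names(eff)) {
      if (length(eff[[oc]]) == 0) next
      cat(sprintf("  %s ~ %s\n", oc,
                  paste(sprintf("%+.3f*%s", eff[[oc]], names(eff[[oc]])),
                        collapse = " ")))
    }
  }
  invisible(x)
}

# sample one group's networks + alter tables; returns list of ego_network
simulate_networks <- function(prof, ids, timepoint) {
  n <- length(ids)
  size_dist <- calibrate_size_dist(prof$size_mean, prof$size_sd,
                                   prof$size_max)
  sizes <- sample.int(size_dist$max, n, replace = TRUE,
                      prob = size_dist$pmf)
  dsh <- beta_shapes(prof$density_mean, prof$density_sd)
  dens <- stats::rbeta(n, dsh["a"], dsh["b"])
  total <- sum(sizes)
  kin <- rbinom(total, 1, prof$kin_prob) == 1
  relationship <- ifelse(kin,
                         sample(c("spouse", "parent", "child", "sibling",
                                  "other_family"), total, replace = TRUE),
                         sample(c("friend", "coworker", "neighbor", "other"),
                                total, replace = TRUE))
  contact <- sample(names(prof$contact_probs), total, replace = TRUE,
                    prob = prof$contact_probs)
  beh <- purrr::map(prof$behavior_probs, function(p) {
    rbinom(total, 1, p) == 1
  })
  ni_lp <- prof$neg_influence_model["intercept"] +
    prof$neg_influence_model["drinks"] * beh$drinks +
    prof$neg_influence_model["smokes"] * beh$smokes +
    prof$neg_influence_model["nonexerciser"] * beh$nonexerciser +
    prof$neg_influence_model["bad_diet"] * beh$bad_diet
  neg_influence <- rbinom(total, 1, plogis(ni_lp)) == 1
  centers <- rep(rnorm(n, 48, prof$alter_age_center_sd), times = sizes)
  ages <- pmax(0, round(centers + rnorm(total, 0, prof$alter_age_sd)))
  alters_all <- tibble::tibble(
    alter_id = unlist(lapply(sizes, seq_len)),
    relationship = relationship,
    age = ages,
    sex = sample(names(prof$sex_probs), total, replace = TRUE,
                 prob = prof$sex_probs),
    race = sample(names(prof$race_probs), total, replace = TRUE,
                  prob = prof$race_probs),
    contact_freq = contact,
    years_known = round(rgamma(total, shape = prof$years_known_shape,
                               scale = prof$years_known_scale), 1),
    distance_gt_15mi = rbinom(total, 1, prof$distance_prob) == 1,
    drinks = beh$drinks, smokes = beh$smokes,
    nonexerciser = beh$nonexerciser, bad_diet = beh$bad_diet,
    negative_influence = neg_influence
  )
  alters_all$alter_id <- as.character(alters_all$alter_id)
  splits <- rep(seq_len(n), times = sizes)
  alter_list <- split(alters_all, factor(splits, levels = seq_len(n)))
  purrr::pmap(list(ids, alter_list, sizes, dens), function(id, a, s, dn) {
    npairs <- s * (s - 1) / 2
    m <- matrix(FALSE, s, s)
    if (npairs > 0) {
      up <- upper.tri(m)
      m[up] <- runif(npairs) < dn
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
    }
    ego_network(id, timepoint, a, m)
  })
}

# participant covariates for one group
simulate_covariates <- function(prof, ids, group) {
  n <- length(ids)
  age <- pmin(90, pmax(18, round(rnorm(n, prof$age_mean, prof$age_sd), 1)))
  sex <- ifelse(rbinom(n, 1, prof$woman_prob) == 1, "woman", "man")
  nhw <- rbinom(n, 1, prof$nhw_prob) == 1
  cb <- persnet_codebook()
  emp <- rbinom(n, 1, prof$employment_prob) == 1
  dd <- if (group == "pwms") {
    round(rgamma(n, shape = prof$disease_duration_shape,
                 scale = prof$disease_duration_scale), 1)
  } else {
    rep(NA_real_, n)
  }
  tibble::tibble(
    participant_id = ids,
    group = group,
    cohort_id = sample(c("c1", "c3", "c8"), n, replace = TRUE,
                       prob = c(0.45, 0.35, 0.20)),
    age = age,
    sex = sex,
    race = ifelse(nhw, "white",
                  sample(setdiff(cb$race_levels, "white"), n, replace = TRUE)),
    ethnicity = ifelse(nhw, "non_hispanic",
                       sample(c("hispanic", "non_hispanic"), n, replace = TRUE,
                              prob = c(0.4, 0.6))),
    disease_duration = dd,
    employment = ifelse(emp,
                        sample(cb$employment_employed, n, replace = TRUE,
                               prob = c(0.88, 0.12)),
                        sample(setdiff(cb$employment_levels,
                                       cb$employment_employed), n,
                               replace = TRUE)),
    education = sample(cb$education_levels, n, replace = TRUE,
                       prob = prof$education_probs),
    occupation = sample(c("professional", "executive_manager",
                          "sales_clerical", "service", "business_owner",
                          "other"), n, replace = TRUE,
                        prob = c(0.50, 0.17, 0.10, 0.02, 0.06, 0.15)),
    income_bracket = sample.int(9L, n, replace = TRUE,
                                prob = prof$income_probs),
    married = rbinom(n, 1, prof$married_prob) == 1,
    lives_alone = rbinom(n, 1, prof$lives_alone_prob) == 1
  )
}

# linear predictor of configured feature effects for a group's rows
feature_effect_lp <- function(eff, feats_reg) {
  if (length(eff) == 0) return(rep(0, nrow(feats_reg)))
  vals <- as.matrix(feats_reg[names(eff)])
  vals[is.na(vals)] <- 0  # an undefined feature contributes no effect
  as.vector(vals %*% eff)
}

# expected covariate values used to solve intercepts for target means
profile_cov_means <- function(prof) {
  c(age = prof$age_mean,
    disease_duration = if (is.null(prof$disease_duration_shape)) 0 else
      prof$disease_duration_shape * prof$disease_duration_scale,
    employment_bin = prof$employment_prob,
    income_bracket = sum(seq_len(9) * prof$income_probs /
                           sum(prof$income_probs)))
}

# generate the three outcomes for one group given covariates + features
simulate_outcomes <- function(parts, feats_reg, config, group) {
  om <- config$outcome
  eff <- config$effects
  prof <- config$profiles[[group]]
  covm <- profile_cov_means(prof)
  enc <- encode_covariates(parts)
  cov_lp <- function(coefs) {
    lp <- rep(0, nrow(parts))
    for (nm in names(coefs)) {
      x <- switch(nm,
                  age = enc$age,
                  disease_duration = enc$disease_duration,
                  employment_bin = enc$employment_bin,
                  income_bracket = enc$income_bracket)
      lp <- lp + coefs[nm] * x
    }
    lp
  }
  expected_lp <- function(coefs) sum(coefs * covm[names(coefs)])
  # nominal mean of the default effect driver (negative influence ~ 0.36)
  nominal_feat_mean <- function(e) {
    if (length(e) == 0) return(0)
    sum(e * 0.36)
  }
  n <- nrow(parts)
  if (group == "pwms") {
    b0_m <- om$target_mean["msrs_r"] -
      expected_lp(om$coefficients$msrs_r) - nominal_feat_mean(eff$msrs_r)
    msrs <- b0_m + cov_lp(om$coefficients$msrs_r) +
      feature_effect_lp(eff$msrs_r, feats_reg) +
      rnorm(n, 0, om$residual_sd["msrs_r"])
    b0_p <- om$target_mean["promis_pf_pwms"] -
      expected_lp(om$coefficients$promis_pf_pwms) -
      nominal_feat_mean(eff$promis_pf_pwms)
    promis <- b0_p + cov_lp(om$coefficients$promis_pf_pwms) +
      feature_effect_lp(eff$promis_pf_pwms, feats_reg) +
      rnorm(n, 0, om$residual_sd["promis_pf_pwms"])
    latent <- cov_lp(om$coefficients$pdds_latent) +
      feature_effect_lp(eff$pdds_latent, feats_reg) +
      rnorm(n, 0, om$residual_sd["pdds_latent"])
    z <- (latent - mean(latent)) / sd(latent)
    cuts <- qnorm(cumsum(om$pdds_probs))[1:8]
    pdds <- findInterval(z, cuts)
    tibble::tibble(pdds = pdds, msrs_r = round(msrs, 2),
                   promis_pf = round(promis, 2))
  } else {
    b0_p <- om$target_mean["promis_pf_control"] -
      expected_lp(om$coefficients$promis_pf_control) -
      nominal_feat_mean(eff$promis_pf_control)
    promis <- b0_p + cov_lp(om$coefficients$promis_pf_control) +
      feature_effect_lp(eff$promis_pf_control, feats_reg) +
      rnorm(n, 0, om$residual_sd["promis_pf_control"])
    tibble::tibble(pdds = NA_real_, msrs_r = NA_real_,
                   promis_pf = round(promis, 2))
  }
}

#' Simulate a synthetic survey cohort
#'
#' Generates a full cohort with the statistical structure the analyses
#' assume: ego networks (size, per-network tie density, alter attributes
#' including behavior-driven negative-influence flags), participant
#' covariates, and the three patient-reported outcomes generated from the
#' configured linear (MSRS-R, PROMIS) and thresholded-latent (PDDS)
#' models with the configured feature effects.  Reproducible: the same
#' seed yields an identical cohort.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed (overrides `config$seed`).
#' @param timepoint Timepoint label for the generated records (default
#'   `"pandemic"` for the cross-sectional preset, `"prepandemic"` for the
#'   longitudinal preset).
#' @return A `simulated_cohort` (subclass of `persnet_cohort`): the
#'   participant tibble carries covariates, outcomes and the `network`
#'   list-column; `$truth` records the generating feature effects (see
#'   [ground_truth_report()]); `$config` stores the configuration.
#' @export
simulate_cohort <- function(config, seed = config$seed,
                            timepoint = NULL) {
  stopifnot(inherits(config, "persnet_config"))
  if (!is.null(seed)) set.seed(seed)
  timepoint <- timepoint %||%
    if (config$preset == "longitudinal") "prepandemic" else "pandemic"
  groups <- list()
  for (g in c("pwms", "control")) {
    ng <- if (g == "pwms") config$n_pwms else config$n_controls
    if (ng == 0) next
    prof <- config$profiles[[g]]
    ids <- sprintf("%s%04d", if (g == "pwms") "ms" else "ct", seq_len(ng))
    parts <- simulate_covariates(prof, ids, g)
    nets <- simulate_networks(prof, ids, timepoint)
    parts$timepoint <- timepoint
    parts$network <- nets
    feats_reg <- features_regression_scale(nets_feature_tbl(nets))
    parts <- dplyr::bind_cols(parts[setdiff(names(parts), "network")],
                              simulate_outcomes(parts, feats_reg, config, g))
    parts$network <- nets
    groups[[g]] <- parts
  }
  participants <- dplyr::bind_rows(groups)
  participants <- dplyr::relocate(participants, "network",
                                  .after = dplyr::last_col())
  out <- new_persnet_cohort(participants, persnet_codebook(),
                            class = c("simulated_cohort", "persnet_cohort"))
  out$config <- config
  out$truth <- build_truth(config)
  out
}

build_truth <- function(config) {
  eff <- config$effects
  grid <- expand.grid(feature = persnet_features(),
                      outcome = c("pdds", "msrs_r", "promis_pf"),
                      group = c("pwms", "control"),
                      stringsAsFactors = FALSE)
  grid <- grid[!(grid$group == "control" &
                   grid$outcome %in% c("pdds", "msrs_r")), ]
  slot <- function(outcome, group) {
    switch(outcome,
           msrs_r = eff$msrs_r,
           pdds = eff$pdds_latent,
           promis_pf = if (group == "pwms") eff$promis_pf_pwms
                       else eff$promis_pf_control)
  }
  grid$beta_true <- purrr::pmap_dbl(grid, function(feature, outcome, group) {
    e <- slot(outcome, group)
    if (feature %in% names(e)) unname(e[feature]) else 0
  })
  tibble::as_tibble(grid)
}

#' Ground-truth effect table of a simulated cohort
#'
#' Machine-readable record of the generating feature effects, one row per
#' (feature, outcome, group) with the true coefficient (zero where no
#' effect was configured), joinable 1:1 to the association results by
#' `feature` and `outcome`.  PDDS truth is reported on the latent scale.
#'
#' @param cohort A `simulated_cohort`.
#' @return A tibble with columns `feature`, `outcome`, `group`,
#'   `beta_true`.
#' @export
ground_truth_report <- function(cohort) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  cohort$truth
}

#' Apply the pandemic contraction operator
#'
#' Produces the pandemic timepoint of a longitudinal cohort by perturbing
#' each prepandemic network the way pandemic-era distancing pruned
#' personal networks: *weak* alters (contacted less than weekly and not
#' kin) are dropped with probability `dropout_weak`; the remaining alters
#' are dropped at the background rate `dropout_other`, reduced by the kin
#' retention boost for kin (`dropout_other * (1 - kin_boost)`); surviving
#' alter-alter ties are removed with probability `tie_removal`.  Pandemic
#' outcomes are regenerated from the configured outcome models on the
#' contracted networks, and `elapsed_years` (uniform on 1-4) and the
#' pandemic assessment records are added.
#'
#' With all rates zero the pandemic networks equal the prepandemic ones.
#' The defaults are calibrated so the expected pwMS pandemic network size
#' matches the published longitudinal pandemic mean (see the vignette).
#'
#' @param cohort A `simulated_cohort` at the prepandemic timepoint.
#' @param contraction Optional override list (defaults to
#'   `cohort$config$contraction`).
#' @param seed Optional integer seed.
#' @return A `simulated_cohort` with both timepoints per participant.
#' @export
apply_contraction <- function(cohort, contraction = NULL, seed = NULL) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  if (!is.null(seed)) set.seed(seed)
  config <- cohort$config
  ctr <- utils::modifyList(config$contraction, contraction %||% list())
  pre <- cohort$participants
  stopifnot(all(pre$timepoint == "prepandemic"))
  kin_codes <- cohort$codebook$kin_codes
  contracted <- purrr::map(pre$network, function(net) {
    a <- net$alters
    n <- nrow(a)
    if (n == 0) return(ego_network(net$participant_id, "pandemic", a))
    kin <- a$relationship %in% kin_codes
    weak <- !kin & a$contact_freq %in% c("monthly", "less")
    p_drop <- ifelse(weak, ctr$dropout_weak,
                     ifelse(kin, ctr$dropout_other * (1 - ctr$kin_boost),
                            ctr$dropout_other))
    keep <- runif(n) >= p_drop
    a2 <- a[keep, , drop = FALSE]
    m2 <- net$ties[keep, keep, drop = FALSE]
    if (ctr$tie_removal > 0 && sum(m2) > 0) {
      up <- which(m2 & upper.tri(m2), arr.ind = TRUE)
      gone <- runif(nrow(up)) < ctr$tie_removal
      m2[up[gone, , drop = FALSE]] <- FALSE
      m2[up[gone, c(2, 1), drop = FALSE]] <- FALSE
    }
    ego_network(net$participant_id, "pandemic", a2, m2)
  })
  pan <- pre
  pan$timepoint <- "pandemic"
  pan$network <- contracted
  pan$elapsed_years <- round(runif(nrow(pan), 1, 4), 2)
  # regenerate outcomes from the contracted networks, per group
  for (g in unique(pan$group)) {
    idx <- pan$group == g
    feats <- nets_feature_tbl(pan$network[idx])
    oc <- simulate_outcomes(pan[idx, ], features_regression_scale(feats),
                            config, g)
    pan[idx, c("pdds", "msrs_r", "promis_pf")] <- oc
  }
  if (!"elapsed_years" %in% names(pre)) pre$elapsed_years <- NA_real_
  both <- dplyr::bind_rows(pre, pan)
  out <- new_persnet_cohort(both, cohort$codebook,
                            class = c("simulated_cohort", "persnet_cohort"))
  out$config <- config
  out$config$contraction <- ctr
  out$truth <- cohort$truth
  out
}
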