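test_that("paired change test handles typical and degenerate inputs", {
  same <- paired_change_test(c(3, 5, 7, 9), c(3, 5, 7, 9))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  balanced <- paired_change_test(c(0, 0, 0, 0), c(1, -1, 1, -1))
  expect_equal(balanced$mean_change, 0)
  expect_equal(balanced$t, 0)
  shifted <- paired_change_test(c(1, 2, 3), c(2, 3, 4))  # constant +1
  expect_true(shifted$degenerate)
  expect_true(is.infinite(shifted$t))
  # paired t equals the one-sample t on differences
  set.seed(31)
  pre <- rnorm(25, 10, 3)
  post <- pre + rnorm(25, 1, 2)
  ours <- paired_change_test(pre, post)
  ref <- t.test(post - pre)
  expect_equal(ours$t, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value)
  # pairs with a missing side are dropped
  with_na <- paired_change_test(c(pre, NA, 5), c(post, 4, NA))
  expect_equal(with_na$n_pairs, 25)
})

test_that("a kin-style shift of 8 points (SD 20) at n=230 is detected", {
  set.seed(32)
  pre <- rnorm(230, 46, 25)
  post <- pre + rnorm(230, 8, 20)
  res <- paired_change_test(pre, post)
  # paired-t power at d = 8/20 and n = 230 exceeds 0.99 at alpha = .05
  expect_lt(res$p, 0.05)
  expect_gt(res$mean_change, 0)
})

test_that("fisher omnibus matches the chi-square closed form", {
  null3 <- fisher_omnibus(c(1, 1, 1))
  expect_equal(null3$chi_sq, 0)
  expect_equal(null3$analytic_p, 1)
  two <- fisher_omnibus(c(0.05, 0.05))
  expect_equal(two$chi_sq, -4 * log(0.05), tolerance = 1e-12)
  expect_equal(round(two$chi_sq, 2), 11.98)
  expect_equal(two$analytic_p, pchisq(-4 * log(0.05), 4, lower.tail = FALSE))
  expect_equal(round(two$analytic_p, 4), 0.0175)
  # k = 1 is the identity
  expect_equal(fisher_omnibus(0.01)$analytic_p, 0.01, tolerance = 1e-12)
  expect_error(fisher_omnibus(c(0.5, 0)), "floor")
  expect_error(fisher_omnibus(c(0.5, 1.2)), "<= 1")
})

test_that("change regression recovers a noise-free change effect", {
  set.seed(33)
  n <- 50
  d <- tibble::tibble(
    participant_id = as.character(1:n),
    delta_f = rnorm(n), age = rnorm(n, 50, 10),
    disease_duration = rgamma(n, 2, scale = 5),
    employment_bin = rbinom(n, 1, 0.5),
    income_bracket = sample(1:9, n, TRUE),
    elapsed_years = runif(n, 1, 4),
    cohort_id = sample(c("c1", "c3", "c8"), n, TRUE)
  )
  d$msrs_r <- 3 * d$delta_f + 0.1 * d$age + 0.5 * d$elapsed_years +
    ifelse(d$cohort_id == "c3", 1, 0)
  res <- suppressWarnings(change_regression(d, "delta_f", "msrs_r"))
  expect_equal(res$beta, 3, tolerance = 1e-8)
})

test_that("omitting a confounded cohort covariate biases the change estimate", {
  set.seed(34)
  n <- 400
  cohort_id <- sample(c("c1", "c8"), n, TRUE)
  delta_f <- rnorm(n) + ifelse(cohort_id == "c8", 1.5, 0)
  d <- tibble::tibble(
    participant_id = as.character(1:n), cohort_id = cohort_id,
    delta_f = delta_f, age = rnorm(n, 50, 10),
    disease_duration = rgamma(n, 2, scale = 5),
    employment_bin = rbinom(n, 1, 0.5),
    income_bracket = sample(1:9, n, TRUE),
    elapsed_years = runif(n, 1, 4)
  )
  d$msrs_r <- 1 * d$delta_f + 4 * (d$cohort_id == "c8") + rnorm(n)
  adj <- change_regression(d, "delta_f", "msrs_r")
  unadj <- change_regression(d, "delta_f", "msrs_r",
                             covariates = c("age", "disease_duration",
                                            "employment_bin",
                                            "income_bracket",
                                            "elapsed_years"))
  expect_equal(adj$beta, 1, tolerance = 0.2)
  expect_gt(unadj$beta, 1.5)  # confounding inflates the slope
})

test_that("the fast p-value battery reproduces lm exactly", {
  set.seed(35)
  n <- 60
  d <- tibble::tibble(
    participant_id = sprintf("p%02d", 1:n),
    f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n),
    age = rnorm(n), cohort_id = sample(c("a", "b"), n, TRUE),
    y = rnorm(n)
  )
  om <- permutation_omnibus(d, c("f1", "f2", "f3"), "y",
                            c("age", "cohort_id"), B = 99, seed = 1)
  for (f in c("f1", "f2", "f3")) {
    ref <- feature_outcome_regression(d, f, "y", c("age", "cohort_id"))
    expect_equal(unname(om$observed_p[f]), ref$p, tolerance = 1e-10)
  }
})

test_that("empirical p follows the add-one permutation formula", {
  set.seed(36)
  n <- 30
  d <- tibble::tibble(
    participant_id = as.character(1:n),
    f1 = rnorm(n), f2 = rnorm(n), age = rnorm(n))
  d$y <- 5 * d$f1 + rnorm(n, 0, 0.5)  # strong association
  om <- suppressWarnings(
    permutation_omnibus(d, c("f1", "f2"), "y", "age", B = 9, seed = 2))
  # observed beats all 9 permutations: (1 + 0) / (9 + 1)
  expect_equal(om$empirical_p, 0.1)
  expect_equal(dim(om$perm_p), c(9, 2))
  expect_warning(permutation_omnibus(d, "f1", "y", "age", B = 50),
                 "too small")
})

test_that("permutation omnibus is invariant to row order given the seed", {
  set.seed(37)
  n <- 40
  d <- tibble::tibble(
    participant_id = sprintf("p%02d", 1:n),
    f1 = rnorm(n), f2 = rnorm(n), age = rnorm(n), y = rnorm(n))
  a <- permutation_omnibus(d, c("f1", "f2"), "y", "age", B = 199, seed = 7)
  b <- permutation_omnibus(d[sample(n), ], c("f1", "f2"), "y", "age",
                           B = 199, seed = 7)
  expect_equal(a$empirical_p, b$empirical_p)
  expect_equal(a$chi_sq, b$chi_sq)
  expect_equal(a$perm_chi, b$perm_chi)
})

test_that("exact enumeration matches a brute-force lm-per-permutation oracle", {
  set.seed(38)
  n <- 6
  d <- tibble::tibble(
    participant_id = letters[1:n],
    f1 = rnorm(n), f2 = rnorm(n),
    y = rnorm(n))
  om <- permutation_omnibus(d, c("f1", "f2"), "y", covariates = NULL,
                            exact = TRUE)
  expect_equal(om$B, factorial(n))
  # oracle: every permutation through plain lm()
  perms <- persnet:::all_permutations(n)
  chi_oracle <- apply(perms, 1, function(idx) {
    ps <- vapply(c("f1", "f2"), function(f) {
      fit <- lm(d$y[idx] ~ d[[f]])
      summary(fit)$coefficients[2, 4]
    }, numeric(1))
    -2 * sum(log(ps))
  })
  expect_equal(sort(om$perm_chi), sort(chi_oracle), tolerance = 1e-9)
  chi_obs <- -2 * sum(log(vapply(c("f1", "f2"), function(f) {
    summary(lm(d$y ~ d[[f]]))$coefficients[2, 4]
  }, numeric(1))))
  expect_equal(om$empirical_p,
               (1 + sum(chi_oracle >= chi_obs)) / (factorial(n) + 1),
               tolerance = 1e-12)
})

test_that("qq envelope has the documented geometry", {
  set.seed(39)
  k <- 18
  B <- 500
  perm_p <- matrix(runif(B * k), B, k)
  obs <- runif(k)
  env <- qq_envelope(obs, perm_p)
  expect_equal(nrow(env), k)
  expect_equal(env$expected, -log10(seq_len(k) / (k + 1)))
  expect_equal(env$observed, -log10(sort(obs)))
  expect_true(all(env$band_upper >= env$band_lower))
  # bands are monotone along the expected quantiles
  expect_true(all(diff(env$band_upper) <= 1e-12))
  # a median observed vector sits inside the band
  med <- apply(apply(perm_p, 1, sort), 1, stats::median)
  env2 <- qq_envelope(med, perm_p)
  expect_true(all(env2$observed >= env2$band_lower - 1e-9 &
                    env2$observed <= env2$band_upper + 1e-9))
  # an injected strong association rises above the band's top point
  strong <- c(sort(runif(k - 1)), 1e-8)
  env3 <- qq_envelope(strong, perm_p)
  expect_gt(env3$observed[1], env3$band_upper[1])
  expect_warning(qq_envelope(obs, perm_p[1:20, ]), "unreliable")
})

test_that("under a null generator the empirical omnibus p is calibrated", {
  set.seed(40)
  n <- 60
  k <- 6
  reps <- 40
  emp <- replicate(reps, {
    F_mat <- matrix(rnorm(n * k), n, k)
    d <- tibble::as_tibble(as.data.frame(F_mat))
    names(d) <- paste0("f", 1:k)
    d$participant_id <- as.character(1:n)
    d$age <- rnorm(n)
    d$y <- rnorm(n)  # independent of all features
    permutation_omnibus(d, paste0("f", 1:k), "y", "age", B = 199)$empirical_p
  })
  # roughly uniform: mean near 0.5, no pile-up at the extremes
  expect_gt(mean(emp), 0.3)
  expect_lt(mean(emp), 0.7)
  expect_lt(mean(emp <= 0.05), 0.25)
})

test_that("fisher omnibus agrees with exhaustive enumeration on a tiny cohort", {
  # n = 5: all 120 permutations, exact equality of counts
  set.seed(41)
  n <- 5
  d <- tibble::tibble(participant_id = letters[1:n],
                      f1 = c(2, -1, 0.5, 1, -2),
                      y = c(1.9, -1.2, 0.6, 0.8, -2.1))
  om <- permutation_omnibus(d, "f1", "y", covariates = NULL, exact = TRUE)
  perms <- persnet:::all_permutations(n)
  chi <- apply(perms, 1, function(idx) {
    -2 * log(summary(lm(d$y[idx] ~ d$f1))$coefficients[2, 4])
  })
  expect_equal(om$B, 120)
  expect_equal(sum(om$perm_chi >= om$chi_sq), sum(chi >= om$chi_sq))
})

test_that("with correlated features only the empirical omnibus p stays calibrated", {
  set.seed(43)
  n <- 80
  k <- 8
  reps <- 60
  ps <- replicate(reps, {
    base <- rnorm(n)
    F_mat <- vapply(seq_len(k), function(j) base + rnorm(n, 0, 0.3),
                    numeric(n))  # strongly correlated features
    d <- tibble::as_tibble(as.data.frame(F_mat))
    names(d) <- paste0("f", seq_len(k))
    d$participant_id <- as.character(seq_len(n))
    d$y <- rnorm(n)  # null outcome
    om <- permutation_omnibus(d, paste0("f", seq_len(k)), "y",
                              covariates = NULL, B = 199)
    c(emp = om$empirical_p, ana = om$analytic_p)
  })
  # empirical p near-uniform: nominal-rate rejections
  expect_lt(mean(ps["emp", ] <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
  # analytic p is anti-conservative here: it rejects far more often
  expect_gt(mean(ps["ana", ] <= 0.05), mean(ps["emp", ] <= 0.05))
})
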