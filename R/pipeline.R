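#' Run the full analysis pipeline
#'
#' Orchestrates an end-to-end run over a cohort — simulated from a
#' [generator_config()] or read from the three-file CSV dialect — and
#' writes the report tables:
#'
#' * `features.csv` — the 18 features per (participant, timepoint);
#' * `group_comparison.csv` — Welch t tests of each feature between pwMS
#'   and controls (18 rows, Bonferroni family m = 18);
#' * `associations.csv` — the covariate-adjusted regression battery
#'   (18 features x 3 outcomes for pwMS; m = 54), plus the control-arm
#'   PROMIS column when controls are present;
#' * `moderation.csv` — interaction and simple-slope estimates per
#'   feature for the joint pwMS + control PROMIS models;
#' * `paired_changes.csv`, `omnibus.json`, `qq_<outcome>.csv` — the
#'   longitudinal within-subject tests, permutation omnibus and Q-Q
#'   envelope (longitudinal runs only);
#' * `run_log.json` — seed, per-analysis complete-case n and exclusion
#'   counts.
#'
#' Deterministic given `seed`: rerunning with the same configuration and
#' seed reproduces every output file.
#'
#' @param config A [generator_config()] (simulated input), or a named
#'   list with `participants`, `alters`, `ties` CSV paths (and optionally
#'   `strict = FALSE` to read leniently, see [read_cohort()]).
#' @param out_dir Output directory.
#' @param analyses Character subset of
#'   `c("cross_sectional", "moderation", "longitudinal")`.
#' @param alpha Family-wise significance level (default .05).
#' @param B Permutation count for the longitudinal omnibus (>= 99).
#' @param seed Integer seed for generation and permutation.
#' @return Invisibly, a list with the in-memory results (`features`,
#'   `group_comparison`, `associations`, `moderation`, `paired_changes`,
#'   `omnibus`, `qq`, `log`).
#' @export
run_pipeline <- function(config, out_dir,
                         analyses = c("cross_sectional", "moderation"),
                         alpha = 0.05, B = 999, seed = 1) {
  analyses <- match.arg(analyses,
                        c("cross_sectional", "moderation", "longitudinal"),
                        several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(seed = seed, analyses = analyses)

  if (inherits(config, "persnet_config")) {
    if ("longitudinal" %in% analyses && B < 99) {
      stop("B must be >= 99 for the longitudinal omnibus")
    }
    cohort <- simulate_cohort(config, seed = seed)
    if ("longitudinal" %in% analyses) {
      if (config$preset != "longitudinal") {
        stop("longitudinal analysis needs a longitudinal-preset config")
      }
      cohort <- apply_contraction(cohort)
    }
  } else {
    missing_tbl <- setdiff(c("participants", "alters", "ties"), names(config))
    if (length(missing_tbl)) {
      stop("missing input table(s): ", paste(missing_tbl, collapse = ", "))
    }
    cohort <- read_cohort(config$participants, config$alters, config$ties,
                          strict = config$strict %||% TRUE)
  }

  feats <- cohort_features(cohort)
  readr::write_csv(feats, file.path(out_dir, "features.csv"))
  results <- list(features = feats)

  frame <- analysis_frame(cohort)
  pan <- frame[frame$timepoint == "pandemic", , drop = FALSE]

  if ("cross_sectional" %in% analyses) {
    feats_pan <- feats[feats$timepoint == "pandemic", , drop = FALSE]
    if (dplyr::n_distinct(feats_pan$group) == 2) {
      cmp <- compare_groups(feats_pan, alpha = alpha)
      readr::write_csv(cmp, file.path(out_dir, "group_comparison.csv"))
      results$group_comparison <- cmp
    }
    assoc <- list()
    if (any(pan$group == "pwms")) {
      assoc$pwms <- regression_battery(pan[pan$group == "pwms", ],
                                       alpha = alpha)
      assoc$pwms$group <- "pwms"
    }
    if (any(pan$group == "control")) {
      assoc$control <- regression_battery(
        pan[pan$group == "control", ], outcomes = "promis_pf",
        covariates = c("age", "employment_bin", "income_bracket"),
        alpha = alpha, m = length(persnet_features()) * 3)
      assoc$control$group <- "control"
    }
    assoc <- dplyr::bind_rows(assoc)
    readr::write_csv(assoc, file.path(out_dir, "associations.csv"))
    results$associations <- assoc
    log$n_association_cells <- nrow(assoc)
  }

  if ("moderation" %in% analyses) {
    if (dplyr::n_distinct(pan$group) == 2) {
      mods <- purrr::map_dfr(persnet_features(), function(f) {
        m <- moderation_analysis(pan, f)
        tibble::tibble(
          feature = f, n = m$n,
          interaction_beta = m$interaction$beta,
          interaction_ci_low = m$interaction$ci_low,
          interaction_ci_high = m$interaction$ci_high,
          interaction_p = m$interaction$p,
          slope_pwms = m$slopes$beta[m$slopes$group == "pwms"],
          slope_pwms_p = m$slopes$p[m$slopes$group == "pwms"],
          slope_control = m$slopes$beta[m$slopes$group == "control"],
          slope_control_p = m$slopes$p[m$slopes$group == "control"],
          q25 = m$anchors[1], q50 = m$anchors[2], q75 = m$anchors[3]
        )
      })
      readr::write_csv(mods, file.path(out_dir, "moderation.csv"))
      results$moderation <- mods
    } else {
      message("moderation analysis skipped: both groups required")
    }
  }

  if ("longitudinal" %in% analyses) {
    paired <- paired_change_tests(feats)
    readr::write_csv(paired, file.path(out_dir, "paired_changes.csv"))
    results$paired_changes <- paired
    ch <- feature_changes(cohort)
    ch_pw <- ch[ch$group == "pwms", , drop = FALSE]
    delta_cols <- paste0("delta_", persnet_features())
    covs <- c("age", "disease_duration", "employment_bin", "income_bracket",
              "elapsed_years", "cohort_id")
    ch_pw <- encode_covariates(ch_pw, cohort$codebook)
    omnibus <- list()
    qq <- list()
    for (oc in c("pdds", "msrs_r", "promis_pf")) {
      om <- permutation_omnibus(ch_pw, delta_cols, oc, covs, B = B,
                                seed = seed)
      omnibus[[oc]] <- om
      env <- qq_envelope(om$observed_p, om$perm_p)
      readr::write_csv(env, file.path(out_dir, paste0("qq_", oc, ".csv")))
      qq[[oc]] <- env
      log[[paste0("n_longitudinal_", oc)]] <- om$n
    }
    jsonlite::write_json(
      purrr::map(omnibus, function(o) {
        o[c("outcome", "k", "n", "chi_sq", "analytic_p", "empirical_p", "B")]
      }),
      file.path(out_dir, "omnibus.json"), auto_unbox = TRUE, digits = NA)
    results$omnibus <- omnibus
    results$qq <- qq
  }

  log$n_records <- nrow(cohort$participants)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE)
  results$log <- log
  invisible(results)
}
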