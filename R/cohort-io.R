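#' Read a PERSNET-style survey export into a cohort
#'
#' Assembles the three tabular exports into a validated cohort object:
#'
#' * `participants.csv` — one row per (participant, timepoint) with group
#'   label (`pwms`/`control`), `cohort_id`, `assessment_date` (ISO),
#'   covariates (`age`, `sex`, `race`, `ethnicity`, `disease_duration`,
#'   `employment`, `education`, `occupation`, `income_bracket`, `married`,
#'   `lives_alone`) and the patient-reported outcomes (`pdds`, `msrs_r`,
#'   `promis_pf`);
#' * `alters.csv` — one row per alter with attribute columns (see
#'   [ego_network()]), keyed by `participant_id` and `timepoint`;
#' * `ties.csv` — columns `participant_id`, `timepoint`, `alter_id_1`,
#'   `alter_id_2` and an optional logical `connected` (default `TRUE`),
#'   one row per reported alter-alter relation.
#'
#' Optional survey questions may be missing; such rows are retained with
#' the field marked missing.  Rows that violate hard invariants are
#' reported with their row numbers.  A pair reported both connected and
#' not connected (contradictory `(A,B)`/`(B,A)` rows) is a validation
#' error naming the offending pair.
#'
#' @param participants_file,alters_file,ties_file CSV paths.
#' @param codebook Codebook list, see [persnet_codebook()] /
#'   [read_codebook()].
#' @param strict If `TRUE` (default), out-of-range outcome or covariate
#'   values are an error; if `FALSE` they are reported as warnings and
#'   the rows retained.  Survey exports should be read strictly;
#'   `strict = FALSE` accommodates synthetic cohorts, whose linear
#'   outcome models produce latent-scale scores that can exceed the
#'   instrument bounds.
#' @return A `persnet_cohort`: a list with `participants` (tibble with a
#'   `network` list-column of [ego_network()] objects) and `codebook`.
#' @export
read_cohort <- function(participants_file, alters_file, ties_file,
                        codebook = persnet_codebook(), strict = TRUE) {
  parts <- readr::read_csv(participants_file, show_col_types = FALSE,
                           progress = FALSE)
  alters <- readr::read_csv(alters_file, show_col_types = FALSE,
                            progress = FALSE)
  ties <- readr::read_csv(ties_file, show_col_types = FALSE, progress = FALSE)

  need <- function(df, cols, file) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop("malformed header in ", file, ": missing column(s) ",
           paste(miss, collapse = ", "))
    }
  }
  need(parts, c("participant_id", "timepoint", "group"), "participants file")
  need(alters, c("participant_id", "timepoint", "alter_id"), "alters file")
  need(ties, c("participant_id", "timepoint", "alter_id_1", "alter_id_2"),
       "ties file")
  if (!"connected" %in% names(ties)) ties$connected <- TRUE
  parts$participant_id <- as.character(parts$participant_id)
  alters$participant_id <- as.character(alters$participant_id)
  alters$alter_id <- as.character(alters$alter_id)
  ties$participant_id <- as.character(ties$participant_id)
  ties$alter_id_1 <- as.character(ties$alter_id_1)
  ties$alter_id_2 <- as.character(ties$alter_id_2)

  key <- function(df) paste(df$participant_id, df$timepoint, sep = "@")
  pk <- key(parts)
  dup_date <- if ("assessment_date" %in% names(parts)) {
    duplicated(paste(pk, parts$assessment_date))
  } else duplicated(pk)
  if (any(dup_date)) {
    stop("duplicate (participant_id, timepoint) rows in participants file: row(s) ",
         paste(which(dup_date), collapse = ", "))
  }

  problems <- character()
  check_range <- function(x, lo, hi, what) {
    bad <- which(!is.na(x) & (x < lo | x > hi))
    if (length(bad)) {
      problems <<- c(problems, paste0(what, " out of range [", lo, ",", hi,
                                      "] in row(s) ",
                                      paste(bad, collapse = ", ")))
    }
  }
  if ("pdds" %in% names(parts)) check_range(parts$pdds, 0, 8, "pdds")
  if ("msrs_r" %in% names(parts)) check_range(parts$msrs_r, 0, 32, "msrs_r")
  if ("income_bracket" %in% names(parts)) {
    check_range(parts$income_bracket, 1, codebook$income_n_brackets,
                "income_bracket")
  }
  if (all(c("group", "disease_duration") %in% names(parts))) {
    bad <- which(parts$group != "pwms" & !is.na(parts$disease_duration))
    if (length(bad)) {
      problems <- c(problems,
                    paste0("disease_duration present for non-pwMS row(s) ",
                           paste(bad, collapse = ", ")))
    }
  }
  if (length(problems)) {
    msg <- paste0("participants file failed validation:\n  ",
                  paste(problems, collapse = "\n  "))
    if (strict) stop(msg) else warning(msg)
  }

  ak <- key(alters)
  tk <- key(ties)
  networks <- vector("list", nrow(parts))
  for (i in seq_len(nrow(parts))) {
    a <- alters[ak == pk[i], , drop = FALSE]
    if (nrow(a) > codebook$max_alters) {
      warning("participant ", parts$participant_id[i], " (", parts$timepoint[i],
              ") reports ", nrow(a), " alters (more than ",
              codebook$max_alters, ")")
    }
    tw <- ties[tk == pk[i], , drop = FALSE]
    m <- matrix(FALSE, nrow(a), nrow(a),
                dimnames = list(a$alter_id, a$alter_id))
    if (nrow(tw)) {
      unknown <- !(tw$alter_id_1 %in% a$alter_id) |
        !(tw$alter_id_2 %in% a$alter_id)
      if (any(unknown)) {
        stop("ties file references unknown alter(s) for participant ",
             parts$participant_id[i], ": row(s) ",
             paste(which(tk == pk[i])[unknown], collapse = ", "))
      }
      # contradictory duplicate/mirror rows are a symmetry violation
      pair <- paste(pmin(tw$alter_id_1, tw$alter_id_2),
                    pmax(tw$alter_id_1, tw$alter_id_2), sep = "~")
      agg <- tapply(tw$connected, pair, function(v) length(unique(v)))
      if (any(agg > 1)) {
        stop("asymmetric tie report for participant ",
             parts$participant_id[i], ", pair(s): ",
             paste(gsub("~", ",", names(agg)[agg > 1]), collapse = "; "))
      }
      on <- tw[tw$connected, , drop = FALSE]
      m[cbind(on$alter_id_1, on$alter_id_2)] <- TRUE
      m[cbind(on$alter_id_2, on$alter_id_1)] <- TRUE
    }
    networks[[i]] <- ego_network(parts$participant_id[i], parts$timepoint[i],
                                 a[setdiff(names(a), c("participant_id",
                                                       "timepoint"))], m)
  }
  parts$network <- networks
  new_persnet_cohort(parts, codebook)
}

new_persnet_cohort <- function(participants, codebook,
                               class = "persnet_cohort") {
  structure(list(participants = tibble::as_tibble(participants),
                 codebook = codebook),
            class = class)
}

#' @export
print.persnet_cohort <- function(x, ...) {
  p <- x$participants
  cat(sprintf("<persnet_cohort> %d records (%d participants)\n",
              nrow(p), dplyr::n_distinct(p$participant_id)))
  tab <- table(p$group, p$timepoint)
  print(tab)
  invisible(x)
}

#' Write a cohort back to the three-file CSV dialect
#'
#' Inverse of [read_cohort()]: emits `participants.csv`, `alters.csv` and
#' `ties.csv` (one row per present alter-alter tie, each pair once) into
#' `dir`.  Reading the files back reproduces the cohort field for field.
#'
#' @param cohort A `persnet_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- cohort$participants
  nets <- p$network
  readr::write_csv(p[setdiff(names(p), c("network", "truth"))],
                   file.path(dir, "participants.csv"))
  alters <- purrr::map_dfr(nets, function(net) {
    if (nrow(net$alters) == 0) return(NULL)
    tibble::tibble(participant_id = net$participant_id,
                   timepoint = net$timepoint, net$alters)
  })
  ties <- purrr::map_dfr(nets, function(net) {
    idx <- which(net$ties & upper.tri(net$ties), arr.ind = TRUE)
    if (nrow(idx) == 0) return(NULL)
    tibble::tibble(participant_id = net$participant_id,
                   timepoint = net$timepoint,
                   alter_id_1 = net$alters$alter_id[idx[, 1]],
                   alter_id_2 = net$alters$alter_id[idx[, 2]],
                   connected = TRUE)
  })
  if (nrow(alters) == 0) {
    alters <- tibble::tibble(participant_id = character(),
                             timepoint = character(), alter_id = character())
  }
  if (nrow(ties) == 0) {
    ties <- tibble::tibble(participant_id = character(),
                           timepoint = character(), alter_id_1 = character(),
                           alter_id_2 = character(), connected = logical())
  }
  readr::write_csv(alters, file.path(dir, "alters.csv"))
  readr::write_csv(ties, file.path(dir, "ties.csv"))
  invisible(dir)
}

#' Dichotomize race and ethnicity
#'
#' Collapses the race and ethnicity codebook categories into the two-level
#' covariate used throughout the analyses: `"non_hispanic_white"` when the
#' participant is both non-Hispanic and White, `"other"` in every other
#' case (including "not sure" responses, which cannot confirm either
#' condition).  Vectorized; a missing race or ethnicity yields `NA`.
#'
#' @param race,ethnicity Character vectors of codebook categories.
#' @return Character vector with levels `"non_hispanic_white"`/`"other"`.
#' @export
#' @examples
#' dichotomize_race_ethnicity(c("white", "white", "asian"),
#'                            c("non_hispanic", "hispanic", "non_hispanic"))
dichotomize_race_ethnicity <- function(race, ethnicity) {
  out <- ifelse(race == "white" & ethnicity == "non_hispanic",
                "non_hispanic_white", "other")
  out[is.na(race) | is.na(ethnicity)] <- NA_character_
  out
}

#' Encode covariates as numeric analysis columns
#'
#' Adds the numeric encodings used by covariate screening and the
#' regression models, chosen so each candidate has a single monotone score
#' (and hence a single Pearson correlation): `employment_bin` — 1 for
#' employed for wages or self-employed, 0 otherwise; `income_bracket` —
#' ordinal 1-9 (kept as is); `education_ord` — ordinal 1-6 over the
#' codebook education levels; `married_bin`, `lives_alone_bin`,
#' `sex_woman` — 0/1; `nhw` — 1 for non-Hispanic White (see
#' [dichotomize_race_ethnicity()]).
#'
#' @param participants Participant tibble (as in a `persnet_cohort`).
#' @param codebook Codebook list.
#' @return The tibble with encoded columns added.
#' @export
encode_covariates <- function(participants, codebook = persnet_codebook()) {
  p <- participants
  as01 <- function(x) as.numeric(as.logical(x))
  if ("employment" %in% names(p)) {
    p$employment_bin <- ifelse(is.na(p$employment), NA_real_,
                               as.numeric(p$employment %in%
                                            codebook$employment_employed))
  }
  if ("education" %in% names(p)) {
    p$education_ord <- as.numeric(match(p$education, codebook$education_levels))
  }
  if ("married" %in% names(p)) p$married_bin <- as01(p$married)
  if ("lives_alone" %in% names(p)) p$lives_alone_bin <- as01(p$lives_alone)
  if ("sex" %in% names(p)) {
    p$sex_woman <- ifelse(is.na(p$sex), NA_real_,
                          as.numeric(p$sex == "woman"))
  }
  if (all(c("race", "ethnicity") %in% names(p))) {
    p$nhw <- as.numeric(dichotomize_race_ethnicity(p$race, p$ethnicity) ==
                          "non_hispanic_white")
  }
  p
}

#' Screen candidate covariates against the three outcomes
#'
#' Applies the predefined univariate selection rule: a candidate covariate
#' is retained iff it is present (non-missing) in more than
#' `presence_min` of the pwMS records, and has absolute Pearson
#' correlation of at least `r_min` with nominal significance
#' (`p < p_max`) against *all three* patient-reported outcomes.  The
#' report lists every candidate with its presence fraction and per-outcome
#' correlation and p-value; a constant candidate (undefined correlation)
#' is excluded and flagged.
#'
#' @param data Tibble of pwMS records with numerically encoded candidate
#'   columns (see [encode_covariates()]) and the outcome columns.
#' @param candidates Character vector of candidate column names.
#' @param outcomes Character vector of outcome column names (default the
#'   three PROs).
#' @param presence_min,r_min,p_max Selection thresholds (defaults 0.70,
#'   0.1, 0.05).
#' @return A tibble with one row per candidate: `covariate`, `presence`,
#'   `r_<outcome>` and `p_<outcome>` columns, `constant`, `selected`.
#' @export
screen_covariates <- function(data, candidates,
                              outcomes = c("pdds", "msrs_r", "promis_pf"),
                              presence_min = 0.70, r_min = 0.1,
                              p_max = 0.05) {
  stopifnot(all(outcomes %in% names(data)))
  rows <- purrr::map(candidates, function(cand) {
    x <- data[[cand]]
    if (is.null(x)) stop("candidate covariate not found: ", cand)
    presence <- mean(!is.na(x))
    sx <- suppressWarnings(sd(x, na.rm = TRUE))
    constant <- is.na(sx) || sx == 0
    stats <- purrr::map(outcomes, function(oc) {
      y <- data[[oc]]
      ok <- !is.na(x) & !is.na(y)
      if (constant || sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
        return(c(r = NA_real_, p = NA_real_))
      }
      ct <- cor.test(x[ok], y[ok])
      c(r = unname(ct$estimate), p = ct$p.value)
    })
    st <- unlist(stats)
    names(st) <- paste0(rep(c("r_", "p_"), times = length(outcomes)),
                        rep(outcomes, each = 2))
    rs <- st[paste0("r_", outcomes)]
    ps <- st[paste0("p_", outcomes)]
    selected <- presence > presence_min && !anyNA(rs) &&
      all(abs(rs) >= r_min) && all(ps < p_max)
    tibble::tibble(covariate = cand, presence = presence,
                   constant = constant, !!!as.list(st), selected = selected)
  })
  dplyr::bind_rows(rows)
}

#' Link prepandemic and pandemic records into a longitudinal subset
#'
#' For each participant with records at both timepoints, pairs the
#' pandemic record with the *most proximal* prepandemic record (the
#' latest assessment strictly before the pandemic assessment, when
#' assessment dates are available; with several prepandemic rows and no
#' dates the last one is used).  Participants lacking either timepoint
#' are excluded and counted.  `elapsed_years` between the paired
#' assessments is computed as days/365.25 rounded to 2 decimals when
#' dates are present.
#'
#' @param cohort A `persnet_cohort`.
#' @return A `persnet_cohort` restricted to the paired records, with
#'   `elapsed_years` filled in on the pandemic rows and an
#'   `n_excluded` attribute giving the number of dropped participants.
#' @export
link_timepoints <- function(cohort) {
  p <- cohort$participants
  has_date <- "assessment_date" %in% names(p)
  if (has_date) p$assessment_date <- as.Date(p$assessment_date)
  keep <- list()
  excluded <- 0L
  for (pid in unique(p$participant_id)) {
    rows <- p[p$participant_id == pid, , drop = FALSE]
    pre <- rows[rows$timepoint == "prepandemic", , drop = FALSE]
    pan <- rows[rows$timepoint == "pandemic", , drop = FALSE]
    if (nrow(pre) == 0 || nrow(pan) == 0) {
      excluded <- excluded + 1L
      next
    }
    pan <- pan[1, , drop = FALSE]
    if (has_date && !is.na(pan$assessment_date)) {
      eligible <- pre[!is.na(pre$assessment_date) &
                        pre$assessment_date < pan$assessment_date, ,
                      drop = FALSE]
      if (nrow(eligible) == 0) {
        stop("pandemic record predates every prepandemic baseline for participant ",
             pid)
      }
      base <- eligible[which.max(as.numeric(eligible$assessment_date)), ,
                       drop = FALSE]
      pan$elapsed_years <- round(
        as.numeric(pan$assessment_date - base$assessment_date) / 365.25, 2)
    } else {
      base <- pre[nrow(pre), , drop = FALSE]
    }
    keep[[pid]] <- dplyr::bind_rows(base, pan)
  }
  if (excluded > 0) {
    message(excluded, " participant(s) lacking a timepoint excluded from the longitudinal subset")
  }
  out <- new_persnet_cohort(dplyr::bind_rows(keep), cohort$codebook)
  attr(out, "n_excluded") <- excluded
  out
}

#' Build the regression analysis frame for a cohort
#'
#' Joins the regression-scale features ([cohort_features()] passed through
#' [features_regression_scale()]) to the participant records with encoded
#' covariates ([encode_covariates()]), one row per (participant,
#' timepoint).  This is the input shape expected by
#' [feature_outcome_regression()], [moderation_analysis()] and the
#' longitudinal machinery.
#'
#' @param cohort A `persnet_cohort`.
#' @return A tibble with feature, covariate and outcome columns.
#' @export
analysis_frame <- function(cohort) {
  enc <- encode_covariates(cohort$participants, cohort$codebook)
  dplyr::left_join(
    features_regression_scale(cohort_features(cohort)),
    enc[setdiff(names(enc), c("group", "network"))],
    by = c("participant_id", "timepoint")
  )
}
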