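#' Egocentric network density
#'
#' Fraction of possible alter-alter ties that are present, excluding the
#' ego's own ties (which exist for every alter by construction and so are
#' uninformative): `t / (n(n-1)/2)` for `t` alter-alter ties among `n`
#' alters.
#'
#' @param net An `ego_network`.
#' @return A number in \[0, 1\]; `NA` for networks with fewer than two
#'   alters, where density is undefined (not zero).
#' @export
#' @examples
#' net <- ego_network("p", alters = data.frame(alter_id = 1:4),
#'                    ties = tie_matrix(4, list(c(1, 2), c(3, 4))))
#' ego_density(net) # 2 of 6 possible ties
ego_density <- function(net) {
  n <- network_size(net)
  if (n < 2) return(NA_real_)
  sum(net$ties) / 2 / (n * (n - 1) / 2)
}

#' Burt's aggregate constraint of the ego
#'
#' Constraint measures the extent to which the ego is invested in alters
#' who are themselves connected to one another; it is a more granular
#' companion to density.  For each alter `j`,
#' `c_j = (p_j + sum_q p_q q_{qj})^2`, where `p` are the ego's
#' proportional tie weights (equal across alters, `1/n`, since the ego is
#' tied to all of them) and `q_{qj}` is alter `q`'s proportional weight on
#' `j` (alter weights spread over the ego plus the alter's alter-alter
#' ties).  The aggregate `C = sum_j c_j` is reported on a 0-100 scale.
#'
#' A star (no alter-alter ties) gives `100/n`; a fully connected network
#' approaches the maximum; an ego with a single alter has constraint 100.
#'
#' @param net An `ego_network`.
#' @return Constraint times 100; `NA` for an empty network.
#' @export
#' @examples
#' star <- ego_network("p", alters = data.frame(alter_id = 1:4))
#' burt_constraint(star) # 25
burt_constraint <- function(net) {
  n <- network_size(net)
  if (n < 1) return(NA_real_)
  a <- net$ties * 1
  # proportional weights: ego spreads evenly over n alters; alter q spreads
  # over its degree in the ego-included graph (1 ego tie + alter ties)
  p_ego <- rep(1 / n, n)
  deg <- rowSums(a) + 1
  p_alter <- a / deg          # p_alter[q, j] = weight of q on j
  indirect <- as.vector(p_ego %*% p_alter)
  100 * sum((p_ego + indirect)^2)
}

#' Burt's effective size of the ego network
#'
#' The number of non-redundant network members: network size discounted
#' for redundancy among the alters.  With binary symmetric ties and the
#' ego tied to every alter this reduces to `n - 2t/n`, where `t` is the
#' number of alter-alter ties; a star retains all `n` alters while a fully
#' connected network collapses to effective size 1.
#'
#' @param net An `ego_network`.
#' @return Effective size (between 1 and `n` for non-empty networks);
#'   `NA` for an empty network.
#' @export
effective_size <- function(net) {
  n <- network_size(net)
  if (n < 1) return(NA_real_)
  n - sum(net$ties) / n
}

#' Maximum and mean alter degree
#'
#' Degrees are counted in the alter-alter graph, excluding the tie each
#' alter has to the ego (including it would add exactly 1 to every
#' degree).
#'
#' @param net An `ego_network`.
#' @return A named list with `max_degree` and `mean_degree`; both `NA` for
#'   an empty network.
#' @export
degree_stats <- function(net) {
  n <- network_size(net)
  if (n < 1) return(list(max_degree = NA_real_, mean_degree = NA_real_))
  deg <- rowSums(net$ties)
  list(max_degree = max(deg), mean_degree = mean(deg))
}

#' Normalized Blau diversity index
#'
#' Blau heterogeneity `1 - sum(p_k^2)` over the category proportions,
#' normalized by its maximum `1 - 1/K` for `K` possible categories and
#' reported on a 0-100 scale: 0 means a single represented category and
#' 100 an equal split across all `K`.  Missing values are excluded.
#'
#' @param values A vector of category labels (character or factor).
#' @param n_categories Number of possible categories `K` (e.g. 2 for sex;
#'   the codebook race levels for race).  Use `"observed"` to normalize by
#'   the number of distinct observed categories instead.
#' @return A score in \[0, 100\]; `NA` if no non-missing values.
#' @export
#' @examples
#' diversity_index(c("woman", "woman", "woman", "man"), 2) # 75
diversity_index <- function(values, n_categories) {
  values <- values[!is.na(values)]
  if (length(values) == 0) return(NA_real_)
  p <- table(values) / length(values)
  blau <- 1 - sum(p^2)
  k <- if (identical(n_categories, "observed")) length(p) else n_categories
  if (k < 2) return(0)
  min(100, 100 * blau / (1 - 1 / k))
}

# share (in percent) of alters with a TRUE flag, over the non-missing ones
pct_flag <- function(flag) {
  flag <- flag[!is.na(flag)]
  if (length(flag) == 0) return(NA_real_)
  100 * mean(flag)
}

#' Compositional percentages and age spread of an ego network
#'
#' Computes the nine percentage features and the standard deviation of
#' alter age.  Every percentage uses the alters with a non-missing value
#' for that attribute as its denominator; an attribute missing (or coded
#' unknown) for all alters yields `NA`.  Conventions:
#' `pct_weekly_or_less` counts alters contacted at weekly frequency or
#' more rarely (i.e. anything less often than daily); `pct_known_lt6y`
#' counts alters known for under 6 years; `sd_age` is the sample standard
#' deviation of alter ages and needs at least two non-missing ages.
#'
#' @param net An `ego_network`.
#' @param kin_codes Character vector of relationship codes counted as kin.
#' @return Named list with `pct_kin`, `sd_age`, `pct_weekly_or_less`,
#'   `pct_known_lt6y`, `pct_gt15mi`, `pct_drink`, `pct_smoke`,
#'   `pct_nonexerciser`, `pct_bad_diet`, `pct_negative_influence`.
#' @export
compositional_metrics <- function(net, kin_codes = persnet_codebook()$kin_codes) {
  a <- net$alters
  n <- nrow(a)
  get <- function(col) if (col %in% names(a)) a[[col]] else rep(NA, n)
  contact <- get("contact_freq")
  contact[contact == "unknown"] <- NA
  ages <- get("age")
  ages <- ages[!is.na(ages)]
  list(
    pct_kin = pct_flag(get("relationship") %in% kin_codes |
                         ifelse(is.na(get("relationship")), NA, FALSE)),
    sd_age = if (length(ages) >= 2) sd(ages) else NA_real_,
    pct_weekly_or_less = pct_flag(contact %in% c("weekly", "monthly", "less") |
                                    ifelse(is.na(contact), NA, FALSE)),
    pct_known_lt6y = pct_flag(get("years_known") < 6),
    pct_gt15mi = pct_flag(as.logical(get("distance_gt_15mi"))),
    pct_drink = pct_flag(as.logical(get("drinks"))),
    pct_smoke = pct_flag(as.logical(get("smokes"))),
    pct_nonexerciser = pct_flag(as.logical(get("nonexerciser"))),
    pct_bad_diet = pct_flag(as.logical(get("bad_diet"))),
    pct_negative_influence = pct_flag(as.logical(get("negative_influence")))
  )
}

#' Compute all 18 network features of an ego network
#'
#' Populates the full feature record: the 6 structural features (size,
#' density, constraint, effective size, maximum and mean degree) and the
#' 12 compositional features (percent kin, SD of age, sex and race
#' diversity, and the contact-frequency, duration, distance and
#' health-behavior percentages).  Undefined metrics (e.g. density of a
#' one-alter network) are returned as `NA` rather than zero.  Percentage
#' and diversity features are on the 0-100 scale used in descriptive
#' tables; see [features_regression_scale()] for the 0-1 regression scale.
#'
#' @param net An `ego_network`.
#' @param codebook A codebook list (see [persnet_codebook()]) supplying
#'   kin codes and race levels.
#' @return A one-row tibble with the 18 feature columns.
#' @export
#' @examples
#' star <- ego_network("p", alters = data.frame(
#'   alter_id = 1:4, relationship = c("spouse", "friend", "child", "friend")
#' ))
#' compute_features(star)[, c("size", "density", "effective_size", "pct_kin")]
compute_features <- function(net, codebook = persnet_codebook()) {
  v <- features_vector(net, codebook)
  tibble::tibble(participant_id = net$participant_id,
                 timepoint = net$timepoint, !!!as.list(v))
}

# numeric feature vector (the fast path behind compute_features and
# cohort_features; one allocation, no per-network tibbles)
features_vector <- function(net, codebook = persnet_codebook()) {
  n <- network_size(net)
  deg <- degree_stats(net)
  race_k <- if (identical(codebook$diversity_race_k, "observed")) "observed"
            else length(codebook$race_levels)
  a <- net$alters
  sex <- if ("sex" %in% names(a)) a$sex else rep(NA_character_, n)
  sex[!sex %in% c("man", "woman")] <- NA  # diversity of sex is over man/woman
  race <- if ("race" %in% names(a)) a$race else rep(NA_character_, n)
  out <- c(
    size = n,
    density = ego_density(net),
    constraint = if (n >= 1) burt_constraint(net) else NA_real_,
    effective_size = effective_size(net),
    max_degree = deg$max_degree,
    mean_degree = deg$mean_degree,
    diversity_sex = if (n >= 1) diversity_index(sex, 2) else NA_real_,
    diversity_race = if (n >= 1) diversity_index(race, race_k) else NA_real_,
    unlist(compositional_metrics(net, codebook$kin_codes))
  )
  out[PERSNET_FEATURES]
}

#' Compute network features for every network in a cohort
#'
#' @param cohort A `persnet_cohort` (see [read_cohort()] or
#'   [simulate_cohort()]).
#' @param codebook Codebook list; defaults to the cohort's own codebook if
#'   recorded, else [persnet_codebook()].
#' @return A tibble with one row per (participant, timepoint): identifier
#'   columns `participant_id`, `timepoint`, `group`, then the 18 features.
#' @export
cohort_features <- function(cohort, codebook = NULL) {
  codebook <- codebook %||% cohort$codebook %||% persnet_codebook()
  p <- cohort$participants
  mat <- vapply(p$network, features_vector,
                numeric(length(PERSNET_FEATURES)), codebook = codebook)
  out <- tibble::as_tibble(t(mat))
  names(out) <- PERSNET_FEATURES
  dplyr::bind_cols(
    tibble::tibble(participant_id = p$participant_id,
                   timepoint = p$timepoint, group = p$group),
    out
  )
}

#' Rescale features for regression
#'
#' Descriptive tables report percentage and diversity features on a 0-100
#' scale; regression models consume them as 0-1 proportions so that a
#' coefficient measures the outcome change for a 0-to-1 sweep of the
#' feature.  Size, degrees, density (already 0-1) and constraint (0-100)
#' keep their native scales.
#'
#' @param features A feature tibble from [cohort_features()].
#' @return The tibble with percentage/diversity columns divided by 100.
#' @export
features_regression_scale <- function(features) {
  cols <- intersect(PERSNET_PERCENT_FEATURES, names(features))
  features[cols] <- features[cols] / 100
  features
}

# feature tibble for a bare list of networks (internal fast path)
nets_feature_tbl <- function(nets, codebook = persnet_codebook()) {
  mat <- vapply(nets, features_vector, numeric(length(PERSNET_FEATURES)),
                codebook = codebook)
  out <- tibble::as_tibble(t(mat))
  names(out) <- PERSNET_FEATURES
  out
}
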