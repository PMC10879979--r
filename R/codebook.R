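#' Default survey codebook
#'
#' The codebook names the category labels used in PERSNET-style exports and
#' the mappings the pipeline needs: which relationship codes count as kin,
#' which employment codes count as "employed" for the binary covariate
#' encoding, and the closed category lists used to normalize the diversity
#' indices.
#'
#' Survey instruments do not define which relationships are "kin"; the set
#' below (spouse/partner, parents, children, siblings, in-laws, other
#' family) is the conventional family roster and can be overridden via a
#' YAML codebook file (see [read_codebook()]).
#'
#' @return A named list with elements `relationship_levels`, `kin_codes`,
#'   `sex_levels`, `race_levels`, `ethnicity_levels`, `contact_levels`,
#'   `employment_levels`, `employment_employed`, `education_levels`,
#'   `income_n_brackets`, `diversity_race_k` (`"codebook"` or `"observed"`),
#'   and `max_alters`.
#' @export
#' @examples
#' persnet_codebook()$kin_codes
persnet_codebook <- function() {
  list(
    relationship_levels = c(
      "spouse", "partner", "parent", "child", "sibling", "in_law",
      "other_family", "friend", "coworker", "neighbor", "professional",
      "other"
    ),
    kin_codes = c("spouse", "partner", "parent", "child", "sibling",
                  "in_law", "other_family"),
    sex_levels = c("man", "woman", "other_unknown"),
    race_levels = c("african_american", "native_hawaiian_pacific_islander",
                    "asian", "white", "multiracial", "other"),
    ethnicity_levels = c("hispanic", "non_hispanic", "not_sure"),
    contact_levels = c("daily", "weekly", "monthly", "less", "unknown"),
    employment_levels = c(
      "employed_for_wages", "self_employed", "out_of_work_looking",
      "out_of_work_not_looking", "homemaker", "student", "military",
      "retired", "unable_to_work"
    ),
    employment_employed = c("employed_for_wages", "self_employed"),
    education_levels = c(
      "some_high_school", "high_school_graduate", "some_college",
      "associate_degree", "bachelors_degree", "graduate_degree"
    ),
    income_n_brackets = 9L,
    diversity_race_k = "codebook",
    max_alters = 25L
  )
}

#' Read a codebook from a YAML file
#'
#' Reads category labels, kin codes and other codebook entries from a YAML
#' key-value file and merges them over the defaults from
#' [persnet_codebook()], so a partial file overriding only `kin_codes` is
#' valid.
#'
#' @param path Path to a YAML file.
#' @return A codebook list as in [persnet_codebook()].
#' @export
read_codebook <- function(path) {
  user <- yaml::read_yaml(path)
  cb <- utils::modifyList(persnet_codebook(), user)
  stopifnot(all(cb$kin_codes %in% cb$relationship_levels))
  cb$diversity_race_k <- match.arg(cb$diversity_race_k,
                                   c("codebook", "observed"))
  cb
}
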