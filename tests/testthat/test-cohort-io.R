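# fixture writer: a small hand-specified three-file export
write_fixture <- function(dir, ties_extra = NULL, participants_extra = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  participants <- c(
    "participant_id,timepoint,assessment_date,group,cohort_id,age,sex,race,ethnicity,disease_duration,employment,education,income_bracket,married,lives_alone,pdds,msrs_r,promis_pf",
    "p1,pandemic,2020-05-02,pwms,c1,51.5,woman,white,non_hispanic,12,employed_for_wages,bachelors_degree,6,TRUE,FALSE,2,9,44.1",
    "p2,pandemic,2020-06-11,control,c1,44,man,white,non_hispanic,,retired,graduate_degree,,FALSE,TRUE,,,57.3",
    participants_extra
  )
  alters <- c(
    "participant_id,timepoint,alter_id,relationship,age,sex,race,contact_freq,years_known,distance_gt_15mi,drinks,smokes,nonexerciser,bad_diet,negative_influence",
    "p1,pandemic,a,spouse,50,man,white,daily,25,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE",
    "p1,pandemic,b,friend,48,woman,white,weekly,4,TRUE,TRUE,FALSE,FALSE,TRUE,TRUE",
    "p1,pandemic,c,parent,78,woman,white,daily,51,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE",
    "p2,pandemic,a,friend,40,man,asian,monthly,2,TRUE,FALSE,TRUE,FALSE,FALSE,TRUE",
    "p2,pandemic,b,sibling,47,woman,white,weekly,47,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE"
  )
  ties <- c(
    "participant_id,timepoint,alter_id_1,alter_id_2,connected",
    "p1,pandemic,a,b,TRUE",
    "p1,pandemic,a,c,TRUE",
    ties_extra
  )
  writeLines(participants, file.path(dir, "participants.csv"))
  writeLines(alters, file.path(dir, "alters.csv"))
  writeLines(ties, file.path(dir, "ties.csv"))
  dir
}

read_fixture <- function(dir) {
  read_cohort(file.path(dir, "participants.csv"),
              file.path(dir, "alters.csv"),
              file.path(dir, "ties.csv"))
}

test_that("a hand-written export round-trips field for field", {
  dir <- write_fixture(withr::local_tempdir())
  cohort <- read_fixture(dir)
  expect_s3_class(cohort, "persnet_cohort")
  expect_equal(nrow(cohort$participants), 2)
  net1 <- cohort$participants$network[[1]]
  expect_equal(network_size(net1), 3)
  expect_equal(sum(net1$ties) / 2, 2)
  # missing income retained as missing, row kept
  expect_true(is.na(cohort$participants$income_bracket[2]))

  out <- withr::local_tempdir()
  write_cohort(cohort, out)
  back <- read_cohort(file.path(out, "participants.csv"),
                      file.path(out, "alters.csv"),
                      file.path(out, "ties.csv"))
  expect_equal(back$participants$age, cohort$participants$age)
  expect_equal(back$participants$network[[1]]$ties,
               cohort$participants$network[[1]]$ties)
  expect_equal(back$participants$network[[2]]$alters,
               cohort$participants$network[[2]]$alters)
})

test_that("contradictory tie reports raise a symmetry error naming the pair", {
  dir <- write_fixture(withr::local_tempdir(),
                       ties_extra = "p1,pandemic,b,a,FALSE")
  expect_error(read_fixture(dir), "asymmetric.*a,b|asymmetric.*b,a")
})

test_that("malformed headers and unknown alters are format errors", {
  dir <- write_fixture(withr::local_tempdir())
  bad <- file.path(dir, "bad.csv")
  writeLines(c("pid,tp", "p1,pandemic"), bad)
  expect_error(read_cohort(bad, file.path(dir, "alters.csv"),
                           file.path(dir, "ties.csv")),
               "malformed header")
  dir2 <- write_fixture(withr::local_tempdir(),
                        ties_extra = "p1,pandemic,a,zz,TRUE")
  expect_error(read_fixture(dir2), "unknown alter")
})

test_that("out-of-range outcomes are reported with row numbers", {
  dir <- write_fixture(
    withr::local_tempdir(),
    participants_extra = "p3,pandemic,2020-07-01,pwms,c1,60,man,white,non_hispanic,5,retired,some_college,2,TRUE,FALSE,11,4,50")
  expect_error(read_fixture(dir), "pdds out of range.*row\\(s\\) 3")
})

test_that("race/ethnicity dichotomization partitions the codebook", {
  expect_equal(dichotomize_race_ethnicity("white", "non_hispanic"),
               "non_hispanic_white")
  expect_equal(dichotomize_race_ethnicity("white", "hispanic"), "other")
  expect_equal(dichotomize_race_ethnicity("asian", "non_hispanic"), "other")
  expect_equal(dichotomize_race_ethnicity("white", "not_sure"), "other")
  # exhaustive over the codebook: every combination maps to exactly one level
  cb <- persnet_codebook()
  grid <- expand.grid(race = cb$race_levels, ethnicity = cb$ethnicity_levels,
                      stringsAsFactors = FALSE)
  out <- dichotomize_race_ethnicity(grid$race, grid$ethnicity)
  expect_true(all(out %in% c("non_hispanic_white", "other")))
  expect_equal(sum(out == "non_hispanic_white"), 1)
})

test_that("covariate screening applies the presence/correlation/significance rule", {
  set.seed(21)
  n <- 600
  age <- rnorm(n, 50, 12)
  noise <- function(sd) rnorm(n, 0, sd)
  # age drives all 3 outcomes (r ~ 0.3)
  d <- tibble::tibble(
    age = age,
    sparse = ifelse(seq_len(n) <= 0.6 * n, rnorm(n), NA), # presence 0.60
    msrs_only = NA_real_,
    const = 1,
    pdds = 0.05 * age + noise(2),
    msrs_r = 0.14 * age + noise(5),
    promis_pf = -0.27 * age + noise(10)
  )
  d$sparse <- 0.5 * d$pdds + 0.5 * d$msrs_r + 0.3 * d$promis_pf +
    ifelse(is.na(d$sparse), NA, 0) # strongly associated but 60% present
  d$msrs_only <- d$msrs_r + rnorm(n, 0, 0.01)  # tracks one outcome only
  scr <- screen_covariates(d, c("age", "sparse", "msrs_only", "const"))
  scr <- tibble::column_to_rownames(scr, "covariate")
  expect_true(scr["age", "selected"])
  expect_false(scr["sparse", "selected"])     # fails the >70% presence rule
  expect_false(scr["msrs_only", "selected"])  # must pass all 3 outcomes
  expect_true(scr["const", "constant"])
  expect_false(scr["const", "selected"])
  # report carries the statistics for every candidate
  expect_equal(scr["sparse", "presence"], 0.6)
  expect_gt(abs(scr["age", "r_msrs_r"]), 0.25)
  # verify r against direct computation
  expect_equal(scr["age", "r_promis_pf"], cor(d$age, d$promis_pf))
})

test_that("screening is invariant to row order and affine rescaling", {
  set.seed(22)
  n <- 200
  d <- tibble::tibble(x = rnorm(n))
  d$pdds <- 0.5 * d$x + rnorm(n)
  d$msrs_r <- 0.5 * d$x + rnorm(n)
  d$promis_pf <- -0.5 * d$x + rnorm(n)
  base <- screen_covariates(d, "x")
  shuf <- screen_covariates(d[sample(n), ], "x")
  expect_equal(shuf, base)
  d2 <- dplyr::mutate(d, x = 100 - 7 * x)
  resc <- screen_covariates(d2, "x")
  expect_equal(abs(resc$r_pdds), abs(base$r_pdds), tolerance = 1e-12)
  expect_equal(resc$p_msrs_r, base$p_msrs_r, tolerance = 1e-12)
  expect_equal(resc$selected, base$selected)
})

test_that("timepoint linking picks the most proximal prepandemic baseline", {
  mk_part <- function(id, tp, date) {
    list(id = id, timepoint = tp, alters = data.frame(alter_id = 1:2),
         fields = list(assessment_date = date))
  }
  cohort <- toy_cohort(list(
    mk_part("p1", "prepandemic", "2017-03-01"),
    mk_part("p1", "prepandemic", "2019-05-01"),
    mk_part("p1", "pandemic", "2020-06-01"),
    mk_part("p2", "pandemic", "2020-04-01"),     # no baseline -> excluded
    mk_part("p3", "prepandemic", "2018-01-01"),
    mk_part("p3", "pandemic", "2020-03-15"),
    mk_part("p4", "prepandemic", "2019-01-01"),  # no pandemic -> excluded
    mk_part("p5", "prepandemic", "2018-06-01"),
    mk_part("p5", "pandemic", "2020-08-01")
  ))
  expect_message(linked <- link_timepoints(cohort), "2 participant")
  expect_equal(attr(linked, "n_excluded"), 2)
  p <- linked$participants
  expect_equal(sort(unique(p$participant_id)), c("p1", "p3", "p5"))
  p1 <- p[p$participant_id == "p1", ]
  expect_equal(as.character(p1$assessment_date[p1$timepoint == "prepandemic"]),
               "2019-05-01")
  expect_equal(p1$elapsed_years[p1$timepoint == "pandemic"], round(397 / 365.25, 2))
  # elapsed years within the 1-4 year design window
  ey <- p$elapsed_years[p$timepoint == "pandemic"]
  expect_true(all(ey >= 1 & ey <= 4))
})

test_that("a pandemic record predating every baseline is an ordering error", {
  cohort <- toy_cohort(list(
    list(id = "p1", timepoint = "prepandemic",
         alters = data.frame(alter_id = 1),
         fields = list(assessment_date = "2021-01-01")),
    list(id = "p1", timepoint = "pandemic",
         alters = data.frame(alter_id = 1),
         fields = list(assessment_date = "2020-06-01"))
  ))
  expect_error(link_timepoints(cohort), "predates")
})

test_that("covariate encoding yields monotone numeric scores", {
  p <- tibble::tibble(
    employment = c("employed_for_wages", "self_employed", "retired", NA),
    education = c("some_college", "graduate_degree", "high_school_graduate",
                  NA),
    married = c(TRUE, FALSE, TRUE, NA),
    lives_alone = c(FALSE, FALSE, TRUE, NA),
    sex = c("woman", "man", "woman", NA),
    race = c("white", "white", "asian", "white"),
    ethnicity = c("non_hispanic", "hispanic", "non_hispanic", "non_hispanic")
  )
  enc <- encode_covariates(p)
  expect_equal(enc$employment_bin, c(1, 1, 0, NA))
  expect_equal(enc$education_ord, c(3, 6, 2, NA))
  expect_equal(enc$married_bin, c(1, 0, 1, NA))
  expect_equal(enc$sex_woman, c(1, 0, 1, NA))
  expect_equal(enc$nhw, c(1, 0, 0, 1))
})

test_that("codebook YAML overrides merge over the defaults", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("kin_codes:\n  - spouse\n  - parent\n", path)
  cb <- read_codebook(path)
  expect_equal(cb$kin_codes, c("spouse", "parent"))
  expect_equal(cb$max_alters, persnet_codebook()$max_alters)
})

test_that("graphml export writes ego plus alter vertices", {
  net <- ego_network("p", alters = data.frame(alter_id = c("a", "b")),
                     ties = tie_matrix(2, list(c(1, 2))))
  path <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(net, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 3)  # 2 ego spokes + 1 alter-alter tie
})
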