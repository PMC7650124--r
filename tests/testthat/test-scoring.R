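# Life-stage score arithmetic, validation and imputation.

childhood_space <- function() {
  expand.grid(
    father_occupation = LC_LEVELS$father_occupation,
    mother_occupation = LC_LEVELS$mother_occupation,
    family_structure = LC_LEVELS$family_structure,
    n_siblings = c(0L, 3L, 4L), # binarised at > 3
    rooms_per_person = LC_LEVELS$rooms_per_person,
    toilet_in_house = c(TRUE, FALSE), parental_car = c(TRUE, FALSE),
    income_upper_half = c(TRUE, FALSE), paternal_unemployment = c(FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

# Independent per-item point lookup (the additivity oracle): maps each item
# value to points without touching the scoring implementation.
oracle_childhood_points <- function(g) {
  pt <- function(values, table) unname(table[as.character(values)])
  pt(g$father_occupation, c(academic = 0, white_collar = 1, blue_or_unskilled = 2)) +
    pt(g$mother_occupation, c(white_collar_or_academic_or_housewife = 0,
                              blue_or_unskilled = 1)) +
    pt(g$family_structure, c(both_parents = 0, one_parent = 1, no_parents = 2)) +
    ifelse(g$n_siblings > 3, 1, 0) +
    pt(g$rooms_per_person, c(gt1 = 0, half_to_1 = 1, lt_half = 2)) +
    ifelse(g$toilet_in_house, 0, 1) + ifelse(g$parental_car, 0, 1) +
    ifelse(g$income_upper_half, 0, 1) + ifelse(g$paternal_unemployment, 1, 0)
}

test_that("childhood score: worked examples, exhaustive range and additivity", {
  expect_identical(score_childhood(subject_row()), 0L)
  worst <- subject_row(father_occupation = "blue_or_unskilled",
                       mother_occupation = "blue_or_unskilled",
                       family_structure = "no_parents", n_siblings = 5L,
                       rooms_per_person = "lt_half", toilet_in_house = 0L,
                       parental_car = 0L, income_upper_half = 0L,
                       paternal_unemployment = 1L)
  expect_identical(score_childhood(worst), 12L)
  mid <- subject_row(father_occupation = "blue_or_unskilled",
                     family_structure = "one_parent", n_siblings = 2L,
                     rooms_per_person = "half_to_1", parental_car = 0L,
                     income_upper_half = 0L)
  expect_identical(score_childhood(mid), 6L)

  g <- childhood_space()
  s <- score_childhood(g)
  expect_identical(s, as.integer(oracle_childhood_points(g)))
  expect_identical(range(s), c(0L, 12L))
  expect_true(all(s %in% 0:12))
})

test_that("adolescence and adulthood scores: worked examples and exhaustive range", {
  expect_identical(score_adolescence(subject_row()), 0L)
  expect_identical(score_adolescence(
    subject_row(school_degree = "primary_school",
                professional_education = "unskilled_incl_housewife")), 8L)
  expect_identical(score_adolescence(
    subject_row(school_degree = "middle_school",
                professional_education = "skilled_worker")), 4L)

  g_adol <- expand.grid(school_degree = LC_LEVELS$school_degree,
                        professional_education = LC_LEVELS$professional_education,
                        stringsAsFactors = FALSE)
  expect_identical(range(score_adolescence(g_adol)), c(0L, 8L))

  expect_identical(score_adulthood(subject_row()), 0L)
  expect_identical(score_adulthood(
    subject_row(last_profession = "unskilled_incl_housewife",
                unemployment_gt6mo = 1L, partnered = 0L)), 8L)
  expect_identical(score_adulthood(
    subject_row(last_profession = "skilled_blue_collar",
                unemployment_gt6mo = 1L, partnered = 1L)), 4L)

  g_adult <- expand.grid(last_profession = LC_LEVELS$last_profession,
                         unemployment_gt6mo = c(0L, 1L), partnered = c(0L, 1L),
                         stringsAsFactors = FALSE)
  expect_identical(range(score_adulthood(g_adult)), c(0L, 8L))
})

test_that("worsening any single item never decreases a score (monotonicity)", {
  g <- childhood_space()
  s <- score_childhood(g)
  worsen <- list(
    father_occupation = LC_LEVELS$father_occupation,
    mother_occupation = LC_LEVELS$mother_occupation,
    family_structure = LC_LEVELS$family_structure,
    rooms_per_person = LC_LEVELS$rooms_per_person,
    toilet_in_house = c(TRUE, FALSE), parental_car = c(TRUE, FALSE),
    income_upper_half = c(TRUE, FALSE), paternal_unemployment = c(FALSE, TRUE),
    n_siblings = c(0L, 3L, 4L)
  )
  for (field in names(worsen)) {
    lev <- worsen[[field]]
    cur <- match(g[[field]], lev)
    can_worsen <- cur < length(lev)
    g2 <- g[can_worsen, , drop = FALSE]
    g2[[field]] <- lev[cur[can_worsen] + 1L]
    expect_true(all(score_childhood(g2) >= s[can_worsen]),
                info = sprintf("field %s", field))
  }
})

test_that("unknown enum levels raise validation errors naming the field", {
  expect_error(score_childhood(subject_row(father_occupation = "farmer")),
               "father_occupation")
  expect_error(score_adolescence(subject_row(school_degree = "phd")),
               "school_degree")
  expect_error(score_adulthood(subject_row(last_profession = "astronaut")),
               "last_profession")
  expect_error(score_childhood(subject_row(father_occupation = NA)),
               "father_occupation")
})

test_that("mode imputation: identity, cell mode, tie-break and hard errors", {
  base <- make_study(list(
    subject_row(status = "case", sex = "m", parental_car = 1L),
    subject_row(status = "control", sex = "m", parental_car = 0L),
    subject_row(status = "control", sex = "m", parental_car = 0L),
    subject_row(status = "control", sex = "m", parental_car = 0L),
    subject_row(status = "control", sex = "f", parental_car = 1L)
  ))
  # zero missing cells: identity
  out <- impute_items(base)
  expect_identical(out[names(base)], base)
  expect_true(all(attr(out, "imputation_log") == 0L))

  # missing parental_car in a control male; all other control males have 0
  withmiss <- base
  withmiss$parental_car[2] <- NA
  out <- impute_items(withmiss)
  expect_identical(out$parental_car[2], 0L)
  expect_identical(attr(out, "imputation_log")[["parental_car"]], 1L)

  # tie within the cell breaks to the lower-risk level (car present)
  tie <- base
  tie$parental_car[3] <- 1L
  tie$parental_car[2] <- NA
  expect_identical(impute_items(tie)$parental_car[2], 1L)

  # deterministic regardless of seed
  expect_identical(impute_items(withmiss, seed = 1L),
                   impute_items(withmiss, seed = 999L))

  # complete-case drops the incomplete row
  cc <- impute_items(withmiss, strategy = "complete_case")
  expect_identical(nrow(cc), nrow(base) - 1L)

  # missing matching variables are a hard error
  bad <- base
  bad$age_years[1] <- NA
  expect_error(impute_items(bad), "age_years")
})

test_that("validate_records reports rows and fields", {
  good <- make_study(list(subject_row(), subject_row(status = "case")))
  expect_identical(nrow(validate_records(good)), 0L)
  bad <- good
  bad$sex[2] <- "x"
  problems <- validate_records(bad)
  expect_identical(problems$row, 2L)
  expect_identical(problems$field, "sex")
  expect_error(validate_records(bad, stop_on_error = TRUE), "row 2")
  expect_error(validate_records(good[, -3]), "age_years")
})
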