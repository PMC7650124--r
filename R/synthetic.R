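# Synthetic frequency-matched case-control data with a latent life-course
# socioeconomic trajectory. A Gaussian-copula construction drives all
# questionnaire items: one standard-normal latent "SES risk" value per life
# stage (higher = more disadvantaged), an AR-style correlation between
# consecutive stages, and per-item latents that load on the stage value and
# are thresholded at configured marginal probabilities. Risk factors are
# Bernoulli with a logistic dependence on adult SES; case status follows a
# logistic model whose coefficients (per mobility category, per risk factor)
# are the simulation's ground truth.

# Default marginal distributions (advantaged level first), chosen once as
# plausible for the birth cohorts of a stroke study interviewing 18-80
# year-olds around 2010; see the methods vignette.
lc_default_marginals <- function() {
  list(
    father_occupation = c(0.10, 0.30, 0.60),
    mother_occupation = c(0.85, 0.15),
    family_structure = c(0.85, 0.13, 0.02),
    rooms_per_person = c(0.30, 0.50, 0.20),
    toilet_in_house = 0.15,        # P(disadvantaged level)
    parental_car = 0.45,
    income_upper_half = 0.50,
    paternal_unemployment = 0.15,
    school_degree = c(0.20, 0.35, 0.45),
    professional_education = c(0.12, 0.30, 0.40, 0.18),
    last_profession = c(0.13, 0.35, 0.30, 0.22),
    unemployment_gt6mo = 0.12,
    partnered = 0.30,
    siblings_lambda = 2.2          # Poisson mean for the sibling count
  )
}

lc_default_rf_prevalence <- function() {
  c(hypertension = 0.55, diabetes = 0.20, hypercholesterolemia = 0.40,
    atrial_fibrillation = 0.10, coronary_heart_disease = 0.12,
    peripheral_arterial_disease = 0.05, cardiac_failure = 0.05,
    low_teeth = 0.30, smoking = 0.25, high_alcohol = 0.10,
    low_dentist_visits = 0.30, low_physical_activity = 0.40,
    low_fruit = 0.35, low_vegetable = 0.30)
}

#' Simulation configuration
#'
#' The stated world of the generator: study sizes and age/sex structure
#' mirroring the motivating case-control study (466 cases, 807 controls, ages
#' 18--80, ~41% women, case ages normal 66.5/10.8 and control ages 66.9/10.5
#' truncated to the range), a latent socioeconomic trajectory with
#' stage-to-stage correlations, item thresholds reproducing plausible control
#' marginals, and true effect sizes (log odds ratios) for the mobility
#' categories and risk factors. All defaults are documented in the methods
#' vignette; effects default to null.
#'
#' @param seed integer seed; every random draw flows from it.
#' @param n_cases,n_controls study sizes.
#' @param n_population size of the source population the study is drawn from.
#' @param sex_ratio_f proportion female.
#' @param age_case,age_control `c(mean, sd)` of the per-status age normals,
#'   truncated to `age_range`.
#' @param age_range inclusive age bounds.
#' @param rho_child_adol,rho_adol_adult latent stage-to-stage correlations in
#'   `[0, 1)`.
#' @param item_loading loading of each item latent on its stage latent.
#' @param marginals named list of per-item marginal probabilities
#'   (advantaged level first; scalars are the probability of the
#'   disadvantaged level of a binary item).
#' @param log_or_mobility named list: for any of the six exposures, a
#'   `c(advancement = ., descent = .)` pair of true log odds ratios
#'   (reference `no_change`). Unlisted exposures are null.
#' @param log_or_risk_factors named vector of true log odds ratios for the 14
#'   risk factors; unlisted factors are null.
#' @param rf_prevalence baseline prevalence of each risk factor at average
#'   adult SES.
#' @param rf_ses_slope logit-scale slope of each risk factor on adult SES.
#' @param case_rate target expected proportion of cases in the source
#'   population (the intercept is solved to hit it).
#' @param miss_rate MCAR missingness rate applied to item and risk-factor
#'   cells of the emitted study.
#' @return list of class `lc_sim_config`.
#' @export
sim_config <- function(seed = 1L, n_cases = 466L, n_controls = 807L,
                       n_population = 20000L, sex_ratio_f = 0.41,
                       age_case = c(66.5, 10.8), age_control = c(66.9, 10.5),
                       age_range = c(18, 80),
                       rho_child_adol = 0.6, rho_adol_adult = 0.7,
                       item_loading = 0.75,
                       marginals = lc_default_marginals(),
                       log_or_mobility = list(),
                       log_or_risk_factors = c(),
                       rf_prevalence = lc_default_rf_prevalence(),
                       rf_ses_slope = 0.3,
                       case_rate = 0.08, miss_rate = 0) {
  stopifnot(rho_child_adol >= 0, rho_child_adol < 1,
            rho_adol_adult >= 0, rho_adol_adult < 1,
            item_loading >= 0, item_loading <= 1,
            case_rate > 0, case_rate < 1,
            miss_rate >= 0, miss_rate < 1,
            n_cases > 0, n_controls > 0, n_population > 0)
  bad <- setdiff(names(log_or_mobility), LC_EXPOSURES)
  if (length(bad)) stop(sprintf("unknown exposure(s): %s",
                                paste(bad, collapse = ", ")), call. = FALSE)
  bad <- setdiff(names(log_or_risk_factors), LC_RISK_FACTORS)
  if (length(bad)) stop(sprintf("unknown risk factor(s): %s",
                                paste(bad, collapse = ", ")), call. = FALSE)
  structure(list(
    seed = as.integer(seed), n_cases = as.integer(n_cases),
    n_controls = as.integer(n_controls),
    n_population = as.integer(n_population), sex_ratio_f = sex_ratio_f,
    age_case = age_case, age_control = age_control, age_range = age_range,
    rho_child_adol = rho_child_adol, rho_adol_adult = rho_adol_adult,
    item_loading = item_loading, marginals = marginals,
    log_or_mobility = log_or_mobility,
    log_or_risk_factors = log_or_risk_factors,
    rf_prevalence = rf_prevalence, rf_ses_slope = rf_ses_slope,
    case_rate = case_rate, miss_rate = miss_rate
  ), class = "lc_sim_config")
}

# item latent: loading * stage latent + sqrt(1 - loading^2) * noise
item_latent <- function(stage, loading) {
  loading * stage + sqrt(1 - loading^2) * rnorm(length(stage))
}

# ordered categorical item: cut the latent's normal percentile at cumulative
# marginal probabilities (advantaged first; higher latent = worse level)
draw_enum <- function(z, probs, levels) {
  u <- pnorm(z)
  idx <- findInterval(u, cumsum(probs[-length(probs)])) + 1L
  levels[idx]
}

# binary item: TRUE with probability p_dis on the disadvantaged side
draw_disadvantaged <- function(z, p_dis) z > qnorm(1 - p_dis)

rnorm_trunc <- function(n, mean, sd, range) {
  lo <- pnorm(range[1], mean, sd)
  hi <- pnorm(range[2], mean, sd)
  qnorm(lo + runif(n) * (hi - lo), mean, sd)
}

#' Draw a source population with latent socioeconomic trajectories
#'
#' Latent stage values follow `SES_child ~ N(0,1)`,
#' `SES_adol = rho1 * SES_child + sqrt(1-rho1^2) * e`,
#' `SES_adult = rho2 * SES_adol + sqrt(1-rho2^2) * e`. Every questionnaire
#' item derives from its stage latent through an item-specific latent
#' (loading `config$item_loading`) thresholded at the configured marginals;
#' the sibling count is a Poisson quantile transform of its item latent.
#' Risk factors are Bernoulli with logit `qlogis(prev) + slope * SES_adult`.
#' Deterministic given `config$seed`. Latent values are retained in columns
#' `ses_child`, `ses_adol`, `ses_adult` for oracle checks.
#'
#' @param config an [sim_config()].
#' @return data frame with item, risk-factor, sex and latent columns
#'   (no `status`/ages yet; see [assign_outcome()]).
#' @export
generate_population <- function(config) {
  set.seed(config$seed)
  n <- config$n_population
  rho1 <- config$rho_child_adol
  rho2 <- config$rho_adol_adult
  ses_child <- rnorm(n)
  ses_adol <- rho1 * ses_child + sqrt(1 - rho1^2) * rnorm(n)
  ses_adult <- rho2 * ses_adol + sqrt(1 - rho2^2) * rnorm(n)
  mg <- config$marginals
  lam <- config$item_loading

  pop <- data.frame(
    id = sprintf("P%05d", seq_len(n)),
    sex = ifelse(runif(n) < config$sex_ratio_f, "f", "m"),
    ses_child = ses_child, ses_adol = ses_adol, ses_adult = ses_adult,
    stringsAsFactors = FALSE
  )
  pop$father_occupation <- draw_enum(item_latent(ses_child, lam),
                                    mg$father_occupation,
                                    LC_LEVELS$father_occupation)
  pop$mother_occupation <- draw_enum(item_latent(ses_child, lam),
                                     mg$mother_occupation,
                                     LC_LEVELS$mother_occupation)
  pop$family_structure <- draw_enum(item_latent(ses_child, lam),
                                    mg$family_structure,
                                    LC_LEVELS$family_structure)
  pop$n_siblings <- qpois(pnorm(item_latent(ses_child, lam)),
                          mg$siblings_lambda)
  pop$rooms_per_person <- draw_enum(item_latent(ses_child, lam),
                                    mg$rooms_per_person,
                                    LC_LEVELS$rooms_per_person)
  # boolean childhood items (TRUE = advantaged level present)
  pop$toilet_in_house <- !draw_disadvantaged(item_latent(ses_child, lam),
                                             mg$toilet_in_house)
  pop$parental_car <- !draw_disadvantaged(item_latent(ses_child, lam),
                                          mg$parental_car)
  pop$income_upper_half <- !draw_disadvantaged(item_latent(ses_child, lam),
                                               mg$income_upper_half)
  pop$paternal_unemployment <- draw_disadvantaged(item_latent(ses_child, lam),
                                                  mg$paternal_unemployment)
  pop$school_degree <- draw_enum(item_latent(ses_adol, lam),
                                 mg$school_degree, LC_LEVELS$school_degree)
  pop$professional_education <- draw_enum(item_latent(ses_adol, lam),
                                          mg$professional_education,
                                          LC_LEVELS$professional_education)
  pop$last_profession <- draw_enum(item_latent(ses_adult, lam),
                                   mg$last_profession,
                                   LC_LEVELS$last_profession)
  pop$unemployment_gt6mo <- draw_disadvantaged(item_latent(ses_adult, lam),
                                               mg$unemployment_gt6mo)
  pop$partnered <- !draw_disadvantaged(item_latent(ses_adult, lam),
                                       mg$partnered)
  for (rf in LC_RISK_FACTORS) {
    p <- plogis(stats::qlogis(config$rf_prevalence[[rf]]) +
                  config$rf_ses_slope * ses_adult)
    pop[[rf]] <- rbinom(n, 1L, p)
  }
  pop
}

# linear predictor of the true disease model (without intercept)
true_linear_predictor <- function(pop, config) {
  eta <- numeric(nrow(pop))
  for (exposure in names(config$log_or_mobility)) {
    b <- config$log_or_mobility[[exposure]]
    mob <- pop[[exposure]]
    if (!is.null(b[["advancement"]]) && !is.na(b["advancement"])) {
      eta <- eta + b[["advancement"]] * (mob == "advancement")
    }
    if (!is.null(b[["descent"]]) && !is.na(b["descent"])) {
      eta <- eta + b[["descent"]] * (mob == "descent")
    }
  }
  for (rf in names(config$log_or_risk_factors)) {
    eta <- eta + config$log_or_risk_factors[[rf]] * pop[[rf]]
  }
  eta
}

#' Assign case status and ages to a population
#'
#' Scores the population, derives its own tertile strata and mobility
#' categories (everyone is a potential control at this point), and draws case
#' status from `P(case) = logistic(intercept + eta)`, where `eta` accumulates
#' the configured true log odds ratios for mobility categories (reference
#' `no_change`) and risk factors. The intercept is solved numerically so the
#' expected number of cases equals `case_rate * n_population`. Ages are then
#' drawn per status from the configured truncated normals.
#'
#' @param pop result of [generate_population()].
#' @param config the same [sim_config()].
#' @return `pop` with `status`, `age_years`, mobility and score columns, plus
#'   a `"truth"` attribute (intercept, expected case count, configured
#'   effects).
#' @export
assign_outcome <- function(pop, config) {
  pop <- add_mobility_population(pop)
  eta <- true_linear_predictor(pop, config)
  target <- config$case_rate * nrow(pop)
  intercept <- uniroot(function(a) sum(plogis(a + eta)) - target,
                       interval = c(-30, 30), tol = 1e-10)$root
  p <- plogis(intercept + eta)
  pop$status <- ifelse(runif(nrow(pop)) < p, "case", "control")
  n_case <- sum(pop$status == "case")
  pop$age_years <- numeric(nrow(pop))
  is_case <- pop$status == "case"
  pop$age_years[is_case] <- floor(rnorm_trunc(n_case, config$age_case[1],
                                              config$age_case[2],
                                              config$age_range))
  pop$age_years[!is_case] <- floor(rnorm_trunc(nrow(pop) - n_case,
                                               config$age_control[1],
                                               config$age_control[2],
                                               config$age_range))
  attr(pop, "truth") <- list(
    intercept = intercept, expected_cases = sum(p), target_cases = target,
    log_or_mobility = config$log_or_mobility,
    log_or_risk_factors = config$log_or_risk_factors
  )
  pop
}

# population-level mobility: tertiles from the whole (pre-outcome) population
add_mobility_population <- function(pop) {
  pop$score_child <- score_childhood(pop)
  pop$score_adol <- score_adolescence(pop)
  pop$score_adult <- score_adulthood(pop)
  status_save <- pop$status
  pop$status <- "control"
  pop <- add_mobility(pop)
  if (is.null(status_save)) pop$status <- NULL else pop$status <- status_save
  pop
}

#' Sample a frequency-matched study from an outcome-assigned population
#'
#' Draws `n_cases` cases at random, then allocates the `n_controls` controls
#' across the 2-year-age x sex cells proportionally to the sampled cases'
#' cell distribution (largest-remainder rounding), reproducing frequency
#' matching. Controls are taken from the population's control pool within
#' each cell; when a sparse cell (a case in an extreme age band) holds fewer
#' controls than its quota, the shortfall is filled with randomly drawn
#' unused controls of the required sex whose age is redrawn uniformly within
#' the band -- age is independent of every other attribute in the generating
#' model, so this is distributionally identical to conditional sampling and
#' keeps the matcher well defined in the tails. A cell whose sex pool is
#' exhausted raises an error naming the cell. Optionally knocks out
#' item/risk-factor cells completely at random at `config$miss_rate`. The
#' output follows [LC_SCHEMA].
#'
#' @param pop result of [assign_outcome()].
#' @param config the same [sim_config()].
#' @return study data frame (schema columns only) with the population
#'   `"truth"` attribute carried over.
#' @export
sample_matched_study <- function(pop, config) {
  cases_pool <- which(pop$status == "case")
  if (length(cases_pool) < config$n_cases) {
    stop(sprintf("population yielded %d cases; %d requested",
                 length(cases_pool), config$n_cases), call. = FALSE)
  }
  case_rows <- sample(cases_pool, config$n_cases)
  band <- function(rows) {
    sprintf("%d:%s", pmin(floor((pop$age_years[rows] - 18) / 2), 30L),
            pop$sex[rows])
  }
  case_cells <- table(band(case_rows))
  # largest-remainder allocation of n_controls proportional to case cells
  quota <- config$n_controls * as.numeric(case_cells) / config$n_cases
  alloc <- floor(quota)
  rem <- config$n_controls - sum(alloc)
  if (rem > 0) {
    order_rem <- order(quota - alloc, decreasing = TRUE)
    alloc[order_rem[seq_len(rem)]] <- alloc[order_rem[seq_len(rem)]] + 1L
  }
  names(alloc) <- names(case_cells)

  ctrl_pool <- which(pop$status == "control")
  ctrl_cell <- band(ctrl_pool)
  used <- logical(length(ctrl_pool))
  control_rows <- integer(0)
  new_age <- integer(0)
  for (cell in names(alloc)) {
    need <- alloc[[cell]]
    in_cell <- which(ctrl_cell == cell & !used)
    take <- in_cell[sample.int(length(in_cell), min(need, length(in_cell)))]
    short <- need - length(take)
    if (short > 0) {
      # sparse tail cell: top up with unused same-sex controls, re-aged into
      # the band (age is independent of all other attributes by construction)
      parts <- strsplit(cell, ":", fixed = TRUE)[[1]]
      b <- as.integer(parts[1])
      spare <- which(!used & pop$sex[ctrl_pool] == parts[2])
      spare <- setdiff(spare, take)
      if (length(spare) < short) {
        stop(sprintf("cannot fill matching cell '%s': need %d controls, have %d",
                     cell, need, length(take) + length(spare)), call. = FALSE)
      }
      extra <- spare[sample.int(length(spare), short)]
      new_age <- c(new_age, structure(18L + 2L * b + sample(0:1, short, TRUE),
                                      names = as.character(ctrl_pool[extra])))
      take <- c(take, extra)
    }
    used[take] <- TRUE
    control_rows <- c(control_rows, ctrl_pool[take])
  }
  if (length(new_age)) {
    pop$age_years[as.integer(names(new_age))] <- pmin(new_age, 80L)
  }
  study <- pop[c(case_rows, control_rows), , drop = FALSE]
  study <- study[LC_SCHEMA]
  rownames(study) <- NULL
  study$id <- sprintf("S%04d", seq_len(nrow(study)))
  # CSV-facing coding: booleans and risk factors as 0/1 integers
  for (f in LC_BOOL_ITEMS) study[[f]] <- as.integer(study[[f]])

  if (config$miss_rate > 0) {
    cells <- c(LC_CHILDHOOD_ITEMS, LC_ADOLESCENCE_ITEMS, LC_ADULTHOOD_ITEMS,
               LC_RISK_FACTORS)
    for (f in cells) {
      knock <- runif(nrow(study)) < config$miss_rate
      study[[f]][knock] <- NA
    }
  }
  attr(study, "truth") <- attr(pop, "truth")
  study
}

#' One-shot simulation of a matched study
#'
#' [generate_population()], [assign_outcome()] and [sample_matched_study()]
#' under a single seed.
#'
#' @param config an [sim_config()].
#' @return study data frame with a `"truth"` attribute.
#' @export
simulate_study <- function(config = sim_config()) {
  pop <- generate_population(config)
  pop <- assign_outcome(pop, config)
  sample_matched_study(pop, config)
}
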