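# Test helpers: independent oracles and small deterministic fixtures.

# Brute-force exact conditional log-likelihood: enumerate every case-label
# subset of the observed size in each stratum. Independent of the recursive
# implementation; usable only for small strata.
brute_loglik <- function(beta, y, X, strata) {
  X <- as.matrix(X)
  ll <- 0
  for (idx in split(seq_len(nrow(X)), strata)) {
    m <- sum(y[idx])
    n <- length(idx)
    if (m == 0 || m == n) next
    eta <- drop(X[idx, , drop = FALSE] %*% beta)
    num <- sum(eta[y[idx] == 1])
    subsets <- utils::combn(n, m)
    terms <- apply(subsets, 2, function(s) sum(eta[s]))
    ll <- ll + num - (max(terms) + log(sum(exp(terms - max(terms)))))
  }
  ll
}

# Brute-force maximiser of the enumerated likelihood.
brute_fit <- function(y, X, strata, start = NULL) {
  X <- as.matrix(X)
  if (is.null(start)) start <- numeric(ncol(X))
  stats::optim(start, function(b) -brute_loglik(b, y, X, strata),
               method = "BFGS", control = list(reltol = 1e-14, maxit = 500))
}

# Random small-strata instance (all strata of size <= max_size).
random_strata_data <- function(n_strata, max_size = 8, p = 2) {
  sizes <- sample(2:max_size, n_strata, replace = TRUE)
  strata <- rep(seq_len(n_strata), sizes)
  n <- length(strata)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  y <- integer(n)
  for (s in seq_len(n_strata)) {
    idx <- which(strata == s)
    m <- sample(seq_len(sizes[s] - 1L), 1L) # ensure informative
    y[idx[sample(length(idx), m)]] <- 1L
  }
  list(y = y, X = X, strata = factor(strata))
}

# One complete, most-advantaged subject row following the schema; fields
# overridable. Used to build tiny deterministic studies in code.
subject_row <- function(...) {
  row <- list(
    id = "S0001", status = "control", age_years = 60, sex = "m",
    father_occupation = "academic",
    mother_occupation = "white_collar_or_academic_or_housewife",
    family_structure = "both_parents", n_siblings = 0L,
    rooms_per_person = "gt1", toilet_in_house = 1L, parental_car = 1L,
    income_upper_half = 1L, paternal_unemployment = 0L,
    school_degree = "high_school", professional_education = "academic_exam",
    last_profession = "academic", unemployment_gt6mo = 0L, partnered = 1L
  )
  for (rf in LC_RISK_FACTORS) row[[rf]] <- 0L
  override <- list(...)
  for (f in names(override)) row[[f]] <- override[[f]]
  as.data.frame(row, stringsAsFactors = FALSE)
}

make_study <- function(rows) {
  df <- do.call(rbind, rows)
  df$id <- sprintf("S%04d", seq_len(nrow(df)))
  df
}

# Printed counts and percentages of the published mobility tables
# (cases n = 466, controls n = 807), used by the table-reproduction checks.
published_table_cells <- function() {
  rows <- rbind(
    # exposure block, category, case_n, case_pct, control_n, control_pct
    c("father_training", "advancement",  90, 19.3, 243, 30.1),
    c("father_training", "no_change",   330, 70.8, 460, 57.0),
    c("father_training", "descent",      46,  9.9, 104, 12.9),
    c("father_last",     "advancement", 110, 23.6, 296, 36.7),
    c("father_last",     "no_change",   312, 67.0, 423, 52.4),
    c("father_last",     "descent",      44,  9.4,  88, 10.9),
    c("training_last",   "advancement",  50, 10.7,  68,  8.4),
    c("training_last",   "no_change",   355, 76.2, 607, 75.2),
    c("training_last",   "descent",      61, 13.1, 132, 16.4),
    c("child_adol",      "advancement", 130, 27.9, 211, 26.2),
    c("child_adol",      "no_change",   244, 52.4, 406, 50.3),
    c("child_adol",      "descent",      92, 19.7, 190, 23.5),
    c("child_adult",     "advancement", 109, 23.4, 208, 25.8),
    c("child_adult",     "no_change",   191, 41.0, 339, 42.0),
    c("child_adult",     "descent",     166, 35.6, 260, 32.2),
    c("adol_adult",      "advancement",  59, 12.7, 130, 16.1),
    c("adol_adult",      "no_change",   235, 50.4, 462, 57.3),
    c("adol_adult",      "descent",     172, 36.9, 215, 26.6)
  )
  data.frame(exposure = rows[, 1], category = rows[, 2],
             case_n = as.numeric(rows[, 3]), case_pct = as.numeric(rows[, 4]),
             control_n = as.numeric(rows[, 5]),
             control_pct = as.numeric(rows[, 6]), stringsAsFactors = FALSE)
}
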