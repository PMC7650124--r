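# Exact conditional logistic regression: strata construction, likelihood
# recursion vs brute-force enumeration, Newton-Raphson fit, Wald intervals.

test_that("build_strata: 2-year bands crossed with sex, uninformative flagged", {
  df <- data.frame(age_years = c(19, 20, 19, 80, 79),
                   sex = c("m", "m", "m", "f", "f"),
                   status = c("case", "case", "control", "case", "case"))
  st <- build_strata(df)
  # 19 and 20 fall in different bands
  expect_false(st$labels[1] == st$labels[2])
  expect_identical(st$labels[1], st$labels[3])
  # ages 79 and 80 share the closed last band [78,80]
  expect_identical(st$labels[4], st$labels[5])
  # case-only stratum is uninformative
  tab <- st$table
  expect_false(tab$informative[tab$stratum == st$labels[4]])
  expect_true(tab$informative[tab$stratum == st$labels[1]])
  expect_error(build_strata(data.frame(age_years = 81, sex = "m",
                                       status = "case")), "age")

  set.seed(5)
  big <- data.frame(
    age_years = runif(1273, 18, 80),
    sex = sample(c("m", "f"), 1273, replace = TRUE),
    status = rep(c("case", "control"), c(466, 807))
  )
  stb <- build_strata(big)
  expect_identical(length(stb$labels), 1273L)
  expect_lte(nrow(stb$table), 62L)
  expect_identical(sum(stb$table$n_cases + stb$table$n_controls), 1273L)
})

test_that("conditional loglik at the null equals -sum log choose(n, m)", {
  set.seed(31)
  d <- random_strata_data(12, max_size = 8, p = 3)
  ll0 <- conditional_loglik(numeric(3), d$y, d$X, d$strata)
  expected <- -sum(sapply(split(seq_along(d$y), d$strata), function(idx) {
    log(choose(length(idx), sum(d$y[idx])))
  }))
  expect_equal(ll0, expected, tolerance = 1e-12)
})

test_that("recursion equals brute-force enumeration on strata of size <= 8", {
  set.seed(32)
  for (rep in 1:20) {
    d <- random_strata_data(sample(3:10, 1), max_size = 8, p = 2)
    beta <- rnorm(2)
    expect_equal(conditional_loglik(beta, d$y, d$X, d$strata),
                 brute_loglik(beta, d$y, d$X, d$strata), tolerance = 1e-10)
  }
})

test_that("analytic gradient matches finite differences of the brute likelihood", {
  set.seed(33)
  d <- random_strata_data(8, max_size = 6, p = 3)
  beta <- c(0.4, -0.2, 0.1)
  idx <- split(seq_along(d$y), d$strata)
  derivs <- lcmob:::clogit_derivs(beta, d$y, d$X, idx, 2L)
  h <- 1e-6
  for (j in 1:3) {
    e <- numeric(3); e[j] <- h
    fd <- (brute_loglik(beta + e, d$y, d$X, d$strata) -
             brute_loglik(beta - e, d$y, d$X, d$strata)) / (2 * h)
    expect_equal(derivs$gradient[j], fd, tolerance = 1e-5)
  }
  # information is symmetric and matches -d2 loglik numerically
  expect_equal(derivs$information, t(derivs$information), tolerance = 1e-10)
  fd2 <- (brute_loglik(beta + c(h, 0, 0), d$y, d$X, d$strata) -
            2 * brute_loglik(beta, d$y, d$X, d$strata) +
            brute_loglik(beta - c(h, 0, 0), d$y, d$X, d$strata)) / h^2
  expect_equal(derivs$information[1, 1], -fd2, tolerance = 1e-3)
})

test_that("fitted coefficients agree with brute-force maximisation and survival", {
  set.seed(34)
  d <- random_strata_data(15, max_size = 7, p = 2)
  fit <- clogit_fit(d$y, d$X, d$strata)
  expect_true(fit$converged)
  bf <- brute_fit(d$y, d$X, d$strata)
  expect_equal(unname(fit$beta), unname(bf$par), tolerance = 1e-5)
  expect_equal(fit$loglik, -bf$value, tolerance = 1e-8)

  skip_if_not_installed("survival")
  # clogit() constructs a coxph() call, so survival must be attached
  suppressPackageStartupMessages(library(survival))
  sf <- survival::clogit(y ~ x1 + x2 + strata(s),
                         data = data.frame(y = d$y, d$X, s = d$strata),
                         method = "exact")
  expect_equal(unname(fit$beta), unname(coef(sf)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(sf)))), tolerance = 1e-6)
})

test_that("mirror strata maximise at zero; 1:1 matching equals the classical pair estimator", {
  # two mirror strata: (case x=1, control x=0) and (case x=0, control x=1)
  y <- c(1, 0, 1, 0)
  X <- matrix(c(1, 0, 0, 1), ncol = 1, dimnames = list(NULL, "x"))
  strata <- c(1, 1, 2, 2)
  fit <- clogit_fit(y, X, strata)
  expect_true(fit$converged)
  expect_equal(unname(fit$beta), 0, tolerance = 1e-8)

  # 1:1 matched pairs with binary exposure: beta-hat = log(n10 / n01)
  set.seed(35)
  n_pairs <- 80
  x_case <- rbinom(n_pairs, 1, 0.6)
  x_ctrl <- rbinom(n_pairs, 1, 0.4)
  y <- rep(c(1, 0), n_pairs)
  X <- matrix(as.numeric(rbind(x_case, x_ctrl)), ncol = 1,
              dimnames = list(NULL, "x"))
  strata <- rep(seq_len(n_pairs), each = 2)
  fit <- clogit_fit(y, X, strata)
  n10 <- sum(x_case == 1 & x_ctrl == 0)
  n01 <- sum(x_case == 0 & x_ctrl == 1)
  expect_equal(unname(fit$beta), log(n10 / n01), tolerance = 1e-7)
})

test_that("separation is flagged, never returned as converged with CIs", {
  y <- c(1, 0, 0)
  X <- matrix(c(1, 0, 0), ncol = 1, dimnames = list(NULL, "x"))
  fit <- clogit_fit(y, X, c(1, 1, 1))
  expect_true(fit$separation)
  expect_false(fit$converged)
  expect_null(fit$or_ci)
  expect_error(wald_or_ci(fit), "converged")
})

test_that("covariates constant within every stratum are dropped; others unchanged", {
  set.seed(36)
  d <- random_strata_data(12, max_size = 6, p = 1)
  # a stratum-constant covariate (e.g. a matching variable snuck into X)
  const <- ave(rnorm(length(d$y)), d$strata)
  X2 <- cbind(d$X, matched_var = const)
  fit1 <- clogit_fit(d$y, d$X, d$strata)
  expect_warning(fit2 <- clogit_fit(d$y, X2, d$strata), "matched_var")
  expect_equal(fit2$beta[["x1"]], fit1$beta[["x1"]], tolerance = 1e-10)
  expect_true(is.na(fit2$beta[["matched_var"]]))
  expect_identical(fit2$dropped, "matched_var")
})

test_that("Wald OR intervals: closed-form examples and edge cases", {
  ci <- wald_or_ci(list(beta = c(a = 0), se = c(a = 0.1)))
  expect_equal(round(c(ci$or, ci$lo, ci$hi), 2), c(1.00, 0.82, 1.22))
  ci <- wald_or_ci(list(beta = c(a = log(2)), se = c(a = 0.2)))
  expect_equal(round(c(ci$or, ci$lo, ci$hi), 2), c(2.00, 1.35, 2.96))
  expect_error(wald_or_ci(list(beta = c(a = 1), se = c(a = 0))), "zero")
  ci <- wald_or_ci(list(beta = c(a = 1), se = c(a = 0)), strict = FALSE)
  expect_equal(ci$lo, ci$or)
  expect_equal(ci$hi, ci$or)
  expect_true(all(ci$lo <= ci$or & ci$or <= ci$hi))
})

test_that("parameter recovery: mean estimate near truth over replicates", {
  set.seed(37)
  truth <- 0.7
  est <- replicate(40, {
    n_strata <- 100
    strata <- rep(seq_len(n_strata), each = 3)
    x <- rbinom(3 * n_strata, 1, 0.5)
    # within each stratum, one of three members becomes the case with
    # probability proportional to exp(truth * x)
    y <- integer(3 * n_strata)
    for (s in seq_len(n_strata)) {
      idx <- 3 * (s - 1) + 1:3
      p <- exp(truth * x[idx])
      y[idx[sample(3, 1, prob = p)]] <- 1L
    }
    fit <- clogit_fit(y, matrix(as.numeric(x), dimnames = list(NULL, "x")),
                      strata)
    fit$beta[["x"]]
  })
  expect_lt(abs(mean(est) - truth), 0.15)
})
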