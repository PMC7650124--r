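# Exact conditional logistic regression for frequency-matched case-control
# strata (2-year age band x sex). The conditional likelihood treats the number
# of cases in each stratum as fixed and conditions it out, eliminating the
# stratum intercepts; the denominator is computed by the elementary-sum
# recursion (src/clogit_core.cpp), never by subset enumeration.

#' Matching strata from age and sex
#'
#' Partitions subjects into 2-year age bands crossed with sex. Bands are
#' half-open `[18,20), [20,22), ...` with the final band closed at 80, so the
#' partition covers ages 18--80 with 31 bands per sex. Strata containing only
#' cases or only controls carry no information about the odds ratio and are
#' flagged uninformative; they are excluded from the conditional likelihood.
#'
#' @param records data frame with `age_years` in `[18, 80]`, `sex` in
#'   `{"m","f"}` and `status` in `{"case","control"}`.
#' @return an object of class `lc_strata`: list with `labels` (stratum label
#'   per record), `table` (per-stratum case/control counts and an
#'   `informative` flag) and `index` (list of row indices per informative
#'   stratum, for the likelihood).
#' @export
build_strata <- function(records) {
  age <- records$age_years
  if (anyNA(age) || any(age < 18 | age > 80)) {
    stop("age_years must be non-missing and lie in [18, 80]", call. = FALSE)
  }
  if (!all(records$sex %in% c("m", "f"))) {
    stop("sex must be 'm' or 'f'", call. = FALSE)
  }
  band <- pmin(floor((age - 18) / 2), 30L) # age 80 folds into [78, 80]
  lo <- 18L + 2L * band
  close <- ifelse(lo == 78L, "]", ")")
  labels <- sprintf("[%d,%d%s:%s", lo, lo + 2L, close, records$sex)
  y <- as.integer(records$status == "case")
  tab <- stats::aggregate(cbind(n_cases = y, n_controls = 1L - y),
                          by = list(stratum = labels), FUN = sum)
  tab$informative <- tab$n_cases > 0L & tab$n_controls > 0L
  index <- split(seq_along(labels), labels)[tab$stratum[tab$informative]]
  structure(list(labels = labels, table = tab, index = unname(index)),
            class = "lc_strata")
}

#' @export
print.lc_strata <- function(x, ...) {
  n_inf <- sum(x$table$informative)
  cat(sprintf("Matched strata: %d total, %d informative (%d subjects in informative strata)\n",
              nrow(x$table), n_inf, length(unlist(x$index))))
  invisible(x)
}

as_stratum_index <- function(strata, n) {
  if (inherits(strata, "lc_strata")) return(strata$index)
  # plain factor/vector of stratum labels: keep informative strata only
  split(seq_len(n), strata)
}

#' Exact conditional log-likelihood
#'
#' Evaluates the conditional logistic log-likelihood
#' \deqn{\sum_s \Big[\sum_{i \in cases_s} x_i'\beta -
#'   \log \sum_{|S| = m_s} \exp\big(\sum_{i \in S} x_i'\beta\big)\Big]}
#' where the inner sum runs over all subsets of stratum `s` of the observed
#' case count \eqn{m_s}. The denominator is computed by the standard recursion
#' over elementary sums; strata without both a case and a control contribute
#' nothing. At `beta = 0` each stratum contributes `-log choose(n_s, m_s)`.
#'
#' @param beta numeric coefficient vector (length `ncol(X)`).
#' @param y 0/1 case indicator per record.
#' @param X numeric covariate matrix, one row per record.
#' @param strata an [build_strata()] object, or a vector of stratum labels.
#' @return the log-likelihood (scalar).
#' @export
conditional_loglik <- function(beta, y, X, strata) {
  X <- as.matrix(X)
  if (length(beta) != ncol(X)) {
    stop(sprintf("length(beta) == %d but ncol(X) == %d", length(beta), ncol(X)),
         call. = FALSE)
  }
  idx <- as_stratum_index(strata, nrow(X))
  idx0 <- lapply(idx, function(i) as.integer(i - 1L))
  .clogit_derivs_cpp(as.numeric(beta), X, as.integer(y), idx0, 0L)$loglik
}

clogit_derivs <- function(beta, y, X, index, order = 2L) {
  idx0 <- lapply(index, function(i) as.integer(i - 1L))
  .clogit_derivs_cpp(as.numeric(beta), X, as.integer(y), idx0, as.integer(order))
}

#' Fitting control parameters for [clogit_fit()]
#'
#' @param max_iter maximum Newton-Raphson iterations.
#' @param score_tol convergence when the largest absolute score component
#'   falls below this.
#' @param step_tol convergence when the largest absolute step falls below this.
#' @param beta_max coefficient magnitude beyond which a monotone likelihood
#'   (separation) is declared.
#' @export
clogit_control <- function(max_iter = 50L, score_tol = 1e-8,
                           step_tol = 1e-10, beta_max = 12) {
  list(max_iter = as.integer(max_iter), score_tol = score_tol,
       step_tol = step_tol, beta_max = beta_max)
}

#' Fit an exact conditional logistic regression
#'
#' Newton-Raphson maximisation of the exact conditional likelihood with
#' analytic gradient and Hessian and step-halving. Covariates with no
#' variation within any informative stratum carry no conditional information
#' and are dropped with a warning (their coefficients are reported as `NA`).
#' A monotone likelihood (separation: some coefficient diverging) is flagged,
#' never silently reported as converged, and confidence intervals are
#' suppressed for such fits.
#'
#' @param y 0/1 case indicator per record.
#' @param X numeric covariate matrix (columns named).
#' @param strata an [build_strata()] object or stratum labels per record.
#' @param control see [clogit_control()].
#' @return object of class `lc_fit`: coefficients `beta`, `se`, covariance
#'   matrix (inverse observed information), `loglik`, `converged`,
#'   `separation`, `n_iter`, `n_informative_strata`, `dropped` covariate
#'   names, and the odds-ratio table from [wald_or_ci()].
#' @export
clogit_fit <- function(y, X, strata, control = clogit_control()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.integer(y)
  index <- as_stratum_index(strata, nrow(X))
  # informative strata only
  index <- Filter(function(i) {
    m <- sum(y[i]); m > 0L && m < length(i)
  }, index)
  if (!length(index)) stop("no informative strata", call. = FALSE)

  # drop covariates constant within every informative stratum
  rows <- unlist(index)
  within_var <- vapply(seq_len(ncol(X)), function(j) {
    any(vapply(index, function(i) {
      v <- X[i, j]; any(v != v[1])
    }, logical(1)))
  }, logical(1))
  dropped <- colnames(X)[!within_var]
  if (length(dropped)) {
    warning(sprintf("dropping covariate(s) constant within all strata: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  }
  keep <- which(within_var)
  Xk <- X[, keep, drop = FALSE]
  p <- ncol(Xk)

  beta <- numeric(p)
  converged <- FALSE
  separation <- FALSE
  iter <- 0L
  d <- clogit_derivs(beta, y, Xk, index, 2L)
  if (p > 0L && max(abs(d$gradient)) < control$score_tol) {
    converged <- TRUE
  } else if (p > 0L) {
    repeat {
      iter <- iter + 1L
      step <- tryCatch(solve(d$information, d$gradient), error = function(e) NULL)
      if (is.null(step)) { separation <- TRUE; break }
      # step-halving to guarantee ascent
      ll_old <- d$loglik
      alpha <- 1
      repeat {
        beta_new <- beta + alpha * step
        ll_new <- clogit_derivs(beta_new, y, Xk, index, 0L)$loglik
        if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
        alpha <- alpha / 2
        if (alpha < 1e-8) break
      }
      beta <- beta + alpha * step
      d <- clogit_derivs(beta, y, Xk, index, 2L)
      if (max(abs(beta)) > control$beta_max) { separation <- TRUE; break }
      if (max(abs(d$gradient)) < control$score_tol ||
          max(abs(alpha * step)) < control$step_tol) { converged <- TRUE; break }
      if (iter >= control$max_iter) break
    }
  } else {
    converged <- TRUE # empty model
  }

  vcov <- matrix(NA_real_, p, p)
  se <- rep(NA_real_, p)
  if (converged && !separation && p > 0L) {
    vc <- tryCatch(solve(d$information), error = function(e) NULL)
    if (is.null(vc) || any(diag(vc) <= 0)) {
      separation <- TRUE
      converged <- FALSE
    } else {
      vcov <- vc
      se <- sqrt(diag(vc))
    }
  }

  # expand back to the full covariate set
  full_beta <- structure(rep(NA_real_, ncol(X)), names = colnames(X))
  full_se <- full_beta
  full_beta[keep] <- beta
  full_se[keep] <- se
  dimnames(vcov) <- list(colnames(Xk), colnames(Xk))

  fit <- structure(list(
    beta = full_beta, se = full_se, vcov = vcov, loglik = d$loglik,
    converged = converged, separation = separation, n_iter = iter,
    n_informative_strata = length(index), dropped = dropped,
    n = length(rows)
  ), class = "lc_fit")
  if (converged && !separation) fit$or_ci <- wald_or_ci(fit)
  fit
}

#' Wald odds-ratio confidence intervals
#'
#' `OR = exp(beta)` with limits `exp(beta +/- z * se)`, `z` the standard
#' normal quantile at `(1 + level)/2`. No rounding is applied here; rounding
#' to two decimals happens only in the presentation layer.
#'
#' @param fit an `lc_fit` object from [clogit_fit()] (must have converged
#'   without separation), or a list with numeric `beta` and `se`.
#' @param level confidence level, default 0.95.
#' @param strict if `TRUE` (default), a zero standard error is an error;
#'   otherwise a degenerate interval `(OR, OR)` is returned for it.
#' @return data frame with columns `term`, `or`, `lo`, `hi`.
#' @export
wald_or_ci <- function(fit, level = 0.95, strict = TRUE) {
  if (inherits(fit, "lc_fit") && (!isTRUE(fit$converged) || isTRUE(fit$separation))) {
    stop("confidence intervals require a converged, non-separated fit",
         call. = FALSE)
  }
  beta <- fit$beta
  se <- fit$se
  if (strict && any(!is.na(se) & se == 0)) {
    stop("zero standard error: degenerate interval (set strict = FALSE to allow)",
         call. = FALSE)
  }
  z <- qnorm((1 + level) / 2)
  data.frame(
    term = if (is.null(names(beta))) paste0("x", seq_along(beta)) else names(beta),
    or = exp(beta),
    lo = exp(beta - z * se),
    hi = exp(beta + z * se),
    row.names = NULL
  )
}

#' @export
print.lc_fit <- function(x, ...) {
  cat(sprintf("Exact conditional logistic fit: %d informative strata, %d subjects\n",
              x$n_informative_strata, x$n))
  cat(sprintf("loglik %.4f, %s in %d iteration(s)%s\n", x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter,
              if (x$separation) " [separation flagged]" else ""))
  if (!is.null(x$or_ci)) print(x$or_ci, digits = 4)
  invisible(x)
}
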