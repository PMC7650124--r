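# Analysis pipeline: questionnaire items -> life-stage scores -> control
# tertile strata -> six mobility exposures -> three nested conditional
# logistic models per exposure -> mobility tables with ORs and 95% CIs.

#' Analysis configuration
#'
#' @param seed integer seed controlling any randomness (imputation strategies
#'   shipped here are deterministic, but the seed is threaded through for
#'   reproducibility of the whole run).
#' @param imputation `"mode_cell"` (default) or `"complete_case"`, see
#'   [impute_items()].
#' @param model3_scores how Model 3 enters the life-stage scores:
#'   `"strata"` (default; two indicator terms per stage, reference `low`) or
#'   `"continuous"` (the raw integer scores).
#' @param ci_level confidence level for Wald intervals.
#' @return list of class `lc_config`.
#' @export
lc_config <- function(seed = 1L, imputation = "mode_cell",
                      model3_scores = "strata", ci_level = 0.95) {
  stopifnot(imputation %in% c("mode_cell", "complete_case"),
            model3_scores %in% c("strata", "continuous"),
            ci_level > 0, ci_level < 1)
  structure(list(seed = as.integer(seed), imputation = imputation,
                 model3_scores = model3_scores, ci_level = ci_level),
            class = "lc_config")
}

#' Percentages as printed in mobility tables
#'
#' `100 * count / total`, rounded half-up to one decimal (so 90 of 466 is
#' 19.3). Rounding is half-up and staged -- first to two decimals, then to
#' one -- which is the only convention consistent with every percentage in
#' the published mobility tables (211 of 807 prints as 26.2, i.e. 26.146 ->
#' 26.15 -> 26.2; single-stage half-up would give 26.1). Base R's `round()`
#' rounds half to even and is not used here.
#'
#' @param counts non-negative integer vector.
#' @param total positive total the percentages refer to.
#' @return numeric vector of percentages with one decimal.
#' @export
make_percentages <- function(counts, total) {
  if (length(total) != 1 || is.na(total) || total <= 0) {
    stop("total must be a single positive count", call. = FALSE)
  }
  if (any(counts < 0) || any(counts > total)) {
    stop("counts must lie in [0, total]", call. = FALSE)
  }
  two <- floor(10000 * counts / total + 0.5 + 1e-9) / 100
  floor(10 * two + 0.5 + 1e-9) / 10
}

#' Crude 2x2 odds ratio with Woolf interval
#'
#' Diagnostic unconditional odds ratio `ad/(bc)` for an
#' exposed/unexposed x case/control table, with the Woolf (log-scale normal)
#' confidence interval. If any cell is zero, 0.5 is added to every cell
#' (Haldane-Anscombe correction) and the result is flagged. This is a sanity
#' check accompanying table rows; the reported estimates come from the
#' conditional models.
#'
#' @param a,b,c,d cell counts: exposed cases, exposed controls, unexposed
#'   cases, unexposed controls.
#' @param level confidence level.
#' @return list with `or`, `lo`, `hi`, `corrected`.
#' @export
crude_or_from_counts <- function(a, b, c, d, level = 0.95) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  corrected <- any(counts == 0)
  if (corrected) counts <- counts + 0.5
  a <- counts[1]; b <- counts[2]; c <- counts[3]; d <- counts[4]
  z <- qnorm((1 + level) / 2)
  log_or <- log(a) + log(d) - log(b) - log(c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = exp(log_or), lo = exp(log_or - z * se), hi = exp(log_or + z * se),
       corrected = corrected)
}

#' Prepare a raw study table for analysis
#'
#' Validation, imputation, scoring, control-tertile strata and mobility
#' classification, in that order.
#'
#' @param records raw subject table following [LC_SCHEMA].
#' @param config an [lc_config()].
#' @return prepared data frame (with `"cutpoints"` and `"imputation_log"`
#'   attributes).
#' @export
lc_prepare <- function(records, config = lc_config()) {
  validate_records(records, stop_on_error = TRUE)
  records <- impute_items(records, strategy = config$imputation,
                          seed = config$seed)
  log <- attr(records, "imputation_log")
  records <- add_mobility(add_scores(records))
  attr(records, "imputation_log") <- log
  records
}

# Model-variant covariate matrix for one exposure. Columns are nested:
# model1 subset of model2 subset of model3.
model_covariates <- function(records, exposure, variant,
                             model3_scores = "strata") {
  mob <- records[[exposure]]
  X <- cbind(advancement = as.integer(mob == "advancement"),
             descent = as.integer(mob == "descent"))
  if (variant %in% c("model2", "model3")) {
    rf <- as.matrix(records[LC_RISK_FACTORS])
    storage.mode(rf) <- "double"
    X <- cbind(X, rf)
  }
  if (variant == "model3") {
    if (model3_scores == "strata") {
      sc <- NULL
      for (st in c("childhood_stratum", "adolescence_stratum", "adulthood_stratum")) {
        v <- records[[st]]
        sc <- cbind(sc,
                    as.integer(v == "middle"),
                    as.integer(v == "high"))
      }
      colnames(sc) <- paste0(rep(c("child", "adol", "adult"), each = 2),
                             c("_middle", "_high"))
      X <- cbind(X, sc)
    } else {
      X <- cbind(X, score_child = records$score_child,
                 score_adol = records$score_adol,
                 score_adult = records$score_adult)
    }
  }
  X
}

fit_one_model <- function(records, strata, exposure, variant, config) {
  X <- model_covariates(records, exposure, variant, config$model3_scores)
  y <- as.integer(records$status == "case")
  withCallingHandlers(
    clogit_fit(y, X, strata),
    warning = function(w) invokeRestart("muffleWarning")
  )
}

#' Run the full mobility analysis
#'
#' For each of the six mobility exposures, fits three nested conditional
#' logistic models: Model 1 conditions on the 2-year-age x sex strata only;
#' Model 2 additionally adjusts for the 14 medical and lifestyle risk
#' factors; Model 3 additionally adjusts for the childhood, adolescence and
#' adulthood socioeconomic scores. Assembles the two mobility tables
#' (occupational comparisons; score-stratum comparisons) with counts,
#' percentages and per-model ORs with Wald CIs. Non-converged or separated
#' fits leave the OR cells `NA`; the run continues. No multiple-testing
#' adjustment is applied (recorded in `meta`).
#'
#' @param records raw subject table following [LC_SCHEMA] (preparation is run
#'   internally), or an already prepared table from [lc_prepare()].
#' @param config an [lc_config()].
#' @return object of class `lc_analysis`: `table1` (occupational mobility),
#'   `table2` (score-stratum mobility), `fits` (nested list
#'   `fits[[exposure]][[variant]]` of `lc_fit` objects), `cutpoints`, `meta`.
#' @export
run_analysis <- function(records, config = lc_config()) {
  if (!all(LC_EXPOSURES %in% names(records))) {
    records <- lc_prepare(records, config)
  }
  strata <- build_strata(records)
  y_case <- records$status == "case"
  n_cases <- sum(y_case)
  n_controls <- sum(!y_case)
  variants <- c("model1", "model2", "model3")

  fits <- list()
  rows <- list()
  for (exposure in LC_EXPOSURES) {
    fits[[exposure]] <- list()
    for (v in variants) {
      fits[[exposure]][[v]] <- fit_one_model(records, strata, exposure, v, config)
    }
    mob <- records[[exposure]]
    for (cat in LC_MOBILITY_LEVELS) {
      cn <- sum(mob == cat & y_case)
      ct <- sum(mob == cat & !y_case)
      row <- data.frame(
        exposure = exposure, category = cat,
        case_n = cn, case_pct = make_percentages(cn, n_cases),
        control_n = ct, control_pct = make_percentages(ct, n_controls)
      )
      for (v in variants) {
        fit <- fits[[exposure]][[v]]
        est <- c(NA_real_, NA_real_, NA_real_)
        if (cat == "no_change") {
          est <- c(1, NA_real_, NA_real_)
        } else if (isTRUE(fit$converged) && !isTRUE(fit$separation) &&
                   cn + ct > 0 && !is.na(fit$beta[[cat]])) {
          ci <- wald_or_ci(fit, level = config$ci_level)
          est <- unlist(ci[ci$term == cat, c("or", "lo", "hi")])
        }
        row[[paste0(v, "_or")]] <- est[1]
        row[[paste0(v, "_lo")]] <- est[2]
        row[[paste0(v, "_hi")]] <- est[3]
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  tab <- do.call(rbind, rows)
  occupational <- LC_EXPOSURES[1:3]
  structure(list(
    table1 = tab[tab$exposure %in% occupational, , drop = FALSE],
    table2 = tab[!tab$exposure %in% occupational, , drop = FALSE],
    fits = fits,
    cutpoints = attr(records, "cutpoints"),
    meta = list(n_cases = n_cases, n_controls = n_controls,
                n_informative_strata = sum(strata$table$informative),
                multiple_testing_adjustment = "none",
                ci_level = config$ci_level, seed = config$seed,
                imputation = config$imputation,
                model3_scores = config$model3_scores)
  ), class = "lc_analysis")
}

#' Sex-stratified Model 3 fits
#'
#' Refits the fully adjusted model on each sex subset separately; within a
#' subset the matching strata reduce to the 2-year age bands. Each subset is
#' prepared independently (its own control tertiles), so a single-sex fit is
#' identical to analysing a file containing only that sex. A sex subset
#' without informative strata is skipped with a warning.
#'
#' @param records raw subject table following [LC_SCHEMA].
#' @param config an [lc_config()].
#' @return named list (`m`, `f`) of lists `fits[[exposure]]` of `lc_fit`
#'   objects; absent sexes are omitted.
#' @export
sex_stratified_fits <- function(records, config = lc_config()) {
  out <- list()
  for (sx in c("m", "f")) {
    sub <- records[records$sex == sx, , drop = FALSE]
    if (!nrow(sub) || length(unique(sub$status)) < 2) {
      warning(sprintf("sex '%s': no informative strata, skipped", sx),
              call. = FALSE)
      next
    }
    prepared <- lc_prepare(sub, config)
    strata <- build_strata(prepared)
    if (!any(strata$table$informative)) {
      warning(sprintf("sex '%s': no informative strata, skipped", sx),
              call. = FALSE)
      next
    }
    out[[sx]] <- lapply(structure(LC_EXPOSURES, names = LC_EXPOSURES),
                        function(exposure) {
                          fit_one_model(prepared, strata, exposure, "model3", config)
                        })
  }
  out
}

format_or_cell <- function(or, lo, hi) {
  ifelse(is.na(or), "",
         ifelse(is.na(lo), sprintf("%.2f", or),
                sprintf("%.2f (%.2f-%.2f)", or, lo, hi)))
}

#' Write analysis outputs to a directory
#'
#' Writes `table1.csv` and `table2.csv` (counts, percentages and formatted OR
#' cells), `fits.json` (coefficients, standard errors, ORs, CIs, log
#' likelihood and diagnostics for every fit), `cutpoints.json`, `bysex.csv`
#' (sex-stratified Model 3 odds ratios) and `run.log`. Output is
#' deterministic: identical inputs and config give byte-identical files.
#'
#' @param analysis an `lc_analysis` from [run_analysis()].
#' @param bysex optional result of [sex_stratified_fits()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_analysis <- function(analysis, outdir, bysex = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fmt_table <- function(tab) {
    out <- tab[c("exposure", "category", "case_n", "case_pct",
                 "control_n", "control_pct")]
    for (v in c("model1", "model2", "model3")) {
      out[[v]] <- format_or_cell(tab[[paste0(v, "_or")]],
                                 tab[[paste0(v, "_lo")]],
                                 tab[[paste0(v, "_hi")]])
    }
    out
  }
  f1 <- file.path(outdir, "table1.csv")
  f2 <- file.path(outdir, "table2.csv")
  write.csv(fmt_table(analysis$table1), f1, row.names = FALSE)
  write.csv(fmt_table(analysis$table2), f2, row.names = FALSE)

  fit_json <- function(fit) {
    list(beta = as.list(fit$beta), se = as.list(fit$se),
         or_ci = if (!is.null(fit$or_ci)) fit$or_ci else NULL,
         loglik = fit$loglik, converged = fit$converged,
         separation = fit$separation, n_iter = fit$n_iter,
         n_informative_strata = fit$n_informative_strata,
         dropped = as.list(fit$dropped))
  }
  fits <- lapply(analysis$fits, function(by_variant) lapply(by_variant, fit_json))
  fj <- file.path(outdir, "fits.json")
  jsonlite::write_json(list(meta = analysis$meta, fits = fits), fj,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  cj <- file.path(outdir, "cutpoints.json")
  jsonlite::write_json(analysis$cutpoints, cj, auto_unbox = TRUE, pretty = TRUE)

  files <- c(f1, f2, fj, cj)
  if (!is.null(bysex)) {
    rows <- list()
    for (sx in names(bysex)) {
      for (exposure in names(bysex[[sx]])) {
        fit <- bysex[[sx]][[exposure]]
        for (cat in c("advancement", "descent")) {
          ok <- isTRUE(fit$converged) && !isTRUE(fit$separation) &&
            !is.na(fit$beta[[cat]])
          ci <- if (ok) wald_or_ci(fit) else NULL
          rows[[length(rows) + 1L]] <- data.frame(
            sex = sx, exposure = exposure, category = cat,
            or = if (ok) ci$or[ci$term == cat] else NA_real_,
            lo = if (ok) ci$lo[ci$term == cat] else NA_real_,
            hi = if (ok) ci$hi[ci$term == cat] else NA_real_
          )
        }
      }
    }
    fb <- file.path(outdir, "bysex.csv")
    write.csv(do.call(rbind, rows), fb, row.names = FALSE)
    files <- c(files, fb)
  }
  invisible(files)
}

#' @export
print.lc_analysis <- function(x, ...) {
  cat(sprintf("Life-course mobility analysis: %d cases, %d controls, %d informative strata\n",
              x$meta$n_cases, x$meta$n_controls, x$meta$n_informative_strata))
  cat("\nOccupational mobility (table1):\n")
  print(x$table1, digits = 3, row.names = FALSE)
  cat("\nScore-stratum mobility (table2):\n")
  print(x$table2, digits = 3, row.names = FALSE)
  invisible(x)
}
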