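# Social-mobility classification: intergenerational occupational mobility
# (three ordered profession categories) and score-stratum mobility between
# life stages (tertile risk strata derived from controls).

# Ordered occupational levels; higher = more advantaged.
LC_PROFESSION_LEVEL <- c(blue_collar_other = 0L, white_collar = 1L, academic = 2L)

#' Collapse raw occupation codes onto the three-category occupational scale
#'
#' Professions are compared on an ordered three-level scale: `academic` >
#' `white_collar` > `blue_collar_other` (combined skilled/unskilled blue
#' collar, other occupations, and housewives). Each questionnaire field has
#' its own finer coding, collapsed here; unknown levels raise a validation
#' error naming the field.
#'
#' @param values character vector of raw codes.
#' @param field one of `"father_occupation"`, `"professional_education"`,
#'   `"last_profession"`, or `"category"` if `values` already uses the
#'   three-category scale.
#' @return character vector with levels `academic`, `white_collar`,
#'   `blue_collar_other`.
#' @export
profession_category <- function(values, field = "category") {
  maps <- list(
    father_occupation = c(academic = "academic", white_collar = "white_collar",
                          blue_or_unskilled = "blue_collar_other"),
    professional_education = c(academic_exam = "academic",
                               white_collar_degree = "white_collar",
                               skilled_worker = "blue_collar_other",
                               unskilled_incl_housewife = "blue_collar_other"),
    last_profession = c(academic = "academic", white_collar = "white_collar",
                        skilled_blue_collar = "blue_collar_other",
                        unskilled_incl_housewife = "blue_collar_other"),
    category = c(academic = "academic", white_collar = "white_collar",
                 blue_collar_other = "blue_collar_other")
  )
  map <- maps[[match.arg(field, names(maps))]]
  out <- map[as.character(values)]
  if (anyNA(out) && !all(is.na(values))) {
    bad <- unique(as.character(values)[is.na(out) & !is.na(values)])
    if (length(bad)) {
      stop(sprintf("unknown level(s) %s in field '%s'",
                   paste(sQuote(bad), collapse = ", "), field), call. = FALSE)
    }
  }
  unname(out)
}

#' Classify intergenerational occupational mobility
#'
#' Compares the subject's occupational category (professional training or last
#' profession) with the paternal one on the ordered three-category scale.
#' A strictly higher subject category is `advancement`, equality is
#' `no_change`, a lower category is `descent`.
#'
#' @param father,subject character vectors of three-category occupation codes
#'   (`academic`, `white_collar`, `blue_collar_other`).
#' @return character vector with values in [LC_MOBILITY_LEVELS].
#' @examples
#' classify_profession_mobility("blue_collar_other", "academic") # advancement
#' @export
classify_profession_mobility <- function(father, subject) {
  f <- LC_PROFESSION_LEVEL[profession_category(father)]
  s <- LC_PROFESSION_LEVEL[profession_category(subject)]
  unname(ifelse(s > f, "advancement", ifelse(s < f, "descent", "no_change")))
}

#' Tertile cutpoints of a discrete score from control values
#'
#' For integer-valued scores with heavy ties the usual quantile definitions
#' are ambiguous; the rule used here is the empirical-CDF threshold rule:
#' `q1` is the smallest observed value `v` with `CDF(v) >= 1/3` and `q2` the
#' smallest with `CDF(v) >= 2/3`. Strata are then `low` for `x <= q1`,
#' `middle` for `q1 < x <= q2`, `high` for `x > q2`. Computed from controls
#' only, so the low stratum is never empty among controls.
#'
#' @param control_scores integer vector of control score values (nonempty).
#' @return list with integer cutpoints `q1 <= q2`.
#' @examples
#' control_tertile_cutpoints(c(0, 0, 1, 1, 2, 2, 3, 3, 4)) # q1 = 1, q2 = 2
#' @export
control_tertile_cutpoints <- function(control_scores) {
  if (!length(control_scores) || anyNA(control_scores)) {
    stop("control_scores must be a nonempty vector without missing values",
         call. = FALSE)
  }
  v <- sort(unique(control_scores))
  cdf <- cumsum(tabulate(match(control_scores, v), length(v))) /
    length(control_scores)
  q1 <- v[which(cdf >= 1 / 3)[1]]
  q2 <- v[which(cdf >= 2 / 3)[1]]
  list(q1 = q1, q2 = q2)
}

#' Assign low/middle/high risk strata from tertile cutpoints
#'
#' @param scores integer vector of score values.
#' @param cutpoints list with `q1`, `q2` as returned by
#'   [control_tertile_cutpoints()].
#' @return character vector with values `low`, `middle`, `high`.
#' @export
score_stratum <- function(scores, cutpoints) {
  ifelse(scores <= cutpoints$q1, "low",
         ifelse(scores <= cutpoints$q2, "middle", "high"))
}

#' Classify score-stratum mobility between two life stages
#'
#' Strata are risk strata (higher score = more disadvantage), so reaching a
#' higher-risk stratum later in life is social `descent` and reaching a
#' lower-risk stratum is `advancement`.
#'
#' @param stratum_early,stratum_late character vectors with values `low`,
#'   `middle`, `high`.
#' @return character vector with values in [LC_MOBILITY_LEVELS].
#' @export
classify_score_mobility <- function(stratum_early, stratum_late) {
  ord <- c(low = 1L, middle = 2L, high = 3L)
  e <- ord[as.character(stratum_early)]
  l <- ord[as.character(stratum_late)]
  if (anyNA(e) || anyNA(l)) {
    stop("strata must be one of 'low', 'middle', 'high'", call. = FALSE)
  }
  unname(ifelse(l > e, "descent", ifelse(l < e, "advancement", "no_change")))
}

#' Derive risk strata and all six mobility classifications
#'
#' Computes control-based tertile cutpoints for the three life-stage scores,
#' assigns `low`/`middle`/`high` strata to every subject, and appends the six
#' mobility columns: three occupational comparisons
#' (`mobility_father_training`, `mobility_father_last`,
#' `mobility_training_last`) and three score-stratum comparisons
#' (`mobility_child_adol`, `mobility_child_adult`, `mobility_adol_adult`).
#'
#' @param records scored subject table (see [add_scores()]); must contain at
#'   least one control.
#' @return `records` with stratum and mobility columns appended and a
#'   `"cutpoints"` attribute (named list of `q1`/`q2` pairs per life stage).
#' @export
add_mobility <- function(records) {
  is_control <- records$status == "control"
  if (!any(is_control)) stop("no controls: tertile cutpoints undefined",
                             call. = FALSE)
  cuts <- list(
    child = control_tertile_cutpoints(records$score_child[is_control]),
    adol = control_tertile_cutpoints(records$score_adol[is_control]),
    adult = control_tertile_cutpoints(records$score_adult[is_control])
  )
  records$childhood_stratum <- score_stratum(records$score_child, cuts$child)
  records$adolescence_stratum <- score_stratum(records$score_adol, cuts$adol)
  records$adulthood_stratum <- score_stratum(records$score_adult, cuts$adult)

  father <- profession_category(records$father_occupation, "father_occupation")
  training <- profession_category(records$professional_education,
                                  "professional_education")
  last <- profession_category(records$last_profession, "last_profession")
  records$mobility_father_training <- classify_profession_mobility(father, training)
  records$mobility_father_last <- classify_profession_mobility(father, last)
  # training vs last profession: the earlier position is the reference
  lvl <- LC_PROFESSION_LEVEL
  records$mobility_training_last <-
    unname(ifelse(lvl[last] > lvl[training], "advancement",
                  ifelse(lvl[last] < lvl[training], "descent", "no_change")))

  records$mobility_child_adol <-
    classify_score_mobility(records$childhood_stratum, records$adolescence_stratum)
  records$mobility_child_adult <-
    classify_score_mobility(records$childhood_stratum, records$adulthood_stratum)
  records$mobility_adol_adult <-
    classify_score_mobility(records$adolescence_stratum, records$adulthood_stratum)
  attr(records, "cutpoints") <- cuts
  records
}
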