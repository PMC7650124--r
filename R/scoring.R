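# Life-stage socioeconomic risk scores.
#
# Each score is an unweighted sum of per-item points; higher values mean more
# disadvantaged conditions. Point values follow the questionnaire coding of
# the underlying case-control study: childhood 0-12, adolescence 0-8,
# adulthood 0-8.

# Per-item point tables. Names are enum levels; values are points.
LC_POINTS <- list(
  father_occupation = c(academic = 0L, white_collar = 1L, blue_or_unskilled = 2L),
  mother_occupation = c(white_collar_or_academic_or_housewife = 0L,
                        blue_or_unskilled = 1L),
  family_structure = c(both_parents = 0L, one_parent = 1L, no_parents = 2L),
  rooms_per_person = c(gt1 = 0L, half_to_1 = 1L, lt_half = 2L),
  school_degree = c(high_school = 0L, middle_school = 2L, primary_school = 4L),
  professional_education = c(academic_exam = 0L, white_collar_degree = 1L,
                             skilled_worker = 2L, unskilled_incl_housewife = 4L),
  last_profession = c(academic = 0L, white_collar = 1L, skilled_blue_collar = 2L,
                      unskilled_incl_housewife = 4L)
)

# Look up points for an enum item, failing loudly on unknown levels.
enum_points <- function(values, item) {
  tab <- LC_POINTS[[item]]
  if (any(is.na(values))) {
    stop(sprintf("missing values in '%s'; impute first", item), call. = FALSE)
  }
  idx <- match(as.character(values), names(tab))
  if (anyNA(idx)) {
    bad <- unique(as.character(values)[is.na(idx)])
    stop(sprintf("unknown level(s) %s in field '%s' (allowed: %s)",
                 paste(sQuote(bad), collapse = ", "), item,
                 paste(names(tab), collapse = ", ")), call. = FALSE)
  }
  unname(tab[idx])
}

bool_points <- function(values, item) {
  if (any(is.na(values))) {
    stop(sprintf("missing values in '%s'; impute first", item), call. = FALSE)
  }
  v <- as.logical(values)
  if (anyNA(v)) stop(sprintf("non-boolean values in field '%s'", item), call. = FALSE)
  if (item %in% LC_BOOL_ADVANTAGE_TRUE) as.integer(!v) else as.integer(v)
}

#' Childhood socioeconomic risk score
#'
#' Sum of nine childhood items: paternal occupation (academic 0, non-academic
#' white collar 1, blue collar/unskilled 2), maternal occupation (white
#' collar/academic/housewife 0, blue collar/unskilled 1), family structure
#' (both parents 0, one parent 1, no parents 2), more than three siblings (1),
#' rooms per person (>1: 0, 0.5--1: 1, <0.5: 2), no toilet in the house (1),
#' no parental car (1), familial income in the lower half (1), and episodes of
#' paternal unemployment (1). Range 0 (advantaged) to 12 (disadvantaged).
#'
#' @param items data frame (or list of equal-length vectors) with the fields
#'   named in [LC_CHILDHOOD_ITEMS]. All fields must be non-missing.
#' @return integer vector of scores in `[0, 12]`.
#' @examples
#' score_childhood(data.frame(
#'   father_occupation = "blue_or_unskilled",
#'   mother_occupation = "white_collar_or_academic_or_housewife",
#'   family_structure = "one_parent", n_siblings = 2,
#'   rooms_per_person = "half_to_1", toilet_in_house = TRUE,
#'   parental_car = FALSE, income_upper_half = FALSE,
#'   paternal_unemployment = FALSE))  # 6
#' @export
score_childhood <- function(items) {
  if (anyNA(items$n_siblings)) {
    stop("missing values in 'n_siblings'; impute first", call. = FALSE)
  }
  if (any(items$n_siblings < 0)) {
    stop("'n_siblings' must be non-negative", call. = FALSE)
  }
  enum_points(items$father_occupation, "father_occupation") +
    enum_points(items$mother_occupation, "mother_occupation") +
    enum_points(items$family_structure, "family_structure") +
    as.integer(items$n_siblings > 3) +
    enum_points(items$rooms_per_person, "rooms_per_person") +
    bool_points(items$toilet_in_house, "toilet_in_house") +
    bool_points(items$parental_car, "parental_car") +
    bool_points(items$income_upper_half, "income_upper_half") +
    bool_points(items$paternal_unemployment, "paternal_unemployment")
}

#' Adolescence socioeconomic risk score
#'
#' Highest school degree (high school 0, middle school 2, primary school 4)
#' plus professional education (academic exam 0, non-academic white-collar
#' degree 1, skilled worker 2, unskilled including housewives 4).
#' Range 0 to 8; higher values indicate lower educational level.
#'
#' @param items data frame with fields named in [LC_ADOLESCENCE_ITEMS].
#' @return integer vector of scores in `[0, 8]`.
#' @export
score_adolescence <- function(items) {
  enum_points(items$school_degree, "school_degree") +
    enum_points(items$professional_education, "professional_education")
}

#' Adulthood socioeconomic risk score
#'
#' Last profession before stroke or retirement (academic 0, non-academic white
#' collar 1, skilled blue collar 2, unskilled including housewives 4), periods
#' of unemployment longer than six months (2), and not being married or
#' partnered (2). Range 0 to 8.
#'
#' @param items data frame with fields named in [LC_ADULTHOOD_ITEMS].
#' @return integer vector of scores in `[0, 8]`.
#' @export
score_adulthood <- function(items) {
  enum_points(items$last_profession, "last_profession") +
    2L * bool_points(items$unemployment_gt6mo, "unemployment_gt6mo") +
    2L * bool_points(items$partnered, "partnered")
}

#' Add the three life-stage scores to a subject table
#'
#' Convenience wrapper computing `score_child`, `score_adol` and `score_adult`
#' columns from the questionnaire items. Requires complete items (run
#' [impute_items()] first if the data contain missing cells).
#'
#' @param records subject-level data frame following [LC_SCHEMA].
#' @return `records` with three integer score columns appended.
#' @export
add_scores <- function(records) {
  records$score_child <- score_childhood(records)
  records$score_adol <- score_adolescence(records)
  records$score_adult <- score_adulthood(records)
  records
}

# Lower-risk-first orderings used as the deterministic imputation tie-break.
impute_candidates <- function(field) {
  if (field %in% names(LC_LEVELS)) return(LC_LEVELS[[field]])
  if (field %in% LC_BOOL_ADVANTAGE_TRUE) return(c(TRUE, FALSE))
  if (field %in% LC_BOOL_ADVANTAGE_FALSE) return(c(FALSE, TRUE))
  if (field %in% LC_RISK_FACTORS) return(c(0L, 1L))
  NULL # numeric: n_siblings, ordered ascending (fewer siblings = lower risk)
}

mode_lower_risk <- function(x, field) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NULL)
  if (field %in% LC_BOOL_ITEMS) x <- as.logical(x) # accept 0/1 or TRUE/FALSE
  cand <- impute_candidates(field)
  tab <- table(x)
  if (is.null(cand)) {
    vals <- sort(as.numeric(names(tab))) # ties -> smaller count
  } else {
    vals <- cand[as.character(cand) %in% names(tab)]
  }
  counts <- as.vector(tab[as.character(vals)])
  vals[which.max(counts)] # which.max keeps the first (lower-risk) maximum
}

#' Impute missing questionnaire items and risk factors
#'
#' Single-pass mode imputation: each missing cell in a socioeconomic item or
#' risk-factor column is replaced by the modal observed value within the
#' subject's sex by case/control cell, with ties broken deterministically
#' towards the lower-risk level. Cells that are entirely missing fall back to
#' the overall mode. Matching variables (`status`, `age_years`, `sex`) must be
#' complete; missingness there is a hard error. The alternative strategy
#' `complete_case` drops rows with any missing item instead.
#'
#' @param records subject-level data frame following [LC_SCHEMA].
#' @param strategy `"mode_cell"` (default) or `"complete_case"`.
#' @param seed integer; kept for interface stability (both strategies are
#'   deterministic, so the seed does not alter the result).
#' @return imputed data frame with an `"imputation_log"` attribute, a named
#'   integer vector of imputed-cell counts per field.
#' @export
impute_items <- function(records, strategy = c("mode_cell", "complete_case"),
                         seed = 1L) {
  strategy <- match.arg(strategy)
  mandatory <- c("status", "age_years", "sex")
  for (f in mandatory) {
    if (anyNA(records[[f]])) {
      stop(sprintf("missing values in mandatory field '%s'", f), call. = FALSE)
    }
  }
  fields <- c(LC_CHILDHOOD_ITEMS, LC_ADOLESCENCE_ITEMS, LC_ADULTHOOD_ITEMS,
              LC_RISK_FACTORS)
  fields <- intersect(fields, names(records))
  if (strategy == "complete_case") {
    keep <- !Reduce(`|`, lapply(records[fields], is.na))
    out <- records[keep, , drop = FALSE]
    log <- structure(integer(length(fields)), names = fields)
    attr(out, "imputation_log") <- log
    attr(out, "n_dropped") <- sum(!keep)
    return(out)
  }
  cell <- interaction(records$sex, records$status, drop = TRUE)
  log <- structure(integer(length(fields)), names = fields)
  for (f in fields) {
    miss <- is.na(records[[f]])
    if (!any(miss)) next
    log[[f]] <- sum(miss)
    overall <- mode_lower_risk(records[[f]], f)
    if (is.null(overall)) {
      stop(sprintf("field '%s' is entirely missing; cannot impute", f),
           call. = FALSE)
    }
    for (g in levels(cell)) {
      rows <- miss & cell == g
      if (!any(rows)) next
      fill <- mode_lower_risk(records[[f]][cell == g], f)
      if (is.null(fill)) fill <- overall
      if (is.logical(fill) && !is.logical(records[[f]])) fill <- as.integer(fill)
      records[[f]][rows] <- fill
    }
  }
  attr(records, "imputation_log") <- log
  records
}

#' Validate a subject-level table against the schema
#'
#' Checks column presence, enum levels, boolean/0-1 coding, `status`/`sex`
#' codes and the 18--80 age range. Returns (invisibly) a data frame of
#' row-level problems; with `stop_on_error = TRUE` any problem is an error.
#'
#' @param records data frame to check.
#' @param stop_on_error raise an error on the first report instead of
#'   returning it.
#' @return invisible data frame with columns `row`, `field`, `problem`.
#' @export
validate_records <- function(records, stop_on_error = FALSE) {
  missing_cols <- setdiff(LC_SCHEMA, names(records))
  if (length(missing_cols)) {
    stop(sprintf("missing mandatory column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  problems <- list()
  note <- function(rows, field, what) {
    if (length(rows)) {
      problems[[length(problems) + 1L]] <<-
        data.frame(row = rows, field = field, problem = what)
    }
  }
  note(which(!records$status %in% c("case", "control")), "status",
       "must be 'case' or 'control'")
  note(which(!records$sex %in% c("m", "f")), "sex", "must be 'm' or 'f'")
  note(which(!is.na(records$age_years) &
               (records$age_years < 18 | records$age_years > 80)),
       "age_years", "must lie in [18, 80]")
  note(which(is.na(records$age_years)), "age_years", "must not be missing")
  for (f in names(LC_LEVELS)) {
    bad <- which(!is.na(records[[f]]) &
                   !as.character(records[[f]]) %in% LC_LEVELS[[f]])
    note(bad, f, sprintf("not an allowed level (%s)",
                         paste(LC_LEVELS[[f]], collapse = ", ")))
  }
  for (f in c(LC_BOOL_ITEMS, LC_RISK_FACTORS)) {
    v <- records[[f]]
    ok <- is.na(v) | v %in% c(0, 1, TRUE, FALSE)
    note(which(!ok), f, "must be 0/1")
  }
  note(which(!is.na(records$n_siblings) & records$n_siblings < 0),
       "n_siblings", "must be non-negative")
  out <- if (length(problems)) do.call(rbind, problems) else
    data.frame(row = integer(), field = character(), problem = character())
  if (stop_on_error && nrow(out)) {
    stop(sprintf("validation failed: row %d, field '%s': %s (%d problem(s) total)",
                 out$row[1], out$field[1], out$problem[1], nrow(out)),
         call. = FALSE)
  }
  invisible(out)
}
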