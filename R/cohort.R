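# Age normalization and adolescent cohort extraction.

.age_unit_factor <- c(
  DEC = 10,           # decades
  YR  = 1,
  MON = 1 / 12,
  WK  = 1 / 52.1775,  # mean weeks per Julian year
  DY  = 1 / 365.25,
  HR  = 1 / 8766
)

#' Convert FAERS age values to years
#'
#' FAERS DEMO carries `age` together with a unit code `age_cod` (DEC, YR,
#' MON, WK, DY, HR). Unparseable values, unknown codes, and results outside
#' [0, 130] come back as `NA`; missingness is a value here, not an error.
#'
#' @param age_value character or numeric vector of raw age values.
#' @param age_code character vector of unit codes (recycled if length 1).
#' @return numeric vector of ages in years, `NA` where undetermined.
#' @export
normalize_age <- function(age_value, age_code) {
  val <- suppressWarnings(as.numeric(age_value))
  code <- toupper(trimws(as.character(age_code)))
  if (length(code) == 1L) code <- rep(code, length(val))
  fac <- unname(.age_unit_factor[code])
  yrs <- val * fac
  yrs[!is.finite(yrs) | yrs < 0 | yrs > 130] <- NA_real_
  yrs
}

#' Filter linked cases to the adolescent age window
#'
#' Retains cases with `min_years <= age_years < max_years_exclusive` on the
#' normalized real-valued age, so "12 to 17 years old" is the half-open
#' window [12, 18): a 17.8-year-old is 17 years old. Cases with missing age
#' are excluded by default; set `admit_missing_age_group` to also admit
#' missing-age cases (useful when an age-group code is trusted instead).
#'
#' @param cases a `faers_cases` object (ages already normalized at link time).
#' @param min_years lower bound in years, inclusive (default 12).
#' @param max_years_exclusive upper bound in years, exclusive (default 18).
#' @param admit_missing_age_group logical; admit missing-age cases
#'   (default `FALSE`).
#' @return a `faers_cohort`: the filtered cases plus a record of the filters
#'   applied and `n_cases`.
#' @export
filter_adolescent <- function(cases, min_years = 12, max_years_exclusive = 18,
                              admit_missing_age_group = FALSE) {
  stopifnot(inherits(cases, "faers_cases"))
  if (min_years >= max_years_exclusive) {
    stop_cfg("filter_adolescent: min_years (", min_years,
             ") must be below max_years_exclusive (", max_years_exclusive, ")")
  }
  age <- cases$demo$age_years
  keep <- !is.na(age) & age >= min_years & age < max_years_exclusive
  if (admit_missing_age_group) keep <- keep | is.na(age)
  out <- cases
  out$demo <- cases$demo[keep, , drop = FALSE]
  rownames(out$demo) <- NULL
  for (tab in c("drugs", "reactions", "indications", "outcomes", "sources")) {
    out[[tab]] <- out[[tab]][out[[tab]]$primaryid %in% out$demo$primaryid, , drop = FALSE]
  }
  structure(
    list(
      cases = out,
      filters = list(age_min_years = min_years,
                     age_max_years_exclusive = max_years_exclusive,
                     missing_age = if (admit_missing_age_group) "admitted" else "excluded",
                     quarters = sort(unique(cases$demo$quarter))),
      n_cases = nrow(out$demo)
    ),
    class = "faers_cohort"
  )
}

#' @export
print.faers_cohort <- function(x, ...) {
  cat("FAERS cohort:", x$n_cases, "cases; age window [",
      x$filters$age_min_years, ",", x$filters$age_max_years_exclusive, ")\n")
  invisible(x)
}

#' Sex breakdown of a set of cases
#'
#' Counts reports by sex code (unknown or blank codes count as undefined)
#' and attaches percentages rounded half-up to 1 decimal.
#'
#' @param x a `faers_cohort`, `faers_cases`, or a character vector of sex
#'   codes (`"male"`, `"female"`, anything else is undefined).
#' @return a `sex_breakdown`: list with `n_total`, `n_male`, `n_female`,
#'   `n_undefined` and `pct_*` fields (percentages `NA` on an empty input).
#' @export
sex_breakdown <- function(x) {
  sexes <-
    if (inherits(x, "faers_cohort")) x$cases$demo$sex
    else if (inherits(x, "faers_cases")) x$demo$sex
    else as.character(x)
  sexes[!(sexes %in% c("male", "female"))] <- "undefined"
  n <- length(sexes)
  nm <- sum(sexes == "male"); nf <- sum(sexes == "female")
  nu <- n - nm - nf
  pct <- function(k) if (n > 0) round_half_up(100 * k / n, 1) else NA_real_
  structure(
    list(n_total = n, n_male = nm, n_female = nf, n_undefined = nu,
         pct_male = pct(nm), pct_female = pct(nf), pct_undefined = pct(nu)),
    class = "sex_breakdown"
  )
}

#' @export
print.sex_breakdown <- function(x, ...) {
  cat(sprintf("n=%d (male=%d [%s%%], female=%d [%s%%], undefined=%d [%s%%])\n",
              x$n_total, x$n_male, x$pct_male, x$n_female, x$pct_female,
              x$n_undefined, x$pct_undefined))
  invisible(x)
}

#' Cohort summary as JSON
#'
#' @param cohort a `faers_cohort`.
#' @param path optional output path.
#' @return JSON string, invisibly when `path` is given.
#' @export
cohort_summary_json <- function(cohort, path = NULL) {
  stopifnot(inherits(cohort, "faers_cohort"))
  sb <- sex_breakdown(cohort)
  out <- list(n_cases = cohort$n_cases,
              sex = unclass(sb),
              filters = cohort$filters)
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
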