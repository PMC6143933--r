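# Designated-control disproportionality statistics.
#
# The case/non-case design here differs from the classic "all other events"
# ROR: eligibility is restricted to reports mentioning exactly one of the
# case event and a single designated control event (e.g. Diarrhoea, the most
# reported PT in the cohort). The 2x2 table is then
#
#               case event   control event
#   drug            a             b
#   no drug         c             d
#
# and ROR = (a/b)/(c/d) = ad/bc. PRR and RRR instead use the whole-cohort
# drug x event margins, matching how OpenVigil-style tools report them.

new_dispro_result <- function(drug, case_event, control_event, statistic,
                              estimate, ci_low, ci_high, p_value, method,
                              corrected = FALSE, unstable = FALSE,
                              closed_form = NULL) {
  structure(
    list(drug = drug, case_event = case_event, control_event = control_event,
         statistic = statistic, estimate = estimate,
         ci_low = ci_low, ci_high = ci_high, p_value = p_value,
         method = method, corrected = corrected, unstable = unstable,
         significant = is.finite(p_value) && p_value < 0.05,
         closed_form = closed_form),
    class = "dispro_result"
  )
}

#' @export
print.dispro_result <- function(x, ...) {
  cat(sprintf("%s %s [%s]: %.4g (95%% CI %.4g-%.4g), p=%.3g%s%s\n",
              x$statistic, x$drug %||% "", x$method, x$estimate,
              x$ci_low, x$ci_high, x$p_value,
              if (isTRUE(x$corrected)) " [Haldane-corrected]" else "",
              if (isTRUE(x$unstable)) " [UNSTABLE]" else ""))
  invisible(x)
}

#' Build the designated-control 2x2 table for one drug
#'
#' Eligible reports are cohort cases whose reaction list contains the case
#' event XOR the control event (matching is case-insensitive exact on the
#' preferred term). Cases mentioning both events have no defined outcome in
#' this design; they are excluded and counted. Cells split the eligible
#' reports by drug exposure under the role policy.
#'
#' @param cohort a `faers_cohort`.
#' @param drug normalized drug name defining exposure.
#' @param case_event,control_event MedDRA preferred terms; must differ.
#' @param roles `"all"` (default) or `"suspect"`.
#' @return a `contingency_table`: list with cells `a`, `b`, `c`, `d`, the
#'   PT labels, `n_both_excluded`, and `corrected = FALSE` (set by
#'   estimators when a zero cell forces the Haldane correction).
#' @export
build_contingency <- function(cohort, drug, case_event, control_event,
                              roles = c("all", "suspect")) {
  stopifnot(inherits(cohort, "faers_cohort"), is_string(drug))
  roles <- match.arg(roles)
  case_pt <- squash_upper(case_event)
  ctrl_pt <- squash_upper(control_event)
  if (identical(case_pt, ctrl_pt)) {
    stop_cfg("case event and control event must differ (both '", case_pt, "')")
  }
  reac <- cohort$cases$reactions
  ids_case <- unique(reac$primaryid[reac$pt == case_pt])
  ids_ctrl <- unique(reac$primaryid[reac$pt == ctrl_pt])
  both <- intersect(ids_case, ids_ctrl)
  only_case <- setdiff(ids_case, both)
  only_ctrl <- setdiff(ids_ctrl, both)
  if (!length(only_case) && !length(only_ctrl)) {
    stop_cfg("no eligible reports mention exactly one of '", case_pt,
             "' and '", ctrl_pt, "'")
  }
  exposed <- exposed_ids(cohort, drug, roles)
  contingency_table(
    a = sum(only_case %in% exposed), b = sum(only_ctrl %in% exposed),
    c = sum(!(only_case %in% exposed)), d = sum(!(only_ctrl %in% exposed)),
    drug = squash_upper(drug), case_event = case_pt, control_event = ctrl_pt,
    n_both_excluded = length(both)
  )
}

#' Construct a 2x2 contingency table from counts
#'
#' @param a,b,c,d nonnegative cell counts (drug/case, drug/control,
#'   no-drug/case, no-drug/control).
#' @param drug,case_event,control_event optional labels.
#' @param n_both_excluded reports mentioning both events (excluded upstream).
#' @return a `contingency_table` object.
#' @export
contingency_table <- function(a, b, c, d, drug = NA_character_,
                              case_event = NA_character_,
                              control_event = NA_character_,
                              n_both_excluded = 0L) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(!is.finite(cells))) {
    stop_cfg("contingency cells must be finite and nonnegative")
  }
  structure(
    list(drug = drug, case_event = case_event, control_event = control_event,
         a = a, b = b, c = c, d = d,
         n_both_excluded = n_both_excluded,
         corrected = FALSE),
    class = "contingency_table"
  )
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("2x2 [%s | %s vs %s]: a=%g b=%g c=%g d=%g (both-event excluded: %d)\n",
              x$drug, x$case_event, x$control_event, x$a, x$b, x$c, x$d,
              x$n_both_excluded))
  invisible(x)
}

haldane <- function(t) {
  cells <- c(t$a, t$b, t$c, t$d)
  if (any(cells == 0)) {
    t$a <- t$a + 0.5; t$b <- t$b + 0.5; t$c <- t$c + 0.5; t$d <- t$d + 0.5
    t$corrected <- TRUE
  }
  t
}

#' Closed-form reporting odds ratio
#'
#' Cross-ratio estimate ROR = ad/bc with a 95% Wald interval on the log
#' scale, SE(log ROR) = sqrt(1/a + 1/b + 1/c + 1/d), and a two-sided normal
#' p-value for log ROR = 0. If any raw cell is zero, 0.5 is added to all
#' four cells (Haldane-Anscombe) and the result flagged `corrected`.
#'
#' @param t a `contingency_table`.
#' @param conf_z normal quantile for the interval (1.96 exactly, for a 95%
#'   interval matching published precision).
#' @return a `dispro_result` with `statistic = "ROR"`,
#'   `method = "closed_form"`.
#' @export
ror_closed_form <- function(t, conf_z = 1.96) {
  stopifnot(inherits(t, "contingency_table"))
  t <- haldane(t)
  est <- (t$a * t$d) / (t$b * t$c)
  se <- sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d)
  z <- log(est) / se
  new_dispro_result(
    t$drug, t$case_event, t$control_event, "ROR",
    estimate = est,
    ci_low = exp(log(est) - conf_z * se),
    ci_high = exp(log(est) + conf_z * se),
    p_value = 2 * stats::pnorm(-abs(z)),
    method = "closed_form", corrected = t$corrected
  )
}

# Weighted logistic fit on the 4-row representation of a 2x2 table.
# For a single binary predictor this has the same likelihood as the
# per-report fit, so estimates and Wald SEs are identical.
logistic_fit_2x2 <- function(t) {
  df <- data.frame(y = c(1, 0, 1, 0), x = c(1, 1, 0, 0),
                   w = c(t$a, t$b, t$c, t$d))
  df <- df[df$w > 0, , drop = FALSE]
  fit <- suppressWarnings(stats::glm(
    y ~ x, family = stats::binomial(), data = df, weights = df$w,
    control = stats::glm.control(epsilon = 1e-12, maxit = 100)
  ))
  co <- summary(fit)$coefficients
  if (!("x" %in% rownames(co))) return(NULL)
  list(beta = co["x", "Estimate"], se = co["x", "Std. Error"],
       p = co["x", "Pr(>|z|)"], converged = fit$converged)
}

#' Reporting odds ratio by logistic regression
#'
#' Fits a binomial logistic model on the eligible reports (outcome 1 = case
#' event, 0 = control event; predictor = drug-exposure indicator) and
#' exponentiates the coefficient; CI and p-value are Wald. On an
#' all-positive table this coincides with [ror_closed_form()] exactly. A
#' zero margin means complete separation (or a degenerate fit): the result
#' is flagged `unstable` and carries the Haldane-corrected closed-form
#' result in `$closed_form`.
#'
#' @param cohort a `faers_cohort`, or a `contingency_table` built elsewhere.
#' @param drug,case_event,control_event,roles as in [build_contingency()]
#'   (ignored when `cohort` is already a table).
#' @param conf_z normal quantile for the interval (default 1.96).
#' @return a `dispro_result` with `method = "logistic"`.
#' @export
ror_logistic <- function(cohort, drug = NULL, case_event = NULL,
                         control_event = NULL, roles = c("all", "suspect"),
                         conf_z = 1.96) {
  t <- if (inherits(cohort, "contingency_table")) cohort
       else build_contingency(cohort, drug, case_event, control_event, roles)
  zero_cell <- any(c(t$a, t$b, t$c, t$d) == 0)
  cf <- ror_closed_form(t, conf_z)
  fit <- logistic_fit_2x2(t)
  if (zero_cell || is.null(fit) || !fit$converged) {
    res <- new_dispro_result(
      t$drug, t$case_event, t$control_event, "ROR",
      estimate = cf$estimate, ci_low = cf$ci_low, ci_high = cf$ci_high,
      p_value = cf$p_value, method = "logistic",
      corrected = TRUE, unstable = TRUE, closed_form = cf
    )
    return(res)
  }
  new_dispro_result(
    t$drug, t$case_event, t$control_event, "ROR",
    estimate = exp(fit$beta),
    ci_low = exp(fit$beta - conf_z * fit$se),
    ci_high = exp(fit$beta + conf_z * fit$se),
    p_value = fit$p, method = "logistic", closed_form = cf
  )
}

# Whole-cohort drug x event 2x2: a = drug & event, b = drug & !event,
# c = !drug & event, d = !drug & !event. Shared by PRR and RRR.
event_contingency <- function(cohort, drug, event, roles = c("all", "suspect")) {
  roles <- match.arg(roles)
  pt <- squash_upper(event)
  reac <- cohort$cases$reactions
  ids_event <- unique(reac$primaryid[reac$pt == pt])
  all_ids <- cohort$cases$demo$primaryid
  exposed <- exposed_ids(cohort, drug, roles)
  has_event <- all_ids %in% ids_event
  has_drug <- all_ids %in% exposed
  contingency_table(
    a = sum(has_drug & has_event), b = sum(has_drug & !has_event),
    c = sum(!has_drug & has_event), d = sum(!has_drug & !has_event),
    drug = squash_upper(drug), case_event = pt,
    control_event = "(all other reports)"
  )
}

#' Proportional reporting ratio
#'
#' Over all cohort reports, PRR compares the event's share among the drug's
#' reports to its share among all other reports:
#' PRR = (a/(a+b)) / (c/(c+d)), with Wald interval from
#' SE(log PRR) = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)). A zero in `a` or `c`
#' triggers the Haldane correction with a flag.
#'
#' @param cohort a `faers_cohort`, or a `contingency_table` whose cells are
#'   already the whole-cohort drug-by-event margins.
#' @param drug normalized drug name (ignored when `cohort` is a table).
#' @param event MedDRA preferred term (ignored when `cohort` is a table).
#' @param roles `"all"` (default) or `"suspect"`.
#' @param conf_z normal quantile (default 1.96).
#' @return a `dispro_result` with `statistic = "PRR"`.
#' @export
prr <- function(cohort, drug = NULL, event = NULL,
                roles = c("all", "suspect"), conf_z = 1.96) {
  t <- if (inherits(cohort, "contingency_table")) cohort
       else event_contingency(cohort, drug, event, roles)
  prr_from_table(t, conf_z)
}

prr_from_table <- function(t, conf_z = 1.96) {
  if (t$a == 0 || t$c == 0) t <- haldane(t)
  est <- (t$a / (t$a + t$b)) / (t$c / (t$c + t$d))
  se <- sqrt(1 / t$a - 1 / (t$a + t$b) + 1 / t$c - 1 / (t$c + t$d))
  z <- log(est) / se
  new_dispro_result(
    t$drug, t$case_event, t$control_event, "PRR",
    estimate = est,
    ci_low = exp(log(est) - conf_z * se),
    ci_high = exp(log(est) + conf_z * se),
    p_value = 2 * stats::pnorm(-abs(z)),
    method = "closed_form", corrected = t$corrected
  )
}

#' Relative reporting ratio
#'
#' Observed over expected report count under independence of drug and
#' event: RRR = a*N / (n_drug * n_event), with a Poisson-based interval
#' from SE(log RRR) = sqrt(1/a). `a = 0` triggers the Haldane correction
#' with a flag.
#'
#' @inheritParams prr
#' @return a `dispro_result` with `statistic = "RRR"`.
#' @export
rrr <- function(cohort, drug = NULL, event = NULL,
                roles = c("all", "suspect"), conf_z = 1.96) {
  t <- if (inherits(cohort, "contingency_table")) cohort
       else event_contingency(cohort, drug, event, roles)
  rrr_from_table(t, conf_z)
}

rrr_from_table <- function(t, conf_z = 1.96) {
  if (t$a == 0) t <- haldane(t)
  n <- t$a + t$b + t$c + t$d
  n_drug <- t$a + t$b
  n_event <- t$a + t$c
  est <- (t$a * n) / (n_drug * n_event)
  se <- sqrt(1 / t$a)
  z <- log(est) / se
  new_dispro_result(
    t$drug, t$case_event, t$control_event, "RRR",
    estimate = est,
    ci_low = exp(log(est) - conf_z * se),
    ci_high = exp(log(est) + conf_z * se),
    p_value = 2 * stats::pnorm(-abs(z)),
    method = "closed_form", corrected = t$corrected
  )
}

#' Geometric mean of Wald confidence bounds
#'
#' A Wald interval on the log-odds scale is symmetric around the log point
#' estimate, so the point estimate equals the geometric mean of the bounds:
#' `sqrt(ci_low * ci_high)`. Useful for checking published OR/CI triples for
#' internal (Wald) consistency.
#'
#' @param ci_low,ci_high positive confidence bounds.
#' @return numeric vector of geometric means.
#' @export
ci_geometric_mean <- function(ci_low, ci_high) {
  stopifnot(all(ci_low > 0), all(ci_high > 0))
  sqrt(ci_low * ci_high)
}

#' Scan a drug list against a case/control event pair
#'
#' Runs [ror_logistic()] for each drug against the same designated control,
#' skipping drugs with no exposed eligible reports (with a message), and
#' sorts results by estimate descending. Estimates below 1 indicate
#' association with the control event rather than the case event.
#'
#' @param cohort a `faers_cohort`.
#' @param case_event,control_event MedDRA preferred terms.
#' @param drugs non-empty character vector of normalized drug names.
#' @param roles `"all"` (default) or `"suspect"`.
#' @return a `dispro_scan`: data frame with one row per scanned drug
#'   (columns drug, case_event, control_event, statistic, estimate, ci_low,
#'   ci_high, p_value, corrected, unstable, significant).
#' @export
scan_drugs <- function(cohort, case_event, control_event, drugs,
                       roles = c("all", "suspect")) {
  stopifnot(inherits(cohort, "faers_cohort"))
  if (!length(drugs)) stop_cfg("scan_drugs: empty drug list")
  roles <- match.arg(roles)
  rows <- list()
  for (drug in drugs) {
    t <- build_contingency(cohort, drug, case_event, control_event, roles)
    if (t$a + t$b == 0) {
      message("scan_drugs: no exposed eligible reports for ", squash_upper(drug),
              "; skipped")
      next
    }
    r <- ror_logistic(t)
    rows[[length(rows) + 1L]] <- data.frame(
      drug = r$drug, case_event = r$case_event, control_event = r$control_event,
      statistic = r$statistic, estimate = r$estimate,
      ci_low = r$ci_low, ci_high = r$ci_high, p_value = r$p_value,
      corrected = r$corrected, unstable = r$unstable,
      significant = r$significant, stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(drug = character(0), case_event = character(0),
               control_event = character(0), statistic = character(0),
               estimate = numeric(0), ci_low = numeric(0), ci_high = numeric(0),
               p_value = numeric(0), corrected = logical(0),
               unstable = logical(0), significant = logical(0))
  out <- out[order(-out$estimate, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dispro_scan", class(out))
  out
}
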