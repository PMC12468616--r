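check_records <- function(records) {
  stopifnot(all(c("time_years", "event") %in% names(records)))
  if (nrow(records) == 0) abort("no survival records supplied")
  if (any(!is.finite(records$time_years)) || any(records$time_years <= 0))
    abort("time_years must be finite and positive")
  if (any(!records$event %in% c(0, 1)))
    abort("event must be 0 (censored) or 1 (death)")
  records
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator for right-censored data (via
#' `survival::survfit`), with 95% confidence bands from the Greenwood
#' variance on the log-log scale. Ties at an event time decrement the curve
#' simultaneously.
#'
#' @param records Data frame with `time_years` (> 0) and `event` (0 =
#'   censored, 1 = death).
#' @return An object of class `km_curve`; `$curve` is a tibble with `time`,
#'   `n_risk`, `n_event`, `survival`, `ci_lower`, `ci_upper`.
#' @export
#' @examples
#' km_estimate(data.frame(time_years = 1:3, event = 1))$curve
km_estimate <- function(records) {
  records <- check_records(records)
  fit <- survival::survfit(
    survival::Surv(time_years, event) ~ 1,
    data = records, conf.int = 0.95, conf.type = "log-log")
  s <- summary(fit, censored = TRUE)
  curve <- tibble::tibble(time = s$time, n_risk = s$n.risk,
                          n_event = s$n.event, survival = s$surv,
                          ci_lower = ifelse(is.na(s$lower), 0, s$lower),
                          ci_upper = ifelse(is.na(s$upper), 1, s$upper))
  structure(list(curve = curve, n = nrow(records), fit = fit),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve n=%d, %d times, median=%s>\n", x$n,
              nrow(x$curve), format(median_survival(x))))
  invisible(x)
}

#' @describeIn km_estimate Tidy the step curve into a tibble.
#' @param x A `km_curve`.
#' @param ... Unused.
#' @export
tidy.km_curve <- function(x, ...) x$curve

#' Median survival time of a Kaplan-Meier curve
#'
#' The smallest observed time at which the survival estimate drops to 0.5
#' or below; `NA` when the curve never reaches 0.5 (median not attained).
#'
#' @param curve A `km_curve` from [km_estimate()].
#' @return Median survival in the curve's time units, or `NA`.
#' @export
median_survival <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  hit <- curve$curve$time[curve$curve$survival <= 0.5]
  if (length(hit) == 0) NA_real_ else min(hit)
}

#' Log-rank test between survival groups
#'
#' Standard log-rank chi-square comparison (via `survival::survdiff`) of
#' two or more right-censored groups, e.g. predicted grade strata.
#'
#' @param records Data frame with `time_years`, `event` and a grouping
#'   column.
#' @param group_col Name of the grouping column.
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @export
logrank <- function(records, group_col = "group") {
  records <- check_records(records)
  stopifnot(group_col %in% names(records))
  g <- factor(records[[group_col]])
  if (nlevels(droplevels(g)) < 2)
    abort("log-rank comparison needs at least two non-empty groups")
  fit <- survival::survdiff(
    survival::Surv(records$time_years, records$event) ~ g)
  df <- length(fit$n) - 1
  tibble::tibble(statistic = fit$chisq, df = df,
                 p_value = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Harrell's concordance index
#'
#' The fraction of admissible patient pairs whose risk ordering agrees with
#' their survival ordering. A pair is admissible when the shorter observed
#' time ends in an event (tied observed times are not compared); it is
#' concordant when the patient with the shorter survival has the higher
#' risk, and tied risks credit 0.5. Grades act as ordinal risk scores
#' (G1 < G2 < G3) when evaluating graded cohorts.
#'
#' @param risk Numeric risk scores aligned with `records` (higher = worse).
#' @param records Data frame with `time_years` and `event`.
#' @return Concordance index in \[0, 1\].
#' @export
#' @examples
#' d <- data.frame(time_years = c(5, 3, 1), event = 1)
#' harrell_c_index(c(1, 2, 3), d) # perfectly anti-ordered: 1
harrell_c_index <- function(risk, records) {
  records <- check_records(records)
  if (length(risk) != nrow(records))
    abort("risk must align with records")
  t <- records$time_years; e <- records$event
  n <- length(t)
  # pair (i, j): i has the shorter time and an event
  ti <- rep(t, each = n); tj <- rep(t, times = n)
  ei <- rep(e, each = n)
  ri <- rep(risk, each = n); rj <- rep(risk, times = n)
  adm <- ti < tj & ei == 1
  if (!any(adm)) abort("no admissible pairs (all times tied or censored)")
  conc <- sum(ri[adm] > rj[adm]) + 0.5 * sum(ri[adm] == rj[adm])
  conc / sum(adm)
}

#' Survival stratification metrics for a graded cohort
#'
#' Convenience wrapper computing, for a cohort with a grade (or risk)
#' column: the Harrell c-index of the grade used as an ordinal risk score,
#' per-grade Kaplan-Meier median survival, and the log-rank p-value across
#' grades.
#'
#' @param cohort Data frame with `time_years`, `event` and `group_col`.
#' @param group_col Grouping/risk column (default `"grade"`).
#' @return A list: `c_index`, `medians` (tibble group/median/n), `logrank`
#'   (tibble).
#' @export
survival_metrics <- function(cohort, group_col = "grade") {
  cohort <- check_records(cohort)
  stopifnot(group_col %in% names(cohort))
  medians <- cohort |>
    dplyr::group_by(.data[[group_col]]) |>
    dplyr::group_modify(function(d, key)
      tibble::tibble(median_years = median_survival(km_estimate(d)),
                     n = nrow(d))) |>
    dplyr::ungroup()
  list(c_index = harrell_c_index(as.numeric(cohort[[group_col]]), cohort),
       medians = medians,
       logrank = logrank(cohort, group_col))
}
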