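#' Construct a survival table
#'
#' @param patient_id unique patient identifiers.
#' @param time positive follow-up times.
#' @param event 1 = death, 0 = censored.
#' @param time_unit `"years"`, `"months"` or `"days"`; recorded so that a
#'   horizon expressed in years can be converted when censoring.
#' @return data.frame with attribute `time_unit`.
#' @export
survival_table <- function(patient_id, time, event, time_unit = "years") {
  stopifnot(!anyDuplicated(patient_id), all(time > 0),
            all(event %in% c(0, 1)),
            time_unit %in% c("years", "months", "days"))
  structure(data.frame(patient_id = as.character(patient_id),
                       time = as.numeric(time), event = as.integer(event),
                       stringsAsFactors = FALSE),
            time_unit = time_unit)
}

.horizon_in_units <- function(horizon_years, time_unit) {
  horizon_years * switch(time_unit, years = 1, months = 12, days = 365.25)
}

#' Administrative censoring at a fixed horizon
#'
#' Events after the horizon are treated as censored at the horizon, so that
#' "5-year survival" analyses ignore later follow-up.
#'
#' @param surv a [survival_table()].
#' @param horizon_years horizon in years.
#' @return censored survival table (same attributes).
#' @export
administrative_censor <- function(surv, horizon_years) {
  unit <- attr(surv, "time_unit") %||% "years"
  h <- .horizon_in_units(horizon_years, unit)
  out <- surv
  out$event[out$time > h] <- 0L
  out$time <- pmin(out$time, h)
  attr(out, "time_unit") <- unit
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Kaplan-Meier product-limit survival curve
#'
#' @param time follow-up times.
#' @param event event indicators (1 death, 0 censored).
#' @return data.frame `time`, `n_risk`, `n_event`, `n_censor`, `surv`; the
#'   curve starts at 1 and steps down only at event times.
#' @export
km_curve <- function(time, event) {
  if (length(time) < 1L) stop("km_curve needs at least one subject")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard two-group log-rank chi-square with one degree of freedom. With
#' no events in either group the statistic is undefined and reported as
#' missing.
#'
#' @param time_a,event_a follow-up and event indicator for group A.
#' @param time_b,event_b follow-up and event indicator for group B.
#' @return list `statistic`, `df`, `p`, `n`, `n_events`.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (length(time_a) == 0L || length(time_b) == 0L) {
    stop("both groups must be non-empty")
  }
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c("a", "b"), c(length(time_a), length(time_b)))
  n_events <- sum(event)
  if (n_events == 0L) {
    message("logrank_test: no events; statistic undefined")
    return(list(statistic = NA_real_, df = 1L, p = NA_real_,
                n = length(time), n_events = 0L))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  list(statistic = unname(sd$chisq), df = 1L,
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       n = length(time), n_events = n_events)
}

#' Compare survival between extreme expression quartiles
#'
#' Splits patients at the empirical quartiles of an expression covariate —
#' the low group at or below Q1, the high group at or above Q3 (ties
#' included on the closed side, the middle half excluded) — administratively
#' censors follow-up at the horizon, and compares the two groups'
#' Kaplan-Meier curves with a log-rank test.
#'
#' @param expression named numeric vector (names = patient ids).
#' @param surv a [survival_table()].
#' @param horizon_years truncation horizon in years; default 5.
#' @return list with `cutpoints` (Q1, Q3), `n_low`, `n_high`, `statistic`,
#'   `p`, `curves` (list of KM data.frames `low`, `high`) and
#'   `horizon_years`.
#' @export
quartile_km_compare <- function(expression, surv, horizon_years = 5) {
  ids <- intersect(names(expression), surv$patient_id)
  if (length(ids) < 8L) {
    stop("quartile comparison needs at least 8 patients with expression")
  }
  expr <- expression[ids]
  s <- surv[match(ids, surv$patient_id), ]
  attr(s, "time_unit") <- attr(surv, "time_unit") %||% "years"
  qs <- stats::quantile(expr, c(0.25, 0.75), names = FALSE)
  if (qs[1] == qs[2]) stop("no quartile separation in expression values")
  low <- expr <= qs[1]
  high <- expr >= qs[2]
  s <- administrative_censor(s, horizon_years)
  lr <- logrank_test(s$time[low], s$event[low], s$time[high], s$event[high])
  list(cutpoints = c(q1 = qs[1], q3 = qs[2]),
       n_low = sum(low), n_high = sum(high),
       statistic = lr$statistic, p = lr$p,
       curves = list(low = km_curve(s$time[low], s$event[low]),
                     high = km_curve(s$time[high], s$event[high])),
       horizon_years = horizon_years)
}

#' Single-covariate Cox proportional-hazards fit
#'
#' Fits a proportional-hazards model with expression as a continuous
#' predictor. By default expression is standardized (z-scored) first, so
#' hazard ratios are per standard deviation and comparable across units;
#' set `standardize = FALSE` for raw-scale coefficients. The partial
#' likelihood is maximized by Newton iteration (convergence tolerance 1e-9
#' on the log-likelihood, at most 50 iterations); monotone-likelihood /
#' non-convergent fits are flagged rather than silently reported.
#'
#' @param expression named numeric vector (names = patient ids).
#' @param surv a [survival_table()].
#' @param ties `"efron"` (default, more accurate with tied event times) or
#'   `"breslow"`.
#' @param standardize z-score the expression before fitting.
#' @param horizon_years optional administrative censoring horizon.
#' @param unit label carried into the result row.
#' @return one-row data.frame: `unit`, `HR`, `beta`, `se`, `p`, `ci_lower`,
#'   `ci_upper`, `n`, `n_events`, `converged`.
#' @export
cox_fit <- function(expression, surv, ties = c("efron", "breslow"),
                    standardize = TRUE, horizon_years = NULL,
                    unit = NA_character_) {
  ties <- match.arg(ties)
  ids <- intersect(names(expression), surv$patient_id)
  x <- expression[ids]
  s <- surv[match(ids, surv$patient_id), ]
  attr(s, "time_unit") <- attr(surv, "time_unit") %||% "years"
  if (!is.null(horizon_years)) s <- administrative_censor(s, horizon_years)
  if (sum(s$event) < 1L) stop("cox_fit needs at least one event")
  if (stats::sd(x) == 0) stop("expression does not vary")
  if (standardize) x <- (x - mean(x)) / stats::sd(x)

  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(s$time, s$event) ~ x, ties = ties,
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15) flagged <- TRUE
  if (flagged) {
    warning("cox_fit: possible non-convergence or monotone likelihood",
            if (!is.na(unit)) paste0(" for unit ", unit), call. = FALSE)
  }
  z <- beta / se
  data.frame(unit = unit, HR = exp(beta), beta = beta, se = se,
             p = 2 * stats::pnorm(-abs(z)),
             ci_lower = exp(beta - stats::qnorm(0.975) * se),
             ci_upper = exp(beta + stats::qnorm(0.975) * se),
             n = length(ids), n_events = sum(s$event),
             converged = !flagged, stringsAsFactors = FALSE)
}

#' Hazard screen over genes or families
#'
#' Fits one single-covariate Cox model per unit (row of the expression
#' matrix) after administrative censoring at the horizon, and returns the
#' results ordered from highest to lowest hazard ratio. Significance is
#' flagged on the raw p-value at `alpha`; Benjamini-Hochberg adjusted
#' q-values are reported alongside. Units whose fits fail are recorded with
#' a reason and the screen continues.
#'
#' @param expr_matrix units x patients numeric matrix (dimnames required).
#' @param surv a [survival_table()].
#' @param horizon_years administrative censoring horizon; default 5.
#' @param alpha raw-p significance level; default 0.05.
#' @param ties,standardize passed to [cox_fit()].
#' @return data.frame, one row per unit, ordered by HR descending: columns
#'   of [cox_fit()] plus `q`, `significant` and `reason`.
#' @export
survival_screen <- function(expr_matrix, surv, horizon_years = 5,
                            alpha = 0.05, ties = "efron",
                            standardize = TRUE) {
  units <- rownames(expr_matrix)
  empty <- data.frame(unit = character(0), HR = numeric(0), beta = numeric(0),
                      se = numeric(0), p = numeric(0), ci_lower = numeric(0),
                      ci_upper = numeric(0), n = integer(0),
                      n_events = integer(0), converged = logical(0),
                      q = numeric(0), significant = logical(0),
                      reason = character(0), stringsAsFactors = FALSE)
  if (is.null(units) || nrow(expr_matrix) == 0L) return(empty)
  rows <- lapply(units, function(u) {
    x <- expr_matrix[u, ]
    names(x) <- colnames(expr_matrix)
    tryCatch({
      r <- suppressWarnings(
        cox_fit(x, surv, ties = ties, standardize = standardize,
                horizon_years = horizon_years, unit = u))
      r$reason <- NA_character_
      r
    }, error = function(e) {
      data.frame(unit = u, HR = NA_real_, beta = NA_real_, se = NA_real_,
                 p = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
                 n = NA_integer_, n_events = NA_integer_, converged = FALSE,
                 reason = conditionMessage(e), stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$p) & out$p < alpha
  out <- out[order(-out$HR, na.last = TRUE), ]
  rownames(out) <- NULL
  out[c("unit", "HR", "beta", "se", "p", "q", "ci_lower", "ci_upper",
        "n", "n_events", "significant", "converged", "reason")]
}
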