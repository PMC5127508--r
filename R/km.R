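#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over the distinct event times
#' `t_i`, with `d_i` events and `n_i` samples at risk. Censored samples
#' leave the risk set without producing a drop; when a censoring time ties
#' an event time, the event is counted first (the censored sample is still
#' at risk at that time).
#'
#' @param time observed months (>= 0).
#' @param event logical, TRUE = death observed.
#' @return object of class `km_curve`: data.frame with columns `time`
#'   (distinct event times), `n_risk`, `n_event`, `surv`; attributes `n`
#'   (samples) and `n_event` (total events). The curve starts at S = 1 at
#'   time 0 implicitly.
#' @export
kaplan_meier <- function(time, event) {
  if (!length(time)) stopf("empty survival data")
  if (any(is.na(time)) || any(time < 0)) stopf("times must be >= 0 and non-missing")
  event <- as.logical(event)
  ut <- sort(unique(time[event]))
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  out <- data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                    surv = surv)
  attr(out, "n") <- length(time)
  attr(out, "n_event") <- sum(event)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Median survival from a Kaplan-Meier curve
#'
#' The smallest time at which the estimated survival reaches 0.5 or below.
#' Returns NA ("not reached") when the curve never crosses 0.5 — common
#' under heavy censoring.
#'
#' @param curve a `km_curve`.
#' @return months, or NA when the median is not reached.
#' @export
median_survival <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  i <- which(curve$surv <= 0.5 + 1e-12)
  if (!length(i)) return(NA_real_)
  curve$time[i[1]]
}

#' Restricted mean survival time from a Kaplan-Meier curve
#'
#' Area under the survival step function from 0 to `tau`. Used as the
#' fallback group-contrast when a median is not reached.
#'
#' @param curve a `km_curve`.
#' @param tau restriction horizon in months.
#' @return months.
#' @export
restricted_mean <- function(curve, tau) {
  stopifnot(inherits(curve, "km_curve"), tau >= 0)
  times <- c(0, curve$time[curve$time < tau], tau)
  s <- c(1, curve$surv[curve$time < tau])
  sum(s * diff(times))
}

#' Two-group log-rank test
#'
#' Unweighted log-rank: at each pooled distinct event time a 2x2 table of
#' events by group gives observed minus expected events under the
#' hypergeometric null; `chi2 = (sum O - sum E)^2 / sum V` is referred to
#' chi-square with 1 df. The sign of `sum O - sum E` for group A is
#' reported so the direction of a survival difference is visible.
#'
#' @param time_a,event_a,time_b,event_b observed months and event flags for
#'   the two groups.
#' @return list with `chi2`, `p`, `observed` and `expected` events in group
#'   A, and `direction` (sign of O - E for group A; positive = group A has
#'   more events than expected, i.e. worse survival).
#' @export
log_rank <- function(time_a, event_a, time_b, event_b) {
  if (!length(time_a) || !length(time_b)) stopf("both groups must be nonempty")
  event_a <- as.logical(event_a); event_b <- as.logical(event_b)
  d_tot <- sum(event_a) + sum(event_b)
  if (d_tot == 0) stopf("log-rank needs at least one event")
  ut <- sort(unique(c(time_a[event_a], time_b[event_b])))
  O <- E <- V <- 0
  for (t in ut) {
    n1 <- sum(time_a >= t); n2 <- sum(time_b >= t)
    d1 <- sum(time_a == t & event_a); d2 <- sum(time_b == t & event_b)
    n <- n1 + n2; d <- d1 + d2
    if (n < 1 || d < 1) next
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (V > 0) (O - E)^2 / V else 0
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  list(chi2 = chi2, p = p, observed = O, expected = E,
       direction = sign(O - E))
}

#' Compare survival of aberrant vs non-aberrant samples
#'
#' Splits the cohort by a per-sample aberrance label (optionally after
#' restricting to a set of tumor grades), estimates a Kaplan-Meier curve
#' and median survival per group, and tests the split with the log-rank
#' test. Degenerate splits (an empty group, or no events) are returned
#' flagged `comparable = FALSE` rather than erroring, so grade strata that
#' collapse are reported as such.
#'
#' @param clinical clinical table (see [read_clinical()]).
#' @param labels named logical vector: TRUE = sample aberrant. Names are
#'   matched to `clinical$sample_id`; an unnamed vector must align with the
#'   clinical rows.
#' @param grades optional character vector of grades to keep (e.g.
#'   `c("II", "III")`).
#' @return object of class `aberrance_comparison`: list with per-group
#'   `curves`, `medians`, `median_difference` (NA when either median is not
#'   reached), `rmst_difference` (restricted-mean fallback contrast),
#'   `logrank` (chi2, p, direction), `n`, `n_event`, and `comparable`.
#' @export
compare_by_aberrance <- function(clinical, labels, grades = NULL) {
  if (!is.null(names(labels))) {
    lab <- labels[match(clinical$sample_id, names(labels))]
  } else {
    if (length(labels) != nrow(clinical))
      stopf("unnamed labels must match clinical rows")
    lab <- labels
  }
  keep <- !is.na(lab) & !is.na(clinical$os_months)
  if (!is.null(grades)) keep <- keep & clinical$grade %in% grades
  cl <- clinical[keep, , drop = FALSE]
  lab <- lab[keep]
  not_comparable <- function(reason) {
    structure(list(comparable = FALSE, reason = reason,
                   n = c(aberrant = sum(lab), non_aberrant = sum(!lab)),
                   grades = grades),
              class = "aberrance_comparison")
  }
  if (!nrow(cl)) return(not_comparable("no samples after filtering"))
  if (!any(lab)) return(not_comparable("no aberrant samples"))
  if (all(lab)) return(not_comparable("no non-aberrant samples"))
  if (sum(cl$event) == 0) return(not_comparable("no events"))
  ca <- kaplan_meier(cl$os_months[lab], cl$event[lab])
  cn <- kaplan_meier(cl$os_months[!lab], cl$event[!lab])
  med <- c(aberrant = median_survival(ca), non_aberrant = median_survival(cn))
  tau <- max(cl$os_months)
  rmst <- c(aberrant = restricted_mean(ca, tau),
            non_aberrant = restricted_mean(cn, tau))
  lr <- log_rank(cl$os_months[lab], cl$event[lab],
                 cl$os_months[!lab], cl$event[!lab])
  structure(list(
    comparable = TRUE,
    curves = list(aberrant = ca, non_aberrant = cn),
    medians = med,
    median_difference = if (anyNA(med)) NA_real_ else abs(diff(med)),
    rmst = rmst,
    rmst_difference = abs(diff(rmst)),
    logrank = lr,
    n = c(aberrant = sum(lab), non_aberrant = sum(!lab)),
    n_event = c(aberrant = sum(cl$event[lab]),
                non_aberrant = sum(cl$event[!lab])),
    grades = grades
  ), class = "aberrance_comparison")
}

#' @export
print.aberrance_comparison <- function(x, ...) {
  if (!x$comparable) {
    cat(sprintf("aberrance comparison: not comparable (%s)\n", x$reason))
    return(invisible(x))
  }
  fmt <- function(m) if (is.na(m)) "not reached" else sprintf("%.2f", m)
  cat(sprintf("aberrant (n=%d): median %s months | non-aberrant (n=%d): median %s months\n",
              x$n[["aberrant"]], fmt(x$medians[["aberrant"]]),
              x$n[["non_aberrant"]], fmt(x$medians[["non_aberrant"]])))
  cat(sprintf("log-rank chi2 = %.3f, p = %.4g\n", x$logrank$chi2, x$logrank$p))
  invisible(x)
}

#' Export Kaplan-Meier curve coordinates for plotting
#'
#' @param comparison an `aberrance_comparison`.
#' @return data.frame with columns `time`, `surv`, `group`, including the
#'   (0, 1) anchor of each curve.
#' @export
km_coordinates <- function(comparison) {
  stopifnot(inherits(comparison, "aberrance_comparison"), comparison$comparable)
  one <- function(curve, group)
    data.frame(time = c(0, curve$time), surv = c(1, curve$surv),
               group = group, stringsAsFactors = FALSE)
  rbind(one(comparison$curves$aberrant, "aberrant"),
        one(comparison$curves$non_aberrant, "non_aberrant"))
}
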