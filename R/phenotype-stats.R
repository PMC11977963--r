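#' Apply the worm censoring taxonomy to raw survival records
#'
#' Deaths enter the analysis set as events at their observed time; animals
#' that crawled off the plate, bagged, or displayed a protruding vulva enter
#' as right-censored at their removal time. The exclusion log counts each
#' censoring fate per group.
#'
#' @param raw data frame with columns `animal_id`, `group`, `time`, `fate`
#'   (see [survival_fates()]).
#' @return list with `analysis` (the input plus a 0/1 `status` column,
#'   1 = death) and `exclusion_log` (counts per group x censoring fate).
#' @export
apply_censoring <- function(raw) {
  need <- c("animal_id", "group", "time", "fate")
  stopifnot(is.data.frame(raw), all(need %in% names(raw)), all(raw$time > 0))
  bad <- setdiff(unique(raw$fate), survival_fates())
  if (length(bad) > 0)
    abort_ss(paste0("unknown fate code(s): ", paste(bad, collapse = ", ")),
             "unknown_fate")
  analysis <- raw
  analysis$status <- as.integer(raw$fate == "death")
  cens <- raw[raw$fate != "death", , drop = FALSE]
  log_tab <- if (nrow(cens) > 0) {
    as.data.frame(table(group = cens$group, fate = cens$fate),
                  stringsAsFactors = FALSE)
  } else {
    data.frame(group = character(), fate = character(), Freq = integer())
  }
  names(log_tab)[3] <- "n"
  log_tab <- log_tab[log_tab$n > 0, , drop = FALSE]
  rownames(log_tab) <- NULL
  list(analysis = analysis, exclusion_log = log_tab)
}

#' Kaplan-Meier product-limit survival curve
#'
#' @param records data frame of survival records ([apply_censoring()] is
#'   applied internally when no `status` column is present).
#' @return data frame of class `km_curve` with columns `time`, `n_risk`,
#'   `n_event`, `survival`; a right-continuous step function with S = 1
#'   before the first event. If all animals are censored the curve is the
#'   degenerate S == 1 and a warning is raised.
#' @export
km_estimate <- function(records) {
  if (!"status" %in% names(records)) records <- apply_censoring(records)$analysis
  stopifnot(nrow(records) >= 1L)
  if (sum(records$status) == 0L)
    warning("no death events: Kaplan-Meier curve is degenerate (S == 1)")
  fit <- survival::survfit(survival::Surv(time, status) ~ 1, data = records)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, survival = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param curve a [km_estimate()] result.
#' @param times numeric vector of times.
#' @return survival probabilities (right-continuous step convention).
#' @export
km_survival_at <- function(curve, times) {
  stopifnot(inherits(curve, "km_curve"))
  ev <- curve[curve$n_event > 0, , drop = FALSE]
  vapply(times, function(t) {
    below <- ev$time <= t
    if (!any(below)) 1 else ev$survival[max(which(below))]
  }, numeric(1))
}

#' Log-rank (Mantel-Cox) test between two survival curves
#'
#' One-degree-of-freedom log-rank statistic over pooled event times; tied
#' events are handled by the standard aggregated risk-set expectations and
#' variances at each distinct time (daily scoring of worm assays guarantees
#' heavy ties).
#'
#' @param group_a,group_b survival record data frames (each must contain at
#'   least one death event).
#' @return list with `chi2`, `p` (from chi-square with 1 df), and the event
#'   counts per group.
#' @export
logrank_test <- function(group_a, group_b) {
  a <- if ("status" %in% names(group_a)) group_a else apply_censoring(group_a)$analysis
  b <- if ("status" %in% names(group_b)) group_b else apply_censoring(group_b)$analysis
  if (sum(a$status) == 0L || sum(b$status) == 0L)
    abort_ss("log-rank undefined: a group has zero death events", "no_events")
  pooled <- data.frame(
    time = c(a$time, b$time), status = c(a$status, b$status),
    arm = rep(c("a", "b"), c(nrow(a), nrow(b)))
  )
  sd_fit <- survival::survdiff(survival::Surv(time, status) ~ arm, data = pooled)
  chi2 <- unname(sd_fit$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       n_events = unname(sd_fit$obs))
}

#' Mean-lifespan comparison between two arms
#'
#' Mean lifespan is the arithmetic mean of death times over event animals
#' only (censored animals are excluded from the mean, not imputed);
#' `mean_policy = "restricted"` uses the restricted mean survival time from
#' the Kaplan-Meier fit instead. Percent extension is
#' `100 * (treated_mean - control_mean) / control_mean`; the log-rank test is
#' attached.
#'
#' @param control,treated survival record data frames.
#' @param mean_policy `"events-only"` (default) or `"restricted"`.
#' @return an object of class `lifespan_comparison` with means, percent
#'   extension, log-rank chi2 and p, and arm sizes.
#' @export
lifespan_comparison <- function(control, treated,
                                mean_policy = c("events-only", "restricted")) {
  mean_policy <- match.arg(mean_policy)
  ctrl <- if ("status" %in% names(control)) control else apply_censoring(control)$analysis
  trt <- if ("status" %in% names(treated)) treated else apply_censoring(treated)$analysis
  if (sum(ctrl$status) < 2L || sum(trt$status) < 2L)
    abort_ss("each arm needs at least two death events", "too_few_events")
  arm_mean <- function(d) {
    if (mean_policy == "events-only") return(mean(d$time[d$status == 1L]))
    fit <- survival::survfit(survival::Surv(time, status) ~ 1, data = d)
    unname(summary(fit, rmean = max(d$time))$table["rmean"])
  }
  cm <- arm_mean(ctrl)
  tm <- arm_mean(trt)
  lr <- logrank_test(ctrl, trt)
  structure(list(
    control_mean = cm, treated_mean = tm,
    percent_extension = 100 * (tm - cm) / cm,
    logrank_chi2 = lr$chi2, logrank_p = lr$p,
    n_control = nrow(ctrl), n_treated = nrow(trt),
    mean_policy = mean_policy
  ), class = "lifespan_comparison")
}

#' Pearson chi-square test on a morphology contingency table
#'
#' Groups x morphology-class contingency test (e.g. tubular / intermediate /
#' fragmented mitochondria), without continuity correction, with
#' `dof = (rows - 1) * (cols - 1)`.
#'
#' @param counts contingency matrix of non-negative counts with positive row
#'   and column sums.
#' @return list with `chi2`, `dof`, `p`.
#' @export
chi_square_morphology <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0), nrow(counts) >= 2L, ncol(counts) >= 2L)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    abort_ss("zero marginal in the contingency table", "zero_marginal")
  ct <- stats::chisq.test(counts, correct = FALSE)
  if (any(ct$expected <= 0))
    abort_ss("expected counts must be positive", "zero_marginal")
  list(chi2 = unname(ct$statistic), dof = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Relative intestinal width
#'
#' `(intestinal_width - luminal_width) / body_width`; dimensionless, so any
#' common length unit (pixels or micrometres) cancels.
#'
#' @param intestinal_width,luminal_width,body_width non-negative widths with
#'   `intestinal_width >= luminal_width` and `body_width > 0` (vectorized).
#' @return fraction(s).
#' @export
relative_intestinal_width <- function(intestinal_width, luminal_width,
                                      body_width) {
  if (any(body_width <= 0))
    abort_ss("body width must be positive", "bad_width")
  if (any(luminal_width < 0) || any(intestinal_width < luminal_width))
    abort_ss("need intestinal_width >= luminal_width >= 0", "bad_width")
  (intestinal_width - luminal_width) / body_width
}

#' Growth-inhibition ratio from absorbance readings
#'
#' Blank-corrected complement of relative viability (CCK-8 style):
#' `100 * (1 - (treated - blank) / (control - blank))`.
#'
#' @param absorbance_treated,absorbance_control,absorbance_blank absorbance
#'   readings (AU); `absorbance_control > absorbance_blank` required.
#' @return inhibition percentage(s).
#' @export
inhibition_ratio <- function(absorbance_treated, absorbance_control,
                             absorbance_blank) {
  if (any(absorbance_control <= absorbance_blank))
    abort_ss("control absorbance must exceed blank", "bad_absorbance")
  100 * (1 - (absorbance_treated - absorbance_blank) /
           (absorbance_control - absorbance_blank))
}

#' Two-proportion survival comparison for fixed-endpoint stress assays
#'
#' Acute assays scored once (e.g. survival 30 minutes after an oxidative
#' challenge) compare the surviving proportions of two arms with a
#' two-proportion test without continuity correction.
#'
#' @param alive_a,n_a survivors and totals in arm A.
#' @param alive_b,n_b survivors and totals in arm B.
#' @return list with the two proportions, `chi2`, and `p`.
#' @export
endpoint_survival_test <- function(alive_a, n_a, alive_b, n_b) {
  stopifnot(alive_a >= 0, alive_b >= 0, alive_a <= n_a, alive_b <= n_b,
            n_a > 0, n_b > 0)
  pt <- stats::prop.test(c(alive_a, alive_b), c(n_a, n_b), correct = FALSE)
  list(prop_a = alive_a / n_a, prop_b = alive_b / n_b,
       chi2 = unname(pt$statistic), p = unname(pt$p.value))
}
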