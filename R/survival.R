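#' Digitized or generated survival curve
#'
#' A monotone non-increasing survival function given as a point series,
#' labelled by endpoint (PFS or OS), genotype and drug. This is the form in
#' which Kaplan-Meier curves digitized from published trial figures enter
#' the model; between points the survival function is interpolated
#' piecewise-linearly on the survival scale.
#'
#' @param times months since start of the line of therapy; strictly
#'   increasing, first element 0.
#' @param survival survival fractions in `[0,1]`; `survival[1]` must be 1
#'   and the series non-increasing.
#' @param endpoint `"PFS"` or `"OS"`.
#' @param genotype `"exon11"`, `"exon9"` or `"other"`.
#' @param drug `"imatinib400"`, `"imatinib800"` or `"sunitinib"`.
#' @return an object of class `survival_curve`.
#' @export
survival_curve <- function(times, survival,
                           endpoint = c("PFS", "OS"),
                           genotype = c("exon11", "exon9", "other"),
                           drug = c("imatinib400", "imatinib800", "sunitinib")) {
  endpoint <- match.arg(endpoint)
  genotype <- match.arg(genotype)
  drug <- match.arg(drug)
  stopifnot(length(times) == length(survival), length(times) >= 2)
  if (times[1] != 0) stop("first time point must be 0", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (survival[1] != 1) stop("survival at time 0 must be 1", call. = FALSE)
  if (any(survival < 0 | survival > 1))
    stop("survival fractions must lie in [0,1]", call. = FALSE)
  if (any(diff(survival) > 1e-12))
    stop("survival must be monotone non-increasing", call. = FALSE)
  structure(list(times = as.numeric(times), survival = as.numeric(survival),
                 endpoint = endpoint, genotype = genotype, drug = drug),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("survival_curve: %s / %s / %s, %d points over %g months (S_end = %.4g)\n",
              x$endpoint, x$genotype, x$drug, length(x$times),
              max(x$times), x$survival[length(x$survival)]))
  invisible(x)
}

#' Parametric survival specification
#'
#' Exponential: `S(t) = exp(-rate * t)`. Weibull: `S(t) = exp(-(rate*t)^shape)`,
#' which reduces to the exponential at `shape = 1`.
#'
#' @param family `"exponential"` or `"weibull"`.
#' @param rate events per month, `> 0` (0 allowed, giving a flat curve).
#' @param shape dimensionless Weibull shape, `> 0`; ignored for exponential.
#' @return an object of class `parametric_survival`.
#' @export
parametric_survival <- function(family = c("exponential", "weibull"),
                                rate, shape = NULL) {
  family <- match.arg(family)
  stopifnot(is.numeric(rate), length(rate) == 1L, rate >= 0)
  if (family == "weibull") {
    if (is.null(shape) || shape <= 0) stop("weibull requires shape > 0", call. = FALSE)
  } else shape <- NULL
  structure(list(family = family, rate = rate, shape = shape),
            class = "parametric_survival")
}

#' Evaluate a parametric survival function
#' @param ps a `parametric_survival` object.
#' @param t times in months.
#' @return survival fractions.
#' @export
psurv_eval <- function(ps, t) {
  stopifnot(inherits(ps, "parametric_survival"))
  if (ps$family == "exponential") exp(-ps$rate * t)
  else exp(-(ps$rate * t)^ps$shape)
}

#' Convert a probability over a period to a constant event rate
#'
#' Inverse of [rate_to_prob()] under the constant-hazard assumption:
#' `r = -log(1 - p) / T`.
#'
#' @param p event probability over the period, `0 <= p < 1`.
#' @param t_months period length in months (default 1).
#' @return rate in events per month.
#' @export
prob_to_rate <- function(p, t_months = 1) {
  stopifnot(t_months > 0)
  if (any(p < 0) || any(p >= 1)) {
    if (any(p == 1)) stop("p = 1 implies an infinite rate", call. = FALSE)
    stop("probabilities must lie in [0, 1)", call. = FALSE)
  }
  -log(1 - p) / t_months
}

#' Convert a constant event rate to a probability over a period
#'
#' `p = 1 - exp(-r * T)`; monotone increasing in both arguments.
#'
#' @param r rate in events per month, `>= 0`.
#' @param t_months period length in months.
#' @return event probability over the period.
#' @export
rate_to_prob <- function(r, t_months) {
  if (any(r < 0)) stop("rates must be non-negative", call. = FALSE)
  stopifnot(t_months > 0)
  1 - exp(-r * t_months)
}

# Interpolated survival at arbitrary times (piecewise linear on the
# survival scale; the least-assumption choice for noisy digitized steps).
surv_at <- function(curve, t) {
  if (max(t) > max(curve$times) + 1e-9)
    stop("coverage error: curve for ", curve$endpoint, "/", curve$genotype, "/",
         curve$drug, " ends at month ", max(curve$times),
         " but month ", max(t), " is required", call. = FALSE)
  stats::approx(curve$times, curve$survival, xout = t, rule = 2)$y
}

#' Convert a survival curve to per-cycle event probabilities
#'
#' For cycle `i` (0-based), `p_i = 1 - S(t_{i+1}) / S(t_i)` with `S`
#' evaluated by monotone piecewise-linear interpolation on the point
#' series. An exponential curve therefore yields a constant schedule
#' (memorylessness).
#'
#' @param curve a [survival_curve()].
#' @param cycle_months cycle length in months.
#' @param n_cycles number of cycles required.
#' @return numeric vector of length `n_cycles`, probabilities in `[0,1]`.
#' @export
km_to_cycle_probs <- function(curve, cycle_months, n_cycles) {
  stopifnot(inherits(curve, "survival_curve"), cycle_months > 0, n_cycles >= 1)
  tt <- (0:n_cycles) * cycle_months
  s <- surv_at(curve, tt)
  s0 <- s[-length(s)]
  s1 <- s[-1]
  if (any(s0 <= 0 & s1 < s0 | (s0 <= 0 & s0 < s1)))
    stop("degenerate denominator: survival reaches 0 before the horizon",
         call. = FALSE)
  p <- ifelse(s0 > 0, 1 - s1 / s0, 0)
  pmin(pmax(p, 0), 1)
}

#' Split progression-free survival into progression-only and death
#'
#' PFS events include both progression and death. Per cycle, both
#' schedules are converted to rates under the constant-hazard-within-cycle
#' assumption and the progression-only rate is taken as
#' `max(0, r_pfs - r_os)`; where the OS hazard exceeds the PFS hazard the
#' progression probability is clamped to 0 with a warning. The death
#' probability passes through unchanged.
#'
#' @param pfs_cycle_probs,os_cycle_probs aligned per-cycle probability
#'   vectors on the same cycle grid.
#' @param cycle_months cycle length in months.
#' @return list with elements `progression` and `death` (per-cycle
#'   probability vectors).
#' @export
decompose_pfs <- function(pfs_cycle_probs, os_cycle_probs, cycle_months) {
  if (length(pfs_cycle_probs) != length(os_cycle_probs))
    stop("alignment error: PFS and OS schedules differ in length", call. = FALSE)
  r_pfs <- prob_to_rate(pfs_cycle_probs, cycle_months)
  r_os <- prob_to_rate(os_cycle_probs, cycle_months)
  clamped <- r_os > r_pfs
  if (any(clamped))
    warning(sum(clamped), " cycle(s) had OS hazard exceeding PFS hazard; ",
            "progression probability clamped to 0", call. = FALSE)
  r_prog <- pmax(0, r_pfs - r_os)
  list(progression = rate_to_prob(r_prog, cycle_months),
       death = os_cycle_probs)
}

#' Extend a death-probability schedule with a constant long-term hazard
#'
#' Trial follow-up covers roughly the first three years; beyond the switch
#' point the per-cycle death probability is replaced by the constant value
#' implied by a registry-style conditional monthly death probability:
#' `rate_to_prob(prob_to_rate(p_month, 1), cycle_months)`.
#'
#' @param os_probs per-cycle death probabilities from trial data; must
#'   cover at least `switch_month`.
#' @param longterm_monthly_death_prob conditional monthly death
#'   probability applied from `switch_month` on.
#' @param switch_month model time (months) at which the extension begins
#'   (default 36).
#' @param n_cycles total schedule length required.
#' @param cycle_months cycle length in months.
#' @return per-cycle death probabilities of length `n_cycles`.
#' @export
extend_longterm <- function(os_probs, longterm_monthly_death_prob,
                            switch_month = 36, n_cycles, cycle_months) {
  first_switched <- which((seq_len(n_cycles) - 1) * cycle_months >= switch_month)
  if (!length(first_switched)) {
    warning("switch_month lies beyond the horizon; schedule unchanged", call. = FALSE)
    if (length(os_probs) < n_cycles)
      stop("coverage error: schedule shorter than horizon with no extension",
           call. = FALSE)
    return(os_probs[seq_len(n_cycles)])
  }
  k <- first_switched[1]
  if (length(os_probs) < k - 1)
    stop("coverage error: trial schedule must cover at least switch_month",
         call. = FALSE)
  p_cycle <- rate_to_prob(prob_to_rate(longterm_monthly_death_prob, 1), cycle_months)
  out <- numeric(n_cycles)
  if (k > 1) out[seq_len(k - 1)] <- os_probs[seq_len(k - 1)]
  out[k:n_cycles] <- p_cycle
  out
}

#' Fit a parametric survival family to a curve
#'
#' Least squares on the log-survival scale. For the exponential family the
#' closed-form estimate is `lambda = -sum(t*log S)/sum(t^2)`; for Weibull,
#' `log(-log S)` is regressed on `log t` (slope = shape). Points with
#' `S = 0`, and for Weibull also points with `S = 1` or `t = 0`, are
#' excluded.
#'
#' @param curve a [survival_curve()] with at least 3 points of positive
#'   survival.
#' @param family `"exponential"` or `"weibull"`.
#' @return a [parametric_survival()] object.
#' @export
fit_parametric <- function(curve, family = c("exponential", "weibull")) {
  family <- match.arg(family)
  stopifnot(inherits(curve, "survival_curve"))
  keep <- curve$survival > 0
  if (sum(keep) < 3)
    stop("need at least 3 points with positive survival", call. = FALSE)
  t <- curve$times[keep]
  s <- curve$survival[keep]
  if (family == "exponential") {
    if (all(s >= 1 - 1e-15)) {
      warning("flat curve: fitted rate is 0", call. = FALSE)
      return(parametric_survival("exponential", 0))
    }
    lam <- -sum(t * log(s)) / sum(t^2)
    return(parametric_survival("exponential", lam))
  }
  ok <- t > 0 & s < 1
  if (sum(ok) < 3) {
    warning("flat curve: returning rate 0, shape 1", call. = FALSE)
    return(parametric_survival("weibull", 0, 1))
  }
  y <- log(-log(s[ok]))
  x <- log(t[ok])
  fit <- stats::lm.fit(cbind(1, x), y)
  k <- fit$coefficients[2]
  lam <- exp(fit$coefficients[1] / k)
  parametric_survival("weibull", unname(lam), unname(k))
}
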