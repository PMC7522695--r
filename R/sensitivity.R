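# Rebuild-and-run for a modified parameter set, reusing schedules when the
# parameter cannot affect them.
affects_schedules <- function(path) {
  field <- strsplit(path, ".", fixed = TRUE)[[1]][1]
  field %in% c("longterm_monthly_death_prob", "longterm_switch_month",
               "cycle_length_months", "horizon_years")
}

eval_at <- function(value, path, params, curves, schedules) {
  p2 <- set_param(params, path, value)
  sch <- if (affects_schedules(path))
    build_schedules(curves, p2, schedules$n_cycles) else schedules
  cea_totals(p2, sch)
}

#' One-way sensitivity analysis with threshold search
#'
#' Re-runs the full deterministic model over a grid of values for one
#' scalar parameter, all else held at base, recording the ICER and the NMB
#' difference (TGT minus empirical) at the willingness-to-pay threshold.
#' If the decision flips between `lo` and `hi`, the break-even parameter
#' value is located by bisection on the NMB difference to a tolerance of
#' $1.
#'
#' @param path parameter path understood by [set_param()], e.g.
#'   `"cost_tgt"` or `"prevalence_exon9"`.
#' @param lo,hi grid range, `lo < hi`.
#' @param n_points grid size (default 21).
#' @param params a `gist_params` object.
#' @param curves survival curves; `NULL` generates the seeded fixtures.
#' @param wtp willingness-to-pay (default: from `params`).
#' @return an object of class `gist_oneway`: a `grid` data frame
#'   (`value`, `icer`, `nmb_diff`, `delta_cost`, `delta_qaly`) and
#'   `threshold` (`NA` if the decision never flips in range).
#' @export
one_way <- function(path, lo, hi, n_points = 21, params = default_parameters(),
                    curves = NULL, wtp = params$wtp_per_qaly) {
  stopifnot(lo < hi, n_points >= 2)
  get_param(params, path) # errors early on a bad path
  if (is.null(curves))
    curves <- generate_fixture_trials(params$rng_seed,
                                      noise_sd = params$fixture_noise_sd)
  n_cycles <- as.integer(round(params$horizon_years * 12 / params$cycle_length_months))
  schedules <- build_schedules(curves, params, n_cycles)

  f <- function(v) {
    tot <- eval_at(v, path, params, curves, schedules)
    inc <- icer(tot$EMPIRICAL, tot$TGT)
    c(icer = inc$icer, nmb_diff = nmb(tot$TGT, wtp) - nmb(tot$EMPIRICAL, wtp),
      delta_cost = inc$delta_cost, delta_qaly = inc$delta_qaly)
  }
  values <- seq(lo, hi, length.out = n_points)
  grid <- as.data.frame(t(vapply(values, f, numeric(4))))
  grid <- cbind(value = values, grid)

  threshold <- NA_real_
  flo <- grid$nmb_diff[1]; fhi <- grid$nmb_diff[n_points]
  if (is.finite(flo) && is.finite(fhi) && sign(flo) != sign(fhi)) {
    a <- lo; b <- hi; fa <- flo
    for (i in 1:200) {
      mid <- (a + b) / 2
      fm <- f(mid)[["nmb_diff"]]
      if (abs(fm) <= 1 || (b - a) < 1e-12 * max(1, abs(hi))) break
      if (sign(fm) == sign(fa)) { a <- mid; fa <- fm } else b <- mid
    }
    threshold <- mid
  }
  structure(list(param = path, grid = grid, threshold = threshold, wtp = wtp),
            class = "gist_oneway")
}

#' @export
print.gist_oneway <- function(x, ...) {
  cat(sprintf("one-way sensitivity on '%s' over [%g, %g]\n", x$param,
              min(x$grid$value), max(x$grid$value)))
  cat(sprintf("  ICER range: %s to %s $/QALY\n",
              format(round(min(x$grid$icer, na.rm = TRUE)), big.mark = ","),
              format(round(max(x$grid$icer, na.rm = TRUE)), big.mark = ",")))
  if (is.na(x$threshold)) cat("  decision does not flip in range\n")
  else cat(sprintf("  decision flips at %s = %.6g (WTP $%s)\n", x$param,
                   x$threshold, format(x$wtp, big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' @export
plot.gist_oneway <- function(x, ...) {
  graphics::plot(x$grid$value, x$grid$icer, type = "l", col = "darkorange",
                 lwd = 2, xlab = x$param, ylab = "ICER ($/QALY)", ...)
  graphics::abline(h = x$wtp, lty = 2)
  if (!is.na(x$threshold)) graphics::abline(v = x$threshold, lty = 3)
  invisible(x)
}

#' ICER as a function of the model time horizon
#'
#' Re-runs the full analysis truncated or extended to each horizon. Costs
#' concentrate early (drug costs while progression-free, progression
#' costs in the first three years) while QALY gains keep accruing, so on
#' curves with the expected qualitative structure the ICER declines as
#' the horizon lengthens.
#'
#' @param years_list integer horizons in years; each must give a whole
#'   number of cycles.
#' @param params a `gist_params` object.
#' @param curves survival curves; `NULL` generates the seeded fixtures.
#' @return data frame with `horizon_years`, `delta_cost`, `delta_qaly`,
#'   `icer`.
#' @export
horizon_sweep <- function(years_list, params = default_parameters(), curves = NULL) {
  if (is.null(curves))
    curves <- generate_fixture_trials(params$rng_seed,
                                      noise_sd = params$fixture_noise_sd)
  rows <- lapply(years_list, function(y) {
    cea <- run_cea(params, curves, horizon_years = y)
    data.frame(horizon_years = y, delta_cost = cea$incremental$delta_cost,
               delta_qaly = cea$incremental$delta_qaly, icer = cea$incremental$icer)
  })
  do.call(rbind, rows)
}

#' Market-share scenario for generic imatinib
#'
#' Recomputes the annual 400 mg imatinib cost as the share-weighted mean
#' of the generic and brand prices (the 800 mg cost staying at exactly
#' twice the 400 mg cost) and re-runs the analysis. At the base 50% share
#' this reproduces the base-case costs exactly.
#'
#' @param share_generic generic market share in `[0,1]`.
#' @param params a `gist_params` object.
#' @param curves survival curves; `NULL` generates the seeded fixtures.
#' @return a `gist_cea` object.
#' @export
market_share_scenario <- function(share_generic, params = default_parameters(),
                                  curves = NULL) {
  stopifnot(share_generic >= 0, share_generic <= 1)
  new_cost <- share_generic * params$price_generic_imatinib400_year +
    (1 - share_generic) * params$price_brand_imatinib400_year
  params$market_share_generic <- share_generic
  params$cost_imatinib400_year$mean <- new_cost
  params$cost_imatinib800_year$mean <- 2 * new_cost
  run_cea(params, curves)
}

#' Method-of-moments distribution parameters
#'
#' Gamma: `shape = (mean/sd)^2`, `scale = sd^2/mean`. Beta:
#' `nu = mean(1-mean)/sd^2 - 1`, `alpha = mean*nu`, `beta = (1-mean)*nu`;
#' requires `sd^2 < mean(1-mean)`.
#'
#' @param family `"gamma"` or `"beta"`.
#' @param mean,sd target moments; gamma needs both positive, beta needs
#'   `mean` in `(0,1)`.
#' @return list with the distribution parameters plus the analytic `mean`
#'   and `sd` they imply (equal to the inputs by construction).
#' @export
moment_match <- function(family = c("gamma", "beta"), mean, sd) {
  family <- match.arg(family)
  stopifnot(sd > 0)
  if (family == "gamma") {
    stopifnot(mean > 0)
    shape <- (mean / sd)^2
    scale <- sd^2 / mean
    return(list(family = "gamma", shape = shape, scale = scale,
                mean = shape * scale, sd = sqrt(shape) * scale))
  }
  if (mean <= 0 || mean >= 1)
    stop("beta requires mean in (0,1)", call. = FALSE)
  if (sd^2 >= mean * (1 - mean))
    stop("parameterization error: beta requires sd^2 < mean(1-mean)", call. = FALSE)
  nu <- mean * (1 - mean) / sd^2 - 1
  a <- mean * nu; b <- (1 - mean) * nu
  list(family = "beta", alpha = a, beta = b,
       mean = a / (a + b), sd = sqrt(a * b / ((a + b)^2 * (a + b + 1))))
}

# n draws from an uncertain value's PSA distribution; degenerate at the
# mean when the SD is 0. `kind` selects the default-SD rule.
draw_uv <- function(uv, n, sd_fraction, kind = "scale") {
  if (uv$distribution == "fixed") return(rep(uv$mean, n))
  sd <- uv_sd(uv, sd_fraction, kind)
  if (sd == 0) return(rep(uv$mean, n))
  m <- abs(uv$mean)
  if (uv$distribution == "gamma") {
    if (m == 0) return(rep(0, n))
    mm <- moment_match("gamma", m, sd)
    draws <- stats::rgamma(n, shape = mm$shape, scale = mm$scale)
  } else {
    # a beta on [0,1] cannot exceed sd = sqrt(m(1-m)); cap wide requests
    sd_max <- sqrt(m * (1 - m))
    if (sd >= sd_max) {
      warning("requested SD ", signif(sd, 4), " infeasible for a beta with mean ",
              m, "; capped at ", signif(0.99 * sd_max, 4), call. = FALSE)
      sd <- 0.99 * sd_max
    }
    mm <- moment_match("beta", m, sd)
    draws <- stats::rbeta(n, mm$alpha, mm$beta)
  }
  draws * sign(uv$mean)
}

# Hazard multipliers: 2 * Beta(a, a) has mean 1 and sd 1/sqrt(2a+1);
# choose a so the sd equals sd_fraction.
draw_multiplier <- function(n, sd_fraction) {
  if (sd_fraction == 0) return(rep(1, n))
  stopifnot(sd_fraction < 1)
  a <- (1 / sd_fraction^2 - 1) / 2
  2 * stats::rbeta(n, a, a)
}

psa_sampled_fields <- function() {
  list(scale = c("cost_tgt", "cost_imatinib400_year", "cost_imatinib800_year",
                 "cost_sunitinib_year", "cost_bsc_year",
                 "cost_other_medical_imatinib_year",
                 "cost_other_medical_sunitinib_year",
                 "cost_ae_imatinib", "cost_ae_sunitinib", "cost_progression",
                 "utility_metastatic", "utility_progression_decrement"),
       probability = c("p_ae_imatinib400_month", "p_ae_imatinib800_month",
                       "p_ae_sunitinib_month"))
}

#' Probabilistic sensitivity analysis
#'
#' Joint Monte-Carlo sampling of all uncertain parameters: costs from
#' gamma distributions and utilities from beta distributions, both
#' moment-matched with SD equal to `sd_fraction` of the mean unless
#' overridden; adverse-event probabilities from beta distributions with
#' SDs derived from their reported 95% CIs; and, when
#' `sample_transition_probs` is on, per-curve hazard uncertainty through a
#' mean-1 beta-scaled multiplier applied to each genotype x drug
#' progression schedule and to each genotype's death schedule (one
#' multiplier per genotype, preserving the dose-equivalence of overall
#' survival), with the resulting probabilities clamped to `[0,1]`. Each
#' iteration re-runs the full deterministic model; results are
#' reproducible bit-for-bit for a fixed seed.
#'
#' @param params a `gist_params` object.
#' @param curves survival curves; `NULL` generates the seeded fixtures.
#' @param n_iter Monte-Carlo iterations (default `params$psa_iterations`).
#' @param seed RNG seed (default `params$rng_seed`).
#' @param wtp_grid willingness-to-pay grid for the acceptability curve.
#' @param sd_fraction SD-of-mean fraction for costs and utilities
#'   (default `params$sd_fraction`).
#' @return an object of class `gist_psa`: per-iteration `delta_cost` and
#'   `delta_qaly`, `ce_probability` at the base WTP, and the `ceac` data
#'   frame over `wtp_grid`.
#' @export
psa <- function(params = default_parameters(), curves = NULL,
                n_iter = params$psa_iterations, seed = params$rng_seed,
                wtp_grid = seq(0, 200000, by = 1000),
                sd_fraction = params$sd_fraction) {
  stopifnot(n_iter >= 1)
  suppressWarnings(validate_parameters(params))
  if (is.null(curves))
    curves <- generate_fixture_trials(params$rng_seed,
                                      noise_sd = params$fixture_noise_sd)
  n_cycles <- as.integer(round(params$horizon_years * 12 / params$cycle_length_months))
  schedules <- build_schedules(curves, params, n_cycles)

  fields <- psa_sampled_fields()
  with_preserved_seed(seed, {
    draws <- list()
    for (nm in fields$scale)
      draws[[nm]] <- draw_uv(params[[nm]], n_iter, sd_fraction, "scale")
    for (nm in fields$probability)
      draws[[nm]] <- draw_uv(params[[nm]], n_iter, sd_fraction, "probability")

    sample_tp <- isTRUE(params$sample_transition_probs)
    if (sample_tp) {
      mult_prog <- list()
      for (g in GENOTYPES) for (d in DRUGS)
        mult_prog[[paste(g, d, sep = ".")]] <- draw_multiplier(n_iter, sd_fraction)
      mult_death <- stats::setNames(
        lapply(GENOTYPES, function(g) draw_multiplier(n_iter, sd_fraction)),
        GENOTYPES)
    }

    delta_cost <- delta_qaly <- numeric(n_iter)
    for (it in seq_len(n_iter)) {
      p2 <- params
      for (nm in c(fields$scale, fields$probability))
        p2[[nm]]$mean <- draws[[nm]][it]
      sch <- schedules
      if (sample_tp) {
        for (g in GENOTYPES) {
          md <- mult_death[[g]][it]
          for (d in DRUGS) {
            mp <- mult_prog[[paste(g, d, sep = ".")]][it]
            sch$progression[[g]][[d]] <-
              pmin(1, pmax(0, schedules$progression[[g]][[d]] * mp))
            sch$death[[g]][[d]] <-
              pmin(1, pmax(0, schedules$death[[g]][[d]] * md))
          }
        }
      }
      tot <- cea_totals(p2, sch)
      delta_cost[it] <- tot$TGT$cost - tot$EMPIRICAL$cost
      delta_qaly[it] <- tot$TGT$qaly - tot$EMPIRICAL$qaly
    }
  })

  wtp <- params$wtp_per_qaly
  ce <- mean(wtp * delta_qaly - delta_cost >= 0)
  ceac <- data.frame(
    wtp = wtp_grid,
    probability = vapply(wtp_grid, function(w) mean(w * delta_qaly - delta_cost >= 0),
                         numeric(1)))
  structure(list(delta_cost = delta_cost, delta_qaly = delta_qaly,
                 ce_probability = ce, ceac = ceac, wtp = wtp,
                 n_iter = n_iter, seed = seed, sd_fraction = sd_fraction),
            class = "gist_psa")
}

#' @export
print.gist_psa <- function(x, ...) {
  cat(sprintf("probabilistic sensitivity analysis: %d iterations (seed %d)\n",
              x$n_iter, x$seed))
  cat(sprintf("  mean incremental cost $%s, mean incremental QALY %.4f\n",
              format(round(mean(x$delta_cost)), big.mark = ","),
              mean(x$delta_qaly)))
  cat(sprintf("  P(TGT cost-effective at $%s/QALY) = %.1f%%\n",
              format(x$wtp, big.mark = ",", scientific = FALSE), 100 * x$ce_probability))
  invisible(x)
}

#' Plot PSA results
#'
#' @param x a `gist_psa` object.
#' @param type `"ceac"` (acceptability curve) or `"plane"`
#'   (cost-effectiveness plane).
#' @param ... passed to the underlying plot call.
#' @export
plot.gist_psa <- function(x, type = c("ceac", "plane"), ...) {
  type <- match.arg(type)
  if (type == "ceac") {
    graphics::plot(x$ceac$wtp, x$ceac$probability, type = "l", lwd = 2,
                   ylim = c(0, 1), xlab = "willingness to pay ($/QALY)",
                   ylab = "P(TGT cost-effective)", ...)
    graphics::abline(v = x$wtp, lty = 2)
  } else {
    graphics::plot(x$delta_qaly, x$delta_cost, pch = ".", col = "grey40",
                   xlab = "incremental QALY", ylab = "incremental cost ($)", ...)
    graphics::abline(a = 0, b = x$wtp, lty = 2)
    graphics::abline(h = 0, v = 0, col = "grey70")
  }
  invisible(x)
}

#' Sensitivity of the PSA to the assumed SD fraction
#'
#' Repeats the PSA at several SD-of-mean fractions for the cost and
#' utility parameters, reporting the cost-effectiveness probability at
#' the base willingness-to-pay for each.
#'
#' @param sd_fractions fractions to sweep (default 0.1, 0.2, 0.4).
#' @param params,curves,n_iter,seed as in [psa()].
#' @return data frame with `sd_fraction` and `ce_probability`.
#' @export
psa_sd_sweep <- function(sd_fractions = c(0.1, 0.2, 0.4),
                         params = default_parameters(), curves = NULL,
                         n_iter = params$psa_iterations, seed = params$rng_seed) {
  if (is.null(curves))
    curves <- generate_fixture_trials(params$rng_seed,
                                      noise_sd = params$fixture_noise_sd)
  rows <- lapply(sd_fractions, function(sf) {
    res <- psa(params, curves, n_iter = n_iter, seed = seed, sd_fraction = sf)
    data.frame(sd_fraction = sf, ce_probability = res$ce_probability)
  })
  do.call(rbind, rows)
}
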