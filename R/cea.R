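config_hash <- function(params) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(params), auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

# Fast path: weighted discounted totals for both strategies, no traces.
cea_totals <- function(params, schedules, n_cycles = schedules$n_cycles) {
  emp <- simulate_strategy("EMPIRICAL", params, schedules, n_cycles, detail = FALSE)
  tgt <- simulate_strategy("TGT", params, schedules, n_cycles, detail = FALSE)
  list(EMPIRICAL = emp, TGT = tgt)
}

#' Run the base-case cost-effectiveness analysis
#'
#' The package's central entry point: builds per-cycle transition
#' schedules from the survival curves (generating the seeded synthetic
#' trial curves if none are given), runs the deterministic Markov cohort
#' for both strategies across the three genomic subpopulations, and
#' compares targeted gene testing (TGT) against empirical imatinib by
#' incremental cost, incremental QALY, ICER and net monetary benefit at
#' the willingness-to-pay threshold.
#'
#' @param params a `gist_params` object (default: packaged base case).
#' @param curves named list of [survival_curve()] objects; `NULL` (the
#'   default) generates the synthetic trial fixtures with
#'   `params$rng_seed`.
#' @param horizon_years override the parameter set's horizon; must divide
#'   into a whole number of cycles.
#' @return an object of class `gist_cea` with per-strategy totals and
#'   traces, the incremental result, NMB per strategy, the decision at
#'   WTP, and provenance (config hash, seed, horizon).
#' @examples
#' cea <- run_cea()
#' print(cea)
#' @export
run_cea <- function(params = default_parameters(), curves = NULL,
                    horizon_years = NULL) {
  suppressWarnings(validate_parameters(params))
  horizon <- horizon_years %||% params$horizon_years
  n_cycles <- horizon * 12 / params$cycle_length_months
  if (abs(n_cycles - round(n_cycles)) > 1e-9)
    stop("horizon of ", horizon, " years is not a whole number of cycles",
         call. = FALSE)
  n_cycles <- as.integer(round(n_cycles))
  if (n_cycles < 1) stop("horizon shorter than one cycle", call. = FALSE)

  if (is.null(curves))
    curves <- generate_fixture_trials(params$rng_seed,
                                      noise_sd = params$fixture_noise_sd)
  schedules <- build_schedules(curves, params, n_cycles)

  emp <- simulate_strategy("EMPIRICAL", params, schedules, n_cycles)
  tgt <- simulate_strategy("TGT", params, schedules, n_cycles)
  inc <- icer(emp, tgt)
  wtp <- params$wtp_per_qaly
  nmbs <- list(EMPIRICAL = nmb(emp, wtp), TGT = nmb(tgt, wtp))
  decision <- if (nmbs$TGT >= nmbs$EMPIRICAL) "TGT cost-effective"
              else "TGT not cost-effective"

  structure(list(strategies = list(EMPIRICAL = emp, TGT = tgt),
                 incremental = inc, nmb = nmbs, wtp = wtp,
                 decision = decision, params = params, schedules = schedules,
                 provenance = list(config_hash = config_hash(params),
                                   seed = params$rng_seed,
                                   horizon_years = horizon,
                                   n_cycles = n_cycles)),
            class = "gist_cea")
}

#' @export
print.gist_cea <- function(x, ...) {
  cat("Cost-effectiveness of TGT-directed vs empirical imatinib, metastatic GIST\n")
  cat(sprintf("  horizon %g years (%d cycles), WTP $%s/QALY\n",
              x$provenance$horizon_years, x$provenance$n_cycles,
              format(x$wtp, big.mark = ",", scientific = FALSE)))
  f <- function(s) sprintf("  %-10s cost $%s  QALY %.3f",
                           s$strategy, format(round(s$cost), big.mark = ","), s$qaly)
  cat(f(x$strategies$EMPIRICAL), "\n")
  cat(f(x$strategies$TGT), "\n")
  inc <- x$incremental
  cat(sprintf("  incremental: $%s / %.4f QALY",
              format(round(inc$delta_cost), big.mark = ","), inc$delta_qaly))
  if (inc$status == "icer")
    cat(sprintf("  ->  ICER $%s per QALY\n", format(round(inc$icer), big.mark = ",")))
  else cat("  -> ", inc$status, "\n")
  cat(" ", x$decision, "\n")
  invisible(x)
}

#' @export
summary.gist_cea <- function(object, ...) {
  rows <- list()
  for (strat in names(object$strategies)) {
    s <- object$strategies[[strat]]
    for (g in names(s$genotypes)) {
      gt <- s$genotypes[[g]]
      rows[[length(rows) + 1]] <- data.frame(
        strategy = strat, genotype = g, weight = gt$weight,
        cost = gt$accrual$cost, qaly = gt$accrual$qaly,
        cost_undisc = gt$accrual$cost_undisc, qaly_undisc = gt$accrual$qaly_undisc)
    }
  }
  out <- list(per_genotype = do.call(rbind, rows),
              incremental = object$incremental,
              nmb = object$nmb, wtp = object$wtp, decision = object$decision)
  class(out) <- "summary.gist_cea"
  out
}

#' @export
print.summary.gist_cea <- function(x, ...) {
  cat("Per-genotype discounted totals:\n")
  print(x$per_genotype, row.names = FALSE, digits = 6)
  cat("\n")
  print(x$incremental)
  cat(sprintf("NMB at $%s/QALY: EMPIRICAL %s, TGT %s -> %s\n",
              format(x$wtp, big.mark = ",", scientific = FALSE),
              format(round(x$nmb$EMPIRICAL), big.mark = ","),
              format(round(x$nmb$TGT), big.mark = ","), x$decision))
  invisible(x)
}

#' Plot a cohort trace
#'
#' State-occupancy curves over model time for one arm.
#'
#' @param x a `cohort_trace`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cohort_trace <- function(x, ...) {
  months <- (0:x$n_cycles) * x$cycle_months
  graphics::matplot(months, x$occupancy, type = "l", lty = 1,
                    xlab = "model time (months)", ylab = "occupancy",
                    ylim = c(0, 1), ...)
  graphics::legend("right", colnames(x$occupancy), lty = 1,
                   col = seq_len(ncol(x$occupancy)), bty = "n", cex = 0.8)
  invisible(x)
}
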