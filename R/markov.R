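GENOTYPES <- c("exon11", "exon9", "other")
DRUGS <- c("imatinib400", "imatinib800", "sunitinib")

get_curve <- function(curves, endpoint, genotype, drug) {
  key <- curve_key(endpoint, genotype, drug)
  cv <- curves[[key]]
  if (is.null(cv))
    stop("configuration error: no survival curve for (", endpoint, ", ",
         genotype, ", ", drug, ")", call. = FALSE)
  cv
}

#' Build per-cycle transition schedules from survival curves
#'
#' For every genotype x drug pair this derives, on the model's cycle grid:
#' the progression-only probability schedule (PFS converted to per-cycle
#' probabilities, then decomposed against the same trial's OS by rate
#' subtraction) indexed by time *in that line*, and the death probability
#' schedule (OS converted to per-cycle probabilities, then extended beyond
#' the trial follow-up with the constant long-term monthly death
#' probability) indexed by *model* time.
#'
#' @param curves named list of [survival_curve()] objects as produced by
#'   [generate_fixture_trials()].
#' @param params a `gist_params` object.
#' @param n_cycles schedule length in cycles.
#' @return a list with elements `progression[[genotype]][[drug]]`,
#'   `death[[genotype]][[drug]]`, `n_cycles` and `cycle_months`.
#' @export
build_schedules <- function(curves, params, n_cycles) {
  cm <- params$cycle_length_months
  prog <- death <- stats::setNames(vector("list", length(GENOTYPES)), GENOTYPES)
  for (g in GENOTYPES) {
    prog[[g]] <- death[[g]] <- stats::setNames(vector("list", length(DRUGS)), DRUGS)
    for (d in DRUGS) {
      pfs <- km_to_cycle_probs(get_curve(curves, "PFS", g, d), cm, n_cycles)
      os <- km_to_cycle_probs(get_curve(curves, "OS", g, d), cm, n_cycles)
      dec <- suppressWarnings(decompose_pfs(pfs, os, cm))
      prog[[g]][[d]] <- dec$progression
      death[[g]][[d]] <- extend_longterm(os, params$longterm_monthly_death_prob,
                                         params$longterm_switch_month, n_cycles, cm)
    }
  }
  list(progression = prog, death = death, n_cycles = n_cycles, cycle_months = cm)
}

#' Treatment sequence for a strategy and genotype
#'
#' Empirical dosing treats every genotype with 400 mg imatinib, escalating
#' to 800 mg at first progression, then sunitinib, then best supportive
#' care. Under targeted gene testing only the exon 9 arm changes: it
#' starts directly on 800 mg imatinib, followed by sunitinib and best
#' supportive care.
#'
#' @param strategy `"EMPIRICAL"` or `"TGT"`.
#' @param genotype `"exon11"`, `"exon9"` or `"other"`.
#' @return character vector of line drugs.
#' @export
treatment_sequence <- function(strategy = c("EMPIRICAL", "TGT"),
                               genotype = c("exon11", "exon9", "other")) {
  strategy <- match.arg(strategy)
  genotype <- match.arg(genotype)
  if (strategy == "TGT" && genotype == "exon9")
    c("imatinib800", "sunitinib")
  else
    c("imatinib400", "imatinib800", "sunitinib")
}

#' Assemble a strategy arm
#'
#' Combines the treatment sequence with the transition schedules: each
#' active line gets the progression-only schedule of its drug (clocked on
#' time in state), death follows the first-line drug's extended OS
#' schedule for the genotype (clocked on model time), the last active line
#' progresses into best supportive care, and BSC transitions only to
#' death. State utilities are the metastatic utility minus one decrement
#' per prior progression, clamped at 0.
#'
#' @param strategy `"EMPIRICAL"` or `"TGT"`.
#' @param genotype `"exon11"`, `"exon9"` or `"other"`.
#' @param params a `gist_params` object.
#' @param schedules output of [build_schedules()].
#' @param warn warn when a negative utility is clamped (default TRUE).
#' @return an object of class `strategy_arm`.
#' @export
build_arm <- function(strategy, genotype, params, schedules, warn = TRUE) {
  drugs <- treatment_sequence(strategy, genotype)
  n_cycles <- schedules$n_cycles
  prog <- matrix(0, length(drugs), n_cycles)
  for (j in seq_along(drugs)) {
    sched <- schedules$progression[[genotype]][[drugs[j]]]
    if (is.null(sched))
      stop("configuration error: no schedule for (", genotype, ", ", drugs[j], ")",
           call. = FALSE)
    prog[j, ] <- sched
  }
  death <- schedules$death[[genotype]][[drugs[1]]]
  if (is.null(death))
    stop("configuration error: no death schedule for (", genotype, ", ", drugs[1], ")",
         call. = FALSE)

  u <- params$utility_metastatic$mean +
    (seq_along(drugs) - 1) * params$utility_progression_decrement$mean
  if (any(u < 0)) {
    if (warn) warning("negative line utility clamped at 0", call. = FALSE)
    u <- pmax(u, 0)
  }

  structure(list(strategy = strategy, genotype = genotype, drugs = drugs,
                 progression = prog, death = death,
                 utilities = u, utility_bsc = params$utility_bsc,
                 tgt_cost_applies = (strategy == "TGT"),
                 n_cycles = n_cycles, cycle_months = schedules$cycle_months),
            class = "strategy_arm")
}

#' @export
print.strategy_arm <- function(x, ...) {
  cat(sprintf("strategy_arm: %s / %s\n  lines: %s -> BSC -> DEAD (%d states)\n",
              x$strategy, x$genotype, paste(x$drugs, collapse = " -> "),
              length(x$drugs) + 2))
  invisible(x)
}

#' Run the deterministic cohort simulation for one arm
#'
#' Propagates the full cohort forward from everyone in first-line therapy.
#' Line states are internally expanded by time-in-state (tunnel states) so
#' that each line's progression clock starts when the line is entered,
#' while the death probability is read off the model-time schedule and
#' applies equally to every alive state in that cycle. Within a cycle,
#' death competes with progression through the jointly adjusted
#' probabilities from the rate-subtraction decomposition; an error is
#' raised if any cell's progression + death probability exceeds 1.
#'
#' @param arm a `strategy_arm` from [build_arm()].
#' @param n_cycles number of cycles to run (default: the arm's schedule
#'   length).
#' @return an object of class `cohort_trace`: occupancy matrix
#'   `(n_cycles+1) x (lines + BSC + DEAD)` whose rows sum to 1, plus
#'   per-cycle progression and death flows.
#' @export
run_cohort <- function(arm, n_cycles = arm$n_cycles) {
  stopifnot(inherits(arm, "strategy_arm"), n_cycles <= arm$n_cycles)
  nl <- length(arm$drugs)
  k <- .cohort_kernel(arm$progression, arm$death, as.integer(n_cycles))
  M <- k$occupancy
  colnames(M) <- c(paste0("LINE", seq_len(nl)), "BSC", "DEAD")
  structure(list(occupancy = M, prog_flow = k$prog_flow,
                 death_flow = k$death_flow,
                 n_cycles = n_cycles, cycle_months = arm$cycle_months),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  n <- x$n_cycles
  cat(sprintf("cohort_trace: %d cycles of %g months; final DEAD fraction %.4f\n",
              n, x$cycle_months, x$occupancy[n + 1, "DEAD"]))
  invisible(x)
}

drug_cost_year <- function(params, drug) {
  switch(drug,
         imatinib400 = params$cost_imatinib400_year$mean,
         imatinib800 = params$cost_imatinib800_year$mean,
         sunitinib = params$cost_sunitinib_year$mean)
}

other_medical_cost_year <- function(params, drug) {
  if (drug == "sunitinib") params$cost_other_medical_sunitinib_year$mean
  else params$cost_other_medical_imatinib_year$mean
}

ae_prob_month <- function(params, drug) {
  switch(drug,
         imatinib400 = params$p_ae_imatinib400_month$mean,
         imatinib800 = params$p_ae_imatinib800_month$mean,
         sunitinib = params$p_ae_sunitinib_month$mean)
}

ae_cost <- function(params, drug) {
  if (drug == "sunitinib") params$cost_ae_sunitinib$mean
  else params$cost_ae_imatinib$mean
}

#' Accrue discounted costs and QALYs over a cohort trace
#'
#' Per cycle, on beginning-of-cycle occupancy (or the average of the
#' beginning and end occupancy when the half-cycle correction is enabled):
#' drug plus line-matched other-medical costs pro-rated to the cycle
#' length; expected adverse-event costs (monthly adverse-event probability
#' converted to a per-cycle probability times the one-time event cost);
#' the one-time progression cost applied to that cycle's progression
#' transition flow, but only for cycles starting within the first
#' `progression_cost_months` of the model; the one-time gene-testing cost
#' at cycle 0 for TGT arms; and QALYs from state utilities. Each cycle's
#' cost and QALY is discounted at the annual rate from the cycle's start
#' time. Totals are returned unrounded.
#'
#' @param trace a `cohort_trace` from [run_cohort()] for the same arm.
#' @param arm the `strategy_arm` that produced `trace`.
#' @param params a `gist_params` object.
#' @param ledger also return the per-cycle ledger data frame (default
#'   TRUE; turn off in tight loops).
#' @return list with `cost`, `qaly` (discounted totals), `cost_undisc`,
#'   `qaly_undisc`, and optionally `ledger`.
#' @export
accrue <- function(trace, arm, params, ledger = TRUE) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(arm, "strategy_arm"))
  n <- trace$n_cycles
  cm <- arm$cycle_months
  per_year <- cm / 12
  nl <- length(arm$drugs)

  occ <- trace$occupancy
  w <- occ[seq_len(n), , drop = FALSE]
  if (isTRUE(params$half_cycle_correction))
    w <- (w + occ[seq_len(n) + 1, , drop = FALSE]) / 2
  line_occ <- w[, seq_len(nl), drop = FALSE]
  bsc_occ <- w[, nl + 1]

  c_drug_line <- vapply(arm$drugs, function(d) drug_cost_year(params, d) * per_year,
                        numeric(1))
  c_om_line <- vapply(arm$drugs, function(d)
    other_medical_cost_year(params, d) * per_year, numeric(1))
  p_ae_cycle <- vapply(arm$drugs, function(d)
    rate_to_prob(prob_to_rate(ae_prob_month(params, d), 1), cm), numeric(1))
  c_ae <- vapply(arm$drugs, function(d) ae_cost(params, d), numeric(1))

  cost_drug <- drop(line_occ %*% c_drug_line)
  cost_othermed <- drop(line_occ %*% c_om_line)
  cost_ae <- drop(line_occ %*% (p_ae_cycle * c_ae))
  cost_bsc <- bsc_occ * params$cost_bsc_year$mean * per_year
  cycle_start_month <- (seq_len(n) - 1) * cm
  cost_prog <- trace$prog_flow * params$cost_progression$mean *
    (cycle_start_month < params$progression_cost_months)
  cost_tgt <- numeric(n)
  if (arm$tgt_cost_applies) cost_tgt[1] <- params$cost_tgt$mean

  cost_cycle <- cost_drug + cost_othermed + cost_ae + cost_bsc + cost_prog + cost_tgt
  qaly_cycle <- (drop(line_occ %*% arm$utilities) + bsc_occ * arm$utility_bsc) * per_year

  disc <- (1 + params$discount_rate_annual)^(-(cycle_start_month / 12))
  out <- list(cost = sum(cost_cycle * disc), qaly = sum(qaly_cycle * disc),
              cost_undisc = sum(cost_cycle), qaly_undisc = sum(qaly_cycle))
  if (ledger)
    out$ledger <- data.frame(
      cycle = seq_len(n) - 1, cycle_start_month = cycle_start_month,
      cost = cost_cycle, cost_disc = cost_cycle * disc,
      qaly = qaly_cycle, qaly_disc = qaly_cycle * disc,
      cost_drug = cost_drug, cost_othermed = cost_othermed,
      cost_ae = cost_ae, cost_bsc = cost_bsc,
      cost_progression = cost_prog, cost_tgt = cost_tgt,
      prog_flow = trace$prog_flow, death_flow = trace$death_flow,
      discount = disc)
  out
}

#' Simulate one strategy across the three genomic subpopulations
#'
#' Runs the genotype arms and returns the prevalence-weighted discounted
#' totals with per-genotype breakdowns.
#'
#' @param strategy `"EMPIRICAL"` or `"TGT"`.
#' @param params a `gist_params` object.
#' @param schedules output of [build_schedules()].
#' @param n_cycles horizon in cycles (default: schedule length).
#' @param detail keep per-genotype traces and ledgers (default TRUE).
#' @return list with `strategy`, weighted `cost` and `qaly`, and
#'   `genotypes` (per-genotype arm, trace, accrual and weight).
#' @export
simulate_strategy <- function(strategy, params, schedules,
                              n_cycles = schedules$n_cycles, detail = TRUE) {
  weights <- c(exon11 = params$prevalence_exon11,
               exon9 = params$prevalence_exon9,
               other = params$prevalence_other)
  cost <- qaly <- 0
  genotypes <- list()
  for (g in GENOTYPES) {
    arm <- build_arm(strategy, g, params, schedules, warn = FALSE)
    trace <- run_cohort(arm, n_cycles)
    acc <- accrue(trace, arm, params, ledger = detail)
    cost <- cost + weights[[g]] * acc$cost
    qaly <- qaly + weights[[g]] * acc$qaly
    genotypes[[g]] <- list(weight = weights[[g]], arm = arm,
                           trace = if (detail) trace else NULL,
                           accrual = acc)
  }
  list(strategy = strategy, cost = cost, qaly = qaly, genotypes = genotypes)
}
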