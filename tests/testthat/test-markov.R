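manual_schedules <- function(p_prog, p_death, n_cycles, cycle_months = 2) {
  gen <- c("exon11", "exon9", "other")
  drugs <- c("imatinib400", "imatinib800", "sunitinib")
  prog <- lapply(setNames(gen, gen), function(g)
    lapply(setNames(drugs, drugs), function(d) rep(p_prog, n_cycles)))
  death <- lapply(setNames(gen, gen), function(g)
    lapply(setNames(drugs, drugs), function(d) rep(p_death, n_cycles)))
  list(progression = prog, death = death, n_cycles = n_cycles,
       cycle_months = cycle_months)
}

test_that("strategy arms have the mandated treatment sequences", {
  expect_identical(treatment_sequence("EMPIRICAL", "exon11"),
                   c("imatinib400", "imatinib800", "sunitinib"))
  expect_identical(treatment_sequence("EMPIRICAL", "exon9"),
                   c("imatinib400", "imatinib800", "sunitinib"))
  expect_identical(treatment_sequence("TGT", "exon9"),
                   c("imatinib800", "sunitinib"))

  p <- default_parameters()
  sch <- build_schedules(flat_exp_curves(0.05, 0.02), p, 60)

  # TGT/exon9: LINE1(im800) -> LINE2(sunitinib) -> BSC -> DEAD
  arm9 <- build_arm("TGT", "exon9", p, sch)
  expect_identical(arm9$drugs, c("imatinib800", "sunitinib"))
  expect_identical(ncol(run_cohort(arm9)$occupancy), 4L)

  # empirical exon 11: 3 lines + BSC + DEAD
  arm11 <- build_arm("EMPIRICAL", "exon11", p, sch)
  expect_identical(ncol(run_cohort(arm11)$occupancy), 5L)

  # TGT management of exon 11 is identical to empirical
  expect_identical(build_arm("TGT", "exon11", p, sch)[c("drugs", "progression", "death", "utilities")],
                   arm11[c("drugs", "progression", "death", "utilities")])

  # utilities fall by one decrement per line
  expect_equal(arm11$utilities, c(0.935, 0.815, 0.695))
  expect_equal(arm9$utilities, c(0.935, 0.815))

  sch_missing <- sch
  sch_missing$progression$exon9$imatinib800 <- NULL
  expect_error(build_arm("TGT", "exon9", p, sch_missing),
               "configuration error.*exon9, imatinib800")
})

test_that("a cohort with zero event probabilities never moves", {
  p <- quiet_params()
  sch <- build_schedules(flat_exp_curves(0, 0), p, 60)
  tr <- run_cohort(build_arm("EMPIRICAL", "exon11", p, sch))
  expect_identical(tr$occupancy[, "LINE1"], rep(1, 61))
  expect_identical(max(abs(tr$occupancy[, -1])), 0)
})

test_that("constant death with no progression decays geometrically", {
  r <- 0.04 # per month
  p <- quiet_params(longterm = 1 - exp(-r))
  sch <- build_schedules(flat_exp_curves(r, r), p, 60)
  arm <- build_arm("EMPIRICAL", "other", p, sch)
  tr <- run_cohort(arm)
  pc <- 1 - exp(-2 * r)
  expect_equal(tr$occupancy[, "LINE1"], (1 - pc)^(0:60), tolerance = 1e-9)
  expect_identical(max(tr$occupancy[, c("LINE2", "LINE3", "BSC")]), 0)
  expect_equal(tr$occupancy[, "DEAD"], 1 - (1 - pc)^(0:60), tolerance = 1e-9)
})

test_that("joint progression+death probabilities above 1 are rejected", {
  p <- default_parameters()
  sch <- manual_schedules(0.7, 0.4, 10)
  arm <- build_arm("EMPIRICAL", "exon11", p, sch)
  expect_error(run_cohort(arm), "schedule error")
})

test_that("mass is conserved and death is monotone on the default fixtures", {
  p <- default_parameters()
  curves <- default_curves()
  sch <- build_schedules(curves, p, 60)
  for (strat in c("EMPIRICAL", "TGT")) {
    for (g in c("exon11", "exon9", "other")) {
      tr <- run_cohort(build_arm(strat, g, p, sch))
      expect_lt(max(abs(rowSums(tr$occupancy) - 1)), 1e-9)
      expect_true(all(diff(tr$occupancy[, "DEAD"]) >= 0))
      expect_true(all(tr$occupancy >= 0 & tr$occupancy <= 1))
    }
  }
})

test_that("accrual matches hand arithmetic on a frozen cohort", {
  # no deaths, no progression, zero discount, 1-year horizon: the cohort
  # sits in first-line imatinib 400 mg for 6 cycles
  p <- quiet_params()
  # the long-term splice lies beyond this 1-year horizon by design
  sch <- suppressWarnings(build_schedules(flat_exp_curves(0, 0), p, 6))
  arm <- build_arm("EMPIRICAL", "exon11", p, sch)
  acc <- accrue(run_cohort(arm), arm, p)

  expect_equal(sum(acc$ledger$cost_drug), 57690, tolerance = 1e-12)
  expect_equal(sum(acc$ledger$cost_othermed), 2315, tolerance = 1e-12)
  expect_equal(acc$qaly, 0.935, tolerance = 1e-12)
  # expected adverse-event cost: per-cycle probability from the monthly rate
  expect_equal(sum(acc$ledger$cost_ae),
               6 * (1 - (1 - 0.033)^2) * 296, tolerance = 1e-12)
  expect_identical(sum(acc$ledger$cost_progression), 0)
  expect_identical(sum(acc$ledger$cost_tgt), 0)

  # discount factor at the cycle starting t = 1 year is 1.03^-1
  p2 <- quiet_params(discount = 0.03)
  sch2 <- build_schedules(flat_exp_curves(0, 0), p2, 60)
  arm2 <- build_arm("EMPIRICAL", "exon11", p2, sch2)
  acc2 <- accrue(run_cohort(arm2), arm2, p2)
  expect_equal(acc2$ledger$discount[7], 1 / 1.03, tolerance = 1e-12)
  expect_lt(acc2$cost, acc2$cost_undisc)
  expect_lt(acc2$qaly, acc2$qaly_undisc)
})

test_that("TGT charges the one-time testing cost at cycle 0 only", {
  p <- quiet_params()
  sch <- build_schedules(flat_exp_curves(0.05, 0.02), p, 60)
  arm <- build_arm("TGT", "exon11", p, sch)
  acc <- accrue(run_cohort(arm), arm, p)
  expect_identical(acc$ledger$cost_tgt, c(2919, rep(0, 59)))
})

test_that("strategy totals are prevalence-weighted convex combinations", {
  p <- default_parameters()
  curves <- default_curves()
  sch <- build_schedules(curves, p, 60)

  emp <- simulate_strategy("EMPIRICAL", p, sch)
  tgt <- simulate_strategy("TGT", p, sch)

  w <- c(exon11 = 0.67, exon9 = 0.15, other = 0.18)
  for (s in list(emp, tgt)) {
    per_g <- vapply(s$genotypes, function(g) g$accrual$cost, numeric(1))
    expect_equal(s$cost, sum(w * per_g[names(w)]), tolerance = 1e-12)
    expect_true(s$cost >= min(per_g) && s$cost <= max(per_g))
  }

  # degenerate mixture: exon-9-only population reproduces the exon 9 arm
  p9 <- set_param(p, "prevalence_exon9", 1)
  tgt9 <- simulate_strategy("TGT", p9, sch)
  expect_equal(tgt9$cost, tgt$genotypes$exon9$accrual$cost, tolerance = 1e-12)
  expect_equal(tgt9$qaly, tgt$genotypes$exon9$accrual$qaly, tolerance = 1e-12)

  # exon 11 pathways are identical, so the subgroup differs by the test cost
  expect_identical(tgt$genotypes$exon11$accrual$qaly, emp$genotypes$exon11$accrual$qaly)
  expect_equal(tgt$genotypes$exon11$accrual$cost - emp$genotypes$exon11$accrual$cost,
               2919, tolerance = 1e-12)
})

test_that("negative line utilities are clamped with a warning", {
  p <- default_parameters()
  p$utility_progression_decrement$mean <- -0.6
  sch <- suppressWarnings(build_schedules(flat_exp_curves(0.05, 0.02), p, 12))
  expect_warning(arm <- build_arm("EMPIRICAL", "exon11", p, sch), "clamped")
  expect_equal(arm$utilities, c(0.935, 0.335, 0))
})

test_that("the half-cycle correction averages start and end occupancy", {
  r <- 0.05
  p <- quiet_params(longterm = 1 - exp(-r))
  sch <- suppressWarnings(build_schedules(flat_exp_curves(r, r), p, 12))
  arm <- build_arm("EMPIRICAL", "exon11", p, sch)
  tr <- run_cohort(arm)
  a0 <- accrue(tr, arm, p)
  p$half_cycle_correction <- TRUE
  a1 <- accrue(tr, arm, p)
  alive <- tr$occupancy[, "LINE1"]
  expect_equal(a1$qaly / a0$qaly,
               sum((alive[1:12] + alive[2:13]) / 2) / sum(alive[1:12]),
               tolerance = 1e-12)
  expect_lt(a1$qaly, a0$qaly)
})
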