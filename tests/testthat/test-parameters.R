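test_that("packaged defaults reproduce the published parameter table exactly", {
  p <- default_parameters()

  expect_identical(
    lapply(list(p$cost_tgt, p$cost_imatinib400_year, p$cost_imatinib800_year,
                p$cost_sunitinib_year, p$cost_bsc_year,
                p$cost_other_medical_imatinib_year,
                p$cost_other_medical_sunitinib_year,
                p$cost_ae_imatinib, p$cost_ae_sunitinib, p$cost_progression),
           function(uv) c(uv$mean, uv$ci_low, uv$ci_high)),
    list(c(2919, 1903, 4150), c(57690, 38064, 85446), c(115380, 76128, 170892),
         c(86726, 51516, 114756), c(9403, 5856, 13194), c(2315, 1500, 3252),
         c(3344, 2178, 4704), c(296, 1164, 2526), c(160, 612, 1392),
         c(46548, 29754, 66636)))

  expect_identical(c(p$p_ae_imatinib400_month$mean, p$p_ae_imatinib800_month$mean,
                     p$p_ae_sunitinib_month$mean), c(0.033, 0.065, 0.031))
  expect_identical(c(p$p_ae_imatinib400_month$ci_low, p$p_ae_imatinib400_month$ci_high),
                   c(0.021, 0.047))
  expect_identical(c(p$utility_metastatic$mean, p$utility_progression_decrement$mean,
                     p$utility_bsc, p$utility_dead), c(0.935, -0.12, 0.577, 0))
  expect_identical(c(p$prevalence_exon9, p$prevalence_exon11, p$prevalence_other),
                   c(0.15, 0.67, 0.18))
  expect_identical(c(p$discount_rate_annual, p$cycle_length_months,
                     p$horizon_years, p$wtp_per_qaly, p$sd_fraction),
                   c(0.03, 2, 10, 1e5, 0.2))

  # cost distributions are gamma, probability/utility distributions beta
  expect_identical(p$cost_tgt$distribution, "gamma")
  expect_identical(p$p_ae_imatinib800_month$distribution, "beta")
  expect_identical(p$utility_metastatic$distribution, "beta")
})

test_that("validation flags CI-inconsistent means but accepts the defaults", {
  # adverse-event cost means sit outside their reported CIs: loadable, flagged
  expect_false(default_parameters()$cost_ae_imatinib$ci_consistent)
  expect_warning(validate_parameters(default_parameters()),
                 "cost_ae_imatinib.*cost_ae_sunitinib")
})

test_that("structural invariants are enforced with all violations listed", {
  p <- default_parameters()
  p$prevalence_exon9 <- 0.5
  p$prevalence_exon11 <- 0.5
  p$prevalence_other <- 0.1
  expect_error(validate_parameters(p), "prevalences sum")

  p2 <- default_parameters()
  p2$cycle_length_months <- 7
  expect_error(validate_parameters(p2), "does not divide")

  p3 <- default_parameters()
  p3$price_generic_imatinib400_year <- 20000
  expect_error(validate_parameters(p3), "market-share-weighted")

  # several violations at once are all reported
  p4 <- default_parameters()
  p4$prevalence_exon9 <- 2
  p4$cycle_length_months <- 7
  err <- tryCatch(validate_parameters(p4), error = conditionMessage)
  expect_match(err, "not a probability")
  expect_match(err, "does not divide")
})

test_that("market-share-weighted imatinib price reproduces the base cost", {
  p <- default_parameters()
  weighted <- p$market_share_generic * p$price_generic_imatinib400_year +
    (1 - p$market_share_generic) * p$price_brand_imatinib400_year
  expect_equal(weighted, p$cost_imatinib400_year$mean, tolerance = 1 / 57690)
  expect_identical(p$cost_imatinib800_year$mean, 2 * p$cost_imatinib400_year$mean)
})

test_that("parameter documents round-trip through load/write idempotently", {
  f1 <- tempfile(fileext = ".yaml")
  f2 <- tempfile(fileext = ".yaml")
  on.exit(unlink(c(f1, f2)))

  p0 <- suppressWarnings(load_parameters())
  write_parameters(p0, f1)
  p1 <- suppressWarnings(load_parameters(f1))
  write_parameters(p1, f2)
  p2 <- suppressWarnings(load_parameters(f2))
  expect_identical(p1, p2)
  expect_equal(p1, p0)

  # partial override on top of packaged defaults
  p3 <- suppressWarnings(load_parameters(
    text = "use_defaults: true\nwtp_per_qaly: 50000\ncost_tgt:\n  mean: 5000\n"))
  expect_identical(p3$wtp_per_qaly, 50000)
  expect_identical(p3$cost_tgt$mean, 5000)
  expect_identical(p3$cost_tgt$distribution, "gamma")

  # a full document missing a field names it
  expect_error(load_parameters(text = "wtp_per_qaly: 50000\n"),
               "missing field.*cost_tgt")
  expect_error(load_parameters(text = "use_defaults: true\nnonsense: 1\n"),
               "unknown field 'nonsense'")
})

test_that("results tables have the documented shape and round-trip losslessly", {
  curves <- flat_exp_curves(0.05, 0.02)
  cea <- run_cea(quiet_params(longterm = 0.01, discount = 0.03), curves)
  dir <- tempfile()
  on.exit(unlink(dir, recursive = TRUE))
  write_results(cea, dir)

  back <- read_results(dir)
  expect_identical(back$results$row, c("EMPIRICAL", "TGT", "INCREMENTAL"))
  expect_identical(back$results$cost[1], cea$strategies$EMPIRICAL$cost)
  expect_identical(back$results$cost[2], cea$strategies$TGT$cost)
  expect_identical(back$results$qaly[3], cea$incremental$delta_qaly)
  expect_identical(back$results$icer[3], cea$incremental$icer)

  # one row per cycle incl. cycle 0, occupancy identical bit-for-bit
  tr <- back$traces[["trace_TGT_exon9"]]
  expect_identical(nrow(tr), cea$provenance$n_cycles + 1L)
  occ <- cea$strategies$TGT$genotypes$exon9$trace$occupancy
  expect_identical(as.matrix(tr[, colnames(occ)]), occ, ignore_attr = TRUE)
})

test_that("uncertain values enforce their distribution domains", {
  expect_error(uncertain_value(-5, distribution = "gamma"), "non-negative")
  expect_error(uncertain_value(1.5, distribution = "beta"), "beta")
  expect_silent(uncertain_value(-0.12, -0.15, -0.08, "beta"))
})

test_that("parameter paths address scalars, with linked side effects", {
  p <- default_parameters()
  expect_identical(get_param(p, "cost_tgt"), 2919)
  expect_identical(get_param(p, "cost_tgt.ci_high"), 4150)
  expect_identical(get_param(p, "prevalence_exon9"), 0.15)
  expect_error(get_param(p, "no_such"), "unknown parameter path")

  p2 <- set_param(p, "prevalence_exon9", 0.32)
  expect_equal(p2$prevalence_exon9 + p2$prevalence_exon11 + p2$prevalence_other, 1)
  expect_equal(p2$prevalence_exon11 / p2$prevalence_other,
               p$prevalence_exon11 / p$prevalence_other)

  p3 <- set_param(p, "cost_imatinib400_year", 2 * 57690)
  expect_identical(p3$cost_imatinib800_year$mean, 4 * 57690)
  # weighted-price link preserved: no structural error (AE-cost CI warning aside)
  expect_error(suppressWarnings(validate_parameters(p3)), NA)
})
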