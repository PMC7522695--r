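# Shared fixtures built in code.

# A curve set in which every genotype x drug pair has the same exponential
# PFS and OS hazards; pfs_rate == os_rate gives zero progression, and
# rate 0 gives a frozen cohort.
flat_exp_curves <- function(pfs_rate, os_rate, t_max = 180) {
  grid <- seq(0, t_max, by = 1)
  out <- list()
  for (g in c("exon11", "exon9", "other")) {
    for (d in c("imatinib400", "imatinib800", "sunitinib")) {
      out[[paste("PFS", g, d, sep = ".")]] <-
        survival_curve(grid, exp(-pfs_rate * grid), "PFS", g, d)
      out[[paste("OS", g, d, sep = ".")]] <-
        survival_curve(grid, exp(-os_rate * grid), "OS", g, d)
    }
  }
  out
}

# Parameters whose death/discounting degeneracies suit closed-form checks.
quiet_params <- function(longterm = 0, discount = 0) {
  p <- default_parameters()
  p$longterm_monthly_death_prob <- longterm
  p$discount_rate_annual <- discount
  p
}

# Default fixture curves shared across tests (seeded, noisy).
default_curves <- function(seed = 1) {
  p <- default_parameters()
  generate_fixture_trials(seed, noise_sd = p$fixture_noise_sd)
}
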