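#' Default synthetic trial-curve specification
#'
#' One exponential hazard per genotype x drug x endpoint, standing in for
#' the progression-free and overall survival curves of the two source
#' trials (a phase III imatinib dose-comparison with genotype subgroups,
#' and a phase I/II sunitinib study). The hazards are set from
#' median-survival figures typical of those trial populations and encode
#' the qualitative structure the model depends on:
#' \itemize{
#'   \item exon 9 progresses much faster on 400 mg imatinib than on
#'     800 mg (median PFS 6 vs 19 months);
#'   \item exon 11 has the lowest 400 mg progression hazard of the three
#'     genotypes (median PFS 24 months);
#'   \item within each genotype the OS hazard is identical across the two
#'     imatinib doses, so dose selection affects progression but not
#'     survival.
#' }
#' Sunitinib rows are an independent parameter block (different source
#' trial); no cross-trial consistency is enforced. All values are
#' synthetic fixtures, not digitized trial data.
#'
#' @return data frame with columns `endpoint`, `genotype`, `drug`,
#'   `family`, `rate` (events/month), `shape`.
#' @export
default_trial_spec <- function() {
  med <- function(m) log(2) / m
  spec <- rbind(
    # PFS, imatinib trial
    data.frame(endpoint = "PFS", genotype = "exon11", drug = "imatinib400", rate = med(24)),
    data.frame(endpoint = "PFS", genotype = "exon11", drug = "imatinib800", rate = med(22)),
    data.frame(endpoint = "PFS", genotype = "exon9", drug = "imatinib400", rate = med(6)),
    data.frame(endpoint = "PFS", genotype = "exon9", drug = "imatinib800", rate = med(19)),
    data.frame(endpoint = "PFS", genotype = "other", drug = "imatinib400", rate = med(12)),
    data.frame(endpoint = "PFS", genotype = "other", drug = "imatinib800", rate = med(12)),
    # PFS, sunitinib trial (measured from start of sunitinib)
    data.frame(endpoint = "PFS", genotype = "exon11", drug = "sunitinib", rate = med(5)),
    data.frame(endpoint = "PFS", genotype = "exon9", drug = "sunitinib", rate = med(19)),
    data.frame(endpoint = "PFS", genotype = "other", drug = "sunitinib", rate = med(8)),
    # OS, imatinib trial: equal across doses within genotype
    data.frame(endpoint = "OS", genotype = "exon11", drug = "imatinib400", rate = med(60)),
    data.frame(endpoint = "OS", genotype = "exon11", drug = "imatinib800", rate = med(60)),
    data.frame(endpoint = "OS", genotype = "exon9", drug = "imatinib400", rate = med(30)),
    data.frame(endpoint = "OS", genotype = "exon9", drug = "imatinib800", rate = med(30)),
    data.frame(endpoint = "OS", genotype = "other", drug = "imatinib400", rate = med(36)),
    data.frame(endpoint = "OS", genotype = "other", drug = "imatinib800", rate = med(36)),
    # OS, sunitinib trial
    data.frame(endpoint = "OS", genotype = "exon11", drug = "sunitinib", rate = med(20)),
    data.frame(endpoint = "OS", genotype = "exon9", drug = "sunitinib", rate = med(27)),
    data.frame(endpoint = "OS", genotype = "other", drug = "sunitinib", rate = med(20))
  )
  spec$family <- "exponential"
  spec$shape <- NA_real_
  spec
}

spec_rate <- function(spec, endpoint, genotype, drug) {
  i <- spec$endpoint == endpoint & spec$genotype == genotype & spec$drug == drug
  if (sum(i) != 1) return(NA_real_)
  spec$rate[i]
}

validate_trial_spec <- function(spec) {
  need <- c("endpoint", "genotype", "drug", "family", "rate")
  if (!all(need %in% names(spec)))
    stop("trial spec must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  errs <- character()
  r9lo <- spec_rate(spec, "PFS", "exon9", "imatinib400")
  r9hi <- spec_rate(spec, "PFS", "exon9", "imatinib800")
  if (!is.na(r9lo) && !is.na(r9hi) && !(r9hi < r9lo))
    errs <- c(errs, "exon 9 PFS hazard on imatinib 800 must be below that on imatinib 400")
  r11 <- spec_rate(spec, "PFS", "exon11", "imatinib400")
  others <- c(spec_rate(spec, "PFS", "exon9", "imatinib400"),
              spec_rate(spec, "PFS", "other", "imatinib400"))
  if (!is.na(r11) && any(!is.na(others) & others <= r11))
    errs <- c(errs, "exon 11 must have the lowest PFS hazard on imatinib 400")
  for (g in c("exon11", "exon9", "other")) {
    o4 <- spec_rate(spec, "OS", g, "imatinib400")
    o8 <- spec_rate(spec, "OS", g, "imatinib800")
    if (!is.na(o4) && !is.na(o8) && abs(o4 - o8) > 1e-12)
      errs <- c(errs, sprintf("OS hazards must be equal across imatinib doses (%s)", g))
  }
  if (length(errs))
    stop("trial spec violates the qualitative survival structure:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  invisible(spec)
}

curve_key <- function(endpoint, genotype, drug) paste(endpoint, genotype, drug, sep = ".")

#' Generate the synthetic trial survival curves
#'
#' Samples each parametric curve from `spec` on a monthly grid and, when
#' `noise_sd > 0`, perturbs the log-survival values with seeded Gaussian
#' noise (emulating digitization error), caps at 1, and re-monotonizes
#' with a simple running minimum. Deterministic for a fixed seed; the
#' caller's RNG state is left untouched.
#'
#' @param seed integer seed.
#' @param spec a trial specification as from [default_trial_spec()]; it is
#'   validated against the qualitative survival structure first.
#' @param noise_sd standard deviation of the log-scale perturbation
#'   (0 gives the exact parametric values).
#' @param t_max last time point in months (default 180, enough for a
#'   15-year horizon).
#' @param by grid spacing in months.
#' @return named list of [survival_curve()] objects keyed
#'   `"<endpoint>.<genotype>.<drug>"`.
#' @export
generate_fixture_trials <- function(seed, spec = default_trial_spec(),
                                    noise_sd = 0.03, t_max = 180, by = 1) {
  validate_trial_spec(spec)
  times <- seq(0, t_max, by = by)
  with_preserved_seed(seed, {
    curves <- vector("list", nrow(spec))
    names(curves) <- curve_key(spec$endpoint, spec$genotype, spec$drug)
    for (i in seq_len(nrow(spec))) {
      ps <- parametric_survival(spec$family[i], spec$rate[i],
                                if (is.na(spec$shape[i])) NULL else spec$shape[i])
      s <- psurv_eval(ps, times)
      if (noise_sd > 0) {
        eps <- c(0, stats::rnorm(length(times) - 1, 0, noise_sd))
        s <- pmin(1, exp(log(pmax(s, 1e-300)) + eps))
        s <- cummin(s)
        s[1] <- 1
      }
      curves[[i]] <- survival_curve(times, s, spec$endpoint[i],
                                    spec$genotype[i], spec$drug[i])
    }
    curves
  })
}
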