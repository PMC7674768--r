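#' @title Synthetic cohorts and packaged fixtures
#' @description A generator of synthetic patients with known kinetic ground
#'   truth, emulating the study's planar-imaging schedule (four acquisition
#'   windows out to 120 h) with multiplicative lognormal measurement noise,
#'   plus loaders for the published 13-patient tables shipped as plain-text
#'   fixtures.
#' @name synthetic_data
NULL

#' Synthetic-cohort generator configuration
#'
#' Defaults emulate the study conditions: 13 patients, four imaging
#' windows (0.5-1, 16-24, 36-48 h, jittered uniformly, plus a fixed 120 h
#' point), 5\% multiplicative lognormal noise, organ masses and body
#' weights drawn uniformly in the published ranges, and per-organ
#' effective (Lu-177) half-lives drawn uniformly in the published ranges
#' so fitted washout matches the cohort's spread.
#'
#' @param n_patients Number of patients, >= 1.
#' @param seed Integer seed; the generator is deterministic given it.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   measurement noise, >= 0 (default 0.05).
#' @param noise_model `"lognormal"` (default) or `"gaussian"`.
#' @param windows List of `c(lo, hi)` sampling windows in hours.
#' @param organs Named list of per-organ specs, each with `mass_g = c(lo,
#'   hi)`, `t_eff_h = c(lo, hi)` (effective half-life range in the Lu-177
#'   context) and `amplitude = c(lo, hi)` (zero-time fraction of injected
#'   activity).
#' @param weight_kg Body-weight range, kg.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_patients = 13, seed = 1, noise_cv = 0.05,
                             noise_model = c("lognormal", "gaussian"),
                             windows = list(c(0.5, 1), c(16, 24), c(36, 48),
                                            c(120, 120)),
                             organs = list(
                               parotid = list(mass_g = c(33, 89),
                                              t_eff_h = c(1.7, 46.2),
                                              amplitude = c(0.005, 0.03)),
                               submandibular = list(mass_g = c(13, 34),
                                                    t_eff_h = c(2.8, 32.7),
                                                    amplitude = c(0.002, 0.015))),
                             weight_kg = c(72, 105)) {
  noise_model <- match.arg(noise_model)
  if (n_patients < 1) stop("'n_patients' must be >= 1")
  if (noise_cv < 0) stop("'noise_cv' must be >= 0")
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 noise_cv = noise_cv, noise_model = noise_model,
                 windows = windows, organs = organs, weight_kg = weight_kg),
            class = "generator_config")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Each patient gets, per organ, a mono-exponential washout truth in the
#' Lu-177 measurement context: value(t) = A * exp(-lam_eff * t), sampled
#' at one jittered time per window and multiplied by measurement noise.
#' The returned truth carries the generating parameters and the closed-form
#' consequences: the Lu-177 residence time `A/lam_eff`, the Ac-225
#' converted residence time `A/(lam_bio + ln2/T_Ac)`, and the sphere-model
#' weighted dose coefficient computed from it with the packaged chain.
#'
#' @param config A [generator_config()].
#' @param chain Decay chain used for the truth dose coefficients.
#' @param rbe_alpha RBE for the truth coefficients (default 5).
#' @return List with `tacs` (data frame `patient_id, organ, t_h, value`)
#'   and `truth` (data frame `patient_id, organ, weight_kg, mass_g,
#'   amplitude, lam_eff_lu, lam_bio, lam_eff_ac, tau_lu_h, tau_ac_h,
#'   dose_coeff_weighted`).
#' @export
generate_cohort <- function(config = generator_config(),
                            chain = build_default_chain(), rbe_alpha = 5) {
  stopifnot(inherits(config, "generator_config"))
  lam_phys_lu <- log(2) / PHYSICAL_HALF_LIFE_H[["Lu-177"]]
  lam_phys_ac <- log(2) / PHYSICAL_HALF_LIFE_H[["Ac-225"]]
  with_preserved_rng(config$seed, {
    tac_rows <- list()
    truth_rows <- list()
    for (i in seq_len(config$n_patients)) {
      weight <- stats::runif(1, config$weight_kg[1], config$weight_kg[2])
      for (organ in names(config$organs)) {
        spec <- config$organs[[organ]]
        mass <- stats::runif(1, spec$mass_g[1], spec$mass_g[2])
        t_eff <- stats::runif(1, spec$t_eff_h[1], spec$t_eff_h[2])
        lam_eff <- log(2) / t_eff
        lam_bio <- max(lam_eff - lam_phys_lu, 1e-8)
        amp <- stats::runif(1, spec$amplitude[1], spec$amplitude[2])
        t_h <- vapply(config$windows,
                      function(w) stats::runif(1, w[1], w[2]), numeric(1))
        clean <- amp * exp(-lam_eff * t_h)
        noise <- if (config$noise_cv == 0) {
          rep(1, length(t_h))
        } else if (config$noise_model == "lognormal") {
          sdlog <- sqrt(log(1 + config$noise_cv^2))
          stats::rlnorm(length(t_h), meanlog = -sdlog^2 / 2, sdlog = sdlog)
        } else {
          pmax(stats::rnorm(length(t_h), 1, config$noise_cv), 0)
        }
        lam_eff_ac <- lam_bio + lam_phys_ac
        tau_ac <- amp / lam_eff_ac
        coeff <- sphere_dose_coefficient(tau_ac, sphere_organ(organ, mass),
                                         chain, rbe_alpha)$total_weighted
        tac_rows[[length(tac_rows) + 1]] <- data.frame(
          patient_id = i, organ = organ, t_h = t_h, value = clean * noise,
          stringsAsFactors = FALSE)
        truth_rows[[length(truth_rows) + 1]] <- data.frame(
          patient_id = i, organ = organ, weight_kg = weight, mass_g = mass,
          amplitude = amp, lam_eff_lu = lam_eff, lam_bio = lam_bio,
          lam_eff_ac = lam_eff_ac, tau_lu_h = amp / lam_eff,
          tau_ac_h = tau_ac, dose_coeff_weighted = coeff,
          stringsAsFactors = FALSE)
      }
    }
    list(tacs = do.call(rbind, tac_rows), truth = do.call(rbind, truth_rows))
  })
}

#' Load the packaged published tables
#'
#' Returns the three published tables shipped as plain-text fixtures: the
#' 13-patient predictive dose coefficients (Bd_RBE5/MBq, six organs), the
#' radiobiology parameter table, and the 13-patient salivary BED table
#' (Gy; parotid, submandibular, and their per-patient mean).
#'
#' @return List with data frames `doses`, `params`, `bed`.
#' @export
load_paper_fixtures <- function() {
  f <- function(name) {
    path <- system.file("extdata", name, package = "actichain")
    if (!nzchar(path)) stop("packaged fixture missing: ", name)
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  list(doses = f("table1_dose_coefficients.csv"),
       params = f("table2_radiobiology_params.csv"),
       bed = f("table3_bed.csv"))
}

#' MD5 checksums of the packaged fixtures
#'
#' @return Named character vector of checksums, one per packaged data
#'   file; used to pin the fixtures against accidental edits.
#' @export
fixture_checksums <- function() {
  dir <- system.file("extdata", package = "actichain")
  files <- sort(list.files(dir, full.names = TRUE))
  sums <- tools::md5sum(files)
  names(sums) <- basename(files)
  sums
}
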