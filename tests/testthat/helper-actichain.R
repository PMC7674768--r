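# Shared helpers: noiseless curves and the parameter-recovery simulation
# reused by the kinetics, synthetic-data and acceptance tests.

mono_tac <- function(a, k, t = c(1, 20, 40, 120),
                     half_life = PHYSICAL_HALF_LIFE_H[["Lu-177"]]) {
  new_tac("parotid", t, a * exp(-k * t), physical_half_life = half_life)
}

# Median relative errors of recovered slow rate and residence time over a
# synthetic cohort generated at the given noise level.
recovery_sim <- function(n_patients, noise_cv, seed) {
  cohort <- generate_cohort(generator_config(n_patients = n_patients,
                                             seed = seed,
                                             noise_cv = noise_cv))
  key <- paste(cohort$tacs$patient_id, cohort$tacs$organ)
  truth_key <- paste(cohort$truth$patient_id, cohort$truth$organ)
  rel_rate <- rel_tau <- numeric(nrow(cohort$truth))
  for (i in seq_len(nrow(cohort$truth))) {
    rows <- cohort$tacs[key == truth_key[i], ]
    fit <- fit_exponential(new_tac(rows$organ[1], rows$t_h, rows$value),
                           model = "mono")
    rel_rate[i] <- slow_rate(fit) / cohort$truth$lam_eff_lu[i] - 1
    rel_tau[i] <- residence_time(fit) / cohort$truth$tau_lu_h[i] - 1
  }
  list(rate = rel_rate, tau = rel_tau)
}
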