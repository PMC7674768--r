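#' @title Cohort-level analysis
#' @description Summary statistics mirroring the published tables,
#'   rescaling to a no-protector reference cohort, threshold counting
#'   against external-beam constraints, and NTCP-versus-injected-activity
#'   curves with bootstrap confidence intervals.
#' @name cohort_analysis
NULL

#' Per-patient salivary gland dose
#'
#' The salivary value is the per-patient mean of the parotid and
#' submandibular values (vectorised).
#'
#' @param pg,sg Parotid and submandibular values (same units).
#' @return Numeric vector of salivary values.
#' @export
salivary_mean <- function(pg, sg) {
  if (length(pg) != length(sg)) stop("'pg' and 'sg' lengths differ")
  (pg + sg) / 2
}

#' Cohort summary statistics
#'
#' Median (standard order-statistic definition), range, mean, and sample
#' standard deviation (n - 1 denominator), the statistics printed in the
#' published tables' "Median (range)" and "Mean (SD)" rows.
#'
#' @param values Numeric vector, n >= 2; `NA`s are dropped.
#' @return A `cohort_summary` list: `n`, `median`, `min`, `max`, `mean`,
#'   `sd`.
#' @export
cohort_summary <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least two non-missing values")
  structure(list(
    n = length(values),
    median = stats::median(values),
    min = min(values),
    max = max(values),
    mean = mean(values),
    sd = stats::sd(values)
  ), class = "cohort_summary")
}

#' Rescale a cohort to a reference mean dose
#'
#' Multiplies every patient's dose coefficients by
#' `reference_mean / cohort_mean`, where the cohort mean is taken over the
#' chosen organ column. This maps a protector-treated cohort onto the dose
#' scale of a published cohort treated without salivary protectors.
#'
#' @param cohort Data frame with one row per patient and numeric dose
#'   coefficient columns.
#' @param reference_mean Reference mean coefficient (same units as the
#'   cohort columns), > 0.
#' @param organ Name of the column whose cohort mean defines the factor
#'   (default `"salivary"`).
#' @param dose_cols Columns to scale; defaults to the standard organ
#'   columns present in `cohort`.
#' @return List with `cohort` (scaled copy) and `scaling` (a
#'   `reference_scaling` list: `reference_mean`, `cohort_mean`, `factor`).
#' @export
rescale_to_reference <- function(cohort, reference_mean, organ = "salivary",
                                 dose_cols = NULL) {
  if (!organ %in% names(cohort)) stop("no column '", organ, "' in cohort")
  if (reference_mean <= 0) stop("'reference_mean' must be > 0")
  cohort_mean <- mean(cohort[[organ]], na.rm = TRUE)
  if (!is.finite(cohort_mean) || cohort_mean <= 0) {
    stop("cohort mean for '", organ, "' must be > 0")
  }
  if (is.null(dose_cols)) {
    dose_cols <- intersect(
      c("kidneys", "liver", "parotid", "submandibular", "red_marrow",
        "whole_body", "salivary"),
      names(cohort))
  }
  factor <- reference_mean / cohort_mean
  scaled <- cohort
  scaled[dose_cols] <- lapply(scaled[dose_cols], function(x) x * factor)
  list(cohort = scaled,
       scaling = structure(list(reference_mean = reference_mean,
                                cohort_mean = cohort_mean,
                                factor = factor),
                           class = "reference_scaling"))
}

#' Count values exceeding a threshold
#'
#' @param values Numeric vector (NAs dropped).
#' @param threshold Threshold in the same units.
#' @return Integer count of values strictly greater than `threshold`.
#' @export
count_exceeding <- function(values, threshold) {
  sum(values > threshold, na.rm = TRUE)
}

#' Convert a Lu-177 effective decay constant to the Ac-225 context
#'
#' Removes the Lu-177 physical component from an effective washout
#' constant and adds the Ac-225 one:
#' `lam_Ac = lam_Lu - ln2/T(Lu-177) + ln2/T(Ac-225)`.
#'
#' @param lam_lu Effective decay constant measured with Lu-177, 1/h.
#' @return Effective decay constant for Ac-225, 1/h.
#' @export
lambda_lu_to_ac <- function(lam_lu) {
  lam_bio <- lam_lu - log(2) / PHYSICAL_HALF_LIFE_H[["Lu-177"]]
  if (any(lam_bio < 0)) stop("biological rate implied by 'lam_lu' is negative")
  lam_bio + log(2) / PHYSICAL_HALF_LIFE_H[["Ac-225"]]
}

#' NTCP as a function of injected activity
#'
#' For each activity concentration (kBq per kg body weight) recomputes
#' every patient's high-LET BED via the mixture formalism (nonlinear in
#' activity), converts to EQD2, aggregates across the cohort, and maps the
#' aggregate through the LKB model. Because the published per-patient
#' washout constants are not available with the dose tables, a cohort
#' default can stand in for missing per-patient values (flagged in the
#' output attributes).
#'
#' @param cohort Data frame with one row per patient; must contain a dose
#'   coefficient column named by `coeff_col` (RBE-weighted, Bd/MBq, when
#'   `dose_input = "weighted_coefficient"`); optional columns `weight_kg`
#'   and `lam` (effective decay constant in the Ac-225 context, 1/h).
#' @param activities_kbq_kg Numeric vector of activity concentrations.
#' @param params A [radiobiology_params()].
#' @param coeff_col Name of the coefficient column (default `"salivary"`).
#' @param dose_input `"alpha_unweighted"` (default): the coefficient column
#'   is an RBE-weighted total and is converted to the unweighted alpha-only
#'   dose through the chain's energy partition before entering the initial
#'   dose rate, as the mixture BED prescribes; `"weighted"`: the
#'   coefficient is used as-is.
#' @param chain,rbe_alpha Chain and RBE used for the weighted-to-alpha
#'   conversion.
#' @param aggregation `"mean_eqd2"`, `"median_eqd2"`, or
#'   `"mean_patient_ntcp"`.
#' @param weight_default kg, used where `weight_kg` is missing (default
#'   80, the cohort median).
#' @param lam_default 1/h, used where `lam` is missing; default is the
#'   cohort-median parotid effective washout (25.5 h half-life, measured
#'   with Lu-177) converted to the Ac-225 context.
#' @param bootstrap List with `B` (replicates) and `seed`; percentile 95\%
#'   CI over patient resampling. `B = 0` disables the CI.
#' @return Data frame with columns `activity_kbq_kg`, `ntcp`, `ci_low`,
#'   `ci_high`, `aggregation`.
#' @export
ntcp_vs_activity <- function(cohort, activities_kbq_kg,
                             params = radiobiology_params(),
                             coeff_col = "salivary",
                             dose_input = c("alpha_unweighted", "weighted"),
                             chain = build_default_chain(),
                             rbe_alpha = 5,
                             aggregation = c("mean_eqd2", "median_eqd2",
                                             "mean_patient_ntcp"),
                             weight_default = 80,
                             lam_default = lambda_lu_to_ac(log(2) / 25.5),
                             bootstrap = list(B = 1000, seed = 20201105)) {
  dose_input <- match.arg(dose_input)
  aggregation <- match.arg(aggregation)
  if (!coeff_col %in% names(cohort)) stop("no column '", coeff_col, "' in cohort")
  coeff <- cohort[[coeff_col]]
  if (any(is.na(coeff))) stop("missing dose coefficients in '", coeff_col, "'")
  n <- nrow(cohort)
  weight <- if ("weight_kg" %in% names(cohort)) cohort$weight_kg else rep(NA_real_, n)
  lam <- if ("lam" %in% names(cohort)) cohort$lam else rep(NA_real_, n)
  used_defaults <- c(weight = anyNA(weight), lam = anyNA(lam))
  weight[is.na(weight)] <- weight_default
  lam[is.na(lam)] <- lam_default
  if (any(lam <= 0)) stop("per-patient 'lam' must be > 0")

  d_alpha <- switch(dose_input,
    alpha_unweighted = alpha_dose_from_weighted(coeff, chain, rbe_alpha),
    weighted = coeff)
  rbe_m <- rbe_max(params$rbe_exp, params$d_ref, params$alpha_beta)

  patient_eqd2 <- function(idx, activity) {
    a_mbq <- activity * weight[idx] / 1000  # kBq/kg * kg -> MBq
    vapply(seq_along(idx), function(j) {
      i <- idx[j]
      rates <- initial_dose_rates(d_alpha[i], a_mbq[j], lam[i])
      eqd2(bed_high(rates, params, rbe_m = rbe_m), params$alpha_beta)
    }, numeric(1))
  }
  aggregate_ntcp <- function(idx, activity) {
    e <- patient_eqd2(idx, activity)
    switch(aggregation,
      mean_eqd2 = ntcp_lkb(mean(e), params$td50, params$m),
      median_eqd2 = ntcp_lkb(stats::median(e), params$td50, params$m),
      mean_patient_ntcp = mean(ntcp_lkb(e, params$td50, params$m)))
  }

  all_idx <- seq_len(n)
  point <- vapply(activities_kbq_kg, function(a) aggregate_ntcp(all_idx, a),
                  numeric(1))
  ci_low <- ci_high <- rep(NA_real_, length(activities_kbq_kg))
  if (!is.null(bootstrap) && bootstrap$B > 0) {
    boot_mat <- with_preserved_rng(bootstrap$seed, {
      replicate(bootstrap$B, {
        idx <- sample.int(n, n, replace = TRUE)
        vapply(activities_kbq_kg, function(a) aggregate_ntcp(idx, a),
               numeric(1))
      })
    })
    boot_mat <- matrix(boot_mat, nrow = length(activities_kbq_kg))
    qs <- apply(boot_mat, 1, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE)
    ci_low <- qs[1, ]
    ci_high <- qs[2, ]
  }
  out <- data.frame(activity_kbq_kg = activities_kbq_kg, ntcp = point,
                    ci_low = ci_low, ci_high = ci_high,
                    aggregation = aggregation,
                    stringsAsFactors = FALSE)
  attr(out, "used_defaults") <- used_defaults
  out
}

# Run code under a seeded RNG without disturbing the caller's RNG state.
with_preserved_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}
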