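#' @title Radiobiological model
#' @description The linear-quadratic machinery that makes high-LET,
#'   continuously decaying irradiation comparable with fractionated
#'   external-beam schedules: maximum RBE, mixture BED for exponentially
#'   decaying dose rates (brachytherapy formalism extended to the Ac-225
#'   daughter mixture), low-LET fractionated BED, EQD2, and the
#'   Lyman-Kutcher-Burman probit NTCP.
#' @name radiobiology
NULL

#' Radiobiology parameter set
#'
#' Defaults are the xerostomia parameter set used throughout: alpha/beta
#' 3 Gy, repair rate mu 0.46 per hour, experimental alpha RBE 5, reference
#' low-LET fraction dose 2 Gy, and the acute grade >= 2 xerostomia LKB
#' parameters TD50 = 14 Gy (EQD2 scale) and slope m = 0.88.
#'
#' @param alpha_beta Gy, > 0.
#' @param mu Sublethal-damage repair rate, 1/h, > 0.
#' @param rbe_exp Experimental high-LET RBE, > 0.
#' @param d_ref Reference low-LET fraction dose, Gy, >= 0.
#' @param td50 LKB 50\%-complication dose on the EQD2 scale, Gy, > 0.
#' @param m LKB slope, > 0.
#' @return A `radiobiology_params` list.
#' @export
radiobiology_params <- function(alpha_beta = 3, mu = 0.46, rbe_exp = 5,
                                d_ref = 2, td50 = 14, m = 0.88) {
  vals <- c(alpha_beta = alpha_beta, mu = mu, rbe_exp = rbe_exp,
            td50 = td50, m = m)
  if (any(vals <= 0) || d_ref < 0) {
    stop("radiobiology parameters must be > 0 (d_ref >= 0)")
  }
  structure(list(alpha_beta = alpha_beta, mu = mu, rbe_exp = rbe_exp,
                 d_ref = d_ref, td50 = td50, m = m),
            class = "radiobiology_params")
}

#' Maximum RBE for the linear LQ term
#'
#' `RBE_M = RBE_exp + (d/alpha_beta) * (RBE_exp^2 - 1) / RBE_exp`, where d
#' is the fraction dose of the reference low-LET schedule. With the
#' defaults (5, 2 Gy, 3 Gy) this is 8.2.
#'
#' @param rbe_exp Experimental RBE, > 0.
#' @param d_ref Reference fraction dose, Gy, >= 0.
#' @param alpha_beta Gy, > 0.
#' @return Dimensionless RBE_M.
#' @export
rbe_max <- function(rbe_exp, d_ref, alpha_beta) {
  if (rbe_exp <= 0 || alpha_beta <= 0 || d_ref < 0) {
    stop("'rbe_exp' and 'alpha_beta' must be > 0, 'd_ref' >= 0")
  }
  rbe_exp + (d_ref / alpha_beta) * (rbe_exp^2 - 1) / rbe_exp
}

#' Initial dose rates of the decaying mixture
#'
#' For each source n with (unweighted, alpha-only) absorbed-dose
#' coefficient `D_n` (Gy/MBq), injected activity `A` (MBq) and shared
#' effective decay constant `lam` (1/h), the initial dose rate is
#' `R0_n = D_n * A * lam` (Gy/h). Under the equilibrium assumption every
#' daughter shares the parent's effective decay constant.
#'
#' @param alpha_dose_per_mbq Numeric vector of per-source coefficients,
#'   Gy/MBq, >= 0 (a single total is equivalent by linearity).
#' @param a_inj_mbq Injected activity, MBq, >= 0.
#' @param lam Effective decay constant, 1/h, > 0 (slow-phase value).
#' @return A `dose_rate_set`: list with `r0` (Gy/h vector) and `lam`.
#' @export
initial_dose_rates <- function(alpha_dose_per_mbq, a_inj_mbq, lam) {
  if (any(alpha_dose_per_mbq < 0)) stop("dose coefficients must be >= 0")
  if (a_inj_mbq < 0) stop("'a_inj_mbq' must be >= 0")
  if (lam <= 0) stop("'lam' must be > 0")
  structure(list(r0 = alpha_dose_per_mbq * a_inj_mbq * lam, lam = lam),
            class = "dose_rate_set")
}

#' High-LET biologically effective dose of a decaying mixture
#'
#' Mixture BED for continuous, exponentially decaying irradiation:
#' \deqn{BED_H = \frac{1}{\lambda}\sum_n R_{0,n}\left\{RBE_M +
#'   \frac{\sum_n\sum_p R_{0,n} R_{0,p}}
#'        {(\lambda+\mu)(\alpha/\beta)\sum_n R_{0,n}}\right\}}
#' The double sum over source pairs is computed explicitly; it collapses
#' algebraically to `S^2` with `S = sum(R0)`, so the result depends on the
#' mixture only through the summed initial dose rate (partition
#' invariance). Only the alpha emissions enter `R0`; RBE enters solely
#' through `RBE_M` in the linear term.
#'
#' @param rates A [initial_dose_rates()] result.
#' @param params A [radiobiology_params()]; supplies `mu`, `alpha_beta`
#'   and, via [rbe_max()], `RBE_M`.
#' @param rbe_m Optional override for RBE_M.
#' @return BED in Gy.
#' @export
bed_high <- function(rates, params = radiobiology_params(), rbe_m = NULL) {
  stopifnot(inherits(rates, "dose_rate_set"))
  if (rates$lam <= 0) stop("'lam' must be > 0")
  if (is.null(rbe_m)) {
    rbe_m <- rbe_max(params$rbe_exp, params$d_ref, params$alpha_beta)
  }
  r0 <- rates$r0
  s <- sum(r0)
  if (s == 0) return(0)
  double_sum <- sum(outer(r0, r0))  # == s^2; kept explicit as the mixture form
  (1 / rates$lam) * s *
    (rbe_m + double_sum / ((rates$lam + params$mu) * params$alpha_beta * s))
}

#' Low-LET fractionated biologically effective dose
#'
#' `BED_L = D * (1 + (D/N) / alpha_beta)` for a total dose D delivered in
#' N fractions. The QUANTEC parotid constraint, 26 Gy in 30 fractions at
#' alpha/beta 3 Gy, gives 33.5 Gy.
#'
#' @param d_total Total dose, Gy, >= 0.
#' @param n_fractions Number of fractions, >= 1.
#' @param alpha_beta Gy, > 0.
#' @return BED in Gy.
#' @export
bed_low <- function(d_total, n_fractions, alpha_beta) {
  if (d_total < 0) stop("'d_total' must be >= 0")
  if (n_fractions < 1) stop("'n_fractions' must be >= 1")
  if (alpha_beta <= 0) stop("'alpha_beta' must be > 0")
  d_total * (1 + (d_total / n_fractions) / alpha_beta)
}

#' Equivalent dose in 2-Gy fractions
#'
#' `EQD2 = BED / (1 + 2/alpha_beta)`.
#'
#' @param bed BED in Gy, >= 0 (vectorised).
#' @param alpha_beta Gy, > 0.
#' @return EQD2 in Gy.
#' @export
eqd2 <- function(bed, alpha_beta) {
  if (any(bed < 0)) stop("'bed' must be >= 0")
  if (alpha_beta <= 0) stop("'alpha_beta' must be > 0")
  bed / (1 + 2 / alpha_beta)
}

#' Lyman-Kutcher-Burman complication probability
#'
#' Probit dose-response: `NTCP = Phi((EQD2 - TD50) / (m * TD50))` with Phi
#' the standard normal CDF. At EQD2 = TD50 the probability is exactly 0.5.
#'
#' @param eqd2_value EQD2 in Gy (vectorised).
#' @param td50 Gy, > 0.
#' @param m Slope, > 0.
#' @return Probability in (0, 1).
#' @export
ntcp_lkb <- function(eqd2_value, td50, m) {
  if (td50 <= 0 || m <= 0) stop("'td50' and 'm' must be > 0")
  stats::pnorm((eqd2_value - td50) / (m * td50))
}
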