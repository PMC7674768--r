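#' @title Organ kinetics from planar imaging
#' @description From planar gamma-camera counts to fitted washout curves,
#'   effective half-lives and MIRD residence times, including conversion of
#'   the measured surrogate-isotope (Lu-177) kinetics to the alpha emitter
#'   (Ac-225) via the biological curve.
#' @name kinetics
NULL

#' Physical half-lives of the isotopes involved, hours.
#' @format Named numeric vector.
#' @export
PHYSICAL_HALF_LIFE_H <- c("Lu-177" = 159.5, "Ac-225" = 238.08)

#' Construct a time-activity curve
#'
#' @param organ Organ label.
#' @param t_h Hours post-injection, strictly increasing, >= 0.
#' @param value Fraction of injected activity at each time (dimensionless,
#'   >= 0), as measured (i.e. embedding the physical decay of the imaging
#'   isotope).
#' @param sd Optional per-point standard deviations.
#' @param physical_half_life Hours; the physical half-life of the isotope
#'   whose decay the values embed. `Inf` marks a purely biological curve.
#' @return A `tac` object (list with `organ`, `points` data frame,
#'   `physical_half_life`).
#' @export
new_tac <- function(organ, t_h, value, sd = NULL,
                    physical_half_life = PHYSICAL_HALF_LIFE_H[["Lu-177"]]) {
  t_h <- as.numeric(t_h); value <- as.numeric(value)
  if (length(t_h) != length(value)) stop("'t_h' and 'value' lengths differ")
  if (any(t_h < 0)) stop("'t_h' must be >= 0")
  if (is.unsorted(t_h, strictly = TRUE)) stop("'t_h' must be strictly increasing")
  if (any(value < 0)) stop("'value' must be >= 0")
  if (!is.null(sd) && length(sd) != length(value)) stop("'sd' length mismatch")
  if (physical_half_life <= 0) stop("'physical_half_life' must be > 0")
  pts <- data.frame(t_h = t_h, value = value)
  if (!is.null(sd)) pts$sd <- as.numeric(sd)
  structure(list(organ = as.character(organ), points = pts,
                 physical_half_life = physical_half_life),
            class = "tac")
}

#' Triple-energy-window scatter correction
#'
#' Estimates the scatter in the main emission window from two flanking
#' narrow windows by trapezoidal interpolation and subtracts it:
#' `main - (lower/w_lower + upper/w_upper) * w_main / 2`, clamped at zero.
#'
#' @param main,lower,upper Counts in the main, lower and upper windows
#'   (all >= 0).
#' @param w_main,w_lower,w_upper Window widths in keV (> 0). For Lu-177 at
#'   208 keV with a 20\% main window and 10\% flanking windows at 175 and
#'   238 keV, these are 41.6, 17.5 and 23.8 keV.
#' @return Scatter-corrected counts, never negative.
#' @export
tew_scatter_correct <- function(main, lower, upper,
                                w_main = 41.6, w_lower = 17.5, w_upper = 23.8) {
  if (any(c(main, lower, upper) < 0)) stop("counts must be >= 0")
  if (any(c(w_main, w_lower, w_upper) <= 0)) stop("window widths must be > 0")
  pmax(0, main - (lower / w_lower + upper / w_upper) * w_main / 2)
}

#' Conjugate-view fraction of injected activity
#'
#' Geometric-mean (anterior x posterior) organ counts divided by the
#' geometric-mean whole-body counts of the earliest acquisition, which
#' represent the injected activity. No attenuation correction is applied.
#'
#' @param organ List or vector with elements `ant` and `post`: scatter-
#'   corrected anterior and posterior counts for the organ.
#' @param whole_body_ref Same structure, for the whole body at the earliest
#'   time point; its geometric mean must be > 0.
#' @return Fraction of injected activity (dimensionless).
#' @export
conjugate_view_fraction <- function(organ, whole_body_ref) {
  gm <- function(x) sqrt(as.numeric(x[["ant"]]) * as.numeric(x[["post"]]))
  ref <- gm(whole_body_ref)
  if (!is.finite(ref) || ref <= 0) {
    stop("whole-body reference geometric mean must be > 0")
  }
  gm(organ) / ref
}

#' Remove physical decay from a time-activity curve
#'
#' Multiplies each value by `exp(+ln2 * t / T_phys)`, turning a measured
#' curve into the purely biological retention curve. The output is marked
#' biological (`physical_half_life = Inf`).
#'
#' @param tac A `tac`.
#' @param physical_half_life Hours; defaults to the half-life recorded on
#'   the curve.
#' @return A biological `tac`.
#' @seealso [apply_physical_decay()] for the inverse.
#' @export
decay_correct <- function(tac, physical_half_life = tac$physical_half_life) {
  stopifnot(inherits(tac, "tac"))
  if (!is.finite(physical_half_life) || physical_half_life <= 0) {
    stop("'physical_half_life' must be finite and > 0")
  }
  out <- tac
  out$points$value <- tac$points$value *
    exp(log(2) * tac$points$t_h / physical_half_life)
  out$physical_half_life <- Inf
  out
}

#' Impose a physical decay on a biological curve
#'
#' Inverse of [decay_correct()]: multiplies each value of a biological
#' curve by `exp(-ln2 * t / T_phys)`, e.g. to convert Lu-177-derived
#' biological kinetics to the Ac-225 context.
#'
#' @param tac_biological A biological `tac` (physical half-life `Inf`).
#' @param physical_half_life Hours, > 0, of the isotope to impose.
#' @return A `tac` embedding the requested physical decay.
#' @export
apply_physical_decay <- function(tac_biological, physical_half_life) {
  stopifnot(inherits(tac_biological, "tac"))
  if (!is.finite(physical_half_life) || physical_half_life <= 0) {
    stop("'physical_half_life' must be finite and > 0")
  }
  out <- tac_biological
  out$points$value <- tac_biological$points$value *
    exp(-log(2) * tac_biological$points$t_h / physical_half_life)
  out$physical_half_life <- physical_half_life
  out
}

#' Fit an exponential washout model
#'
#' Fits `sum_i A_i * exp(-k_i * t)` to a time-activity curve by nonlinear
#' least squares on the linear scale (Levenberg-Marquardt), initialised
#' from a log-linear regression (mono) or curve peeling (bi). Amplitudes
#' are constrained >= 0 (washout only, no uptake phase) and rates
#' > 1e-6 per hour.
#'
#' @param tac A `tac` with >= 2 points (mono) or >= 4 points (bi).
#' @param model `"mono"` or `"bi"`.
#' @param weighting `"none"` (default; unweighted least squares) or
#'   `"value"` (weights 1/value^2, i.e. relative error).
#' @return An `exp_fit` object: list with `model`, `terms` (data frame
#'   `amplitude`, `rate`, ordered by rate ascending so the slow phase is
#'   first), and `rss`.
#' @export
fit_exponential <- function(tac, model = c("mono", "bi"),
                            weighting = c("none", "value")) {
  stopifnot(inherits(tac, "tac"))
  model <- match.arg(model)
  weighting <- match.arg(weighting)
  pts <- tac$points
  npar <- if (model == "mono") 2L else 4L
  if (nrow(pts) < npar) {
    stop(sprintf("'%s' fit needs >= %d points, got %d", model, npar, nrow(pts)))
  }
  t <- pts$t_h; y <- pts$value
  w <- if (weighting == "value") 1 / pmax(y, max(y) * 1e-6)^2 else rep(1, length(y))

  ok <- y > 0
  if (sum(ok) < 2) stop("need at least two positive values to initialise fit")
  loglin <- stats::lm(log(y[ok]) ~ t[ok])
  a0 <- exp(stats::coef(loglin)[[1]])
  k0 <- max(-stats::coef(loglin)[[2]], 1e-6)

  rate_lo <- 1e-6
  if (model == "mono") {
    start <- list(A = a0, k = k0)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-k * t),
                        start = start, weights = w,
                        lower = c(A = 0, k = rate_lo),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) {
        stop("mono-exponential fit did not converge (initialiser A=",
             signif(a0, 6), ", k=", signif(k0, 6), "): ", conditionMessage(e))
      })
    cf <- stats::coef(fit)
    terms <- data.frame(amplitude = cf[["A"]], rate = cf[["k"]])
  } else {
    # curve peeling: slow phase from the tail, fast phase from the residual
    tail_idx <- which(ok)[seq(from = max(1, sum(ok) - 1), to = sum(ok))]
    tail_idx <- which(ok)[which(ok) >= stats::median(seq_along(t))]
    if (length(tail_idx) < 2) tail_idx <- utils::tail(which(ok), 2)
    slow <- stats::lm(log(y[tail_idx]) ~ t[tail_idx])
    a_s <- exp(stats::coef(slow)[[1]])
    k_s <- max(-stats::coef(slow)[[2]], rate_lo)
    resid <- y - a_s * exp(-k_s * t)
    pos <- resid > 0 & t < stats::median(t)
    if (sum(pos) >= 2) {
      fast <- stats::lm(log(resid[pos]) ~ t[pos])
      a_f <- exp(stats::coef(fast)[[1]])
      k_f <- max(-stats::coef(fast)[[2]], k_s * 5)
    } else {
      a_f <- a0 / 2
      k_f <- k0 * 5
    }
    start <- list(A1 = a_s, k1 = k_s, A2 = a_f, k2 = k_f)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A1 * exp(-k1 * t) + A2 * exp(-k2 * t),
                        start = start, weights = w,
                        lower = c(A1 = 0, k1 = rate_lo, A2 = 0, k2 = rate_lo),
                        control = minpack.lm::nls.lm.control(maxiter = 1000)),
      error = function(e) {
        stop("bi-exponential fit did not converge (initialiser ",
             paste(sprintf("%s=%s", names(start), signif(unlist(start), 6)),
                   collapse = ", "), "): ", conditionMessage(e))
      })
    cf <- stats::coef(fit)
    terms <- data.frame(amplitude = c(cf[["A1"]], cf[["A2"]]),
                        rate = c(cf[["k1"]], cf[["k2"]]))
    terms <- terms[order(terms$rate), , drop = FALSE]
    rownames(terms) <- NULL
  }
  res <- y - vapply(t, function(tt) sum(terms$amplitude * exp(-terms$rate * tt)),
                    numeric(1))
  structure(list(model = model, terms = terms, rss = sum(w * res^2)),
            class = "exp_fit")
}

#' Effective half-life of the slow washout phase
#'
#' `ln2 / rate` of the slow (smallest-rate) phase of a fitted washout
#' model; this is the rate that governs the long-term dose delivery and
#' enters the high-LET BED.
#'
#' @param fit An `exp_fit`.
#' @return Hours.
#' @export
effective_half_life <- function(fit) {
  stopifnot(inherits(fit, "exp_fit"))
  log(2) / slow_rate(fit)
}

#' Slow-phase rate constant of a fit
#' @param fit An `exp_fit`.
#' @return Rate in 1/h (the smallest fitted rate).
#' @export
slow_rate <- function(fit) {
  stopifnot(inherits(fit, "exp_fit"))
  min(fit$terms$rate)
}

#' MIRD residence time of a fitted curve
#'
#' Analytic integral of the fitted washout model from 0 to infinity per
#' unit injected activity: `sum_i A_i / k_i`, in hours.
#'
#' @param fit An `exp_fit` with all rates > 0.
#' @return Residence time in hours.
#' @export
residence_time <- function(fit) {
  stopifnot(inherits(fit, "exp_fit"))
  if (any(fit$terms$rate <= 0)) stop("all fitted rates must be > 0")
  sum(fit$terms$amplitude / fit$terms$rate)
}

#' Convert surrogate-isotope kinetics to the alpha emitter
#'
#' Applies the predictive-dosimetry pipeline to one measured curve:
#' strip the surrogate's physical decay (biological curve), impose the
#' alpha emitter's physical decay, fit, and integrate. For a
#' mono-exponential biological curve with rate `k_bio`, the resulting
#' residence time is `A / (k_bio + ln2/T_new)` in closed form.
#'
#' @param tac Measured `tac` (embedding the surrogate's physical decay).
#' @param new_half_life Physical half-life of the target isotope, hours
#'   (default Ac-225).
#' @param model Fit model passed to [fit_exponential()].
#' @return List with the converted `tac`, its `fit`, and `tau_h`, the
#'   residence time of the target isotope.
#' @export
convert_isotope <- function(tac,
                            new_half_life = PHYSICAL_HALF_LIFE_H[["Ac-225"]],
                            model = "mono") {
  bio <- decay_correct(tac)
  conv <- apply_physical_decay(bio, new_half_life)
  fit <- fit_exponential(conv, model = model)
  list(tac = conv, fit = fit, tau_h = residence_time(fit))
}
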