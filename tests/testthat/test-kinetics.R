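test_that("triple-energy-window correction follows the trapezoid estimator", {
  expect_equal(tew_scatter_correct(1000, 0, 0, 41.6, 17.5, 23.8), 1000)
  # hand evaluation: 1000 - (100/20 + 100/20) * 40 / 2 = 800
  expect_equal(tew_scatter_correct(1000, 100, 100, 40, 20, 20), 800)
  expect_equal(tew_scatter_correct(100, 1000, 1000, 40, 20, 20), 0)
  expect_error(tew_scatter_correct(-1, 0, 0), ">= 0")
})

test_that("conjugate-view fraction is the ratio of geometric means", {
  ref <- list(ant = 10000, post = 10000)
  expect_equal(conjugate_view_fraction(list(ant = 400, post = 100), ref), 0.02)
  expect_equal(conjugate_view_fraction(ref, ref), 1.0)
  expect_equal(conjugate_view_fraction(list(ant = 0, post = 500), ref), 0.0)
  expect_error(conjugate_view_fraction(ref, list(ant = 0, post = 0)), "> 0")
})

test_that("decay correction round-trips and reproduces the closed-form factor", {
  t_lu <- PHYSICAL_HALF_LIFE_H[["Lu-177"]]
  t_ac <- PHYSICAL_HALF_LIFE_H[["Ac-225"]]
  tac <- new_tac("parotid", c(0.75, 20, 42, 120), c(0.02, 0.012, 0.008, 0.003))

  bio <- decay_correct(tac)
  expect_identical(bio$physical_half_life, Inf)
  back <- apply_physical_decay(bio, t_lu)
  expect_equal(back$points$value, tac$points$value, tolerance = 1e-13)

  # one half-life: value doubles when the physical decay is stripped
  one <- new_tac("x", c(0, t_lu), c(1, 0.5), physical_half_life = t_lu)
  expect_equal(decay_correct(one)$points$value[2], 1.0)

  # surrogate-to-alpha-emitter pipeline, checked per point in closed form
  conv <- apply_physical_decay(decay_correct(tac, t_lu), t_ac)
  expected <- tac$points$value *
    exp(log(2) * tac$points$t_h * (1 / t_lu - 1 / t_ac))
  expect_equal(conv$points$value, expected, tolerance = 1e-12)
})

test_that("mono-exponential fitting recovers noiseless parameters exactly", {
  fit <- fit_exponential(mono_tac(0.05, 0.0272), model = "mono")
  expect_equal(fit$terms$amplitude, 0.05, tolerance = 1e-6)
  expect_equal(fit$terms$rate, 0.0272, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
})

test_that("bi-exponential fitting recovers the slow rate from noisy data", {
  a1 <- 0.02; k1 <- 0.02; a2 <- 0.03; k2 <- 0.3
  times <- c(1, 4, 8, 16, 24, 48, 72, 120)
  sdlog <- sqrt(log(1 + 0.05^2))
  slow <- withr::with_seed(42, {
    replicate(200, {
      y <- (a1 * exp(-k1 * times) + a2 * exp(-k2 * times)) *
        rlnorm(length(times), -sdlog^2 / 2, sdlog)
      fit <- fit_exponential(new_tac("x", times, y), model = "bi")
      slow_rate(fit)
    })
  })
  expect_lt(abs(median(slow) / k1 - 1), 0.15)
  # slow phase is listed first
  fit <- fit_exponential(
    new_tac("x", times, a1 * exp(-k1 * times) + a2 * exp(-k2 * times)), "bi")
  expect_true(!is.unsorted(fit$terms$rate))
})

test_that("degenerate and under-determined inputs are handled explicitly", {
  flat <- new_tac("x", c(1, 20, 40, 120), rep(0.05, 4))
  fit <- fit_exponential(flat, model = "mono")
  expect_lte(slow_rate(fit), 1e-5)  # rate pinned at the lower bound
  expect_error(fit_exponential(new_tac("x", c(1, 2, 3), c(3, 2, 1)), "bi"),
               ">= 4 points")
})

test_that("effective half-life uses the slow phase", {
  fit <- fit_exponential(mono_tac(0.05, 0.0272), "mono")
  expect_equal(effective_half_life(fit), 25.5, tolerance = 0.002)
  fit1 <- structure(list(model = "mono", rss = 0,
                         terms = data.frame(amplitude = 1, rate = log(2))),
                    class = "exp_fit")
  expect_equal(effective_half_life(fit1), 1.0)
  fit2 <- structure(list(model = "bi", rss = 0,
                         terms = data.frame(amplitude = c(1, 1),
                                            rate = c(0.02, 0.5))),
                    class = "exp_fit")
  expect_equal(effective_half_life(fit2), log(2) / 0.02, tolerance = 1e-12)
})

test_that("residence time is the analytic integral of the fitted curve", {
  fit <- fit_exponential(mono_tac(0.05, 0.0272), "mono")
  expect_equal(residence_time(fit), 0.05 / 0.0272, tolerance = 1e-6)

  fit2 <- structure(list(model = "bi", rss = 0,
                         terms = data.frame(amplitude = c(0.03, 0.02),
                                            rate = c(0.3, 0.02))),
                    class = "exp_fit")
  expect_equal(residence_time(fit2), 0.1 + 1.0, tolerance = 1e-12)

  # quadrature oracle: trapezoid to 10 effective half-lives plus analytic tail
  a <- 0.05; k <- 0.0272
  grid <- seq(0, 10 * log(2) / k, length.out = 20001)
  y <- a * exp(-k * grid)
  trap <- sum((y[-1] + y[-length(y)]) / 2 * diff(grid))
  tail <- a * exp(-k * max(grid)) / k
  expect_equal(residence_time(fit), trap + tail, tolerance = 0.005)
})

test_that("isotope conversion scales the residence time by the closed form", {
  a <- 0.02; k_bio <- 0.02
  t_ac <- PHYSICAL_HALF_LIFE_H[["Ac-225"]]
  bio <- new_tac("parotid", c(1, 20, 40, 120), a * exp(-k_bio * c(1, 20, 40, 120)),
                 physical_half_life = Inf)
  tau_bio <- residence_time(fit_exponential(bio, "mono"))
  ac <- apply_physical_decay(bio, t_ac)
  tau_ac <- residence_time(fit_exponential(ac, "mono"))
  lam_phys <- log(2) / t_ac
  expect_equal(tau_ac / tau_bio, k_bio / (k_bio + lam_phys), tolerance = 1e-6)

  # full pipeline helper from a measured Lu-177 curve
  measured <- apply_physical_decay(bio, PHYSICAL_HALF_LIFE_H[["Lu-177"]])
  conv <- convert_isotope(measured)
  expect_equal(conv$tau_h, a / (k_bio + lam_phys), tolerance = 1e-6)
})

test_that("residence time is linear in amplitude and order-invariant", {
  f <- function(amps, rates) {
    structure(list(model = "bi", rss = 0,
                   terms = data.frame(amplitude = amps, rate = rates)),
              class = "exp_fit")
  }
  expect_equal(residence_time(f(c(0.06, 0.04), c(0.3, 0.02))),
               2 * residence_time(f(c(0.03, 0.02), c(0.3, 0.02))))
  expect_equal(residence_time(f(c(0.02, 0.03), c(0.02, 0.3))),
               residence_time(f(c(0.03, 0.02), c(0.3, 0.02))))
})
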