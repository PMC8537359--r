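test_that("emission integration is exact on rectangles and Gaussians", {
  flat <- spectrum_trace(seq(380, 520, by = 1), rep(1, 141))
  expect_equal(integrate_emission(flat, c(400, 500)), 100)
  zero <- spectrum_trace(seq(380, 520, by = 1), rep(0, 141))
  expect_equal(integrate_emission(zero, c(400, 500)), 0)
  # analytic Gaussian area: amp * sigma * sqrt(2*pi)
  g <- generate_spectrum(440, 15, amplitude = 2, grid = seq(300, 600, by = 0.25))
  expect_equal(integrate_emission(g, c(300, 600)), 2 * 15 * sqrt(2 * pi),
               tolerance = 1e-3)
  # window edges between grid points are interpolated
  expect_equal(integrate_emission(flat, c(400.5, 499.5)), 99)
  expect_error(integrate_emission(flat, c(500, 400)), "empty")
  expect_error(integrate_emission(flat, c(100, 500)), "within")
})

test_that("quantum yield reproduces the reference identity and ratio scaling", {
  qbs <- qy_measurement(A = 5000, Abs = 0.05, eta = 1.33, phi = 0.54)
  expect_identical(quantum_yield(qbs, qbs), 0.54)
  # emission-area ratio 0.2093 at matched absorbance and solvent
  cqd <- qy_measurement(A = 5000 * 0.2093, Abs = 0.05, eta = 1.33)
  expect_equal(quantum_yield(cqd, qbs), 0.54 * 0.2093, tolerance = 1e-12)
  expect_equal(round(quantum_yield(cqd, qbs), 4), 0.113)
  zero <- qy_measurement(A = 0, Abs = 0.05, eta = 1.33)
  expect_identical(quantum_yield(zero, qbs), 0)
  expect_error(qy_measurement(A = 1, Abs = 0), "> 0")
  expect_warning(
    quantum_yield(qy_measurement(A = 1, Abs = 0.3, eta = 1.33), qbs),
    "inner filter")
})

test_that("quantum yield obeys its scale invariances", {
  set.seed(31)
  st <- qy_measurement(A = 4000, Abs = 0.08, eta = 1.33, phi = 0.54)
  for (r in runif(5, 0.2, 5)) {
    base <- qy_measurement(A = 1200, Abs = 0.04, eta = 1.40)
    scaled <- qy_measurement(A = 1200 * r, Abs = 0.04 * r, eta = 1.40)
    expect_equal(suppressWarnings(quantum_yield(scaled, st)),
                 quantum_yield(base, st))
    # eta enters squared
    keta <- qy_measurement(A = 1200, Abs = 0.04, eta = 1.40 * sqrt(2))
    expect_equal(quantum_yield(keta, st), 2 * quantum_yield(base, st))
  }
})

test_that("Stern-Volmer refit recovers the constant from noiseless data", {
  conc <- c(0, 0.5, 1, 2.5, 5, 7.5, 10, 12.5, 15, 17.5, 20, 25, 50, 75, 100)
  I <- 1000 / (1 + 0.08 * conc)
  cal <- fit_quench_curve(conc, I, "stern_volmer")
  expect_equal(unname(cal$params[["K"]]), 0.08, tolerance = 1e-7)
  expect_true(all(abs(cal$residuals) < 1e-9))
  expect_true(all(diff(cal$rel_intensity) <= 0))

  flat <- fit_quench_curve(c(0, 10, 20, 50), rep(700, 4))
  expect_equal(unname(flat$params[["K"]]), 0)
  expect_error(fit_quench_curve(c(0, 10), c(1, 0.5)), "at least 3")
  expect_error(fit_quench_curve(c(5, 10, 20), c(1, 0.8, 0.6)), "c = 0")
})

test_that("Stern-Volmer K estimates tighten as measurement noise shrinks", {
  conc <- c(0, 0.5, 1, 2.5, 5, 7.5, 10, 12.5, 15, 17.5, 20, 25, 50, 75, 100)
  truth <- 1000 / (1 + 0.08 * conc)
  bias_at <- function(rel_sd, seed) {
    set.seed(seed)
    ks <- replicate(40, {
      I <- truth * (1 + rnorm(length(conc), 0, rel_sd))
      fit_quench_curve(conc, pmax(I, 1), "stern_volmer")$params[["K"]]
    })
    abs(mean(ks) - 0.08)
  }
  b_hi <- bias_at(0.05, 101)
  b_lo <- bias_at(0.002, 103)
  expect_lt(b_lo, b_hi)
  expect_lt(b_lo, 1e-3)
})

test_that("exponential IFE model also refits its coefficient", {
  conc <- c(0, 1, 2.5, 5, 10, 20, 50, 100)
  I <- 500 * 10^(-0.012 * conc)
  cal <- fit_quench_curve(conc, I, "ife_exponential")
  expect_equal(unname(cal$params[["k"]]), 0.012, tolerance = 1e-7)
})

test_that("stepwise time course recovers segment means and drops", {
  r <- stepwise_quench_timecourse(0:100, rep(50, 101))
  expect_equal(r$segment_means, 50)
  expect_length(r$drops, 0)

  t <- seq(0, 1200, by = 10)
  I <- c(rep(100, 30), rep(80, 30), rep(60, 30), rep(40, 31))
  r <- stepwise_quench_timecourse(t, I, addition_times = c(300, 600, 900))
  expect_equal(r$segment_means, c(100, 80, 60, 40))
  expect_equal(r$drops, c(-20, -20, -20))
  expect_equal(r$segments$n, c(30, 30, 30, 31))
  expect_error(stepwise_quench_timecourse(t, I, c(600, 300)), "increasing")
  expect_error(stepwise_quench_timecourse(t, I, c(300, 2000)), "window")
  expect_error(stepwise_quench_timecourse(c(3, 1, 2), c(1, 2, 3)), "sorted")
})

test_that("noisy stepwise segments estimate truth within Monte-Carlo error", {
  set.seed(55)
  t <- seq(0, 1200, by = 2)
  mu <- ifelse(t < 300, 100, ifelse(t < 600, 80, ifelse(t < 900, 60, 40)))
  I <- mu + rnorm(length(t), 0, 5)
  r <- stepwise_quench_timecourse(t, I, addition_times = c(300, 600, 900))
  for (s in 1:4)
    expect_lt(abs(r$segment_means[s] - c(100, 80, 60, 40)[s]),
              4 * 5 / sqrt(r$segments$n[s]))
})

test_that("spectral overlap is 0/1 at the extremes and matches the Gaussian formula", {
  e <- generate_spectrum(440, 10, grid = seq(400, 480, by = 0.5))
  a <- generate_spectrum(700, 10, grid = seq(650, 750, by = 0.5))
  expect_equal(spectral_overlap(e, a), 0)
  expect_equal(spectral_overlap(e, e), 1, tolerance = 1e-12)

  g1 <- generate_spectrum(440, 20, grid = seq(200, 900, by = 0.5))
  g2 <- generate_spectrum(410, 20, amplitude = 3, grid = seq(200, 900, by = 0.5))
  # closed form: exp(-(delta mu)^2 / (4 sigma^2))
  expect_equal(spectral_overlap(g1, g2), exp(-30^2 / (4 * 20^2)),
               tolerance = 1e-3)
  # symmetric and bounded
  expect_equal(spectral_overlap(g2, g1), spectral_overlap(g1, g2))
  expect_error(
    spectral_overlap(spectrum_trace(1:5, rep(0, 5)), g1), "all-zero")
})

test_that("spectral overlap is symmetric and bounded on random Gaussian pairs", {
  set.seed(77)
  for (i in 1:8) {
    p1 <- runif(1, 380, 700); p2 <- runif(1, 380, 700)
    w1 <- runif(1, 5, 60); w2 <- runif(1, 5, 60)
    s1 <- generate_spectrum(p1, w1, grid = seq(300, 800, by = 1))
    s2 <- generate_spectrum(p2, w2, amplitude = runif(1, 0.1, 10),
                            grid = seq(300, 800, by = 1))
    o <- spectral_overlap(s1, s2)
    expect_gte(o, 0); expect_lte(o, 1)
    expect_equal(o, spectral_overlap(s2, s1), tolerance = 1e-12)
  }
})

test_that("photostability drift detects decay and accepts flat traces", {
  r <- photostability_drift(0:359 * 10, rep(1000, 360))
  expect_equal(r$slope, 0)
  expect_equal(r$relative_change, 0)

  r <- photostability_drift(0:99, 500 - 1 * (0:99))
  expect_equal(r$slope, -1, tolerance = 1e-12)
  expect_error(photostability_drift(rep(5, 10), rnorm(10)), "constant")
  expect_error(photostability_drift(1:2, 1:2), "3 time points")
})

test_that("a stable fluorophore rarely shows a significant slope", {
  # 1-h recording at 10-s sampling under the null of no drift
  rejections <- 0
  for (s in 1:200) {
    set.seed(s + 9000)
    I <- 1000 + rnorm(360, 0, 20)
    if (photostability_drift(0:359 * 10, I)$p_value < 0.05)
      rejections <- rejections + 1
  }
  expect_lte(rejections, 20)   # p > 0.05 in at least 90% of runs
})

test_that("spectra and calibrations round-trip through CSV and JSON", {
  dir <- withr::local_tempdir()
  s <- generate_spectrum(440, 25, amplitude = 123.45)
  p <- file.path(dir, "em.csv")
  write_spectrum_csv(s, p)
  s2 <- read_spectrum_csv(p)
  expect_equal(s2$intensity, s$intensity)

  conc <- c(0, 5, 10, 25, 50)
  cal <- fit_quench_curve(conc, 800 / (1 + 0.04 * conc))
  jp <- file.path(dir, "cal.json")
  write_calibration_json(cal, jp)
  cal2 <- read_calibration_json(jp)
  expect_equal(cal2$params[["K"]], cal$params[["K"]], tolerance = 1e-12)
  expect_equal(
    quench_factor_from_concentration(25, cal2), 0.5, tolerance = 1e-6)
})
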