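make_series <- function(...) simulate_titration(quench_sim_spec(...), 298)

test_that("quench ratios are anchored at 1 and scale-invariant", {
  s <- make_series(noise_sd = 0)
  r <- quench_ratios(s)
  expect_equal(r$f0_over_f[r$conc == 0], 1)
  expect_equal(nrow(r), length(s$quencher_concs))
  # uniform rescaling of all spectra leaves the ratios untouched
  scaled <- titration_series(
    dplyr::mutate(s$spectra, intensity = intensity * 37.5),
    temperature = s$temperature)
  expect_equal(quench_ratios(scaled)$f0_over_f, r$f0_over_f, tolerance = 1e-12)
  # identical spectra at every concentration: no quenching, all ratios 1
  flat <- titration_series(
    tidyr::expand_grid(conc = c(0, 1e-6, 2e-6), wavelength = 300:360) |>
      dplyr::mutate(intensity = exp(-(wavelength - 330)^2 / 200)),
    temperature = 298)
  expect_true(all(abs(quench_ratios(flat)$f0_over_f - 1) < 1e-12))
})

test_that("quench ratios name the offending concentration on bad intensities", {
  s <- make_series(noise_sd = 0)
  broken <- s$spectra
  broken$intensity[broken$conc == 8e-6] <- 0
  bad <- titration_series(broken, temperature = 298)
  expect_error(quench_ratios(bad), "8e-06")
})

test_that("Stern-Volmer fit recovers Ksv and Kq from clean data", {
  s <- make_series(ksv_true = 4.142e4, noise_sd = 0)
  fit <- suppressWarnings(stern_volmer_fit(quench_ratios(s), 298, tau0 = 4.688))
  expect_equal(fit$ksv, 4.142e4, tolerance = 1e-9)
  expect_equal(fit$intercept, 1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # Ksv / (tau0 in seconds): frozen direct evaluation 4.142e4 / 4.688e-9
  expect_equal(fit$kq, 8.835324e12, tolerance = 1e-6)
  expect_equal(fit$temperature, 298)
})

test_that("Stern-Volmer slope equals the closed-form OLS solution", {
  set.seed(42)
  x <- seq(0, 24e-6, by = 4e-6)
  y <- 1 + 3e4 * x + rnorm(length(x), 0, 0.01)
  fit <- stern_volmer_fit(tibble::tibble(conc = x, f0_over_f = y), 304)
  oracle <- ols_oracle(x, y)
  expect_equal(fit$ksv, unname(oracle["slope"]), tolerance = 1e-9)
  expect_equal(fit$intercept, unname(oracle["intercept"]), tolerance = 1e-9)
  # flat ratios give zero slope; too few points are rejected
  flat <- tibble::tibble(conc = x, f0_over_f = 1)
  expect_lt(abs(stern_volmer_fit(flat, 298)$ksv), 1e-8)
  expect_error(stern_volmer_fit(flat[1:2, ], 298), "3 points")
})

test_that("double-log fit recovers Ka and n from clean generator data", {
  s <- simulate_titration(quench_sim_spec(ka_true = 8.978e4, n_true = 1.073,
                                          noise_sd = 0),
                          298, model = "double_log")
  fit <- double_log_fit(quench_ratios(s), 298)
  expect_equal(fit$ka, 8.978e4, tolerance = 1e-3)
  expect_equal(fit$n, 1.073, tolerance = 1e-3)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # identity line (F0-F)/F = [Q]: intercept 0, Ka = 1, n = 1
  q <- c(0, 1e-6 * 2^(0:4))
  ident <- tibble::tibble(conc = q, f0_over_f = 1 + q)
  ifit <- double_log_fit(ident, 298)
  expect_equal(ifit$log_ka_intercept, 0, tolerance = 1e-9)
  expect_equal(ifit$ka, 1, tolerance = 1e-9)
  expect_equal(ifit$n, 1, tolerance = 1e-9)
})

test_that("double-log fit drops unquenched points with a warning", {
  q <- seq(0, 24e-6, by = 4e-6)
  r <- tibble::tibble(conc = q, f0_over_f = 1 + 4e4 * q)
  r$f0_over_f[3] <- 0.999   # F above F0: no signal
  expect_warning(fit <- double_log_fit(r, 298), "Dropping 1")
  expect_equal(nrow(fit$data), 5)
  r$f0_over_f[-1] <- 0.99
  expect_error(suppressWarnings(double_log_fit(r, 298)), "3 usable")
})

test_that("Ksv recovery under 1% noise stays within a few percent", {
  errs <- vapply(1:20, function(s) {
    ser <- simulate_titration(quench_sim_spec(noise_sd = 0.01, seed = s), 298)
    fit <- stern_volmer_fit(quench_ratios(ser), 298)
    abs(fit$ksv / 4.142e4 - 1)
  }, numeric(1))
  expect_lt(median(errs), 0.03)
})

test_that("mechanism classification reproduces the three-criterion logic", {
  static_call <- classify_mechanism(
    dplyr::mutate(table2[c("temperature", "ksv")],
                  kq = c(8.835e12, NA, NA)),
    lifetime_flag = TRUE)
  expect_equal(static_call$label, "static")
  expect_true(all(c("ksv_trend", "kq_ceiling", "lifetime_invariance") %in%
                    static_call$evidence$criterion))

  dynamic_call <- classify_mechanism(
    tibble::tibble(temperature = c(298, 304, 310),
                   ksv = c(1, 1.2, 1.5) * 1e3, kq = 5e9),
    lifetime_flag = FALSE)
  expect_equal(dynamic_call$label, "dynamic")

  # one vote each way with no lifetime data: inconclusive by enumeration
  split_call <- classify_mechanism(
    tibble::tibble(temperature = c(298, 310), ksv = c(2e4, 1e4), kq = 5e9))
  expect_equal(split_call$label, "inconclusive")

  expect_error(classify_mechanism(
    tibble::tibble(temperature = c(298, 298), ksv = c(1e4, 2e4))), "distinct")
  expect_error(classify_mechanism(
    tibble::tibble(temperature = 298, ksv = 1e4)), ">= 2")
})
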