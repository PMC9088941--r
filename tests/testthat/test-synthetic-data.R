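test_that("noiseless titrations satisfy the Stern-Volmer relation exactly", {
  spec <- quench_sim_spec(ksv_true = 4.142e4, noise_sd = 0)
  s <- simulate_titration(spec, temperature = 298)
  r <- quench_ratios(s)
  expect_lt(max(abs(r$f0_over_f - (1 + spec$ksv_true * r$conc))), 1e-12)
  # direct evaluation at the top concentration: 1 + 4.142e4 * 2.4e-5
  expect_equal(r$f0_over_f[r$conc == 2.4e-5], 1.99408, tolerance = 1e-9)
  # zero-quencher spectrum is the unquenched Gaussian band
  f0 <- dplyr::filter(s$spectra, conc == 0)
  expect_equal(f0$intensity,
               spec$f0_peak * exp(-(f0$wavelength - 345)^2 / (2 * 25^2)),
               tolerance = 1e-12)
})

test_that("titration generator is deterministic and validates its ladder", {
  spec <- quench_sim_spec(noise_sd = 0.02, seed = 11L)
  a <- simulate_titration(spec, 298)
  b <- simulate_titration(spec, 298)
  expect_identical(a$spectra, b$spectra)
  expect_error(quench_sim_spec(quencher_concs = c(0, 2e-6, 2e-6)),
               "strictly increasing")
  expect_error(quench_sim_spec(quencher_concs = c(4e-6, 8e-6)), "must be 0")
  expect_error(quench_sim_spec(ksv_true = -1), "ksv_true")
})

test_that("decay counts follow the analytic multi-exponential expectation", {
  spec <- decay_sim_spec(total_counts = 1e6, seed = 4L)
  d <- simulate_decay(spec)
  t <- d$time_ns
  mu <- spec$total_counts *
    colSums(spec$amplitudes * exp(-outer(1 / spec$lifetimes, t)))
  # every channel within 5 sigma of its Poisson mean
  expect_true(all(abs(d$counts - mu) <= 5 * sqrt(mu) + 5))
  # peak channel expectation equals total_counts (amplitudes sum to 1)
  expect_equal(mu[1], spec$total_counts, tolerance = 1e-12)
  expect_identical(simulate_decay(spec)$counts, d$counts)
  expect_error(decay_sim_spec(lifetimes = c(1, 2), amplitudes = c(0.6, 0.6)),
               "sum to 1")
})

test_that("noiseless mono-exponential decays are log-linear with slope -1/tau", {
  spec <- decay_sim_spec(lifetimes = 3.2, amplitudes = 1, total_counts = 1e5)
  d <- simulate_decay(spec, poisson_noise = FALSE)
  keep <- d$counts > 0
  fit <- lm(log(d$counts[keep]) ~ d$time_ns[keep])
  expect_equal(unname(coef(fit)[2]), -1 / 3.2, tolerance = 1e-10)
})

test_that("EEM generator places Gaussian peaks and the Rayleigh ridge", {
  e <- simulate_eem(tibble::tibble(ex = 280, em = 340, height = 100,
                                   width = 12))
  off <- abs(outer(e$ex, e$em, "-")) > 10
  top <- which(e$intensity == max(e$intensity[off]), arr.ind = TRUE)
  expect_equal(e$ex[top[1]], 280)
  expect_equal(e$em[top[2]], 340)
  # recovered peak height equals the requested height (ridge far away)
  expect_equal(max(e$intensity[off]), 100, tolerance = 1e-6)
  # scatter-only EEM: nonzero cells concentrated on the diagonal band
  e0 <- simulate_eem(tibble::tibble(ex = numeric(), em = numeric(),
                                    height = numeric(), width = numeric()))
  far <- abs(outer(e0$ex, e0$em, "-")) > 40
  expect_lt(max(e0$intensity[far]), 1e-6 * max(e0$intensity))
  expect_error(simulate_eem(grid_step = 7), "divide")
  expect_error(simulate_eem(tibble::tibble(ex = 150, em = 340, height = 1,
                                           width = 5)), "inside")
})

test_that("trajectory generator honours jitter and rigid-motion settings", {
  still <- simulate_trajectory(traj_sim_spec(n_frames = 4, n_atoms = 8,
                                             jitter_sd = 0))
  coords <- split(still[c("x", "y", "z")], still$frame)
  for (i in 2:4) expect_equal(coords[[i]], coords[[1]], ignore_attr = TRUE)
  spec <- traj_sim_spec(n_frames = 6, n_atoms = 12, jitter_sd = 0.4,
                        rigid_motion = TRUE, seed = 9L)
  expect_identical(simulate_trajectory(spec), simulate_trajectory(spec))
  expect_error(traj_sim_spec(n_frames = 1), "n_frames")
  expect_error(traj_sim_spec(n_atoms = 2), "n_atoms")
})
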