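gauss_scans <- function(centers, heights, wl = seq(300, 400, by = 2)) {
  purrr::map2_dfr(centers, heights, function(c0, h) {
    tibble::tibble(conc = NA_real_, wavelength = wl,
                   intensity = h * exp(-(wl - c0)^2 / (2 * 8^2)))
  }) |>
    dplyr::mutate(conc = rep(seq(0, by = 4e-6,
                                 length.out = length(centers)),
                             each = length(wl)))
}

test_that("synchronous shift verdicts track the peak centre", {
  none <- sync_shift(gauss_scans(rep(345, 5), c(10, 8, 6, 4, 2)),
                     delta_lambda = 60)
  expect_equal(none$verdict, "none")
  expect_lt(abs(none$shift_nm), 0.01)
  expect_true(all(diff(none$peaks$intensity) < 0))

  red <- sync_shift(gauss_scans(c(345, 348, 351), c(10, 8, 6)))
  expect_equal(red$verdict, "red")
  blue <- sync_shift(gauss_scans(c(345, 342, 339), c(10, 8, 6)))
  expect_equal(blue$verdict, "blue")

  expect_error(sync_shift(gauss_scans(345, 10)), "2 scans")
  flat <- tibble::tibble(conc = rep(c(0, 1e-6), each = 11),
                         wavelength = rep(300:310, 2), intensity = 1)
  expect_error(sync_shift(flat), "Flat scan")
})

test_that("synchronous verdict is invariant to uniform intensity rescaling", {
  scans <- gauss_scans(rep(345, 4), c(10, 8, 6, 4))
  a <- sync_shift(scans)
  b <- sync_shift(dplyr::mutate(scans, intensity = intensity * 1e3))
  expect_equal(a$verdict, b$verdict)
  expect_equal(a$peaks$lambda_max, b$peaks$lambda_max, tolerance = 1e-12)
})

test_that("parabolic interpolation resolves sub-grid peak positions", {
  wl <- seq(300, 400, by = 5)
  scan <- tibble::tibble(conc = rep(c(0, 1e-6), each = length(wl)),
                         wavelength = rep(wl, 2),
                         intensity = exp(-(rep(wl, 2) - 343.4)^2 / 200))
  sh <- sync_shift(scan)
  expect_equal(sh$peaks$lambda_max[1], 343.4, tolerance = 0.05)
})

test_that("EEM peak picking separates fluorophores from Rayleigh scatter", {
  e <- simulate_eem(tibble::tibble(ex = 280, em = 340, height = 592.596,
                                   width = 12))
  pk <- eem_peaks(e)
  fluor <- dplyr::filter(pk, kind == "fluorophore")
  expect_equal(fluor$ex[1], 280)
  expect_equal(fluor$em[1], 340)
  # the diagonal band never yields a fluorophore record
  expect_true(all(abs(fluor$ex - fluor$em) > 10))
  expect_true(any(pk$kind == "rayleigh"))

  ridge_only <- simulate_eem(tibble::tibble(ex = numeric(), em = numeric(),
                                            height = numeric(),
                                            width = numeric()))
  pk0 <- eem_peaks(ridge_only)
  expect_equal(sum(pk0$kind == "fluorophore"), 0)
})

test_that("EEM intensity ordering survives peak extraction", {
  e <- simulate_eem(tibble::tibble(ex = c(280, 230), em = c(340, 330),
                                   height = c(592.596, 424.454),
                                   width = c(10, 10)))
  fluor <- dplyr::filter(eem_peaks(e), kind == "fluorophore")
  expect_gte(nrow(fluor), 2)
  expect_equal(fluor$intensity[1] > fluor$intensity[2], TRUE)
  expect_equal(fluor$ex[1], 280)   # stronger peak first
})

test_that("peak attenuation is the matched-intensity ratio", {
  before <- list(ex = 280, em = 340, intensity = 592.596)
  after <- list(ex = 280, em = 340, intensity = 424.454)
  expect_equal(peak_attenuation(before, after), 0.716262, tolerance = 1e-5)
  expect_equal(peak_attenuation(before, before), 1)
  shifted <- list(ex = 285, em = 340, intensity = 400)
  expect_error(peak_attenuation(before, shifted, tolerance = 2), "differ")
})

test_that("CD band extraction labels extrema with their signs", {
  wl <- seq(178, 260, by = 1)
  curve <- tibble::tibble(
    wavelength = wl,
    ellipticity = 6 * exp(-(wl - 185)^2 / 18) - 8 * exp(-(wl - 200)^2 / 32))
  bands <- cd_bands(curve)
  expect_equal(nrow(bands), 2)
  expect_equal(bands$sign, c("+", "-"))
  expect_equal(bands$wavelength, c(185, 200), tolerance = 0.02)

  flipped <- cd_bands(dplyr::mutate(curve, ellipticity = -ellipticity))
  expect_equal(flipped$wavelength, bands$wavelength)
  expect_equal(flipped$sign, c("-", "+"))

  zero <- tibble::tibble(wavelength = wl, ellipticity = 0)
  expect_equal(nrow(cd_bands(zero)), 0)
  expect_error(cd_bands(curve[1:10, ]), ">= 20 points")
})
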