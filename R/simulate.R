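#' Simulate a static-quenching fluorescence titration
#'
#' Generates emission spectra at each quencher concentration of a spec. The
#' emission band is a single Gaussian; static quenching reduces it uniformly
#' across the band (no wavelength shift). Under `model = "stern_volmer"` the
#' band intensity at concentration q is `f0_peak / (1 + ksv_true * q)`, i.e.
#' F0/F = 1 + Ksv q holds exactly at noise 0. Under `model = "double_log"` it
#' is `f0_peak / (1 + ka_true * q^n_true)`, so the double-logarithmic relation
#' lg((F0-F)/F) = lg Ka + n lg q holds exactly instead. Noise is multiplicative
#' Gaussian per grid point (a shot-noise proxy).
#'
#' @param spec A [quench_sim_spec()].
#' @param temperature Temperature, K (recorded in the series metadata).
#' @param model Which quenching relation generates the intensities.
#' @param wavelengths Emission wavelength grid, nm.
#' @return A `titration_series`: see [titration_series()]. Its `truth` field
#'   records every ground-truth parameter of `spec`.
#' @export
#' @examples
#' s <- simulate_titration(quench_sim_spec(noise_sd = 0), temperature = 298)
#' quench_ratios(s)
simulate_titration <- function(spec, temperature = 298,
                               model = c("stern_volmer", "double_log"),
                               wavelengths = seq(300, 500, by = 1)) {
  stopifnot(inherits(spec, "quench_sim_spec"))
  model <- match.arg(model)
  band <- exp(-(wavelengths - spec$peak_wavelength)^2 / (2 * spec$peak_width^2))
  withr::with_seed(spec$seed, {
    spectra <- purrr::map_dfr(spec$quencher_concs, function(q) {
      peak <- switch(model,
        stern_volmer = spec$f0_peak / (1 + spec$ksv_true * q),
        double_log   = spec$f0_peak / (1 + spec$ka_true * q^spec$n_true)
      )
      noise <- if (spec$noise_sd > 0) {
        rnorm(length(wavelengths), 0, spec$noise_sd)
      } else {
        rep(0, length(wavelengths))
      }
      tibble(conc = q, wavelength = wavelengths,
             intensity = peak * band * (1 + noise))
    })
  })
  titration_series(spectra, temperature = temperature,
                   protein_conc = spec$protein_conc,
                   truth = c(spec[c("ksv_true", "ka_true", "n_true",
                                    "f0_peak", "noise_sd", "seed")],
                             list(model = model)))
}

#' Construct a titration series
#'
#' Bundles per-concentration emission spectra with their metadata. The zero
#' concentration defines F0 and must be present and first.
#'
#' @param spectra Tibble with columns `conc` (mol L^-1), `wavelength` (nm) and
#'   `intensity` (arbitrary units); all concentrations must share one
#'   wavelength grid.
#' @param temperature Temperature, K.
#' @param protein_conc Protein concentration, mol L^-1 (optional metadata).
#' @param truth Optional list of ground-truth generator parameters.
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(spectra, temperature, protein_conc = NA_real_,
                             truth = NULL) {
  spectra <- as_tibble(spectra)
  stopifnot(all(c("conc", "wavelength", "intensity") %in% names(spectra)))
  concs <- sort(unique(spectra$conc))
  check_conc_ladder(concs)
  grids <- spectra |>
    dplyr::group_by(.data$conc) |>
    dplyr::summarise(g = paste(signif(.data$wavelength, 12), collapse = ","),
                     .groups = "drop")
  if (length(unique(grids$g)) != 1) {
    abort("All spectra in a titration series must share one wavelength grid.")
  }
  structure(
    list(spectra = dplyr::arrange(spectra, .data$conc, .data$wavelength),
         quencher_concs = concs, temperature = temperature,
         protein_conc = protein_conc, truth = truth),
    class = "titration_series"
  )
}

#' @export
print.titration_series <- function(x, ...) {
  cat("<titration_series> ", length(x$quencher_concs), " concentrations (",
      format(min(x$quencher_concs), digits = 3), "-",
      format(max(x$quencher_concs), digits = 3), " M), T = ",
      x$temperature, " K\n", sep = "")
  invisible(x)
}

#' @method tidy titration_series
#' @export
tidy.titration_series <- function(x, ...) x$spectra

#' Simulate a TCSPC decay histogram
#'
#' Draws Poisson counts around the multi-exponential model
#' `total_counts * sum(alpha_i * exp(-t / tau_i))` on the spec's channel grid,
#' with channel 1 at t = 0 (the decay peak). No instrument-response
#' convolution is applied, matching tail fitting.
#'
#' @param spec A [decay_sim_spec()].
#' @param poisson_noise If `FALSE`, return the noiseless expectation instead
#'   of Poisson draws (counts are then non-integer).
#' @return A `decay_curve`: a tibble with columns `time_ns` and `counts`, plus
#'   attributes `meta` (label, wavelengths) and `truth`.
#' @export
#' @examples
#' d <- simulate_decay(decay_sim_spec(total_counts = 1e4, seed = 7))
#' fit_decay(d, n_components = 3)
simulate_decay <- function(spec, poisson_noise = TRUE) {
  stopifnot(inherits(spec, "decay_sim_spec"))
  t <- (seq_len(spec$n_channels) - 1) * spec$channel_width
  mu <- spec$total_counts *
    colSums(spec$amplitudes * exp(-outer(1 / spec$lifetimes, t)))
  counts <- if (poisson_noise) {
    withr::with_seed(spec$seed, rpois(length(mu), mu))
  } else {
    mu
  }
  decay_curve(tibble(time_ns = t, counts = counts),
              meta = list(label = "synthetic", ex_nm = 280, em_nm = 345),
              truth = spec[c("lifetimes", "amplitudes", "total_counts", "seed")])
}

#' Construct a decay curve
#'
#' @param data Tibble with strictly increasing `time_ns` and non-negative
#'   `counts`; at least 64 channels.
#' @param meta Optional list: sample label, excitation/emission wavelengths.
#' @param truth Optional generator ground truth.
#' @return A tibble of class `decay_curve`.
#' @export
decay_curve <- function(data, meta = list(), truth = NULL) {
  data <- as_tibble(data)
  stopifnot(all(c("time_ns", "counts") %in% names(data)))
  if (nrow(data) < 64) abort("A decay curve needs at least 64 channels.")
  if (any(diff(data$time_ns) <= 0)) abort("`time_ns` must be strictly increasing.")
  if (any(data$counts < 0)) abort("`counts` must be non-negative.")
  structure(data, meta = meta, truth = truth,
            class = c("decay_curve", class(data)))
}

#' Simulate an excitation-emission matrix
#'
#' Builds a 200-400 nm EEM grid holding Gaussian fluorophore peaks plus a
#' first-order Rayleigh scatter ridge along the diagonal (excitation equal to
#' emission wavelength).
#'
#' @param peaks Tibble (or data frame) with columns `ex`, `em`, `height`,
#'   `width` (Gaussian sigma, nm); may have zero rows for a scatter-only EEM.
#' @param grid_step Grid step, nm; must divide the 200 nm range.
#' @param ridge_height Peak intensity of the Rayleigh ridge.
#' @param ridge_width Gaussian sigma of the ridge across the diagonal, nm.
#' @return An `eem` object: list with `ex`, `em` grids and an `intensity`
#'   matrix (rows = excitation, columns = emission).
#' @export
#' @examples
#' eem <- simulate_eem(tibble::tibble(ex = 280, em = 340,
#'                                    height = 592.596, width = 12))
#' eem_peaks(eem)
simulate_eem <- function(peaks = tibble(ex = 280, em = 340, height = 1,
                                        width = 12),
                         grid_step = 5, ridge_height = 50, ridge_width = 6) {
  peaks <- as_tibble(peaks)
  rng <- c(200, 400)
  if ((diff(rng) %% grid_step) != 0) {
    abort("`grid_step` must divide the 200-400 nm range.")
  }
  g <- seq(rng[1], rng[2], by = grid_step)
  if (nrow(peaks) > 0 &&
      (any(peaks$ex < rng[1] | peaks$ex > rng[2]) ||
       any(peaks$em < rng[1] | peaks$em > rng[2]))) {
    abort("Peak coordinates must lie inside the 200-400 nm grid.")
  }
  ex <- matrix(g, nrow = length(g), ncol = length(g))
  em <- t(ex)
  z <- ridge_height * exp(-(ex - em)^2 / (2 * ridge_width^2))
  for (i in seq_len(nrow(peaks))) {
    z <- z + peaks$height[i] *
      exp(-((ex - peaks$ex[i])^2 + (em - peaks$em[i])^2) /
            (2 * peaks$width[i]^2))
  }
  eem(ex_grid = g, em_grid = g, intensity = z)
}

#' Construct an EEM object
#'
#' @param ex_grid,em_grid Strictly increasing wavelength grids, nm.
#' @param intensity Matrix, rows indexed by `ex_grid`, columns by `em_grid`.
#' @return An object of class `eem`.
#' @export
eem <- function(ex_grid, em_grid, intensity) {
  if (any(diff(ex_grid) <= 0) || any(diff(em_grid) <= 0)) {
    abort("EEM grids must be strictly increasing.")
  }
  if (!is.matrix(intensity) || nrow(intensity) != length(ex_grid) ||
      ncol(intensity) != length(em_grid)) {
    abort("`intensity` must be a matrix matching the grids.")
  }
  structure(list(ex = as.numeric(ex_grid), em = as.numeric(em_grid),
                 intensity = intensity), class = "eem")
}

#' @export
print.eem <- function(x, ...) {
  cat("<eem> ", length(x$ex), " x ", length(x$em), " grid, ",
      min(x$ex), "-", max(x$ex), " nm\n", sep = "")
  invisible(x)
}

#' @method tidy eem
#' @export
tidy.eem <- function(x, ...) {
  tidyr::expand_grid(ex = x$ex, em = x$em) |>
    dplyr::mutate(intensity = as.vector(t(x$intensity)))
}

#' Simulate a toy multi-frame trajectory
#'
#' Frame 1 is a deterministic helix of pseudo C-alpha atoms (one residue per
#' atom, chain A); subsequent frames add iid Gaussian jitter per coordinate
#' and, when `rigid_motion` is set, an additional random proper rotation and
#' translation of the whole frame. Useful for exercising the trajectory
#' metrics against known noise levels.
#'
#' @param spec A [traj_sim_spec()].
#' @return A `trajectory` tibble: one row per atom per frame with columns
#'   `frame`, `atom`, `name`, `element`, `resname`, `resid`, `chain`,
#'   `ligand`, `x`, `y`, `z`.
#' @export
#' @examples
#' tr <- simulate_trajectory(traj_sim_spec(n_frames = 10, n_atoms = 20))
#' radius_of_gyration(tr)
simulate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "traj_sim_spec"))
  i <- seq_len(spec$n_atoms)
  # idealized alpha-helix backbone trace: 100 deg turn, 1.5 A rise, r = 2.3 A
  base <- cbind(x = 2.3 * cos(i * 100 * pi / 180),
                y = 2.3 * sin(i * 100 * pi / 180),
                z = 1.5 * i)
  atoms <- tibble(atom = i, name = "CA", element = "C", resname = "ALA",
                  resid = i, chain = "A", ligand = FALSE)
  withr::with_seed(spec$seed, {
    frames <- purrr::map_dfr(seq_len(spec$n_frames), function(f) {
      xyz <- base
      if (f > 1 && spec$jitter_sd > 0) {
        xyz <- xyz + matrix(rnorm(length(xyz), 0, spec$jitter_sd), ncol = 3)
      }
      if (f > 1 && spec$rigid_motion) {
        rot <- random_rotation()
        xyz <- xyz %*% t(rot) +
          matrix(rnorm(3, 0, 5), nrow(xyz), 3, byrow = TRUE)
      }
      dplyr::mutate(atoms, frame = f, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    })
  })
  as_trajectory(dplyr::relocate(frames, "frame"))
}

# Uniform random proper rotation via QR of a Gaussian matrix.
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Coerce a per-atom-per-frame tibble to a trajectory
#'
#' @param x Tibble with columns `frame`, `atom`, `x`, `y`, `z` and (optionally)
#'   `name`, `element`, `resname`, `resid`, `chain`, `ligand`; every frame must
#'   contain the same atom list.
#' @return The tibble with class `trajectory` prepended.
#' @export
as_trajectory <- function(x) {
  x <- as_tibble(x)
  need <- c("frame", "atom", "x", "y", "z")
  if (!all(need %in% names(x))) {
    abort(paste("A trajectory needs columns:", paste(need, collapse = ", ")))
  }
  defaults <- list(name = "CA", element = "C", resname = "UNK",
                   chain = "A", ligand = FALSE)
  for (nm in names(defaults)) {
    if (!nm %in% names(x)) x[[nm]] <- defaults[[nm]]
  }
  if (!"resid" %in% names(x)) x$resid <- x$atom
  if (any(!is.finite(x$x) | !is.finite(x$y) | !is.finite(x$z))) {
    abort("Trajectory coordinates must be finite.")
  }
  per_frame <- x |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(sig = paste(sort(.data$atom), collapse = ","),
                     .groups = "drop")
  if (length(unique(per_frame$sig)) != 1) {
    abort("All frames must share the same atom list.")
  }
  class(x) <- unique(c("trajectory", class(x)))
  x
}
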