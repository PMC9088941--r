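#' Specification for a synthetic quenching titration
#'
#' Describes the ground truth for a 1:1 static-quenching titration: the
#' Stern-Volmer constant, the binding constant and site number for the
#' double-logarithmic model, the shape of the (single-Gaussian) emission band,
#' the quencher concentration ladder, and the multiplicative noise level.
#' The defaults mirror a tryptophan-region titration: emission band at 345 nm,
#' protein at 16 uM, ligand added in 4 uM steps from 0 to 24 uM.
#'
#' @param ksv_true Stern-Volmer association constant, L mol^-1.
#' @param ka_true Binding constant for the double-log model, L mol^-1.
#' @param n_true Apparent number of binding sites (dimensionless).
#' @param f0_peak Unquenched peak intensity, arbitrary units (instrument scale
#'   is never absolute; only ratios matter downstream).
#' @param peak_wavelength Emission-band centre, nm.
#' @param peak_width Gaussian sigma of the emission band, nm.
#' @param quencher_concs Added-ligand concentrations, mol L^-1; must start at 0
#'   and be strictly increasing.
#' @param protein_conc Protein concentration, mol L^-1 (metadata only).
#' @param noise_sd Relative (multiplicative) Gaussian noise standard deviation.
#' @param seed Integer seed; the generator is bit-reproducible under it.
#' @return An object of class `quench_sim_spec`.
#' @export
#' @examples
#' quench_sim_spec(ksv_true = 4.142e4, noise_sd = 0)
quench_sim_spec <- function(ksv_true = 4.142e4,
                            ka_true = 8.978e4,
                            n_true = 1.073,
                            f0_peak = 600,
                            peak_wavelength = 345,
                            peak_width = 25,
                            quencher_concs = seq(0, 24e-6, by = 4e-6),
                            protein_conc = 1.6e-5,
                            noise_sd = 0.01,
                            seed = 1L) {
  if (!is.numeric(ksv_true) || ksv_true <= 0) abort("`ksv_true` must be > 0.")
  if (!is.numeric(ka_true) || ka_true <= 0) abort("`ka_true` must be > 0.")
  if (!is.numeric(n_true) || n_true <= 0) abort("`n_true` must be > 0.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  check_conc_ladder(quencher_concs)
  structure(
    list(ksv_true = ksv_true, ka_true = ka_true, n_true = n_true,
         f0_peak = f0_peak, peak_wavelength = peak_wavelength,
         peak_width = peak_width, quencher_concs = as.numeric(quencher_concs),
         protein_conc = protein_conc, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "quench_sim_spec"
  )
}

check_conc_ladder <- function(q) {
  if (length(q) < 2) abort("Need at least two quencher concentrations.")
  if (any(q < 0)) abort("Quencher concentrations must be non-negative.")
  if (q[1] != 0) abort("The first quencher concentration must be 0 (defines F0).")
  if (any(diff(q) <= 0)) {
    abort("Quencher concentrations must be strictly increasing.")
  }
  invisible(q)
}

#' Specification for a synthetic TCSPC decay histogram
#'
#' Ground truth for a multi-exponential photon-counting decay: component
#' lifetimes and fractional amplitudes, the peak count level, and the channel
#' grid. Counts are Poisson draws around
#' `total_counts * sum(alpha_i * exp(-t / tau_i))`, with channel 0 at the decay
#' peak (tail model; no instrument-response convolution).
#'
#' @param lifetimes Component lifetimes tau_i, ns; all > 0.
#' @param amplitudes Fractional amplitudes alpha_i, summing to 1.
#' @param total_counts Expected counts in the peak channel.
#' @param channel_width Channel width, ns.
#' @param n_channels Number of channels (>= 64).
#' @param seed Integer seed.
#' @return An object of class `decay_sim_spec`.
#' @export
#' @examples
#' decay_sim_spec(lifetimes = c(1.836, 5.719, 0.474),
#'                amplitudes = c(0.1671, 0.7601, 0.0727) / 0.9999)
decay_sim_spec <- function(lifetimes = c(1.836, 5.719, 0.474),
                           amplitudes = c(0.1671, 0.7601, 0.0727) / 0.9999,
                           total_counts = 1e4,
                           channel_width = 0.05,
                           n_channels = 1024L,
                           seed = 1L) {
  if (any(lifetimes <= 0)) abort("All `lifetimes` must be > 0.")
  if (length(amplitudes) != length(lifetimes)) {
    abort("`amplitudes` and `lifetimes` must have equal length.")
  }
  if (abs(sum(amplitudes) - 1) > 1e-9) {
    abort("`amplitudes` must sum to 1 (within 1e-9).")
  }
  if (n_channels < 64) abort("`n_channels` must be >= 64.")
  if (total_counts <= 0 || channel_width <= 0) {
    abort("`total_counts` and `channel_width` must be > 0.")
  }
  structure(
    list(lifetimes = as.numeric(lifetimes),
         amplitudes = as.numeric(amplitudes),
         total_counts = total_counts, channel_width = channel_width,
         n_channels = as.integer(n_channels), seed = as.integer(seed)),
    class = "decay_sim_spec"
  )
}

#' Specification for a synthetic toy trajectory
#'
#' A fixture generator for the trajectory-metric operators: frame 1 is a
#' deterministic helical chain of pseudo C-alpha atoms (one residue per atom);
#' later frames add iid Gaussian jitter and, optionally, a random rigid
#' rotation + translation per frame.
#'
#' @param n_frames Number of frames (>= 2).
#' @param n_atoms Number of atoms (>= 3).
#' @param jitter_sd Per-coordinate Gaussian jitter, Angstrom.
#' @param rigid_motion Apply a random proper rotation and translation to each
#'   frame after jittering?
#' @param seed Integer seed.
#' @return An object of class `traj_sim_spec`.
#' @export
traj_sim_spec <- function(n_frames = 100L, n_atoms = 50L, jitter_sd = 0.5,
                          rigid_motion = FALSE, seed = 1L) {
  if (n_frames < 2) abort("`n_frames` must be >= 2.")
  if (n_atoms < 3) abort("`n_atoms` must be >= 3.")
  if (jitter_sd < 0) abort("`jitter_sd` must be >= 0.")
  structure(
    list(n_frames = as.integer(n_frames), n_atoms = as.integer(n_atoms),
         jitter_sd = jitter_sd, rigid_motion = isTRUE(rigid_motion),
         seed = as.integer(seed)),
    class = "traj_sim_spec"
  )
}
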