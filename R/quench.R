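#' Fluorescence quenching ratios F0/F from a titration series
#'
#' Evaluates F at each quencher concentration and returns the Stern-Volmer
#' left-hand side F0/F. By default F is read at the fixed wavelength where the
#' unquenched (zero-concentration) spectrum peaks; because static quenching
#' shifts no bands, peak and fixed-wavelength readings coincide on clean data.
#'
#' @param series A [titration_series()].
#' @param mode How to evaluate F: `"peak"` (intensity at the F0-maximum
#'   wavelength; default), `"fixed"` (intensity at `wavelength`), or
#'   `"integrated"` (trapezoidal band area).
#' @param wavelength Evaluation wavelength, nm (required for `mode = "fixed"`).
#' @return A tibble with columns `conc` (mol L^-1), `f` (intensity, a.u.) and
#'   `f0_over_f`; the zero-concentration row has `f0_over_f = 1`.
#' @export
#' @examples
#' s <- simulate_titration(quench_sim_spec(noise_sd = 0), 298)
#' quench_ratios(s)
quench_ratios <- function(series, mode = c("peak", "fixed", "integrated"),
                          wavelength = NULL) {
  stopifnot(inherits(series, "titration_series"))
  mode <- match.arg(mode)
  sp <- series$spectra
  f0_spec <- dplyr::filter(sp, .data$conc == 0)
  eval_f <- switch(mode,
    peak = {
      wl <- f0_spec$wavelength[which.max(f0_spec$intensity)]
      function(d) d$intensity[which.min(abs(d$wavelength - wl))]
    },
    fixed = {
      if (is.null(wavelength)) abort("`wavelength` is required for mode = \"fixed\".")
      function(d) d$intensity[which.min(abs(d$wavelength - wavelength))]
    },
    integrated = function(d) {
      x <- d$wavelength; y <- d$intensity
      sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
    }
  )
  out <- sp |>
    dplyr::group_by(conc = .data$conc) |>
    dplyr::group_modify(~ tibble(f = eval_f(.x))) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$conc)
  bad <- out$conc[out$f <= 0]
  if (length(bad) > 0) {
    abort(sprintf("Non-positive fluorescence at concentration(s): %s",
                  paste(format(bad, digits = 4), collapse = ", ")))
  }
  f0 <- out$f[out$conc == 0]
  dplyr::mutate(out, f0_over_f = f0 / .data$f)
}

#' Stern-Volmer fit of quenching ratios
#'
#' Ordinary least squares of F0/F on the quencher concentration:
#' `F0/F = 1 + Ksv [Q]`. When the unquenched mean lifetime `tau0` is supplied,
#' the bimolecular quenching rate constant is derived as
#' `Kq = Ksv / tau0` (tau0 in seconds; the argument is in ns and converted
#' internally). A Kq far above the diffusion-controlled ceiling of
#' 2e10 L mol^-1 s^-1 is diagnostic of static quenching.
#'
#' @param ratios Tibble from [quench_ratios()] (columns `conc`, `f0_over_f`),
#'   with at least 3 points.
#' @param temperature Temperature, K.
#' @param tau0 Unquenched mean fluorescence lifetime, ns (optional).
#' @return A `quench_fit` with fields `ksv` (L mol^-1), `ksv_stderr`,
#'   `intercept`, `r_squared`, `kq` (L mol^-1 s^-1 or `NA`), `temperature`,
#'   and `data`.
#' @export
#' @examples
#' s <- simulate_titration(quench_sim_spec(noise_sd = 0), 298)
#' stern_volmer_fit(quench_ratios(s), 298, tau0 = 4.688)
stern_volmer_fit <- function(ratios, temperature, tau0 = NULL) {
  ratios <- as_tibble(ratios)
  stopifnot(all(c("conc", "f0_over_f") %in% names(ratios)))
  if (nrow(ratios) < 3) abort("Stern-Volmer fit needs at least 3 points.")
  fit <- lm(f0_over_f ~ conc, data = ratios)
  sm <- suppressWarnings(summary(fit))  # perfect synthetic fits warn
  ksv <- unname(coef(fit)[2])
  structure(
    list(ksv = ksv,
         ksv_stderr = sm$coefficients[2, 2],
         intercept = unname(coef(fit)[1]),
         r_squared = sm$r.squared,
         kq = if (is.null(tau0)) NA_real_ else ksv / (tau0 * 1e-9),
         tau0 = if (is.null(tau0)) NA_real_ else tau0,
         temperature = temperature,
         data = ratios),
    class = "quench_fit"
  )
}

#' Double-logarithmic binding fit
#'
#' For a static-quenching system the binding constant Ka and apparent site
#' number n follow from `lg((F0 - F)/F) = lg Ka + n lg [Q]`, a base-10
#' regression over the nonzero concentrations. Points with F >= F0 carry no
#' binding signal and are dropped with a warning.
#'
#' @inheritParams stern_volmer_fit
#' @return A `binding_fit` with fields `ka` (L mol^-1), `n`,
#'   `log_ka_intercept`, `r_squared`, `temperature`, and `data`.
#' @export
#' @examples
#' s <- simulate_titration(quench_sim_spec(noise_sd = 0), 298,
#'                         model = "double_log")
#' double_log_fit(quench_ratios(s), 298)
double_log_fit <- function(ratios, temperature) {
  ratios <- as_tibble(ratios)
  stopifnot(all(c("conc", "f0_over_f") %in% names(ratios)))
  pts <- dplyr::filter(ratios, .data$conc > 0)
  drop <- pts$f0_over_f <= 1
  if (any(drop)) {
    warn(sprintf("Dropping %d point(s) with F >= F0 (no net quenching).",
                 sum(drop)))
    pts <- pts[!drop, ]
  }
  if (nrow(pts) < 3) abort("Double-log fit needs at least 3 usable points.")
  d <- tibble(x = log10(pts$conc), y = log10(pts$f0_over_f - 1))
  fit <- lm(y ~ x, data = d)
  sm <- suppressWarnings(summary(fit))
  structure(
    list(log_ka_intercept = unname(coef(fit)[1]),
         ka = 10^unname(coef(fit)[1]),
         n = unname(coef(fit)[2]),
         r_squared = sm$r.squared,
         temperature = temperature,
         data = pts),
    class = "binding_fit"
  )
}

#' Classify the quenching mechanism across temperatures
#'
#' Combines up to three independent diagnostics into a static/dynamic call:
#' \itemize{
#'   \item Ksv trend: a Stern-Volmer constant that decreases with temperature
#'     (ground-state complex destabilized by heat) votes static; an increasing
#'     one (faster diffusive collisions) votes dynamic. Strict monotonicity is
#'     judged at a 1% relative tolerance.
#'   \item Kq ceiling: an apparent bimolecular rate constant above the
#'     diffusion-controlled maximum of 2e10 L mol^-1 s^-1 votes static.
#'   \item Lifetime invariance: an unchanged excited-state lifetime on ligand
#'     addition votes static; a shortening one votes dynamic (skipped when no
#'     lifetime data are supplied).
#' }
#' The label is `"static"` or `"dynamic"` only when at least two criteria
#' agree and none contradicts; otherwise `"inconclusive"`.
#'
#' @param fits List of [stern_volmer_fit()] results at distinct temperatures
#'   (>= 2), or a tibble with columns `temperature`, `ksv` and optionally `kq`.
#' @param lifetime_flag Optional logical from [lifetime_invariance()].
#' @param rel_tol Relative tolerance for the Ksv monotonicity test.
#' @return A `mechanism_call`: list with `label` and an `evidence` tibble of
#'   (criterion, verdict) pairs.
#' @export
#' @examples
#' tab <- tibble::tibble(temperature = c(298, 304, 310),
#'                       ksv = c(4.142, 3.447, 2.338) * 1e4,
#'                       kq = c(8.835e12, NA, NA))
#' classify_mechanism(tab, lifetime_flag = TRUE)
classify_mechanism <- function(fits, lifetime_flag = NULL, rel_tol = 0.01) {
  tab <- if (is.data.frame(fits)) {
    as_tibble(fits)
  } else {
    purrr::map_dfr(fits, ~ tibble(temperature = .x$temperature,
                                  ksv = .x$ksv, kq = .x$kq))
  }
  stopifnot(all(c("temperature", "ksv") %in% names(tab)))
  if (!"kq" %in% names(tab)) tab$kq <- NA_real_
  if (nrow(tab) < 2) abort("Mechanism classification needs >= 2 temperatures.")
  if (anyDuplicated(tab$temperature)) {
    abort("Temperatures must be distinct.")
  }
  tab <- dplyr::arrange(tab, .data$temperature)

  votes <- list()
  r <- diff(tab$ksv) / head(tab$ksv, -1)
  trend <- if (all(r < -rel_tol)) {
    "static"
  } else if (all(r > rel_tol)) {
    "dynamic"
  } else {
    "inconclusive"
  }
  votes$ksv_trend <- trend

  kq <- tab$kq[is.finite(tab$kq)]
  votes$kq_ceiling <- if (length(kq) == 0) {
    NA_character_
  } else if (max(kq) > .KQ_DYNAMIC_MAX) {
    "static"
  } else {
    "dynamic"
  }

  votes$lifetime <- if (is.null(lifetime_flag)) {
    NA_character_
  } else if (isTRUE(lifetime_flag)) {
    "static"
  } else {
    "dynamic"
  }

  ev <- tibble(criterion = c("ksv_trend", "kq_ceiling", "lifetime_invariance"),
               verdict = unlist(votes, use.names = FALSE))
  cast <- ev$verdict[!is.na(ev$verdict) & ev$verdict != "inconclusive"]
  label <- if (length(cast) >= 2 && length(unique(cast)) == 1) {
    unique(cast)
  } else {
    "inconclusive"
  }
  structure(list(label = label, evidence = ev, ksv_table = tab),
            class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat("<mechanism_call> label:", x$label, "\n")
  print(x$evidence)
  invisible(x)
}

#' @method tidy mechanism_call
#' @export
tidy.mechanism_call <- function(x, ...) x$evidence

#' @export
print.quench_fit <- function(x, ...) {
  cat(sprintf("<quench_fit> T = %g K: Ksv = %.4g L/mol (se %.2g), R^2 = %.4f\n",
              x$temperature, x$ksv, x$ksv_stderr, x$r_squared))
  if (is.finite(x$kq)) cat(sprintf("  Kq = %.4g L/mol/s (tau0 = %g ns)\n",
                                   x$kq, x$tau0))
  invisible(x)
}

#' @method tidy quench_fit
#' @export
tidy.quench_fit <- function(x, ...) {
  tibble(term = c("intercept", "ksv"),
         estimate = c(x$intercept, x$ksv),
         std.error = c(NA_real_, x$ksv_stderr))
}

#' @method glance quench_fit
#' @export
glance.quench_fit <- function(x, ...) {
  tibble(temperature = x$temperature, ksv = x$ksv, ksv_stderr = x$ksv_stderr,
         kq = x$kq, r.squared = x$r_squared, n_points = nrow(x$data))
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> T = %g K: Ka = %.4g L/mol, n = %.3f, R^2 = %.4f\n",
              x$temperature, x$ka, x$n, x$r_squared))
  invisible(x)
}

#' @method tidy binding_fit
#' @export
tidy.binding_fit <- function(x, ...) {
  tibble(term = c("log10_ka", "n"),
         estimate = c(x$log_ka_intercept, x$n))
}

#' @method glance binding_fit
#' @export
glance.binding_fit <- function(x, ...) {
  tibble(temperature = x$temperature, ka = x$ka, n = x$n,
         r.squared = x$r_squared, n_points = nrow(x$data))
}

#' @method autoplot quench_fit
#' @export
autoplot.quench_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$conc,
                                            y = .data$f0_over_f)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$ksv,
                         colour = "steelblue") +
    ggplot2::labs(x = "[Q] (mol/L)", y = expression(F[0] / F),
                  title = sprintf("Stern-Volmer plot, %g K", object$temperature))
}

#' @method autoplot binding_fit
#' @export
autoplot.binding_fit <- function(object, ...) {
  d <- tibble(x = log10(object$data$conc),
              y = log10(object$data$f0_over_f - 1))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$log_ka_intercept, slope = object$n,
                         colour = "steelblue") +
    ggplot2::labs(x = "lg [Q]", y = "lg((F0 - F)/F)",
                  title = sprintf("Double-log binding plot, %g K",
                                  object$temperature))
}
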