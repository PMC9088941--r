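#' Van't Hoff analysis of binding constants across temperatures
#'
#' Linear Van't Hoff regression `ln Ka = -dH/(R T) + dS/R`: ordinary least
#' squares of ln Ka on 1/T gives the binding enthalpy from the slope
#' (`dH = -R * slope`) and the binding entropy from the intercept
#' (`dS = R * intercept`), with R = 8.314 J mol^-1 K^-1. The Gibbs energy is
#' then filled in at every input temperature from the unrounded dH and dS via
#' `dG = dH - T dS`, and the dominant intermolecular force is labelled from
#' the signs of dH and dS (see [classify_force()]).
#'
#' Note Ka enters the logarithm carrying its L mol^-1 units (the field's
#' convention for these fits); dS therefore contains the implicit standard
#' state.
#'
#' @param ka_by_temperature Tibble (or data frame) with columns `temperature`
#'   (K) and `ka` (L mol^-1); at least 2 distinct temperatures, all Ka > 0.
#'   A list of [double_log_fit()] results is also accepted.
#' @param weights Optional per-point weights for a weighted fit (default
#'   unweighted, matching the usual linear Van't Hoff plot).
#' @return A `thermo_result` with fields `delta_h` (kJ mol^-1), `delta_s`
#'   (J mol^-1 K^-1), `delta_g` (tibble: temperature, delta_g in kJ mol^-1),
#'   `r_squared`, `force_label`, `spontaneous`, and `data`.
#' @export
#' @examples
#' vant_hoff(tibble::tibble(temperature = c(298, 304, 310),
#'                          ka = c(8.978, 4.998, 1.782) * 1e4))
vant_hoff <- function(ka_by_temperature, weights = NULL) {
  tab <- if (is.data.frame(ka_by_temperature)) {
    as_tibble(ka_by_temperature)
  } else {
    purrr::map_dfr(ka_by_temperature,
                   ~ tibble(temperature = .x$temperature, ka = .x$ka))
  }
  stopifnot(all(c("temperature", "ka") %in% names(tab)))
  if (any(tab$ka <= 0)) abort("All Ka must be > 0.")
  if (length(unique(tab$temperature)) < 2) {
    abort("Van't Hoff analysis needs >= 2 distinct temperatures.")
  }
  tab <- dplyr::arrange(tab, .data$temperature)
  d <- tibble(x = 1 / tab$temperature, y = log(tab$ka))
  fit <- if (is.null(weights)) lm(y ~ x, data = d) else
    lm(y ~ x, data = d, weights = weights)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  delta_h <- -.R_GAS * slope / 1000      # kJ/mol
  delta_s <- .R_GAS * intercept          # J/mol/K
  dg <- tibble(temperature = tab$temperature,
               delta_g = gibbs(delta_h, delta_s, tab$temperature))
  force <- tryCatch(classify_force(delta_h, delta_s),
                    error = function(e) NA_character_)
  structure(
    list(delta_h = delta_h, delta_s = delta_s, delta_g = dg,
         r_squared = suppressWarnings(summary(fit)$r.squared),
         force_label = force, spontaneous = all(dg$delta_g < 0),
         data = tab),
    class = "thermo_result"
  )
}

#' Gibbs free energy from enthalpy and entropy
#'
#' `dG = dH - T dS`, with dH in kJ mol^-1 and dS in J mol^-1 K^-1 (the J/kJ
#' conversion is handled internally). Vectorized over `temperature`.
#'
#' @param delta_h Enthalpy change, kJ mol^-1.
#' @param delta_s Entropy change, J mol^-1 K^-1.
#' @param temperature Temperature(s), K; must be > 0.
#' @return Gibbs energy change(s), kJ mol^-1.
#' @export
#' @examples
#' gibbs(-103.28, -251.12, c(298, 304, 310))
gibbs <- function(delta_h, delta_s, temperature) {
  if (any(temperature <= 0)) abort("`temperature` must be > 0 K.")
  delta_h - temperature * delta_s / 1000
}

#' Dominant binding force from thermodynamic signs
#'
#' Sign-rule classification of the principal non-covalent force driving
#' complex formation: dH < 0 and dS < 0 indicate hydrogen bonding and/or
#' van der Waals contacts; dH > 0 and dS > 0 indicate hydrophobic
#' interactions; dH < 0 with dS > 0 indicates electrostatic forces. An
#' exactly zero dH or dS is indeterminate and raises an error.
#'
#' @param delta_h Enthalpy change, kJ mol^-1.
#' @param delta_s Entropy change, J mol^-1 K^-1.
#' @return One of `"hydrogen-bond/van-der-Waals"`, `"hydrophobic"`,
#'   `"electrostatic"`.
#' @export
#' @examples
#' classify_force(-103.28, -251.12)
classify_force <- function(delta_h, delta_s) {
  if (!is.finite(delta_h) || !is.finite(delta_s)) {
    abort("`delta_h` and `delta_s` must be finite.")
  }
  if (delta_h == 0 || delta_s == 0) {
    abort("Zero enthalpy or entropy change: force assignment indeterminate.",
          class = "quenchbind_indeterminate")
  }
  if (delta_h < 0 && delta_s < 0) return("hydrogen-bond/van-der-Waals")
  if (delta_h > 0 && delta_s > 0) return("hydrophobic")
  if (delta_h < 0 && delta_s > 0) return("electrostatic")
  # dH > 0, dS < 0: no spontaneous regime under the sign rules
  "unfavorable"
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("<thermo_result> dH = %.2f kJ/mol, dS = %.2f J/mol/K (R^2 = %.5f)\n",
              x$delta_h, x$delta_s, x$r_squared))
  print(dplyr::mutate(x$delta_g, delta_g = round(.data$delta_g, 2)))
  cat("dominant force:", x$force_label,
      if (x$spontaneous) "(spontaneous at all temperatures)\n" else "\n")
  invisible(x)
}

#' @method tidy thermo_result
#' @export
tidy.thermo_result <- function(x, ...) {
  dplyr::bind_rows(
    tibble(term = "delta_h_kJ_mol", estimate = x$delta_h),
    tibble(term = "delta_s_J_mol_K", estimate = x$delta_s),
    tibble(term = paste0("delta_g_kJ_mol_", x$delta_g$temperature, "K"),
           estimate = x$delta_g$delta_g)
  )
}

#' @method glance thermo_result
#' @export
glance.thermo_result <- function(x, ...) {
  tibble(delta_h = x$delta_h, delta_s = x$delta_s,
         r.squared = x$r_squared, force_label = x$force_label,
         spontaneous = x$spontaneous, n_temperatures = nrow(x$data))
}

#' @method autoplot thermo_result
#' @export
autoplot.thermo_result <- function(object, ...) {
  d <- tibble(inv_t = 1 / object$data$temperature, ln_ka = log(object$data$ka))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$inv_t, y = .data$ln_ka)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$delta_s / .R_GAS,
                         slope = -object$delta_h * 1000 / .R_GAS,
                         colour = "steelblue") +
    ggplot2::labs(x = "1/T (1/K)", y = "ln Ka",
                  title = sprintf("Van't Hoff plot: dH = %.1f kJ/mol, dS = %.1f J/mol/K",
                                  object$delta_h, object$delta_s))
}
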