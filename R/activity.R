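#' Enzyme inhibition rate from an absorbance assay table
#'
#' Modified-Anson assay arithmetic: the inhibition rate at each ligand
#' concentration is `(OD_blank - OD_sample) / OD_blank * 100`, where the blank
#' is the zero-ligand row. Negative values mean activation (the ligand
#' enhances catalysis) and are reported as-is. Replicate rows at one
#' concentration are averaged first, with the standard deviation carried
#' along.
#'
#' @param table Tibble with columns `conc` (ligand, mol L^-1) and `od660`
#'   (absorbance at 660 nm, a.u.); the blank is the row (or rows) with
#'   `conc == 0` and must have positive absorbance.
#' @return Tibble: `conc`, `od660` (replicate mean), `od_sd` (NA without
#'   replicates), `inhibition_pct`.
#' @export
#' @examples
#' tab <- tibble::tibble(conc = c(0, 8e-6, 24e-6),
#'                       od660 = c(0.500, 0.520, 0.540))
#' inhibition_rate(tab)  # negative: activation
inhibition_rate <- function(table) {
  tab <- validate_activity(table)
  blank <- tab$od660[tab$conc == 0]
  dplyr::mutate(tab, inhibition_pct = (blank - .data$od660) / blank * 100)
}

#' Relative enzyme activity
#'
#' Activity of each sample relative to the ligand-free blank, whose activity
#' is defined as 1: `od_sample / od_blank`. Algebraically this equals
#' `1 - inhibition_rate/100` row for row.
#'
#' @inheritParams inhibition_rate
#' @return Tibble: `conc`, `od660`, `od_sd`, `relative_activity`.
#' @export
#' @examples
#' tab <- tibble::tibble(conc = c(0, 8e-6), od660 = c(0.500, 0.550))
#' relative_activity(tab)
relative_activity <- function(table) {
  tab <- validate_activity(table)
  blank <- tab$od660[tab$conc == 0]
  dplyr::mutate(tab, relative_activity = .data$od660 / blank)
}

validate_activity <- function(table) {
  tab <- as_tibble(table)
  stopifnot(all(c("conc", "od660") %in% names(tab)))
  if (any(tab$conc < 0)) abort("Ligand concentrations must be non-negative.")
  if (any(tab$od660 < 0)) abort("Absorbances must be non-negative.")
  if (!any(tab$conc == 0)) abort("No blank row (conc == 0) found.")
  # average replicates per concentration, keep the spread
  tab <- tab |>
    dplyr::group_by(conc = .data$conc) |>
    dplyr::summarise(od_sd = if (dplyr::n() > 1) sd(.data$od660) else NA_real_,
                     od660 = mean(.data$od660), .groups = "drop") |>
    dplyr::relocate("conc", "od660", "od_sd") |>
    dplyr::arrange(.data$conc)
  if (tab$od660[tab$conc == 0] <= 0) {
    abort("Blank absorbance must be > 0.")
  }
  tab
}
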