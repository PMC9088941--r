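
# ---- shared CSV helpers -----------------------------------------------------

# `#`-prefixed "key: value" metadata header, then a CSV table
read_meta_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines)
  meta <- list()
  for (l in lines[meta_lines]) {
    m <- regmatches(l, regexec("^#\\s*([^:]+):\\s*(.*)$", l))[[1]]
    if (length(m) == 3) {
      val <- suppressWarnings(as.numeric(m[3]))
      meta[[trimws(m[2])]] <- if (is.na(val)) trimws(m[3]) else val
    }
  }
  body <- if (length(meta_lines)) lines[-meta_lines] else lines
  body <- body[nzchar(trimws(body))]
  tab <- utils::read.csv(text = paste(body, collapse = "\n"),
                         check.names = FALSE)
  list(meta = meta, table = as_tibble(tab))
}

write_meta_csv <- function(table, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, format(meta[[k]], digits = 12)), con)
  }
  utils::write.table(table, con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

check_monotone_wl <- function(wl, path) {
  if (any(diff(wl) <= 0)) {
    abort(sprintf("%s: wavelength column must be strictly increasing.", path))
  }
}

# ---- titration / synchronous scans ------------------------------------------

#' Read and write titration spectra
#'
#' CSV dialect: `#`-prefixed metadata (`temperature_K`, `protein_conc_M`),
#' then a header row `wavelength_nm` followed by one column per quencher
#' concentration (column name = molarity), one row per wavelength.
#'
#' @param path File path.
#' @return [read_titration()]: a [titration_series()].
#' @export
read_titration <- function(path) {
  x <- read_meta_csv(path)
  tab <- x$table
  if (names(tab)[1] != "wavelength_nm") {
    abort(sprintf("%s: expected first column `wavelength_nm`, found `%s`.",
                  path, names(tab)[1]))
  }
  check_monotone_wl(tab$wavelength_nm, path)
  concs <- as.numeric(names(tab)[-1])
  if (anyNA(concs)) abort(sprintf("%s: non-numeric concentration header.", path))
  spectra <- tidyr::pivot_longer(tab, -"wavelength_nm", names_to = "conc",
                                 values_to = "intensity") |>
    dplyr::mutate(conc = as.numeric(.data$conc)) |>
    dplyr::rename(wavelength = "wavelength_nm")
  titration_series(spectra,
                   temperature = x$meta$temperature_K %||% NA_real_,
                   protein_conc = x$meta$protein_conc_M %||% NA_real_)
}

#' @rdname read_titration
#' @param series A [titration_series()].
#' @export
write_titration <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  wide <- tidyr::pivot_wider(series$spectra, names_from = "conc",
                             values_from = "intensity") |>
    dplyr::rename(wavelength_nm = "wavelength")
  write_meta_csv(wide, path,
                 meta = list(temperature_K = series$temperature,
                             protein_conc_M = series$protein_conc))
}

# generic multi-column scan (synchronous scans; concentrations in the header)
read_scan_series <- function(path) {
  x <- read_meta_csv(path)
  tab <- x$table
  check_monotone_wl(tab[[1]], path)
  names(tab)[1] <- "wavelength"
  tidyr::pivot_longer(tab, -"wavelength", names_to = "conc",
                      values_to = "intensity") |>
    dplyr::mutate(conc = as.numeric(.data$conc)) |>
    dplyr::relocate("conc")
}

# ---- decay ------------------------------------------------------------------

#' Read and write TCSPC decay histograms
#'
#' Two-column CSV (`time_ns`, `counts`) with optional `#`-prefixed metadata
#' (`label`, `ex_nm`, `em_nm`).
#'
#' @param path File path.
#' @return [read_decay()]: a [decay_curve()].
#' @export
read_decay <- function(path) {
  x <- read_meta_csv(path)
  tab <- x$table
  if (!all(c("time_ns", "counts") %in% names(tab))) {
    abort(sprintf("%s: expected columns `time_ns`, `counts`.", path))
  }
  decay_curve(tab[c("time_ns", "counts")], meta = x$meta)
}

#' @rdname read_decay
#' @param curve A [decay_curve()].
#' @export
write_decay <- function(curve, path) {
  stopifnot(inherits(curve, "decay_curve"))
  meta <- attr(curve, "meta")
  write_meta_csv(as_tibble(curve)[c("time_ns", "counts")], path,
                 meta = meta[vapply(meta, is.atomic, logical(1))])
}

# ---- EEM --------------------------------------------------------------------

#' Read and write excitation-emission matrices
#'
#' Grid CSV: first row holds the emission grid (first cell `ex_nm`), the
#' first column holds the excitation grid, the body holds intensities.
#'
#' @param path File path.
#' @return [read_eem()]: an [eem()] object.
#' @export
read_eem <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  cells <- strsplit(lines, ",")
  width <- length(cells[[1]])
  bad <- which(vapply(cells, length, integer(1)) != width)
  if (length(bad) > 0) {
    abort(sprintf("%s: row %d has %d fields, expected %d.",
                  path, bad[1], length(cells[[bad[1]]]), width))
  }
  em <- as.numeric(cells[[1]][-1])
  ex <- as.numeric(vapply(cells[-1], `[[`, character(1), 1))
  z <- do.call(rbind, lapply(cells[-1], function(r) as.numeric(r[-1])))
  if (anyNA(em) || anyNA(ex) || anyNA(z)) {
    abort(sprintf("%s: non-numeric cells in EEM grid.", path))
  }
  eem(ex_grid = ex, em_grid = em, intensity = z)
}

#' @rdname read_eem
#' @param x An [eem()] object.
#' @export
write_eem <- function(x, path) {
  stopifnot(inherits(x, "eem"))
  header <- paste(c("ex_nm", format(x$em, digits = 12, trim = TRUE)),
                  collapse = ",")
  rows <- vapply(seq_along(x$ex), function(i) {
    paste(c(format(x$ex[i], digits = 12, trim = TRUE),
            format(x$intensity[i, ], digits = 12, trim = TRUE)),
          collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

# ---- activity / ka ----------------------------------------------------------

#' Read an enzyme-activity assay table
#'
#' CSV with columns `ligand_conc_M` and `od660`; the blank is the
#' zero-concentration row.
#'
#' @param path File path.
#' @return Tibble with columns `conc`, `od660`.
#' @export
read_activity <- function(path) {
  x <- read_meta_csv(path)
  tab <- x$table
  if (!all(c("ligand_conc_M", "od660") %in% names(tab))) {
    abort(sprintf("%s: expected columns `ligand_conc_M`, `od660`.", path))
  }
  tibble(conc = tab$ligand_conc_M, od660 = tab$od660)
}

#' Read a binding-constant table
#'
#' CSV with columns `temperature_K` and `ka` for standalone Van't Hoff
#' analysis.
#'
#' @param path File path.
#' @return Tibble with columns `temperature`, `ka`.
#' @export
read_ka <- function(path) {
  x <- read_meta_csv(path)
  tab <- x$table
  if (!all(c("temperature_K", "ka") %in% names(tab))) {
    abort(sprintf("%s: expected columns `temperature_K`, `ka`.", path))
  }
  tibble(temperature = tab$temperature_K, ka = tab$ka)
}

# ---- multi-model PDB --------------------------------------------------------

#' Read and write multi-model PDB trajectories
#'
#' Fixed-column PDB v3.3: MODEL/ENDMDL records delimit frames; ATOM and
#' HETATM records supply coordinates. HETATM atoms are flagged as ligand by
#' default. Only the fields the trajectory metrics need are kept.
#'
#' @param path File path.
#' @return [read_pdb_trajectory()]: a trajectory tibble
#'   (see [as_trajectory()]).
#' @export
read_pdb_trajectory <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frame <- 0L
  in_model <- FALSE
  rows <- list()
  serial_seen <- FALSE
  for (ln in lines) {
    tag <- substr(ln, 1, 6)
    if (startsWith(tag, "MODEL")) {
      frame <- frame + 1L
      in_model <- TRUE
    } else if (startsWith(tag, "ENDMDL")) {
      in_model <- FALSE
    } else if (tag == "ATOM  " || tag == "HETATM") {
      if (!in_model && frame == 0L) frame <- 1L
      rows[[length(rows) + 1]] <- tibble(
        frame = frame,
        atom = as.integer(substr(ln, 7, 11)),
        name = trimws(substr(ln, 13, 16)),
        resname = trimws(substr(ln, 18, 20)),
        chain = trimws(substr(ln, 22, 22)),
        resid = as.integer(substr(ln, 23, 26)),
        x = as.numeric(substr(ln, 31, 38)),
        y = as.numeric(substr(ln, 39, 46)),
        z = as.numeric(substr(ln, 47, 54)),
        element = trimws(substr(ln, 77, 78)),
        ligand = tag == "HETATM"
      )
    }
  }
  if (length(rows) == 0) abort(sprintf("%s: no ATOM/HETATM records.", path))
  d <- dplyr::bind_rows(rows)
  # element column is optional in old files: fall back to the atom-name head
  blank <- d$element == ""
  d$element[blank] <- substr(gsub("[0-9]", "", d$name[blank]), 1, 1)
  as_trajectory(d)
}

#' @rdname read_pdb_trajectory
#' @param traj A trajectory tibble.
#' @export
write_pdb_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in sort(unique(traj$frame))) {
    writeLines(sprintf("MODEL     %4d", as.integer(f)), con)
    d <- dplyr::arrange(dplyr::filter(traj, .data$frame == f), .data$atom)
    recs <- sprintf(
      "%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      ifelse(d$ligand, "HETATM", "ATOM"),
      as.integer(d$atom) %% 100000,
      substr(d$name, 1, 4), substr(d$resname, 1, 3),
      substr(d$chain, 1, 1), as.integer(d$resid) %% 10000,
      d$x, d$y, d$z, 1, 0, toupper(substr(d$element, 1, 2)))
    writeLines(recs, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---- dispatcher -------------------------------------------------------------

#' Read any supported input file by dialect
#'
#' One entry point over all the package's plain-text readers.
#'
#' @param path File path.
#' @param dialect One of `"titration"`, `"sync"`, `"eem"`, `"cd"`, `"decay"`,
#'   `"activity"`, `"ka"`, `"pdb"`.
#' @return The corresponding validated object (see the individual readers).
#' @export
read_table <- function(path, dialect = c("titration", "sync", "eem", "cd",
                                         "decay", "activity", "ka", "pdb")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  switch(dialect,
    titration = read_titration(path),
    sync = read_scan_series(path),
    eem = read_eem(path),
    cd = {
      x <- read_meta_csv(path)
      tab <- x$table
      check_monotone_wl(tab[[1]], path)
      tibble(wavelength = tab[[1]], ellipticity = tab[[2]])
    },
    decay = read_decay(path),
    activity = read_activity(path),
    ka = read_ka(path),
    pdb = read_pdb_trajectory(path)
  )
}
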