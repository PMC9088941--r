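# standard atomic masses (u) for mass-weighted metrics
.ATOM_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
                S = 32.06, FE = 55.845, ZN = 65.38, MG = 24.305, NA. = 22.99,
                CL = 35.45, K = 39.098, CA = 40.078)

atom_masses <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  m <- .ATOM_MASS[key]
  if (anyNA(m)) {
    warn(sprintf("Unknown element(s) %s: using mass 12.0.",
                 paste(unique(element[is.na(m)]), collapse = ", ")))
    m[is.na(m)] <- 12
  }
  unname(m)
}

# Evaluate a selection predicate (tidy expression over atom columns) against
# the frame-1 atom table; returns atom ids.
select_atoms <- function(traj, selection) {
  atoms <- dplyr::filter(traj, .data$frame == min(.data$frame))
  keep <- eval_tidy(selection, data = atoms)
  if (is.null(keep)) keep <- rep(TRUE, nrow(atoms))
  atoms$atom[keep]
}

# frames as a list of n_atoms x 3 matrices, ordered by atom id
frame_coords <- function(traj, atom_ids = NULL) {
  d <- traj
  if (!is.null(atom_ids)) d <- dplyr::filter(d, .data$atom %in% atom_ids)
  d <- dplyr::arrange(d, .data$frame, .data$atom)
  fr <- unique(d$frame)
  n <- nrow(d) / length(fr)
  lapply(seq_along(fr), function(i) {
    rows <- d[((i - 1) * n + 1):(i * n), ]
    cbind(rows$x, rows$y, rows$z)
  }) |> setNames(fr)
}

#' Kabsch optimal rigid superposition
#'
#' Returns the proper rotation and translation that superpose `mobile` onto
#' `reference` with minimal squared deviation. Both are n x 3 coordinate
#' matrices with matching rows. The rotation determinant is forced to +1
#' (SVD sign correction), so mirror images are never produced.
#'
#' @param mobile,reference n x 3 coordinate matrices, n >= 3.
#' @return List with `rotation` (3 x 3), the centroids, the superposed
#'   coordinates `xyz`, and the post-fit `rmsd`.
#' @export
kabsch <- function(mobile, reference) {
  if (nrow(mobile) < 3) {
    abort("Superposition needs at least 3 atoms.")
  }
  stopifnot(all(dim(mobile) == dim(reference)))
  cm <- colMeans(mobile); cr <- colMeans(reference)
  p <- sweep(mobile, 2, cm)
  q <- sweep(reference, 2, cr)
  s <- svd(crossprod(p, q))            # H = P^T Q
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  xyz <- p %*% t(rot)
  xyz <- sweep(xyz, 2, cr, "+")
  list(rotation = rot, centroid_mobile = cm, centroid_reference = cr,
       xyz = xyz, rmsd = sqrt(mean(rowSums((xyz - reference)^2))))
}

#' RMSD time series after optimal superposition
#'
#' For each frame, superposes the selected atoms onto the reference frame by
#' the Kabsch algorithm (proper rotation + translation) and reports the
#' root-mean-square deviation over the selection. The conventional selection
#' for protein backbones is the C-alpha trace (the default).
#'
#' @param traj A trajectory tibble (see [as_trajectory()]).
#' @param selection Atom predicate over the atom columns, e.g.
#'   `name == "CA"`; unquoted, tidy-evaluated. `NULL` selects all atoms.
#' @param reference Reference frame id (default: the first frame).
#' @return Tibble: `frame`, `rmsd` (Angstrom).
#' @export
#' @examples
#' tr <- simulate_trajectory(traj_sim_spec(n_frames = 5, n_atoms = 10,
#'                                         jitter_sd = 0, rigid_motion = TRUE))
#' rmsd_series(tr)  # all zero: rigid motion is removed by superposition
rmsd_series <- function(traj, selection = NULL, reference = NULL) {
  sel <- enquo(selection)
  ids <- select_atoms(traj, sel)
  if (length(ids) == 0) abort("Empty atom selection.")
  if (length(ids) < 3) abort("RMSD needs >= 3 selected atoms (superposition).")
  coords <- frame_coords(traj, ids)
  frames <- as.numeric(names(coords))
  if (is.null(reference)) reference <- frames[1]
  ref <- coords[[as.character(reference)]]
  if (is.null(ref)) abort("Reference frame not found in trajectory.")
  tibble(frame = frames,
         rmsd = unname(vapply(coords, function(m) kabsch(m, ref)$rmsd,
                               numeric(1))))
}

#' Per-residue RMSF about the trajectory-average structure
#'
#' Each frame is first superposed (Kabsch) onto the selection's mean
#' structure, iterated once so the average is self-consistent; the RMSF of an
#' atom is the root-mean-square displacement from its average position over
#' the window, and a residue's RMSF is the mean over its selected atoms.
#'
#' @inheritParams rmsd_series
#' @param window Optional frame ids to include (default: all frames).
#' @return Tibble: `chain`, `resid`, `resname`, `rmsf` (Angstrom).
#' @export
rmsf_per_residue <- function(traj, selection = NULL, window = NULL) {
  sel <- enquo(selection)
  ids <- select_atoms(traj, sel)
  if (length(ids) == 0) abort("Empty atom selection.")
  d <- dplyr::filter(traj, .data$atom %in% ids)
  if (!is.null(window)) d <- dplyr::filter(d, .data$frame %in% window)
  if (nrow(d) == 0) abort("Empty frame window.")
  coords <- frame_coords(d)
  # superpose all frames on frame 1, average, then re-superpose on the mean
  if (length(ids) >= 3) {
    ref <- coords[[1]]
    for (pass in 1:2) {
      coords <- lapply(coords, function(m) kabsch(m, ref)$xyz)
      ref <- Reduce(`+`, coords) / length(coords)
    }
  }
  mean_xyz <- Reduce(`+`, coords) / length(coords)
  disp2 <- Reduce(`+`, lapply(coords, function(m) {
    rowSums((m - mean_xyz)^2)
  })) / length(coords)
  atoms <- d |>
    dplyr::filter(.data$frame == min(.data$frame)) |>
    dplyr::arrange(.data$atom)
  tibble(chain = atoms$chain, resid = atoms$resid, resname = atoms$resname,
         rmsf_atom = sqrt(disp2)) |>
    dplyr::group_by(.data$chain, .data$resid, .data$resname) |>
    dplyr::summarise(rmsf = mean(.data$rmsf_atom), .groups = "drop") |>
    dplyr::arrange(.data$chain, .data$resid)
}

#' Radius of gyration per frame
#'
#' `Rg = sqrt(sum(w_i |r_i - rbar|^2) / sum(w_i))` with the (optionally
#' mass-) weighted centroid `rbar`; a compactness measure that is invariant
#' under rigid motion and scales linearly with the coordinates.
#'
#' @inheritParams rmsd_series
#' @param mass_weighted Weight atoms by standard atomic mass (by element)?
#'   Default `FALSE` (unit weights).
#' @return Tibble: `frame`, `rg` (Angstrom).
#' @export
#' @examples
#' sq <- tibble::tibble(frame = 1, atom = 1:4, x = c(1, 1, -1, -1),
#'                      y = c(1, -1, 1, -1), z = 0)
#' radius_of_gyration(as_trajectory(sq))  # sqrt(2)
radius_of_gyration <- function(traj, selection = NULL, mass_weighted = FALSE) {
  sel <- enquo(selection)
  ids <- select_atoms(traj, sel)
  if (length(ids) < 2) abort("Radius of gyration needs >= 2 selected atoms.")
  d <- dplyr::filter(traj, .data$atom %in% ids)
  atoms <- dplyr::arrange(
    dplyr::filter(d, .data$frame == min(.data$frame)), .data$atom)
  w <- if (mass_weighted) atom_masses(atoms$element) else
    rep(1, length(ids))
  coords <- frame_coords(d)
  tibble(frame = as.numeric(names(coords)),
         rg = unname(vapply(coords, function(m) {
           ctr <- colSums(m * w) / sum(w)
           sqrt(sum(w * rowSums(sweep(m, 2, ctr)^2)) / sum(w))
         }, numeric(1))))
}

#' Ligand-residue distance series
#'
#' Per frame, the minimum over all ligand-atom x residue-atom pairwise
#' distances (closest-contact convention), plus its mean and minimum over
#' frames. A centre-of-mass variant is available.
#'
#' @inheritParams rmsd_series
#' @param ligand Atom predicate selecting the ligand (default: the `ligand`
#'   flag column).
#' @param resid Residue sequence number of the target residue.
#' @param chain Chain of the target residue (default any).
#' @param method `"closest"` (minimum atom-pair distance, default) or
#'   `"com"` (distance between unweighted centroids).
#' @return List of class `residue_distance`: `series` tibble (`frame`,
#'   `distance`), `mean`, `min`, `resid`.
#' @export
ligand_residue_distance <- function(traj, resid, ligand = NULL, chain = NULL,
                                    method = c("closest", "com")) {
  method <- match.arg(method)
  lig <- enquo(ligand)
  atoms <- dplyr::filter(traj, .data$frame == min(.data$frame))
  lig_keep <- eval_tidy(lig, data = atoms)
  if (is.null(lig_keep)) lig_keep <- atoms$ligand
  lig_ids <- atoms$atom[lig_keep]
  res_rows <- atoms$resid == resid & !atoms$ligand
  if (!is.null(chain)) res_rows <- res_rows & atoms$chain == chain
  res_ids <- atoms$atom[res_rows]
  if (length(lig_ids) == 0) abort("Empty ligand selection.")
  if (length(res_ids) == 0) {
    abort(sprintf("Residue %s not found. Available residues: %s", resid,
                  paste(sort(unique(atoms$resid[!atoms$ligand])),
                        collapse = ", ")))
  }
  lc <- frame_coords(traj, lig_ids)
  rc <- frame_coords(traj, res_ids)
  dist_fun <- switch(method,
    closest = function(a, b) {
      d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
      sqrt(max(min(d2), 0))
    },
    com = function(a, b) sqrt(sum((colMeans(a) - colMeans(b))^2))
  )
  series <- tibble(frame = as.numeric(names(lc)),
                   distance = unname(purrr::map2_dbl(lc, rc, dist_fun)))
  structure(list(series = series, mean = mean(series$distance),
                 min = min(series$distance), resid = resid, method = method),
            class = "residue_distance")
}

#' @export
print.residue_distance <- function(x, ...) {
  cat(sprintf(
    "<residue_distance> residue %s (%s): mean = %.3f A, min = %.3f A over %d frames\n",
    format(x$resid), x$method, x$mean, x$min, nrow(x$series)))
  invisible(x)
}

#' @method tidy residue_distance
#' @export
tidy.residue_distance <- function(x, ...) x$series

#' Geometric hydrogen-bond count per frame
#'
#' Counts donor-H...acceptor triples satisfying a distance-angle criterion:
#' H...acceptor distance at most `d_max` and donor-H...acceptor angle at
#' least `angle_min`. Hydrogens are attached to donor heavy atoms by a
#' covalent distance cutoff (1.25 A) in the first frame; donors without an
#' attached hydrogen raise an error naming them. Triples whose donor and
#' acceptor coincide, and duplicated triples under overlapping selections,
#' are excluded.
#'
#' @inheritParams rmsd_series
#' @param donors Atom predicate for donor heavy atoms (typically N/O with H).
#' @param acceptors Atom predicate for acceptor atoms (typically N/O).
#' @param d_max Maximum H...acceptor distance, Angstrom.
#' @param angle_min Minimum donor-H...acceptor angle, degrees.
#' @return Tibble: `frame`, `n_hbonds`.
#' @export
hbond_count <- function(traj, donors, acceptors, d_max = 3.5,
                        angle_min = 120) {
  don_q <- enquo(donors); acc_q <- enquo(acceptors)
  atoms <- dplyr::filter(traj, .data$frame == min(.data$frame))
  don_ids <- atoms$atom[eval_tidy(don_q, data = atoms)]
  acc_ids <- atoms$atom[eval_tidy(acc_q, data = atoms)]
  if (length(don_ids) == 0) abort("Empty donor selection.")
  if (length(acc_ids) == 0) abort("Empty acceptor selection.")
  h_ids <- atoms$atom[toupper(atoms$element) == "H"]
  if (length(h_ids) == 0) {
    abort("Trajectory has no hydrogen atoms; cannot evaluate donors.")
  }
  # attach hydrogens to donors by covalent distance in the first frame
  xyz1 <- cbind(atoms$x, atoms$y, atoms$z)
  rownames(xyz1) <- atoms$atom
  pairs <- list()
  orphan <- character()
  for (d_id in don_ids) {
    dv <- xyz1[as.character(d_id), ]
    hd <- sqrt(colSums((t(xyz1[as.character(h_ids), , drop = FALSE]) - dv)^2))
    att <- h_ids[hd <= 1.25]
    if (length(att) == 0) {
      orphan <- c(orphan, as.character(d_id))
      next
    }
    for (h in att) pairs[[length(pairs) + 1]] <- c(d_id, h)
  }
  if (length(orphan) > 0) {
    abort(sprintf("Donor atom(s) without an attached hydrogen: %s",
                  paste(orphan, collapse = ", ")))
  }
  all_ids <- sort(atoms$atom)
  coords <- frame_coords(traj, all_ids)
  idx <- function(id) match(id, all_ids)
  frames <- as.numeric(names(coords))
  counts <- vapply(coords, function(m) {
    seen <- character()
    n <- 0L
    for (p in pairs) {
      dpos <- m[idx(p[1]), ]; hpos <- m[idx(p[2]), ]
      for (a_id in acc_ids) {
        if (a_id == p[1] || a_id == p[2]) next
        key <- paste(p[1], p[2], a_id)
        if (key %in% seen) next
        apos <- m[idx(a_id), ]
        ha <- apos - hpos
        dist_ha <- sqrt(sum(ha^2))
        if (dist_ha > d_max) next
        hd <- dpos - hpos
        cosang <- sum(hd * ha) / (sqrt(sum(hd^2)) * dist_ha)
        ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
        if (ang >= angle_min) {
          n <- n + 1L
          seen <- c(seen, key)
        }
      }
    }
    n
  }, integer(1))
  tibble(frame = frames, n_hbonds = unname(counts))
}

#' All standard trajectory observables in one call
#'
#' Convenience wrapper producing a tidy table of RMSD, radius of gyration and
#' (optionally) per-residue RMSF for one trajectory.
#'
#' @inheritParams rmsd_series
#' @return Tibble: `frame`, `metric`, `value`.
#' @export
traj_metrics <- function(traj, selection = NULL, reference = NULL) {
  sel <- enquo(selection)
  rmsd <- rmsd_series(traj, !!sel, reference = reference)
  rg <- radius_of_gyration(traj, !!sel)
  dplyr::bind_rows(
    dplyr::transmute(rmsd, frame = .data$frame, metric = "rmsd",
                     value = .data$rmsd),
    dplyr::transmute(rg, frame = .data$frame, metric = "rg",
                     value = .data$rg)
  )
}
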