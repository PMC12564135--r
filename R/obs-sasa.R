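# Deterministic, nearly uniform unit-sphere point set (golden-section
# spiral), so SASA values are exactly reproducible without a seed.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' For each atom of the subset, the fraction of `n_sphere_points`
#' deterministic unit-sphere points, placed at radius \eqn{r_i + r_p}, that
#' fall inside no neighbouring inflated sphere, times
#' \eqn{4\pi (r_i+r_p)^2}. Occluders default to all non-water atoms, so
#' the result is the area accessible to water probes.
#'
#' @param xyz Frame coordinates (`n x 3`, Angstrom).
#' @param top The matching [topology()]; every subset atom needs a radius.
#' @param subset [selection()] (or string) of atoms to report.
#' @param probe_radius Probe radius, Angstrom (water: 1.4).
#' @param n_sphere_points Number of test points per atom (default 960).
#' @param occluders Selection of atoms that can bury surface; default
#'   everything except water.
#' @return A tibble with `atom_id`, `mol_id`, `area` (Angstrom^2).
#' @export
sasa <- function(xyz, top, subset = selection(), probe_radius = 1.4,
                 n_sphere_points = 960, occluders = NULL) {
  sub <- select_atoms(top, subset, xyz)
  if (!length(sub)) abort("empty subset selection")
  occ <- if (is.null(occluders)) {
    which(top$species != "water")
  } else {
    select_atoms(top, occluders, xyz)
  }
  r <- top$radius
  if (anyNA(r[sub]) || anyNA(r[occ])) abort("atom without a radius")
  pts <- sphere_points(n_sphere_points)
  areas <- vapply(sub, function(i) {
    ri <- r[i] + probe_radius
    nb <- occ[occ != i]
    if (length(nb)) {
      d <- sqrt(colSums((t(xyz[nb, , drop = FALSE]) - xyz[i, ])^2))
      nb <- nb[d < ri + r[nb] + probe_radius]
    }
    p <- sweep(pts * ri, 2, xyz[i, ], "+")
    free <- rep(TRUE, nrow(p))
    for (j in nb) {
      rj <- r[j] + probe_radius
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      free <- free & dj2 >= rj^2
      if (!any(free)) break
    }
    4 * pi * ri^2 * mean(free)
  }, numeric(1))
  tibble::tibble(atom_id = sub, mol_id = top$mol_id[sub], area = areas)
}

#' Per-molecule SASA
#'
#' Sums [sasa()] areas per molecule over the frames of a trajectory.
#'
#' @inheritParams sasa
#' @param traj An [trajectory()].
#' @return A tibble with `frame`, `time`, `mol_id`, `area`.
#' @export
sasa_per_molecule <- function(traj, top, subset = selection(),
                              probe_radius = 1.4, n_sphere_points = 960,
                              occluders = NULL) {
  purrr::map2_dfr(traj$frame, traj$coords, function(fr, xyz) {
    a <- sasa(xyz, top, subset, probe_radius, n_sphere_points, occluders)
    a <- dplyr::summarise(dplyr::group_by(a, .data$mol_id),
                          area = sum(.data$area), .groups = "drop")
    tibble::tibble(frame = fr, time = traj$time[traj$frame == fr],
                   mol_id = a$mol_id, area = a$area)
  })
}
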