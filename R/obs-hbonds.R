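#' Geometric hydrogen-bond criteria
#'
#' A donor-acceptor pair is hydrogen bonded when the donor-acceptor
#' distance is at most `d_DA_max` and the H-donor-acceptor angle at most
#' `angle_HDA_max`. The criterion is configurable and is always recorded in
#' analysis metadata, since absolute bond counts depend on it; the default
#' (3.5 Angstrom, 30 degrees) is a widely used trajectory-analysis choice.
#'
#' @param d_DA_max Donor-acceptor distance cutoff, Angstrom.
#' @param angle_HDA_max H-donor-acceptor angle cutoff, degrees (0, 90].
#' @return An object of class `fr_hbond_criteria`.
#' @export
hbond_criteria <- function(d_DA_max = 3.5, angle_HDA_max = 30) {
  stopifnot_scalar_pos(d_DA_max, "d_DA_max")
  if (angle_HDA_max <= 0 || angle_HDA_max > 90) {
    abort("angle_HDA_max must be in (0, 90] degrees")
  }
  structure(list(d_DA_max = d_DA_max, angle_HDA_max = angle_HDA_max),
            class = "fr_hbond_criteria")
}

hbond_one_way <- function(xyz, top, criteria, donors, acceptors, box,
                          intermolecular) {
  donors <- donors[top$donor[donors]]
  acceptors <- acceptors[top$acceptor[acceptors]]
  if (!length(donors) || !length(acceptors)) {
    return(NULL)
  }
  bad <- donors[lengths(top$h_ids[donors]) == 0]
  if (length(bad)) {
    abort(paste0("donor without bonded hydrogen: atom ",
                 paste(bad, collapse = ", ")))
  }
  d_mat <- pair_dist_xy(xyz[donors, , drop = FALSE],
                        xyz[acceptors, , drop = FALSE], box)
  hit <- which(d_mat <= criteria$d_DA_max, arr.ind = TRUE)
  if (!nrow(hit)) {
    return(NULL)
  }
  rows <- list()
  for (k in seq_len(nrow(hit))) {
    di <- donors[hit[k, 1]]
    ai <- acceptors[hit[k, 2]]
    if (di == ai) next
    if (intermolecular && top$mol_id[di] == top$mol_id[ai]) next
    v_da <- min_image_xy(matrix(xyz[ai, ] - xyz[di, ], 1), box)[1, ]
    for (hi in top$h_ids[[di]]) {
      v_dh <- xyz[hi, ] - xyz[di, ]
      cosang <- sum(v_da * v_dh) / (vnorm(v_da) * vnorm(v_dh))
      ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      if (ang <= criteria$angle_HDA_max) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          donor_id = di, hydrogen_id = hi, acceptor_id = ai,
          d_DA = d_mat[hit[k, 1], hit[k, 2]], angle_HDA = ang
        )
      }
    }
  }
  if (length(rows)) dplyr::bind_rows(rows) else NULL
}

#' Detect hydrogen bonds in a frame
#'
#' Enumerates hydrogen-bond events between two atom groups under geometric
#' criteria, in both donor directions (donor in A with acceptor in B, and
#' donor in B with acceptor in A), with minimum-image wrapping in x/y.
#'
#' @param xyz Frame coordinates (`n x 3`).
#' @param top The matching [topology()] (donor/acceptor flags and bonded
#'   hydrogens are required).
#' @param criteria An [hbond_criteria()].
#' @param groupA,groupB [selection()]s (or strings) for the two groups.
#' @param box Box edge lengths (or `NULL`).
#' @param intermolecular Keep only events whose donor and acceptor belong
#'   to different molecules (default `TRUE`).
#' @return A tibble of events: `donor_id`, `hydrogen_id`, `acceptor_id`,
#'   `d_DA`, `angle_HDA`.
#' @export
detect_hbonds <- function(xyz, top, criteria = hbond_criteria(),
                          groupA, groupB, box = NULL,
                          intermolecular = TRUE) {
  ia <- select_atoms(top, groupA, xyz)
  ib <- select_atoms(top, groupB, xyz)
  out <- dplyr::bind_rows(
    hbond_one_way(xyz, top, criteria, ia, ib, box, intermolecular),
    hbond_one_way(xyz, top, criteria, ib, ia, box, intermolecular)
  )
  if (!nrow(out)) {
    out <- tibble::tibble(donor_id = integer(), hydrogen_id = integer(),
                          acceptor_id = integer(), d_DA = numeric(),
                          angle_HDA = numeric())
  }
  dplyr::distinct(out)
}

#' Hydrogen-bond counts per frame
#'
#' @inheritParams detect_hbonds
#' @param traj An [trajectory()].
#' @return A tibble with `frame`, `time`, `n_hbonds`.
#' @export
hbond_timeseries <- function(traj, top, criteria = hbond_criteria(),
                             groupA, groupB, intermolecular = TRUE) {
  purrr::pmap_dfr(list(traj$frame, traj$time, traj$coords, traj$box),
    function(fr, tm, xyz, bx) {
      ev <- detect_hbonds(xyz, top, criteria, groupA, groupB,
                          box = if (anyNA(bx)) NULL else bx,
                          intermolecular = intermolecular)
      tibble::tibble(frame = fr, time = tm, n_hbonds = nrow(ev))
    })
}

#' Normalized distribution of hydrogen-bond counts
#'
#' @param counts Integer counts per frame (e.g. `hbond_timeseries()$n_hbonds`).
#' @return An `fr_profile` over integer counts (bin width 1) in
#'   `probability_density` mode.
#' @export
hbond_distribution <- function(counts) {
  if (!length(counts)) abort("empty count series")
  k <- 0:max(counts)
  p <- vapply(k, function(x) mean(counts == x), numeric(1))
  new_profile(z = k, value = p, width = 1, mode = "probability_density",
              n_frames = length(counts))
}

#' Joint histogram of hydrogen-bond count against z-distance
#'
#' Bins frames by a z-distance series (aligned with the trajectory frames)
#' and the per-frame hydrogen-bond count between the solute and a partner
#' group, normalized to total mass 1; the count marginal of the result is
#' exactly the distance distribution of `z_series` on the same bins.
#'
#' @inheritParams hbond_timeseries
#' @param solute,partners Selections for the two groups.
#' @param z_series Numeric z-distance per frame (same length as the
#'   trajectory).
#' @param z_bin_width Bin width on the z axis, Angstrom.
#' @return An `fr_density2d` (tibble `x` = z bin centre, `y` = count,
#'   `density`).
#' @export
hbond_vs_z <- function(traj, top, criteria = hbond_criteria(), solute,
                       partners, z_series, z_bin_width = 1) {
  if (length(z_series) != nrow(traj)) {
    abort("z_series length must match the number of frames")
  }
  ts <- hbond_timeseries(traj, top, criteria, solute, partners)
  conformation_map(z_series, ts$n_hbonds, x_bin_width = z_bin_width,
                   y_bin_width = 1)
}
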