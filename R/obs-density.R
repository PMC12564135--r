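#' Number density profile across the bilayer
#'
#' Histogram of selected-atom positions along z relative to the per-frame
#' bilayer centre, averaged over frames. In `counts` mode the values are
#' mean atoms per bin and satisfy the sum rule
#' \eqn{\sum_i \rho_i \, A \, \Delta z = N} exactly (with
#' \eqn{\rho_i = \mathrm{counts}_i/(A\,\Delta z)}); in `number_density`
#' mode they are atoms per Angstrom^3. Optional symmetrization averages the
#' bins at +-z.
#'
#' @param traj An [trajectory()] with box metadata (required for
#'   `number_density`).
#' @param top The matching [topology()].
#' @param sel An [selection()] or selection string.
#' @param bin_width Bin width, Angstrom (default 0.5).
#' @param mode `"number_density"` or `"counts"`.
#' @param symmetrize Average bins at +-z (off by default).
#' @param z_range Optional fixed range for the profile axis; defaults to
#'   `c(-Lz/2, Lz/2)` (or the data range without a box).
#' @return An `fr_profile`; its `n_frames` attribute records the average.
#' @export
number_density_profile <- function(traj, top, sel, bin_width = 0.5,
                                   mode = c("number_density", "counts"),
                                   symmetrize = FALSE, z_range = NULL) {
  mode <- match.arg(mode)
  if (!nrow(traj)) abort("empty trajectory")
  box <- traj$box[[1]]
  if (anyNA(box) && (mode == "number_density" || is.null(z_range))) {
    if (mode == "number_density") abort("number_density mode requires a box")
  }
  if (is.null(z_range)) {
    z_range <- if (!anyNA(box)) c(-box[3] / 2, box[3] / 2) else {
      zr <- range(unlist(purrr::map2(traj$coords, seq_len(nrow(traj)),
        function(xyz, i) {
          idx <- select_atoms(top, sel, xyz)
          xyz[idx, 3] - bilayer_center(top, xyz)
        })))
      zr
    }
  }
  breaks <- uniform_breaks(z_range, bin_width)
  nb <- length(breaks) - 1
  acc <- numeric(nb)
  for (i in seq_len(nrow(traj))) {
    xyz <- traj$coords[[i]]
    idx <- select_atoms(top, sel, xyz)
    zc <- xyz[idx, 3] - bilayer_center(top, xyz)
    acc <- acc + bin_counts(zc, breaks)
  }
  counts <- acc / nrow(traj)
  value <- if (mode == "counts") {
    counts
  } else {
    area <- mean(vapply(traj$box, function(b) b[1] * b[2], numeric(1)))
    counts / (area * bin_width)
  }
  centers <- breaks[-length(breaks)] + bin_width / 2
  if (symmetrize) {
    mirror <- vapply(centers, function(z) which.min(abs(centers + z)),
                     integer(1))
    value <- (value + value[mirror]) / 2
  }
  new_profile(z = centers, value = value, width = bin_width, mode = mode,
              n_frames = nrow(traj))
}
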