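#' Centre-of-mass z-distance series
#'
#' For each frame, the mass-weighted centre-of-mass z of the solute
#' selection minus the mean z of the reference selection (typically the
#' upper-leaflet headgroup nitrogens). The sign convention is negative when
#' the solute lies below the reference plane, i.e. inserted into the
#' bilayer, and positive toward the water.
#'
#' @param traj An [trajectory()].
#' @param top The matching [topology()].
#' @param solute,reference [selection()]s (or selection strings); both must
#'   be non-empty in every frame.
#' @param per_molecule If `TRUE`, one centre of mass (and one row) per
#'   solute molecule per frame; otherwise the selection is one body.
#' @return A tibble with columns `frame`, `time`, (`mol_id`,) `dz`
#'   (Angstrom).
#' @export
com_z_distance <- function(traj, top, solute, reference,
                           per_molecule = FALSE) {
  purrr::map2_dfr(traj$frame, traj$coords, function(fr, xyz) {
    si <- select_atoms(top, solute, xyz)
    ri <- select_atoms(top, reference, xyz)
    if (!length(si)) abort(sprintf("empty solute selection at frame %d", fr))
    if (!length(ri)) {
      abort(sprintf("empty reference selection at frame %d", fr))
    }
    ref_z <- mean(xyz[ri, 3])
    if (per_molecule) {
      d <- tibble::tibble(mol_id = top$mol_id[si], m = top$mass[si],
                          z = xyz[si, 3])
      d <- dplyr::summarise(dplyr::group_by(d, .data$mol_id),
                            dz = sum(.data$m * .data$z) / sum(.data$m) - ref_z,
                            .groups = "drop")
      tibble::tibble(frame = fr, time = traj$time[traj$frame == fr],
                     mol_id = d$mol_id, dz = d$dz)
    } else {
      com <- sum(top$mass[si] * xyz[si, 3]) / sum(top$mass[si])
      tibble::tibble(frame = fr, time = traj$time[traj$frame == fr],
                     dz = com - ref_z)
    }
  })
}

#' Centered running average
#'
#' Centered moving mean with edges truncated to the available support, as
#' used to smooth centre-of-mass traces (the study smooths over 10 ns
#' windows). Output length equals input length; an even `window` is
#' enlarged by one to centre it.
#'
#' @param x Numeric series.
#' @param window Window length in samples (>= 1).
#' @return Numeric series of the same length.
#' @export
running_average <- function(x, window) {
  n <- length(x)
  if (!is_count(window) || window < 1) {
    abort("window must be a positive integer")
  }
  if (window > n) abort("window exceeds series length")
  if (window %% 2 == 0) window <- window + 1
  h <- (window - 1) / 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Distance distribution
#'
#' Normalized (probability-density) histogram of a distance series, e.g.
#' the solute-to-headgroup z-distances of [com_z_distance()]. The density
#' integrates to exactly 1 over the bins.
#'
#' @param x Numeric series (at least one sample).
#' @param bin_width Bin width in the series' units (default 1 Angstrom).
#' @param range Optional range to bin over; defaults to the data range.
#' @return An `fr_profile` in `probability_density` mode.
#' @export
distance_distribution <- function(x, bin_width = 1, range = NULL) {
  if (!length(x)) abort("empty series")
  stopifnot_scalar_pos(bin_width, "bin_width")
  breaks <- uniform_breaks(range %||% range(x), bin_width)
  cnt <- bin_counts(x, breaks)
  dens <- cnt / (sum(cnt) * bin_width)
  new_profile(z = breaks[-length(breaks)] + bin_width / 2, value = dens,
              width = bin_width, mode = "probability_density")
}
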