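#' End-to-end distance series
#'
#' Euclidean distance between two named terminal atoms of a molecule over
#' the frames of a trajectory (the study measures O4-O9 for the monomer
#' units). A compact-versus-extended two-state solute shows up as two modes
#' in this series.
#'
#' @param traj An [trajectory()].
#' @param top The matching [topology()].
#' @param mol_ids Molecule ids to measure; defaults to all non-lipid,
#'   non-water molecules.
#' @param terminal_pair Two atom names, default `c("O4", "O9")`.
#' @return A tibble with `frame`, `time`, `mol_id`, `r_ee` (Angstrom).
#' @export
end_to_end <- function(traj, top, mol_ids = NULL,
                       terminal_pair = c("O4", "O9")) {
  mol_ids <- mol_ids %||%
    unique(top$mol_id[!top$species %in% c("lipid", "water")])
  idx <- lapply(mol_ids, function(m) {
    rows <- which(top$mol_id == m & top$name %in% terminal_pair)
    if (length(rows) != 2) {
      abort(sprintf("molecule %d lacks terminal atoms %s", m,
                    paste(terminal_pair, collapse = "/")))
    }
    rows
  })
  purrr::map2_dfr(traj$frame, traj$coords, function(fr, xyz) {
    tibble::tibble(
      frame = fr, time = traj$time[traj$frame == fr], mol_id = mol_ids,
      r_ee = vapply(idx, function(p) vnorm(xyz[p[1], ] - xyz[p[2], ]),
                    numeric(1))
    )
  })
}

# Signed dihedral of points p1-p2-p3-p4, IUPAC convention: cis = 0, trans =
# 180, sign by the standard right-hand rule, range (-180, 180].
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / vnorm(b2)
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Dihedral angle series
#'
#' Signed torsion of four named atoms of a molecule in the IUPAC
#' convention (trans = 180 degrees, cis = 0, range (-180, 180]).
#'
#' @inheritParams end_to_end
#' @param quad Four atom names defining the torsion.
#' @return A tibble with `frame`, `time`, `mol_id`, `phi` (degrees).
#' @export
dihedral <- function(traj, top, mol_ids = NULL, quad) {
  if (length(quad) != 4) abort("quad must name four atoms")
  mol_ids <- mol_ids %||%
    unique(top$mol_id[!top$species %in% c("lipid", "water")])
  idx <- lapply(mol_ids, function(m) {
    rows <- match(quad, ifelse(top$mol_id == m, top$name, NA))
    if (anyNA(rows)) {
      abort(sprintf("molecule %d lacks dihedral atoms %s", m,
                    paste(quad, collapse = "-")))
    }
    rows
  })
  purrr::map2_dfr(traj$frame, traj$coords, function(fr, xyz) {
    tibble::tibble(
      frame = fr, time = traj$time[traj$frame == fr], mol_id = mol_ids,
      phi = vapply(idx, function(q) {
        dihedral_angle(xyz[q[1], ], xyz[q[2], ], xyz[q[3], ], xyz[q[4], ])
      }, numeric(1))
    )
  })
}

#' Two-dimensional conformation map
#'
#' Normalized joint frequency of two aligned series (e.g. end-to-end
#' distance against z-distance, or dihedral against dihedral). Frequencies
#' sum to exactly 1.
#'
#' @param x,y Aligned numeric series.
#' @param x_bin_width,y_bin_width Bin widths in the series' units.
#' @param x_range,y_range Optional fixed ranges.
#' @return An `fr_density2d` tibble with columns `x`, `y` (bin centres) and
#'   `density` (normalized frequency); attributes carry the bin widths.
#' @export
conformation_map <- function(x, y, x_bin_width = 1, y_bin_width = 1,
                             x_range = NULL, y_range = NULL) {
  if (length(x) != length(y)) abort("x and y must be aligned")
  if (!length(x)) abort("empty series")
  bx <- uniform_breaks(x_range %||% range(x), x_bin_width)
  by <- uniform_breaks(y_range %||% range(y), y_bin_width)
  ix <- findInterval(x, bx, rightmost.closed = TRUE)
  iy <- findInterval(y, by, rightmost.closed = TRUE)
  keep <- ix >= 1 & ix <= length(bx) - 1 & iy >= 1 & iy <= length(by) - 1
  tab <- table(factor(ix[keep], levels = seq_len(length(bx) - 1)),
               factor(iy[keep], levels = seq_len(length(by) - 1)))
  grid <- expand.grid(xi = seq_len(length(bx) - 1),
                      yi = seq_len(length(by) - 1))
  out <- tibble::tibble(
    x = bx[grid$xi] + x_bin_width / 2,
    y = by[grid$yi] + y_bin_width / 2,
    density = as.numeric(tab[cbind(grid$xi, grid$yi)]) / sum(tab)
  )
  structure(out, class = c("fr_density2d", class(out)),
            x_bin_width = x_bin_width, y_bin_width = y_bin_width)
}
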