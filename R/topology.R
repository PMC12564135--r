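#' Build an atom topology
#'
#' A topology is a tibble with one row per atom and the static metadata
#' every analysis needs: identity, residue, element, van der Waals radius,
#' hydrogen-bond donor/acceptor capability, bonded hydrogens and molecule
#' grouping. Species labels (`"guaiacyl"`, `"syringyl"`, `"derivative"`,
#' `"lipid"`, `"water"`, ...) group molecules for per-species statistics.
#'
#' @param atoms A data frame with columns `atom_id` (unique, dense 1..n),
#'   `name`, `resname`, `resid`, `element`, `radius` (Angstrom), `mass`
#'   (defaults to 1 for toy pseudo-atoms), `donor`, `acceptor` (logical),
#'   `h_ids` (list column of bonded hydrogen atom ids; required non-empty
#'   for donors), `mol_id` (integer molecule id), `species`.
#' @return A tibble of class `fr_topology`.
#' @export
topology <- function(atoms) {
  atoms <- tibble::as_tibble(atoms)
  need <- c("atom_id", "name", "resname", "resid", "element", "radius",
            "mol_id", "species")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) abort(paste0("topology missing columns: ",
                                 paste(miss, collapse = ", ")))
  if (!"mass" %in% names(atoms)) atoms$mass <- 1
  if (!"donor" %in% names(atoms)) atoms$donor <- FALSE
  if (!"acceptor" %in% names(atoms)) atoms$acceptor <- FALSE
  if (!"h_ids" %in% names(atoms)) atoms$h_ids <- rep(list(integer()),
                                                     nrow(atoms))
  n <- nrow(atoms)
  if (n == 0) abort("topology must contain at least one atom")
  if (anyDuplicated(atoms$atom_id)) abort("duplicate atom ids")
  if (!identical(sort(as.integer(atoms$atom_id)), seq_len(n))) {
    abort("atom ids must be dense 1..n")
  }
  bad <- atoms$donor & lengths(atoms$h_ids) == 0
  if (any(bad)) {
    abort(paste0("donor atoms without bonded hydrogens: ",
                 paste(atoms$atom_id[bad], collapse = ", ")))
  }
  structure(atoms, class = c("fr_topology", class(atoms)))
}

n_atoms <- function(top) nrow(top)

#' Assemble a trajectory
#'
#' A trajectory holds per-frame coordinates for a fixed topology: a tibble
#' with one row per frame, the frame time (ns), an `n_atoms x 3` coordinate
#' matrix (Angstrom) in a list column, and the orthorhombic box edge lengths
#' (or `NA` when absent).
#'
#' @param coords List of `n_atoms x 3` numeric matrices, one per frame.
#' @param times Frame times in ns (nondecreasing); defaults to `0, 1, 2, ...`.
#' @param box A length-3 numeric `(Lx, Ly, Lz)` shared by all frames, a list
#'   of per-frame boxes, or `NULL` for no box.
#' @return A tibble of class `fr_trajectory` with columns `frame`, `time`,
#'   `coords`, `box`.
#' @export
trajectory <- function(coords, times = NULL, box = NULL) {
  if (is.matrix(coords)) coords <- list(coords)
  nf <- length(coords)
  na <- if (nf > 0) nrow(coords[[1]]) else 0L
  for (i in seq_len(nf)) {
    if (!is.matrix(coords[[i]]) || ncol(coords[[i]]) != 3) {
      abort(sprintf("frame %d: coordinates must be an n x 3 matrix", i))
    }
    if (nrow(coords[[i]]) != na) {
      abort(sprintf("frame %d: atom count %d differs from frame 1 (%d)",
                    i, nrow(coords[[i]]), na))
    }
  }
  times <- times %||% (seq_len(nf) - 1)
  if (nf > 0 && any(diff(times) < 0)) abort("frame times must be nondecreasing")
  if (is.null(box)) {
    box <- rep(list(rep(NA_real_, 3)), nf)
  } else if (is.numeric(box)) {
    if (length(box) != 3 || any(box <= 0, na.rm = TRUE)) {
      abort("box must be three positive edge lengths")
    }
    box <- rep(list(as.numeric(box)), nf)
  } else if (length(box) != nf) {
    abort("per-frame box list length must match frame count")
  }
  out <- tibble::tibble(frame = seq_len(nf), time = as.numeric(times),
                        coords = coords, box = box)
  structure(out, class = c("fr_trajectory", class(out)), n_atoms = na)
}

traj_n_atoms <- function(traj) attr(traj, "n_atoms")

#' Long (tidy) view of a trajectory
#'
#' @param traj An [trajectory()].
#' @param top Optional [topology()] whose per-atom columns are joined in.
#' @return A tibble with one row per atom per frame (`frame`, `time`,
#'   `atom_id`, `x`, `y`, `z`, plus topology columns if given).
#' @export
traj_tidy <- function(traj, top = NULL) {
  out <- purrr::map2_dfr(traj$frame, traj$coords, function(fr, xyz) {
    tibble::tibble(frame = fr, atom_id = seq_len(nrow(xyz)),
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  })
  out <- dplyr::left_join(out, dplyr::select(tibble::as_tibble(traj),
                                             "frame", "time"), by = "frame")
  out <- dplyr::relocate(out, "time", .after = "frame")
  if (!is.null(top)) {
    out <- dplyr::left_join(out, tibble::as_tibble(top), by = "atom_id")
  }
  out
}

# Per-frame bilayer centre: mean z of all lipid-species atoms.
bilayer_center <- function(top, xyz) {
  idx <- which(top$species == "lipid")
  if (!length(idx)) {
    return(0)
  }
  mean(xyz[idx, 3])
}
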