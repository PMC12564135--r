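#' Default van der Waals radii
#'
#' Bondi-style radii per element (Angstrom), used when building topologies
#' from PDB files. Override by passing a modified table to [read_pdb()];
#' SASA values depend on it, so analyses record the table in their metadata.
#'
#' @return A named numeric vector.
#' @export
default_radii <- function() {
  c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, P = 1.8, S = 1.8,
    F = 1.47, CL = 1.75, NA. = 2.27, BR = 1.85, X = 1.7)
}

element_from_name <- function(name) {
  two_letter <- c("CL", "NA", "BR", "MG", "FE", "ZN")
  vapply(name, function(nm) {
    s <- gsub("[^A-Za-z]", "", nm)
    if (nchar(s) == 0) {
      return("X")
    }
    s <- toupper(s)
    if (substr(s, 1, 2) %in% two_letter) {
      return(substr(s, 1, 2))
    }
    substr(s, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

lookup_radius <- function(element, table) {
  key <- ifelse(element == "NA", "NA.", element)
  r <- unname(table[key])
  r[is.na(r)] <- unname(table["X"])
  r
}

#' Read a PDB file
#'
#' Parses ATOM/HETATM records (wwPDB v3.3 columns) into a topology and a
#' single coordinate frame. Atom and residue names are preserved verbatim;
#' the element is taken from columns 77-78 when present and otherwise
#' inferred from the leading characters of the atom name; van der Waals
#' radii come from `radius_table`. A CRYST1 record supplies the box;
#' without one the frame's box is flagged absent.
#'
#' @param path Path to a PDB file.
#' @param radius_table Named element-to-radius table (Angstrom); see
#'   [default_radii()].
#' @return A list with `topology` (class `fr_topology`) and `trajectory`
#'   (a one-frame [trajectory()]).
#' @export
read_pdb <- function(path, radius_table = default_radii()) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  at <- which(rec %in% c("ATOM  ", "HETATM"))
  if (!length(at)) abort(sprintf("no ATOM/HETATM records in '%s'", path))
  box <- NULL
  cr <- which(rec == "CRYST1")
  if (length(cr)) {
    box <- as.numeric(c(substr(lines[cr[1]], 7, 15),
                        substr(lines[cr[1]], 16, 24),
                        substr(lines[cr[1]], 25, 33)))
  }
  f <- function(l, a, b) substr(l, a, b)
  parse_num <- function(s, line_no, col, what) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v))
    if (length(bad)) {
      abort(sprintf("malformed ATOM record at line %d, columns %s (%s)",
                    line_no[bad[1]], col, what))
    }
    v
  }
  l <- lines[at]
  serial <- parse_num(f(l, 7, 11), at, "7-11", "serial")
  if (anyDuplicated(serial)) {
    abort(sprintf("duplicate atom serial %d", serial[anyDuplicated(serial)]))
  }
  name <- trimws(f(l, 13, 16))
  resname <- trimws(f(l, 18, 21))
  resid <- parse_num(f(l, 23, 26), at, "23-26", "resSeq")
  x <- parse_num(f(l, 31, 38), at, "31-38", "x")
  y <- parse_num(f(l, 39, 46), at, "39-46", "y")
  z <- parse_num(f(l, 47, 54), at, "47-54", "z")
  element <- toupper(trimws(f(l, 77, 78)))
  element <- ifelse(element == "" | is.na(element),
                    element_from_name(name), element)
  top <- topology(tibble::tibble(
    atom_id = seq_along(at), name = name, resname = resname,
    resid = as.integer(resid), element = element,
    radius = lookup_radius(element, radius_table),
    mol_id = cumsum(c(1L, diff(as.integer(resid)) != 0L)),
    species = "unknown"
  ))
  traj <- trajectory(cbind(x, y, z), times = 0, box = box)
  list(topology = top, trajectory = traj)
}

#' Write a PDB file
#'
#' Writes a topology plus one coordinate frame as ATOM records (wwPDB v3.3
#' columns), with a CRYST1 record when the box is known. Atom names longer
#' than 4 characters are rejected.
#'
#' @param top A [topology()].
#' @param xyz `n x 3` coordinate matrix (Angstrom).
#' @param path Output path.
#' @param box Optional `(Lx, Ly, Lz)`.
#' @export
write_pdb <- function(top, xyz, path, box = NULL) {
  if (any(nchar(top$name) > 4)) abort("atom names longer than 4 characters")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(box) && !anyNA(box)) {
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       box[1], box[2], box[3], 90, 90, 90), con)
  }
  nm <- ifelse(nchar(top$name) < 4, paste0(" ", top$name), top$name)
  writeLines(sprintf(
    "ATOM  %5d %-4s %-4s%5d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    top$atom_id %% 100000L, nm, substr(top$resname, 1, 4),
    top$resid %% 10000L, xyz[, 1], xyz[, 2], xyz[, 3], top$element
  ), con)
  writeLines("END", con)
  invisible(path)
}

#' Read and write multi-frame XYZ trajectories
#'
#' The XYZ dialect used here stores, per frame, the atom count, a comment
#' line `time=<ns> box=<Lx> <Ly> <Lz>` (box optional), and one
#' `name x y z` line per atom with six decimals, so write-then-read is an
#' identity to 1e-6 Angstrom.
#'
#' @param path File path.
#' @param top The matching [topology()]; frame atom counts are validated
#'   against it and mismatches are reported with the frame index.
#' @return `read_xyz_trajectory()`: an [trajectory()] (zero frames for an
#'   empty file).
#' @export
read_xyz_trajectory <- function(path, top) {
  lines <- readLines(path)
  n <- n_atoms(top)
  coords <- list()
  times <- numeric()
  boxes <- list()
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) {
      i <- i + 1L
      next
    }
    frame <- frame + 1L
    cnt <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(cnt)) {
      abort(sprintf("frame %d: expected an atom count at line %d", frame, i))
    }
    if (cnt != n) {
      abort(sprintf("frame %d: atom count %d does not match topology (%d)",
                    frame, cnt, n))
    }
    if (i + 1L + cnt > length(lines)) {
      abort(sprintf("truncated final frame (frame %d)", frame))
    }
    cm <- lines[i + 1L]
    tm <- regmatches(cm, regexec("time= *([-0-9.eE+]+)", cm))[[1]]
    times <- c(times, if (length(tm) == 2) as.numeric(tm[2]) else frame - 1)
    bx <- regmatches(cm, regexec(
      "box= *([-0-9.eE+]+) +([-0-9.eE+]+) +([-0-9.eE+]+)", cm))[[1]]
    boxes[[frame]] <- if (length(bx) == 4) as.numeric(bx[2:4]) else
      rep(NA_real_, 3)
    body <- lines[(i + 2L):(i + 1L + cnt)]
    parts <- strsplit(trimws(body), "[[:space:]]+")
    bad <- which(lengths(parts) < 4)
    if (length(bad)) {
      abort(sprintf("frame %d: malformed coordinate line %d", frame,
                    i + 1L + bad[1]))
    }
    m <- matrix(as.numeric(unlist(lapply(parts, function(p) p[2:4]))),
                ncol = 3, byrow = TRUE)
    if (anyNA(m)) abort(sprintf("frame %d: non-numeric coordinates", frame))
    coords[[frame]] <- m
    i <- i + 2L + cnt
  }
  trajectory(coords, times = times, box = if (frame) boxes else NULL)
}

#' @rdname read_xyz_trajectory
#' @param traj An [trajectory()] to write.
#' @export
write_xyz_trajectory <- function(traj, top, path) {
  if (nrow(traj) > 0 && traj_n_atoms(traj) != n_atoms(top)) {
    abort("trajectory atom count does not match topology")
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(traj))) {
    xyz <- traj$coords[[i]]
    bx <- traj$box[[i]]
    cm <- sprintf("time=%.6f", traj$time[i])
    if (!anyNA(bx)) {
      cm <- paste0(cm, sprintf(" box=%.6f %.6f %.6f", bx[1], bx[2], bx[3]))
    }
    writeLines(as.character(nrow(xyz)), con)
    writeLines(cm, con)
    writeLines(sprintf("%-4s %14.6f %14.6f %14.6f", top$name,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

#' Read a DCD trajectory (optional, via bio3d)
#'
#' Thin wrapper over `bio3d::read.dcd()` mapping the result onto a
#' [trajectory()] for an existing topology. DCD support is read-only.
#'
#' @param path DCD file path.
#' @param top The matching [topology()].
#' @return An [trajectory()].
#' @export
read_dcd <- function(path, top) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("read_dcd requires the bio3d package")
  }
  m <- bio3d::read.dcd(path, verbose = FALSE)
  n <- n_atoms(top)
  if (ncol(m) != 3L * n) {
    abort(sprintf("DCD atom count %d does not match topology (%d)",
                  ncol(m) / 3L, n))
  }
  coords <- lapply(seq_len(nrow(m)), function(i) {
    matrix(m[i, ], ncol = 3, byrow = TRUE)
  })
  trajectory(coords)
}
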