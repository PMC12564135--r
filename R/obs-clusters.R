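# Minimal union-find for connected components.
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Cluster solute molecules at a distance cutoff
#'
#' Molecules are nodes; an edge joins two molecules when any interatomic
#' distance (minimum image in x/y) is at most `cutoff`; clusters are the
#' connected components. The per-species normalized count reported by
#' [cluster_timeseries()] is the number of clusters containing at least one
#' molecule of a species divided by the number of molecules of that
#' species, so 1 means fully dispersed and small values mean aggregated.
#'
#' @param xyz Frame coordinates (`n x 3`).
#' @param top The matching [topology()].
#' @param mol_ids Molecule ids to cluster (>= 1); defaults to all molecules
#'   whose species is neither `"lipid"` nor `"water"`.
#' @param cutoff Any-atom distance cutoff, Angstrom (default 3.5, the
#'   hydrogen-bond length scale).
#' @param box Box edge lengths (or `NULL`).
#' @return A tibble with `mol_id`, `species`, `cluster` (component label);
#'   attribute `cutoff`.
#' @export
count_clusters <- function(xyz, top, mol_ids = NULL, cutoff = 3.5,
                           box = NULL) {
  stopifnot_scalar_pos(cutoff, "cutoff")
  mol_ids <- mol_ids %||%
    unique(top$mol_id[!top$species %in% c("lipid", "water")])
  if (!length(mol_ids)) abort("need at least one solute molecule")
  n <- length(mol_ids)
  atoms_of <- lapply(mol_ids, function(m) which(top$mol_id == m))
  parent <- seq_len(n)
  for (i in seq_len(max(n - 1, 0))) {
    ai <- xyz[atoms_of[[i]], , drop = FALSE]
    for (j in (i + 1):n) {
      ri <- uf_find(parent, i)
      rj <- uf_find(parent, j)
      if (ri == rj) next
      aj <- xyz[atoms_of[[j]], , drop = FALSE]
      if (min(pair_dist_xy(ai, aj, box)) <= cutoff) {
        parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  labels <- match(roots, unique(roots))
  sp <- vapply(mol_ids, function(m) top$species[match(m, top$mol_id)],
               character(1))
  structure(
    tibble::tibble(mol_id = mol_ids, species = sp, cluster = labels),
    class = c("fr_clusters", class(tibble::tibble())),
    cutoff = cutoff
  )
}

#' Per-species normalized cluster counts over a trajectory
#'
#' @inheritParams count_clusters
#' @param traj An [trajectory()].
#' @return A tibble with `frame`, `time`, `species`, `n_clusters`,
#'   `n_molecules`, `normalized` (in (0, 1]).
#' @export
cluster_timeseries <- function(traj, top, mol_ids = NULL, cutoff = 3.5) {
  purrr::pmap_dfr(list(traj$frame, traj$time, traj$coords, traj$box),
    function(fr, tm, xyz, bx) {
      cl <- count_clusters(xyz, top, mol_ids, cutoff,
                           box = if (anyNA(bx)) NULL else bx)
      out <- dplyr::summarise(
        dplyr::group_by(cl, .data$species),
        n_clusters = dplyr::n_distinct(.data$cluster),
        n_molecules = dplyr::n(), .groups = "drop"
      )
      out$normalized <- out$n_clusters / out$n_molecules
      tibble::tibble(frame = fr, time = tm, species = out$species,
                     n_clusters = out$n_clusters,
                     n_molecules = out$n_molecules,
                     normalized = out$normalized)
    })
}
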