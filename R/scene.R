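#' Toy solute template
#'
#' A minimal pseudo-atom model of a lignin-derived solute: a short zig-zag
#' chain `O4-C1-...-Cn-O9` with a hydroxyl hydrogen on O4 (hydrogen-bond
#' donor) and acceptor oxygens at both ends. Two-state conformers are
#' realised by a torsion about the central C-C bond solved so that the
#' O4-O9 end-to-end distance hits the requested mode values: the study
#' solutes show a compact state near 5.5 Angstrom and an extended one near
#' 8 Angstrom.
#'
#' @param species Molecule label (`"guaiacyl"`, `"syringyl"`,
#'   `"derivative"`, ...); used only for grouping statistics.
#' @param conformer_modes Named numeric vector of target end-to-end
#'   distances (Angstrom).
#' @param weights Mixture weights of the modes (must sum to 1).
#' @param n_chain Number of chain carbons between the terminal oxygens.
#' @return An object of class `fr_solute_template` with the per-mode
#'   coordinate sets precomputed.
#' @export
solute_template <- function(species = "guaiacyl",
                            conformer_modes = c(compact = 5.5, extended = 8),
                            weights = c(0.5, 0.5),
                            n_chain = 6) {
  if (length(weights) != length(conformer_modes)) {
    abort("weights and conformer_modes must have equal length")
  }
  if (abs(sum(weights) - 1) > 1e-8) abort("mixture weights must sum to 1")
  if (n_chain < 4) abort("n_chain must be at least 4 for a torsion quad")
  n_at <- n_chain + 2L # O4, C1..Cn, O9
  zig <- 0.4
  e_max <- max(conformer_modes)
  # chain advance per bond so the planar trans geometry hits the largest mode
  dx <- sqrt(e_max^2 - (zig * ((n_at - 1) %% 2))^2) / (n_at - 1)
  base <- cbind((seq_len(n_at) - 1) * dx, 0, zig * ((seq_len(n_at) - 1) %% 2))
  names_heavy <- c("O4", paste0("C", seq_len(n_chain)), "O9")
  # conformers: in-plane hinge at the mid-chain atom (rotation of the distal
  # arm about the y-axis through the pivot), solved so the end-to-end
  # distance hits each requested mode; the molecule stays planar, so the
  # central torsion flips between the trans and cis orientations
  pivot <- (n_at + 1L) %/% 2L
  quad <- names_heavy[(pivot - 1L):(pivot + 2L)]
  rot_hinge <- function(xyz, theta) {
    ctr <- xyz[pivot, ]
    move <- seq(pivot + 1L, n_at)
    dx <- xyz[move, 1] - ctr[1]
    dz <- xyz[move, 3] - ctr[3]
    xyz[move, 1] <- ctr[1] + dx * cos(theta) - dz * sin(theta)
    xyz[move, 3] <- ctr[3] + dx * sin(theta) + dz * cos(theta)
    xyz
  }
  e2e <- function(theta) {
    xyz <- rot_hinge(base, theta)
    vnorm(xyz[n_at, ] - xyz[1, ])
  }
  mode_coords <- lapply(conformer_modes, function(target) {
    if (target > e2e(0) + 1e-9) {
      abort(sprintf("conformer mode %.2f exceeds the maximum end-to-end %.2f",
                    target, e2e(0)))
    }
    if (abs(target - e2e(0)) < 1e-9) {
      th <- 0
    } else {
      if (target < e2e(pi) - 1e-9) {
        abort(sprintf("conformer mode %.2f below the reachable minimum %.2f",
                      target, e2e(pi)))
      }
      th <- uniroot(function(t) e2e(t) - target, c(1e-9, pi - 1e-6),
                    tol = 1e-10)$root
    }
    xyz <- rot_hinge(base, th)
    # hydroxyl hydrogen on O4
    rbind(xyz, xyz[1, ] + c(-0.33, 0.9, 0))
  })
  atoms <- tibble::tibble(
    name = c(names_heavy, "HO4"),
    element = c("O", rep("C", n_chain), "O", "H"),
    radius = c(1.52, rep(1.7, n_chain), 1.52, 1.2),
    mass = c(16, rep(12, n_chain), 16, 1),
    donor = c(TRUE, rep(FALSE, n_chain + 2L)),
    acceptor = c(TRUE, rep(FALSE, n_chain), TRUE, FALSE)
  )
  structure(
    list(species = species, atoms = atoms, mode_coords = mode_coords,
         conformer_modes = conformer_modes, weights = weights,
         terminal_pair = c("O4", "O9"), dihedral_quad = quad,
         h_of_donor = c(O4 = "HO4")),
    class = "fr_solute_template"
  )
}

#' Specify a toy bilayer scene
#'
#' Describes a two-leaflet pseudo-lipid slab with water above and below and
#' an `m x m` lateral grid of solute molecules, mirroring the study systems
#' (800 lipids, 400 per leaflet; solutes on 3x3 or 5x5 grids; headgroup
#' nitrogen planes near +-20 Angstrom). Each pseudo-lipid is one headgroup
#' nitrogen (`NF`) plus four chain carbons pointing toward the bilayer
#' centre.
#'
#' @param n_lipids_per_leaflet Lipids per leaflet.
#' @param leaflet_z Height of the headgroup nitrogen planes (+-, Angstrom).
#' @param solute_grid Lateral grid dimension m (m^2 solutes).
#' @param template A [solute_template()].
#' @param box Optional `(Lx, Ly, Lz)`; by default sized from the lipid count
#'   at ~49 Angstrom^2 per lipid with 15 Angstrom water slabs.
#' @param lattice_jitter Gaussian jitter (sd, Angstrom) on lattice positions.
#' @param water_number_density Water pseudo-atom number density in the
#'   slabs beyond the headgroups, Angstrom^-3 (bulk water is ~0.0334).
#' @param solute_z Default solute centre-of-mass height(s) when no dynamics
#'   paths are supplied (recycled over solutes).
#' @param planted_clusters Optional list of integer vectors: groups of
#'   solute molecule indices to place within clustering contact.
#' @param planted_conformers Optional integer vector (one mode index per
#'   solute) forcing the conformer assignment; by default modes are drawn
#'   from the template mixture weights.
#' @param seed Integer seed (mandatory for reproducibility).
#' @return An object of class `fr_scene_spec`.
#' @export
scene_spec <- function(n_lipids_per_leaflet = 400, leaflet_z = 20,
                       solute_grid = 3, template = solute_template(),
                       box = NULL, lattice_jitter = 0.5,
                       water_number_density = 0.0334,
                       solute_z = NULL, planted_clusters = NULL,
                       planted_conformers = NULL, seed) {
  if (missing(seed)) abort("scene_spec requires an explicit seed")
  if (!is_count(n_lipids_per_leaflet) || n_lipids_per_leaflet < 1) {
    abort("n_lipids_per_leaflet must be a positive integer")
  }
  if (!is_count(solute_grid) || solute_grid < 1) {
    abort("solute_grid must be a positive integer")
  }
  stopifnot_scalar_pos(leaflet_z, "leaflet_z")
  if (water_number_density < 0) abort("water_number_density must be >= 0")
  if (water_number_density > 0.08) {
    abort("water_number_density infeasible (> 0.08 Angstrom^-3): box overfilled")
  }
  if (is.null(box)) {
    g <- ceiling(sqrt(n_lipids_per_leaflet))
    L <- g * 7
    box <- c(L, L, 2 * (leaflet_z + 15))
  }
  if (any(box <= 0)) abort("box edges must be positive")
  if (box[3] / 2 <= leaflet_z) abort("box too short for the leaflet height")
  structure(
    list(n_lipids_per_leaflet = as.integer(n_lipids_per_leaflet),
         leaflet_z = leaflet_z, solute_grid = as.integer(solute_grid),
         template = template, box = as.numeric(box),
         lattice_jitter = lattice_jitter,
         water_number_density = water_number_density,
         solute_z = solute_z, planted_clusters = planted_clusters,
         planted_conformers = planted_conformers, seed = as.integer(seed)),
    class = "fr_scene_spec"
  )
}

lipid_block <- function(spec, sign_z, first_atom, first_mol, first_res, rng) {
  n <- spec$n_lipids_per_leaflet
  g <- ceiling(sqrt(n))
  sp <- spec$box[1] / g
  idx <- seq_len(n) - 1L
  gx <- (idx %% g + 0.5) * sp
  gy <- (idx %/% g + 0.5) * sp
  chain_dz <- spec$leaflet_z / 5
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    jit <- rng(3)
    zs <- sign_z * (spec$leaflet_z - chain_dz * (0:4))
    rows[[i]] <- tibble::tibble(
      name = c("NF", paste0("C", 1:4)),
      element = c("N", rep("C", 4)),
      x = gx[i] + jit[1], y = gy[i] + jit[2],
      z = zs + c(jit[3], rng(4) * 0.3),
      resname = "CER", mol = first_mol + i - 1L, res = first_res + i - 1L
    )
  }
  dplyr::bind_rows(rows)
}

#' Build a toy bilayer scene
#'
#' Realises a [scene_spec()] as a concrete topology plus trajectory: two
#' pseudo-lipid leaflets, water slabs, and the solute grid. When Langevin
#' paths are supplied, the solute centre-of-mass z follows them frame by
#' frame (one path per solute, sampled at the path's recorded times);
#' otherwise a single frame is emitted. The builder is a pure function of
#' the spec and seed.
#'
#' @param spec A [scene_spec()].
#' @param solute_paths Optional list of [simulate_langevin_1d()] paths, one
#'   per solute molecule, all with the same length.
#' @return A list with elements `topology`, `trajectory` and `ground_truth`
#'   (planted conformer assignment, solute centre heights, planted
#'   clusters).
#' @export
build_bilayer_scene <- function(spec, solute_paths = NULL) {
  m2 <- spec$solute_grid^2
  tpl <- spec$template
  out <- with_seed(component_seed(spec$seed, "scene"), {
    rng <- function(n) stats::rnorm(n, sd = spec$lattice_jitter)
    up <- lipid_block(spec, +1, 1L, 1L, 1L, rng)
    lo <- lipid_block(spec, -1, 1L, spec$n_lipids_per_leaflet + 1L,
                      spec$n_lipids_per_leaflet + 1L, rng)
    lip <- dplyr::bind_rows(up, lo)
    n_lip_mol <- 2L * spec$n_lipids_per_leaflet

    # water slabs beyond the headgroups
    half <- spec$box[3] / 2
    slab_lo <- spec$leaflet_z + 1.5
    slab_hi <- half - 0.5
    vol <- spec$box[1] * spec$box[2] * max(slab_hi - slab_lo, 0)
    nw <- round(spec$water_number_density * vol)
    wat <- NULL
    if (nw > 0) {
      wat <- tibble::tibble(
        name = "OW", element = "O",
        x = runif(2 * nw) * spec$box[1], y = runif(2 * nw) * spec$box[2],
        z = c(runif(nw, slab_lo, slab_hi), -runif(nw, slab_lo, slab_hi)),
        resname = "TIP", mol = NA_integer_, res = NA_integer_
      )
    }

    # solute conformer assignment
    modes <- if (!is.null(spec$planted_conformers)) {
      if (length(spec$planted_conformers) != m2) {
        abort("planted_conformers must assign one mode per solute")
      }
      as.integer(spec$planted_conformers)
    } else {
      sample.int(length(tpl$weights), m2, replace = TRUE,
                 prob = tpl$weights)
    }

    # lateral placement: grid points, planted cluster members pulled together
    sp_s <- spec$box[1] / spec$solute_grid
    si <- seq_len(m2) - 1L
    sx <- (si %% spec$solute_grid + 0.5) * sp_s
    sy <- (si %/% spec$solute_grid + 0.5) * sp_s
    if (!is.null(spec$planted_clusters)) {
      for (grp in spec$planted_clusters) {
        anchor <- grp[1]
        for (k in seq_along(grp)[-1]) {
          ang <- 2 * pi * (k - 1) / length(grp)
          # 2 Angstrom centre offsets guarantee an any-atom contact below the
          # default 3.5 Angstrom cluster cutoff for this template
          sx[grp[k]] <- sx[anchor] + 2.0 * cos(ang)
          sy[grp[k]] <- sy[anchor] + 2.0 * sin(ang)
        }
      }
    }
    zdef <- spec$solute_z %||% (spec$leaflet_z + 4)
    zsol <- rep_len(zdef, m2)
    rot <- runif(m2, 0, 2 * pi)
    list(lip = lip, wat = wat, nw = nw, modes = modes, sx = sx, sy = sy,
         zsol = zsol, rot = rot, n_lip_mol = n_lip_mol)
  })

  # frame times / solute z series
  if (!is.null(solute_paths)) {
    if (length(solute_paths) != m2) {
      abort(sprintf("need one path per solute (%d), got %d", m2,
                    length(solute_paths)))
    }
    nf <- nrow(solute_paths[[1]])
    if (!all(vapply(solute_paths, nrow, 1L) == nf)) {
      abort("all solute paths must have the same length")
    }
    times <- solute_paths[[1]]$time
    zmat <- vapply(solute_paths, function(p) p$z, numeric(nf))
  } else {
    nf <- 1L
    times <- 0
    zmat <- matrix(out$zsol, nrow = 1)
  }

  # solute atoms (local coords per assigned conformer, rotated about z)
  n_tpl <- nrow(tpl$atoms)
  sol_rows <- vector("list", m2)
  sol_local <- vector("list", m2)
  w_com <- tpl$atoms$mass / sum(tpl$atoms$mass)
  for (i in seq_len(m2)) {
    xyz <- tpl$mode_coords[[out$modes[i]]]
    xyz <- sweep(xyz, 2, colSums(xyz * w_com)) # mass-weighted COM at origin
    th <- out$rot[i]
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    xyz <- xyz %*% t(R)
    sol_local[[i]] <- xyz
    sol_rows[[i]] <- tibble::tibble(
      name = tpl$atoms$name, element = tpl$atoms$element,
      resname = toupper(substr(tpl$species, 1, 3)),
      mol = NA_integer_, res = NA_integer_
    )
  }

  # assemble topology
  lip_at <- out$lip
  n_lip_at <- nrow(lip_at)
  nw2 <- if (is.null(out$wat)) 0L else nrow(out$wat)
  radius_of <- function(el) default_radii()[el]
  top_df <- tibble::tibble(
    atom_id = seq_len(n_lip_at + nw2 + m2 * n_tpl),
    name = c(lip_at$name, if (nw2) out$wat$name, unlist(lapply(
      sol_rows, function(r) r$name))),
    resname = c(lip_at$resname, if (nw2) out$wat$resname, unlist(lapply(
      sol_rows, function(r) r$resname))),
    element = c(lip_at$element, if (nw2) out$wat$element, unlist(lapply(
      sol_rows, function(r) r$element)))
  )
  n_lip_mol <- out$n_lip_mol
  top_df$resid <- c(lip_at$res,
                    if (nw2) n_lip_mol + seq_len(nw2),
                    rep(n_lip_mol + nw2 + seq_len(m2), each = n_tpl))
  top_df$mol_id <- top_df$resid
  top_df$species <- c(rep("lipid", n_lip_at), rep("water", nw2),
                      rep(tpl$species, m2 * n_tpl))
  top_df$radius <- unname(radius_of(top_df$element))
  top_df$mass <- rep(1, nrow(top_df))
  sol_off <- n_lip_at + nw2
  top_df$mass[sol_off + seq_len(m2 * n_tpl)] <- rep(tpl$atoms$mass, m2)
  top_df$donor <- FALSE
  top_df$acceptor <- FALSE
  top_df$h_ids <- rep(list(integer()), nrow(top_df))
  if (nw2) top_df$acceptor[n_lip_at + seq_len(nw2)] <- TRUE
  for (i in seq_len(m2)) {
    off <- sol_off + (i - 1L) * n_tpl
    top_df$donor[off + which(tpl$atoms$donor)] <- TRUE
    top_df$acceptor[off + which(tpl$atoms$acceptor)] <- TRUE
    h_row <- which(tpl$atoms$name == "HO4")
    d_row <- which(tpl$atoms$name == "O4")
    top_df$h_ids[[off + d_row]] <- as.integer(off + h_row)
  }
  top <- topology(top_df)

  # frames
  frames <- vector("list", nf)
  base_static <- rbind(
    as.matrix(out$lip[, c("x", "y", "z")]),
    if (nw2) as.matrix(out$wat[, c("x", "y", "z")])
  )
  for (f in seq_len(nf)) {
    sol_xyz <- do.call(rbind, lapply(seq_len(m2), function(i) {
      sweep(sol_local[[i]], 2, c(out$sx[i], out$sy[i], zmat[f, i]), "+")
    }))
    frames[[f]] <- unname(rbind(base_static, sol_xyz))
  }
  # solute-solute clash check (tolerance 0.8 Angstrom), first frame
  if (m2 > 1) {
    f1 <- frames[[1]]
    same_cluster <- function(a, b) {
      any(vapply(spec$planted_clusters %||% list(),
                 function(g) a %in% g && b %in% g, logical(1)))
    }
    for (i in seq_len(m2 - 1L)) {
      ai <- f1[sol_off + (i - 1L) * n_tpl + seq_len(n_tpl), , drop = FALSE]
      for (j in (i + 1L):m2) {
        if (same_cluster(i, j)) next # deliberate contact
        aj <- f1[sol_off + (j - 1L) * n_tpl + seq_len(n_tpl), , drop = FALSE]
        if (min(pair_dist_xy(ai, aj, spec$box)) < 0.8) {
          abort(sprintf("solute molecules %d and %d clash beyond tolerance",
                        i, j))
        }
      }
    }
  }
  traj <- trajectory(frames, times = times, box = spec$box)
  list(
    topology = top, trajectory = traj,
    ground_truth = list(
      conformers = out$modes,
      conformer_targets = tpl$conformer_modes[out$modes],
      solute_com_z = zmat,
      solute_mol_ids = n_lip_mol + nw2 + seq_len(m2),
      planted_clusters = spec$planted_clusters
    )
  )
}

#' Plant exact hydrogen-bond geometries
#'
#' Emits frames containing donor-hydrogen/acceptor triplets with the exact
#' requested donor-acceptor distances and H-D-A angles, so the number of
#' hydrogen bonds under any geometric criterion is known in advance. Each
#' pair is an isolated donor molecule (O + H) and acceptor molecule (O)
#' placed far from the other pairs.
#'
#' @param pairs A data frame with columns `d_DA` (Angstrom) and `angle_HDA`
#'   (degrees), one row per planted pair; or a list of such data frames
#'   (equal row counts) for a multi-frame schedule.
#' @param spacing Lateral spacing between planted pairs (Angstrom).
#' @return A list with `topology`, `trajectory` and `pairs` (the planted
#'   geometries, with donor/acceptor atom ids attached).
#' @export
plant_hbond_frames <- function(pairs, spacing = 15) {
  if (is.data.frame(pairs)) pairs <- list(pairs)
  np <- nrow(pairs[[1]])
  if (np == 0) abort("at least one pair must be requested")
  for (p in pairs) {
    if (!all(c("d_DA", "angle_HDA") %in% names(p))) {
      abort("pairs need columns d_DA and angle_HDA")
    }
    if (nrow(p) != np) abort("all frames must plant the same number of pairs")
    if (any(p$d_DA < 1.2)) {
      abort("requested donor-acceptor distance violates atom-clash tolerance")
    }
  }
  g <- ceiling(sqrt(np))
  px <- ((seq_len(np) - 1) %% g + 0.5) * spacing
  py <- ((seq_len(np) - 1) %/% g + 0.5) * spacing
  box <- c(g * spacing, g * spacing, 40)
  top_df <- tibble::tibble(
    atom_id = seq_len(3L * np),
    name = rep(c("OD", "HD", "OA"), np),
    resname = rep(c("DON", "DON", "ACC"), np),
    resid = rep(seq_len(2L * np), rep(c(2L, 1L), np)),
    element = rep(c("O", "H", "O"), np),
    radius = rep(c(1.52, 1.2, 1.52), np),
    mass = rep(c(16, 1, 16), np),
    donor = rep(c(TRUE, FALSE, FALSE), np),
    acceptor = rep(c(FALSE, FALSE, TRUE), np),
    h_ids = rep(list(integer()), 3L * np),
    mol_id = rep(seq_len(2L * np), rep(c(2L, 1L), np)),
    species = rep(c("donor", "donor", "acceptor"), np)
  )
  for (i in seq_len(np)) {
    top_df$h_ids[[(i - 1L) * 3L + 1L]] <- (i - 1L) * 3L + 2L
  }
  top <- topology(top_df)
  frames <- lapply(pairs, function(p) {
    xyz <- matrix(0, 3L * np, 3L)
    for (i in seq_len(np)) {
      o <- c(px[i], py[i], 0)
      a <- p$angle_HDA[i] * pi / 180
      xyz[(i - 1L) * 3L + 1L, ] <- o
      xyz[(i - 1L) * 3L + 2L, ] <- o + 0.96 * c(cos(a), sin(a), 0)
      xyz[(i - 1L) * 3L + 3L, ] <- o + c(p$d_DA[i], 0, 0)
    }
    xyz
  })
  traj <- trajectory(frames, box = box)
  planted <- dplyr::bind_rows(pairs, .id = "frame")
  planted$frame <- as.integer(planted$frame)
  planted$donor_id <- rep((seq_len(np) - 1L) * 3L + 1L, length(pairs))
  planted$acceptor_id <- rep((seq_len(np) - 1L) * 3L + 3L, length(pairs))
  list(topology = top, trajectory = traj, pairs = tibble::as_tibble(planted))
}

#' Solute-to-lipid molar ratio
#'
#' @param n_solute Number of solute molecules.
#' @param n_lipids Number of lipids.
#' @return A tibble with the rounded `1:N` label (`N = round(n_lipids /
#'   n_solute)`) and the exact fraction; the study systems give
#'   `9:800 ~ 1:89` and `25:800 = 1:32`.
#' @examples
#' compute_molar_ratio(9, 800)
#' @export
compute_molar_ratio <- function(n_solute, n_lipids) {
  if (!is_count(n_solute) || n_solute == 0) {
    abort("n_solute must be a positive count")
  }
  if (!is_count(n_lipids) || n_lipids == 0) {
    abort("n_lipids must be a positive count")
  }
  N <- round(n_lipids / n_solute)
  tibble::tibble(
    n_solute = as.integer(n_solute), n_lipids = as.integer(n_lipids),
    N = as.integer(N), label = paste0("1:", N),
    fraction = n_solute / n_lipids
  )
}
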