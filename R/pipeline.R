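#' Load and validate a run configuration
#'
#' Reads a YAML run configuration (or takes an equivalent named list),
#' validates it against the schema and materializes every default, so the
#' persisted copy written by [run_pipeline()] contains no implicit
#' settings. Schema violations report the offending field path.
#'
#' Top-level keys: `seed` (required integer), `out_dir` (required),
#' `scene` (passed to [scene_spec()]; `template` is a species name),
#' `dynamics` (`D`, `temperature`, `dt` or `NULL` for automatic),
#' `paths` (`n_steps`, `record_stride` for unbiased solute dynamics; or
#' `null` for a static scene), `observables` (character vector among
#' `density`, `com_z`, `sasa`, `hbonds`, `clusters`, `conformation`, plus
#' optional `criteria`/`bins` settings), and `pmf` (`potential` form +
#' params, `v`, `k_spring`, `z_start`, `z_end`, `n_pulls`, `grid_dz`,
#' `anchor`; or `null` to skip).
#'
#' @param config Path to a YAML file, or a named list.
#' @return A validated config list of class `fr_run_config` with all
#'   defaults filled in.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) abort("config must be a list or a YAML file path")
  need <- function(field) {
    if (is.null(config[[field]])) {
      abort(sprintf("config field '%s' is required", field))
    }
  }
  need("seed")
  need("out_dir")
  if (!is_count(config$seed)) abort("config field 'seed': must be an integer")
  sc <- config$scene %||% list()
  defaults_scene <- list(n_lipids_per_leaflet = 16, leaflet_z = 20,
                         solute_grid = 3, species = "guaiacyl",
                         lattice_jitter = 0.5, water_number_density = 0.02)
  for (k in names(defaults_scene)) sc[[k]] <- sc[[k]] %||% defaults_scene[[k]]
  unknown <- setdiff(names(sc), c(names(defaults_scene), "box", "solute_z"))
  if (length(unknown)) {
    abort(sprintf("config field 'scene.%s' is not recognised", unknown[1]))
  }
  dy <- config$dynamics %||% list()
  dy$D <- dy$D %||% 100
  dy$temperature <- dy$temperature %||% 300
  pa <- config$paths
  if (!is.null(pa)) {
    pa$n_steps <- pa$n_steps %||% 20000
    pa$record_stride <- pa$record_stride %||% 200
  }
  ob <- config$observables %||% list()
  ob$which <- ob$which %||% character()
  known_obs <- c("density", "com_z", "sasa", "hbonds", "clusters",
                 "conformation")
  bad <- setdiff(ob$which, known_obs)
  if (length(bad)) {
    abort(sprintf("config field 'observables.which': unknown observable '%s'",
                  bad[1]))
  }
  ob$hbond_d_max <- ob$hbond_d_max %||% 3.5
  ob$hbond_angle_max <- ob$hbond_angle_max %||% 30
  ob$cluster_cutoff <- ob$cluster_cutoff %||% 3.5
  ob$density_bin <- ob$density_bin %||% 0.5
  ob$distance_bin <- ob$distance_bin %||% 1.0
  pm <- config$pmf
  if (!is.null(pm)) {
    pm$potential <- pm$potential %||% list(form = "double_well",
                                           params = c(2.5, 3, 16))
    pm$v <- pm$v %||% 0.1
    pm$k_spring <- pm$k_spring %||% 10
    pm$z_start <- pm$z_start %||% 0
    pm$z_end <- pm$z_end %||% 19
    pm$n_pulls <- pm$n_pulls %||% 20
    pm$grid_dz <- pm$grid_dz %||% 0.5
    pm$anchor <- pm$anchor %||% pm$z_end
  }
  out <- list(seed = as.integer(config$seed), out_dir = config$out_dir,
              scene = sc, dynamics = dy, paths = pa, observables = ob,
              pmf = pm)
  structure(out, class = "fr_run_config")
}

# Hash of the scientific content of a config (the output location does not
# change what is computed, so it is excluded).
config_hash <- function(x) {
  x <- unclass(x)
  x$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  path
}

#' Run the generate-analyze-estimate pipeline
#'
#' Executes the configured stages in dependency order: scene generation
#' (PDB + XYZ + provenance sidecar), Langevin solute dynamics, the
#' requested observables (tidy CSV + JSON metadata sidecars each), steered
#' pulls and the forward-reverse PMF. Stages whose inputs (config section +
#' seed) are unchanged since a previous run in the same directory are
#' skipped based on recorded checksums. Returns (and writes) a manifest
#' listing every produced file with its checksum.
#'
#' @param config A [run_config()] (or path / list accepted by it).
#' @return The manifest, invisibly also written to
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "fr_run_config")) config else run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_err <- function(stage, e) {
    abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
  }
  prev <- NULL
  mf_path <- file.path(cfg$out_dir, "manifest.json")
  if (file.exists(mf_path)) {
    prev <- tryCatch(jsonlite::read_json(mf_path), error = function(e) NULL)
  }
  stage_hash <- function(section) config_hash(list(cfg$seed, section))
  stage_fresh <- function(stage, section, files) {
    if (is.null(prev) || is.null(prev$stages[[stage]])) {
      return(FALSE)
    }
    rec <- prev$stages[[stage]]
    if (!identical(rec$hash, stage_hash(section))) {
      return(FALSE)
    }
    all(file.exists(file.path(cfg$out_dir, unlist(files))))
  }
  files <- list()
  stages <- list()
  log_msg <- function(...) message(sprintf(...))

  # --- scene stage ---------------------------------------------------
  scene_files <- c("scene.pdb", "scene.xyz", "scene_provenance.json")
  tpl <- solute_template(species = cfg$scene$species)
  spec <- scene_spec(
    n_lipids_per_leaflet = cfg$scene$n_lipids_per_leaflet,
    leaflet_z = cfg$scene$leaflet_z, solute_grid = cfg$scene$solute_grid,
    template = tpl, box = cfg$scene$box,
    lattice_jitter = cfg$scene$lattice_jitter,
    water_number_density = cfg$scene$water_number_density,
    solute_z = cfg$scene$solute_z, seed = cfg$seed
  )
  dyn <- NULL
  paths <- NULL
  scene <- tryCatch({
    pot_surface <- potential("flat", 0,
                             domain = c(cfg$scene$leaflet_z + 1,
                                        spec$box[3] / 2 - 1))
    dt <- cfg$dynamics$dt %||% suggest_dt(pot_surface, cfg$dynamics$D,
                                          cfg$dynamics$temperature)
    dyn <- langevin_params(cfg$dynamics$D, cfg$dynamics$temperature, dt)
    if (!is.null(cfg$paths)) {
      m2 <- spec$solute_grid^2
      paths <- lapply(seq_len(m2), function(i) {
        simulate_langevin_1d(pot_surface, dyn, cfg$paths$n_steps,
                             z0 = cfg$scene$leaflet_z + 4,
                             seed = cfg$seed + i,
                             record_stride = cfg$paths$record_stride)
      })
    }
    build_bilayer_scene(spec, solute_paths = paths)
  }, error = function(e) stage_err("scene", e))
  if (!stage_fresh("scene", cfg$scene, scene_files)) {
    tryCatch({
      write_pdb(scene$topology, scene$trajectory$coords[[1]],
                file.path(cfg$out_dir, "scene.pdb"), box = spec$box)
      write_xyz_trajectory(scene$trajectory, scene$topology,
                           file.path(cfg$out_dir, "scene.xyz"))
      write_sidecar(file.path(cfg$out_dir, "scene_provenance.json"), list(
        config_hash = config_hash(cfg), seed = cfg$seed,
        scene_seed = component_seed(cfg$seed, "scene"),
        dynamics_seed = component_seed(cfg$seed, "dynamics"),
        n_solutes = spec$solute_grid^2,
        molar_ratio = compute_molar_ratio(
          spec$solute_grid^2, 2L * spec$n_lipids_per_leaflet)$label
      ))
    }, error = function(e) stage_err("scene", e))
    log_msg("stage scene: wrote %d files", length(scene_files))
  } else {
    log_msg("stage scene: up to date, skipped")
  }
  files <- c(files, scene_files)
  stages$scene <- list(hash = stage_hash(cfg$scene))

  # --- observables ---------------------------------------------------
  obs_section <- c(cfg$observables, cfg$scene, cfg$paths)
  top <- scene$topology
  traj <- scene$trajectory
  for (obs in cfg$observables$which) {
    fcsv <- paste0("obs_", obs, ".csv")
    fjson <- paste0("obs_", obs, ".json")
    if (stage_fresh(paste0("obs_", obs), obs_section, list(fcsv, fjson))) {
      log_msg("stage obs_%s: up to date, skipped", obs)
    } else {
      tryCatch({
        meta <- list(observable = obs, seed = cfg$seed,
                     units = list(length = "Angstrom", time = "ns"))
        sol_sel <- selection(species = tpl$species)
        tab <- switch(obs,
          density = {
            meta$bin_width <- cfg$observables$density_bin
            meta$selection <- "name:NF"
            number_density_profile(traj, top, selection(name = "NF"),
                                   bin_width = cfg$observables$density_bin)
          },
          com_z = {
            meta$reference <- "name:NF leaflet:upper"
            com_z_distance(traj, top, sol_sel,
                           selection(name = "NF", leaflet = "upper"),
                           per_molecule = TRUE)
          },
          sasa = {
            meta$probe_radius <- 1.4
            meta$n_sphere_points <- 960
            meta$radius_table <- as.list(default_radii())
            sasa_per_molecule(traj, top, sol_sel)
          },
          hbonds = {
            meta$criteria <- list(d_DA_max = cfg$observables$hbond_d_max,
                                  angle_HDA_max =
                                    cfg$observables$hbond_angle_max)
            hbond_timeseries(traj, top,
                             hbond_criteria(cfg$observables$hbond_d_max,
                                            cfg$observables$hbond_angle_max),
                             sol_sel, selection(species = "water"))
          },
          clusters = {
            meta$cutoff <- cfg$observables$cluster_cutoff
            cluster_timeseries(traj, top,
                               cutoff = cfg$observables$cluster_cutoff)
          },
          conformation = {
            meta$terminal_pair <- tpl$terminal_pair
            end_to_end(traj, top, terminal_pair = tpl$terminal_pair)
          }
        )
        readr::write_csv(tibble::as_tibble(tab),
                         file.path(cfg$out_dir, fcsv))
        write_sidecar(file.path(cfg$out_dir, fjson), meta)
      }, error = function(e) stage_err(paste0("obs_", obs), e))
      log_msg("stage obs_%s: done", obs)
    }
    files <- c(files, fcsv, fjson)
    stages[[paste0("obs_", obs)]] <- list(hash = stage_hash(obs_section))
  }

  # --- pulls + pmf ---------------------------------------------------
  if (!is.null(cfg$pmf)) {
    pmf_files <- c("pmf.csv", "pmf.json", "work_traces.csv")
    if (stage_fresh("pmf", cfg$pmf, pmf_files)) {
      log_msg("stage pmf: up to date, skipped")
    } else {
      tryCatch({
        pm <- cfg$pmf
        pot <- potential(pm$potential$form,
                         if (is.list(pm$potential$params)) {
                           pm$potential$params
                         } else {
                           as.numeric(pm$potential$params)
                         },
                         domain = sort(c(pm$z_start, pm$z_end)))
        dtp <- suggest_dt(pot, cfg$dynamics$D, cfg$dynamics$temperature,
                          k_extra = pm$k_spring)
        dynp <- langevin_params(cfg$dynamics$D, cfg$dynamics$temperature,
                                dtp)
        traces <- fr_pull_set(pot, dynp, v = pm$v, k_spring = pm$k_spring,
                              z_start = pm$z_start, z_end = pm$z_end,
                              n_pulls = pm$n_pulls, seed = cfg$seed)
        grid <- seq(min(pm$z_start, pm$z_end), max(pm$z_start, pm$z_end),
                    by = pm$grid_dz)
        mw <- average_works(traces, grid)
        est <- estimate_pmf(mw, anchor = pm$anchor)
        wd <- estimate_dissipation(mw)
        dd <- estimate_friction_diffusion(wd, v = pm$v,
                                          temperature =
                                            cfg$dynamics$temperature)
        out_tab <- tibble::tibble(z = est$z, dU = est$dU, se = est$se,
                                  Wd = wd$Wd, D = dd$D)
        readr::write_csv(out_tab, file.path(cfg$out_dir, "pmf.csv"))
        long <- purrr::imap_dfr(traces, function(tr, i) {
          tibble::tibble(pull = i,
                         direction = attr(tr, "direction"),
                         t = tr$t, lambda = tr$lambda, z = tr$z,
                         f = tr$f, W = tr$W)
        })
        readr::write_csv(long, file.path(cfg$out_dir, "work_traces.csv"))
        write_sidecar(file.path(cfg$out_dir, "pmf.json"), list(
          potential = pm$potential, v = pm$v, k_spring = pm$k_spring,
          interval = c(pm$z_start, pm$z_end), n_pulls = pm$n_pulls,
          grid_dz = pm$grid_dz, anchor = pm$anchor, seed = cfg$seed,
          pulls_seed = component_seed(cfg$seed, "pulls")
        ))
      }, error = function(e) stage_err("pmf", e))
      log_msg("stage pmf: done")
    }
    files <- c(files, pmf_files)
    stages$pmf <- list(hash = stage_hash(cfg$pmf))
  }

  # --- persisted config + manifest -----------------------------------
  cfg_path <- file.path(cfg$out_dir, "config_materialized.yaml")
  yaml::write_yaml(unclass(cfg), cfg_path)
  files <- c(files, "config_materialized.yaml")
  sums <- tools::md5sum(file.path(cfg$out_dir, unlist(files)))
  manifest <- list(
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    component_seeds = list(
      dynamics = component_seed(cfg$seed, "dynamics"),
      scene = component_seed(cfg$seed, "scene"),
      planting = component_seed(cfg$seed, "planting"),
      pulls = component_seed(cfg$seed, "pulls")
    ),
    files = purrr::map2(unlist(files), unname(sums),
                        function(f, s) list(path = f, md5 = s)),
    stages = stages,
    versions = list(package = as.character(utils::packageVersion("frpmf")),
                    R = R.version.string),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  write_sidecar(mf_path, manifest)
  invisible(manifest)
}

#' Simulate a matched set of forward and reverse pulls
#'
#' Convenience wrapper producing `n_pulls` forward traces (ascending from
#' `z_start` to `z_end`) and `n_pulls` reverse traces over the same
#' interval, with per-pull seeds derived from one study seed.
#'
#' @inheritParams pull_protocol
#' @param pot A [potential()].
#' @param dynamics [langevin_params()].
#' @param n_pulls Pulls per direction.
#' @param seed Study seed.
#' @return A list of [simulate_smd_pull()] traces (F first, then R).
#' @export
fr_pull_set <- function(pot, dynamics, v = 0.1, k_spring = 10, z_start = 0,
                        z_end = 19, n_pulls = 20, seed) {
  pf <- pull_protocol("F", v = v, k_spring = k_spring, z_start = z_start,
                      z_end = z_end)
  pr <- pull_protocol("R", v = v, k_spring = k_spring, z_start = z_end,
                      z_end = z_start)
  c(
    lapply(seq_len(n_pulls), function(i) {
      simulate_smd_pull(pot, dynamics, pf, seed = seed * 1000 + i)
    }),
    lapply(seq_len(n_pulls), function(i) {
      simulate_smd_pull(pot, dynamics, pr, seed = seed * 1000 + 500 + i)
    })
  )
}

#' Summarise a pipeline run
#'
#' Pure function of the manifest and the files it lists: per-species means
#' of hydrogen-bond counts, per-molecule SASA and normalized cluster
#' counts, plus PMF minima located by a local quadratic fit around the
#' grid minimum. Writes `report.csv` and `report.json` next to the
#' manifest.
#'
#' @param manifest A manifest list from [run_pipeline()], or the path to a
#'   `manifest.json`.
#' @param out_dir Directory holding the run outputs (defaults to the
#'   manifest's directory when a path is given).
#' @return A tibble with columns `quantity`, `group`, `value`; empty (with
#'   zero rows) for an empty manifest.
#' @export
report <- function(manifest, out_dir = NULL) {
  if (is.character(manifest)) {
    out_dir <- out_dir %||% dirname(manifest)
    manifest <- jsonlite::read_json(manifest)
  }
  if (is.null(out_dir)) abort("out_dir is required with an in-memory manifest")
  listed <- vapply(manifest$files %||% list(),
                   function(f) f$path, character(1))
  missing <- listed[!file.exists(file.path(out_dir, listed))]
  if (length(missing)) {
    abort(paste0("missing stage outputs: ", paste(missing, collapse = ", ")))
  }
  rows <- list()
  grab <- function(name) {
    if (name %in% listed) {
      readr::read_csv(file.path(out_dir, name), show_col_types = FALSE)
    }
  }
  hb <- grab("obs_hbonds.csv")
  if (!is.null(hb)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      quantity = "mean_hbonds_per_frame", group = "solute-water",
      value = mean(hb$n_hbonds)
    )
  }
  sa <- grab("obs_sasa.csv")
  if (!is.null(sa)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      quantity = "mean_sasa_per_molecule", group = "solute",
      value = mean(sa$area)
    )
  }
  cl <- grab("obs_clusters.csv")
  if (!is.null(cl)) {
    m <- dplyr::summarise(dplyr::group_by(cl, .data$species),
                          value = mean(.data$normalized), .groups = "drop")
    rows[[length(rows) + 1L]] <- tibble::tibble(
      quantity = "mean_normalized_clusters", group = m$species,
      value = m$value
    )
  }
  pm <- grab("pmf.csv")
  if (!is.null(pm)) {
    i <- which.min(pm$dU)
    sel <- max(1, i - 1):min(nrow(pm), i + 1)
    zmin <- if (length(sel) == 3) {
      fit <- stats::lm(dU ~ poly(z, 2, raw = TRUE), data = pm[sel, ])
      b <- stats::coef(fit)
      v <- -b[2] / (2 * b[3])
      if (is.finite(v) && v >= min(pm$z[sel]) && v <= max(pm$z[sel])) v else
        pm$z[i]
    } else {
      pm$z[i]
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      quantity = c("pmf_min_z", "pmf_min_dU"), group = "pmf",
      value = c(zmin, min(pm$dU))
    )
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(quantity = character(), group = character(),
                   value = numeric())
  readr::write_csv(out, file.path(out_dir, "report.csv"))
  jsonlite::write_json(out, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  out
}
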