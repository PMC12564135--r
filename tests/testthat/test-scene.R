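test_that("solute grids give the study molecule counts and molar ratios", {
  for (m in c(3, 5)) {
    spec <- scene_spec(n_lipids_per_leaflet = 9, solute_grid = m,
                       water_number_density = 0, box = c(60, 60, 70),
                       seed = 1)
    s <- build_bilayer_scene(spec)
    n_sol <- length(unique(s$topology$mol_id[
      s$topology$species == "guaiacyl"]))
    expect_equal(n_sol, m^2)
  }
  expect_equal(compute_molar_ratio(9, 800)$label, "1:89")
  expect_equal(compute_molar_ratio(25, 800)$label, "1:32")
  expect_equal(compute_molar_ratio(800, 800)$label, "1:1")
  expect_error(compute_molar_ratio(0, 800), "positive")
})

test_that("zero water density removes water without touching other counts", {
  base <- list(n_lipids_per_leaflet = 16, solute_grid = 3, seed = 7,
               box = c(50, 50, 70))
  dry <- build_bilayer_scene(do.call(scene_spec,
                                     c(base, water_number_density = 0)))
  wet <- build_bilayer_scene(do.call(scene_spec,
                                     c(base, water_number_density = 0.02)))
  expect_equal(sum(dry$topology$species == "water"), 0)
  expect_gt(sum(wet$topology$species == "water"), 0)
  for (sp in c("lipid", "guaiacyl")) {
    expect_equal(sum(dry$topology$species == sp),
                 sum(wet$topology$species == sp))
  }
})

test_that("scene builder is a pure function of spec and seed", {
  spec <- scene_spec(n_lipids_per_leaflet = 9, solute_grid = 2,
                     water_number_density = 0.01, seed = 33)
  a <- build_bilayer_scene(spec)
  b <- build_bilayer_scene(spec)
  expect_identical(a$trajectory$coords, b$trajectory$coords)
  expect_identical(as.data.frame(a$topology), as.data.frame(b$topology))
  spec2 <- scene_spec(n_lipids_per_leaflet = 9, solute_grid = 2,
                      water_number_density = 0.01, seed = 34)
  c <- build_bilayer_scene(spec2)
  expect_false(identical(a$trajectory$coords, c$trajectory$coords))
})

test_that("headgroup nitrogen planes sit at +-leaflet_z", {
  spec <- scene_spec(n_lipids_per_leaflet = 36, solute_grid = 2,
                     leaflet_z = 20, water_number_density = 0, seed = 5)
  s <- build_bilayer_scene(spec)
  xyz <- s$trajectory$coords[[1]]
  nf <- s$topology$name == "NF"
  up <- xyz[nf & xyz[, 3] > 0, 3]
  dn <- xyz[nf & xyz[, 3] < 0, 3]
  expect_equal(mean(up), 20, tolerance = 0.05 * 20)
  expect_equal(mean(dn), -20, tolerance = 0.05 * 20)
  expect_equal(length(up), 36)
  expect_equal(length(dn), 36)
})

test_that("solute centre-of-mass heights follow supplied Langevin paths", {
  pot <- potential("flat", 0, domain = c(22, 32))
  dyn <- langevin_params(50, 300, 1e-3)
  paths <- lapply(1:4, function(i) {
    simulate_langevin_1d(pot, dyn, 50, z0 = 26, seed = i,
                         record_stride = 10)
  })
  spec <- scene_spec(n_lipids_per_leaflet = 9, solute_grid = 2,
                     water_number_density = 0, box = c(60, 60, 70), seed = 2)
  s <- build_bilayer_scene(spec, solute_paths = paths)
  expect_equal(nrow(s$trajectory), nrow(paths[[1]]))
  top <- s$topology
  for (i in seq_along(paths)) {
    mol <- s$ground_truth$solute_mol_ids[i]
    rows <- which(top$mol_id == mol)
    com <- vapply(s$trajectory$coords, function(xyz) {
      sum(top$mass[rows] * xyz[rows, 3]) / sum(top$mass[rows])
    }, numeric(1))
    expect_equal(com, paths[[i]]$z, tolerance = 1e-9)
  }
})

test_that("planted conformers are realised to their exact targets", {
  tpl <- solute_template(conformer_modes = c(compact = 5.5, extended = 8),
                         weights = c(0.5, 0.5))
  spec <- scene_spec(n_lipids_per_leaflet = 9, solute_grid = 3,
                     water_number_density = 0, box = c(80, 80, 70),
                     template = tpl,
                     planted_conformers = c(1, 1, 1, 1, 2, 2, 2, 2, 2),
                     seed = 11)
  s <- build_bilayer_scene(spec)
  ee <- end_to_end(s$trajectory, s$topology)
  expect_equal(sort(ee$r_ee), sort(c(rep(5.5, 4), rep(8, 5))),
               tolerance = 1e-9)
})

test_that("planted hydrogen-bond geometries match their request exactly", {
  set.seed(41)
  req <- tibble::tibble(d_DA = runif(50, 2.4, 4.6),
                        angle_HDA = runif(50, 0, 60))
  ph <- plant_hbond_frames(req)
  xyz <- ph$trajectory$coords[[1]]
  for (i in seq_len(nrow(req))) {
    d <- ph$pairs$donor_id[i]
    a <- ph$pairs$acceptor_id[i]
    expect_equal(sqrt(sum((xyz[a, ] - xyz[d, ])^2)), req$d_DA[i],
                 tolerance = 1e-9)
    vda <- xyz[a, ] - xyz[d, ]
    vdh <- xyz[d + 1L, ] - xyz[d, ]
    ang <- acos(sum(vda * vdh) / sqrt(sum(vda^2) * sum(vdh^2))) * 180 / pi
    expect_equal(ang, req$angle_HDA[i], tolerance = 1e-6)
  }
  expect_error(plant_hbond_frames(tibble::tibble(d_DA = 0.5,
                                                 angle_HDA = 10)),
               "clash")
})

test_that("infeasible scenes are rejected", {
  expect_error(scene_spec(water_number_density = 0.2, seed = 1),
               "overfilled")
  expect_error(scene_spec(box = c(40, 40, 30), leaflet_z = 20, seed = 1),
               "too short")
  expect_error(scene_spec(seed = 1, solute_grid = 0), "positive")
})
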