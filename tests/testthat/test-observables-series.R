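test_that("com_z_distance does plain COM arithmetic with the stated sign", {
  # two-atom solute at z = 28/32 (COM 30), reference single atom at z = 20
  top <- topology(tibble::tibble(
    atom_id = 1:3, name = c("A1", "A2", "NF"), resname = "TOY",
    resid = c(1L, 1L, 2L), element = "C", radius = 1.7, mass = c(1, 1, 1),
    mol_id = c(1L, 1L, 2L), species = c("solute", "solute", "lipid")
  ))
  xyz <- cbind(0, 0, c(28, 32, 20))
  traj <- trajectory(xyz)
  dz <- com_z_distance(traj, top, selection(species = "solute"),
                       selection(name = "NF"))
  expect_equal(dz$dz, 10) # above the plane -> positive
  # solute below the reference plane is negative (inserted)
  xyz2 <- cbind(0, 0, c(12, 16, 20))
  dz2 <- com_z_distance(trajectory(xyz2), top,
                        selection(species = "solute"),
                        selection(name = "NF"))
  expect_equal(dz2$dz, -6)
  # identical single-atom selections give identically zero
  dz3 <- com_z_distance(traj, top, selection(name = "NF"),
                        selection(name = "NF"))
  expect_equal(dz3$dz, 0)
})

test_that("com_z_distance uses mass weighting and reports empty frames", {
  top <- topology(tibble::tibble(
    atom_id = 1:3, name = c("O1", "H1", "NF"), resname = "TOY",
    resid = c(1L, 1L, 2L), element = c("O", "H", "N"), radius = 1.5,
    mass = c(16, 1, 14), mol_id = c(1L, 1L, 2L),
    species = c("solute", "solute", "lipid")
  ))
  xyz <- cbind(0, 0, c(30, 13, 0))
  dz <- com_z_distance(trajectory(xyz), top, selection(species = "solute"),
                       selection(name = "NF"))
  expect_equal(dz$dz, (16 * 30 + 1 * 13) / 17)
  expect_error(
    com_z_distance(trajectory(xyz), top, selection(name = "NOPE2"),
                   selection(name = "NF")),
    "frame 1"
  ) |> suppressWarnings()
})

test_that("scripted solute paths are recovered as a COM distance series", {
  pot <- potential("flat", 0, domain = c(22, 34))
  dyn <- langevin_params(60, 300, 1e-3)
  paths <- lapply(1:4, function(i) {
    simulate_langevin_1d(pot, dyn, 200, z0 = 28, seed = 40 + i,
                         record_stride = 20)
  })
  spec <- scene_spec(n_lipids_per_leaflet = 9, solute_grid = 2,
                     lattice_jitter = 0, water_number_density = 0,
                     box = c(60, 60, 72), seed = 6)
  s <- build_bilayer_scene(spec, solute_paths = paths)
  mol <- s$ground_truth$solute_mol_ids[2]
  dz <- com_z_distance(s$trajectory, s$topology,
                       selection(species = "guaiacyl"),
                       selection(name = "NF", leaflet = "upper"),
                       per_molecule = TRUE)
  got <- dz$dz[dz$mol_id == mol]
  # equals the scripted path minus the constant nitrogen-plane height
  offset <- got - paths[[2]]$z
  expect_lt(diff(range(offset)), 1e-9)
  expect_equal(mean(offset), -20, tolerance = 0.01)
})

test_that("running averages match the direct windowed mean", {
  expect_equal(running_average(rep(3.5, 10), 5), rep(3.5, 10))
  x <- rnorm(50)
  expect_equal(running_average(x, 1), x)
  got <- running_average(x, 5)
  oracle <- vapply(seq_along(x), function(i) {
    mean(x[max(1, i - 2):min(50, i + 2)])
  }, numeric(1))
  expect_equal(got, oracle)
  expect_error(running_average(x, 51), "exceeds")
  expect_error(running_average(x, 0), "positive")
})

test_that("distance distributions are normalized probability densities", {
  # all samples equal: one occupied bin with density 1/width
  p1 <- distance_distribution(rep(4.2, 100), bin_width = 0.5)
  expect_equal(sum(p1$value > 0), 1)
  expect_equal(max(p1$value), 1 / 0.5)
  # two planted peaks appear as the two modes
  x <- c(rnorm(4000, 5.5, 0.1), rnorm(2000, 8, 0.1))
  p2 <- distance_distribution(x, bin_width = 0.5)
  expect_equal(sum(p2$value) * profile_bin_width(p2), 1, tolerance = 1e-9)
  top2 <- p2$z[order(p2$value, decreasing = TRUE)][1:2]
  expect_equal(sort(top2), c(5.5, 8), tolerance = 0.5)
  # uniform samples give a flat profile within multinomial error
  # (edge bins only half-covered by the data range are excluded)
  set.seed(2)
  u <- runif(20000, 0, 10)
  p3 <- distance_distribution(u, bin_width = 1, range = c(0, 10))
  inner <- p3$z > 0.5 & p3$z < 9.5
  expect_lt(max(abs(p3$value[inner] - 0.1)), 5 * sqrt(0.1 * 0.9 / 20000))
  expect_error(distance_distribution(numeric()), "empty")
})
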