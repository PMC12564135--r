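quad_topology <- function() {
  topology(tibble::tibble(
    atom_id = 1:4, name = c("O4", "C1", "C2", "O9"), resname = "TOY",
    resid = 1L, element = c("O", "C", "C", "O"), radius = 1.5,
    mol_id = 1L, species = "solute"
  ))
}

test_that("end-to-end distance is plain Euclidean geometry", {
  top <- quad_topology()
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 4, 0))
  ee <- end_to_end(trajectory(xyz), top, terminal_pair = c("O4", "O9"))
  expect_equal(ee$r_ee, 5) # 3-4-5 triangle
  expect_error(end_to_end(trajectory(xyz), top,
                          terminal_pair = c("O4", "O8")), "lacks")
})

test_that("trans and cis quads give the defining dihedral values", {
  top <- quad_topology()
  trans <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
  expect_equal(dihedral(trajectory(trans), top,
                        quad = c("O4", "C1", "C2", "O9"))$phi, 180)
  cis <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(dihedral(trajectory(cis), top,
                        quad = c("O4", "C1", "C2", "O9"))$phi, 0)
  # right-handed sign convention
  plus <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 0, 1))
  expect_equal(abs(dihedral(trajectory(plus), top,
                            quad = c("O4", "C1", "C2", "O9"))$phi), 90)
})

test_that("rigid motions leave end-to-end and dihedral invariant", {
  set.seed(77)
  top <- quad_topology()
  xyz <- matrix(rnorm(12, sd = 2), 4, 3)
  th <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
              c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  moved <- xyz %*% t(Rx %*% Rz) + matrix(c(5, -3, 11), 4, 3, byrow = TRUE)
  tr1 <- trajectory(xyz)
  tr2 <- trajectory(moved)
  q <- c("O4", "C1", "C2", "O9")
  expect_equal(end_to_end(tr2, top)$r_ee, end_to_end(tr1, top)$r_ee,
               tolerance = 1e-9)
  expect_equal(dihedral(tr2, top, quad = q)$phi,
               dihedral(tr1, top, quad = q)$phi, tolerance = 1e-9)
})

test_that("conformation maps are normalized and recover planted modes", {
  set.seed(4)
  x <- c(rnorm(3000, 5.5, 0.15), rnorm(3000, 8, 0.15))
  y <- c(rnorm(3000, 2, 0.5), rnorm(3000, 6, 0.5))
  cm <- conformation_map(x, y, x_bin_width = 0.5, y_bin_width = 1)
  expect_equal(sum(cm$density), 1, tolerance = 1e-12)
  top2 <- cm[order(cm$density, decreasing = TRUE)[1:2], ]
  expect_equal(sort(top2$x), c(5.5, 8), tolerance = 0.5)
  expect_error(conformation_map(1:3, 1:4), "aligned")
})

test_that("a planted two-state solute mixture shows both end-to-end modes", {
  tpl <- solute_template(conformer_modes = c(compact = 5.5, extended = 8),
                         weights = c(0.5, 0.5))
  spec <- scene_spec(n_lipids_per_leaflet = 16, solute_grid = 5,
                     water_number_density = 0, box = c(120, 120, 70),
                     template = tpl, seed = 23)
  s <- build_bilayer_scene(spec)
  ee <- end_to_end(s$trajectory, s$topology)
  dz <- com_z_distance(s$trajectory, s$topology,
                       selection(species = "guaiacyl"),
                       selection(name = "NF", leaflet = "upper"),
                       per_molecule = TRUE)
  cm <- conformation_map(ee$r_ee, dz$dz, x_bin_width = 0.5, y_bin_width = 1)
  marg <- dplyr::summarise(dplyr::group_by(cm, x),
                           density = sum(density), .groups = "drop")
  occupied <- marg$x[marg$density > 0]
  # modes land within one bin of the planted 5.5 / 8 Angstrom states
  expect_true(any(abs(occupied - 5.5) <= 0.5))
  expect_true(any(abs(occupied - 8) <= 0.5))
  expect_equal(length(occupied), 2)
})

test_that("hbond-count against z marginalizes to the distance distribution", {
  frames <- list(
    tibble::tibble(d_DA = c(2.8, 3.0), angle_HDA = c(5, 5)),
    tibble::tibble(d_DA = c(2.8, 4.5), angle_HDA = c(5, 5)),
    tibble::tibble(d_DA = c(2.8, 4.5), angle_HDA = c(5, 5)),
    tibble::tibble(d_DA = c(4.5, 4.5), angle_HDA = c(5, 5))
  )
  ph <- plant_hbond_frames(frames)
  z <- c(2.2, 5.1, 5.3, 9.4)
  jm <- hbond_vs_z(ph$trajectory, ph$topology, hbond_criteria(3.5, 30),
                   selection(species = "donor"),
                   selection(species = "acceptor"),
                   z_series = z, z_bin_width = 2)
  expect_equal(sum(jm$density), 1, tolerance = 1e-12)
  # single pinned z with constant bonds occupies a single cell
  jm2 <- hbond_vs_z(ph$trajectory[1, ], ph$topology,
                    hbond_criteria(3.5, 30), selection(species = "donor"),
                    selection(species = "acceptor"), z_series = 3,
                    z_bin_width = 2)
  expect_equal(sum(jm2$density > 0), 1)
  # marginal over counts equals the z histogram
  marg <- dplyr::summarise(dplyr::group_by(jm, x), d = sum(density),
                           .groups = "drop")
  dd <- distance_distribution(z, bin_width = 2, range = range(z))
  dd_mass <- dd$value * profile_bin_width(dd)
  expect_equal(marg$d[marg$d > 0], dd_mass[dd_mass > 0])
  expect_error(
    hbond_vs_z(ph$trajectory, ph$topology, hbond_criteria(),
               selection(species = "donor"),
               selection(species = "acceptor"), z_series = c(1, 2)),
    "length"
  )
})
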