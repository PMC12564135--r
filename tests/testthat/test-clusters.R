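# molecules of a few atoms each, placed by centre
cluster_fixture <- function(centres, atoms_per_mol = 3, spread = 0.8,
                            seed = 1) {
  set.seed(seed)
  n_mol <- nrow(centres)
  n <- n_mol * atoms_per_mol
  top <- topology(tibble::tibble(
    atom_id = seq_len(n), name = paste0("X", seq_len(n)), resname = "TOY",
    resid = rep(seq_len(n_mol), each = atoms_per_mol), element = "C",
    radius = 1.7, mol_id = rep(seq_len(n_mol), each = atoms_per_mol),
    species = "solute"
  ))
  xyz <- do.call(rbind, lapply(seq_len(n_mol), function(i) {
    sweep(matrix(runif(atoms_per_mol * 3, -spread, spread),
                 atoms_per_mol, 3), 2, as.numeric(centres[i, ]), "+")
  }))
  list(topology = top, xyz = xyz)
}

test_that("mutually distant molecules form one cluster each", {
  centres <- expand.grid(x = c(0, 20, 40), y = c(0, 20, 40), z = 0)
  fx <- cluster_fixture(as.matrix(centres))
  cl <- count_clusters(fx$xyz, fx$topology, cutoff = 3.5)
  expect_equal(dplyr::n_distinct(cl$cluster), 9)
  expect_equal(glance(cl)$normalized, 1.0)
})

test_that("chains connect transitively: A-B and B-C within cutoff merge", {
  centres <- rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0))
  fx <- cluster_fixture(centres, spread = 0.3)
  cl <- count_clusters(fx$xyz, fx$topology, cutoff = 3.5)
  expect_equal(dplyr::n_distinct(cl$cluster), 1)
  # A and C alone are beyond any-atom contact
  d_ac <- min(dist(rbind(fx$xyz[1:3, ], fx$xyz[7:9, ])))
  cl2 <- count_clusters(fx$xyz[c(1:3, 7:9), ],
                        cluster_fixture(centres[c(1, 3), ],
                                        spread = 0.3)$topology,
                        cutoff = 3.5)
  expect_equal(dplyr::n_distinct(cl2$cluster), 2)
})

test_that("partitions equal the brute-force transitive closure", {
  for (seed in 1:20) {
    set.seed(seed)
    n_mol <- 25
    centres <- matrix(runif(n_mol * 3, 0, 30), n_mol, 3)
    fx <- cluster_fixture(centres, seed = seed + 100)
    box <- c(30, 30, 60)
    cutoff <- 4
    cl <- count_clusters(fx$xyz, fx$topology, cutoff = cutoff, box = box)
    # independent adjacency with explicit minimum image
    adj <- matrix(FALSE, n_mol, n_mol)
    for (i in 1:(n_mol - 1)) {
      for (j in (i + 1):n_mol) {
        ai <- fx$xyz[fx$topology$mol_id == i, , drop = FALSE]
        aj <- fx$xyz[fx$topology$mol_id == j, , drop = FALSE]
        dmin <- Inf
        for (r in seq_len(nrow(ai))) {
          d <- t(aj) - ai[r, ]
          d[1, ] <- d[1, ] - box[1] * round(d[1, ] / box[1])
          d[2, ] <- d[2, ] - box[2] * round(d[2, ] / box[2])
          dmin <- min(dmin, sqrt(colSums(d^2)))
        }
        adj[i, j] <- adj[j, i] <- dmin <= cutoff
      }
    }
    oracle <- brute_components(adj)
    # same partition up to label permutation
    expect_equal(dplyr::n_distinct(cl$cluster), dplyr::n_distinct(oracle))
    expect_true(all(tapply(cl$cluster, oracle,
                           function(v) length(unique(v))) == 1))
  }
})

test_that("per-species normalization counts clusters touching each species", {
  n <- 6
  top <- topology(tibble::tibble(
    atom_id = seq_len(n), name = paste0("X", seq_len(n)), resname = "TOY",
    resid = seq_len(n), element = "C", radius = 1.7,
    mol_id = seq_len(n),
    species = rep(c("guaiacyl", "syringyl"), each = 3)
  ))
  # guaiacyl: one pair + one singleton (2 clusters); syringyl: 3 singletons
  xyz <- rbind(c(0, 0, 0), c(2, 0, 0), c(30, 0, 0),
               c(0, 30, 0), c(15, 30, 0), c(30, 30, 0))
  ts <- cluster_timeseries(trajectory(xyz), top, cutoff = 3.5)
  g <- ts[ts$species == "guaiacyl", ]
  s <- ts[ts$species == "syringyl", ]
  expect_equal(g$n_clusters, 2L)
  expect_equal(g$normalized, 2 / 3)
  expect_equal(s$n_clusters, 3L)
  expect_equal(s$normalized, 1)
})

test_that("planted scene clusters are recovered with the matching cutoff", {
  spec <- scene_spec(n_lipids_per_leaflet = 9, solute_grid = 3,
                     water_number_density = 0, box = c(90, 90, 70),
                     planted_clusters = list(c(1, 2), c(4, 5, 6)),
                     seed = 19)
  s <- build_bilayer_scene(spec)
  cl <- count_clusters(s$trajectory$coords[[1]], s$topology, cutoff = 3.5,
                       box = spec$box)
  lab <- cl$cluster[match(s$ground_truth$solute_mol_ids, cl$mol_id)]
  expect_equal(lab[1], lab[2])
  expect_equal(lab[4], lab[5])
  expect_equal(lab[5], lab[6])
  expect_equal(dplyr::n_distinct(lab), 9 - 1 - 2) # 6 components
  expect_error(count_clusters(s$trajectory$coords[[1]], s$topology,
                              cutoff = -1), "positive")
})
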