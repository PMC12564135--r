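# Shared fixtures, built in code.

kB <- 1.9872041e-3

# Small topology of free-floating atoms with explicit flags.
toy_topology <- function(n, radius = 1.5, species = "solute",
                         mol_per_atom = TRUE) {
  topology(tibble::tibble(
    atom_id = seq_len(n), name = paste0("X", seq_len(n)),
    resname = "TOY", resid = seq_len(n), element = "C", radius = radius,
    mol_id = if (mol_per_atom) seq_len(n) else rep(1L, n),
    species = species
  ))
}

# A random frame of donors (O + bonded H) and acceptors for hydrogen-bond
# oracle tests: n_d donor molecules, n_a acceptor molecules in a box.
random_hbond_frame <- function(n_d, n_a, box, seed) {
  set.seed(seed)
  n_at <- 2L * n_d + n_a
  top <- topology(tibble::tibble(
    atom_id = seq_len(n_at),
    name = c(rep(c("OD", "HD"), n_d), rep("OA", n_a)),
    resname = c(rep("DON", 2L * n_d), rep("ACC", n_a)),
    resid = c(rep(seq_len(n_d), each = 2), n_d + seq_len(n_a)),
    element = c(rep(c("O", "H"), n_d), rep("O", n_a)),
    radius = 1.5,
    donor = c(rep(c(TRUE, FALSE), n_d), rep(FALSE, n_a)),
    acceptor = c(rep(FALSE, 2L * n_d), rep(TRUE, n_a)),
    h_ids = c(unlist(lapply(seq_len(n_d), function(i) {
      list(2L * i, integer())
    }), recursive = FALSE), rep(list(integer()), n_a)),
    mol_id = c(rep(seq_len(n_d), each = 2), n_d + seq_len(n_a)),
    species = c(rep("donor", 2L * n_d), rep("acceptor", n_a))
  ))
  xyz <- cbind(runif(n_at) * box[1], runif(n_at) * box[2],
               runif(n_at) * box[3])
  # keep each hydrogen bonded near its donor
  for (i in seq_len(n_d)) {
    d <- 2L * i - 1L
    xyz[d + 1L, ] <- xyz[d, ] + rnorm(3)
    xyz[d + 1L, ] <- xyz[d, ] +
      0.96 * (xyz[d + 1L, ] - xyz[d, ]) / sqrt(sum((xyz[d + 1L, ] -
                                                      xyz[d, ])^2))
  }
  list(topology = top, xyz = xyz, box = box)
}

# Brute-force O(n^2) hydrogen-bond count (independent oracle: direct pair
# scan with explicit minimum-image arithmetic, no shared helpers).
brute_hbond_count <- function(top, xyz, box, d_max, ang_max) {
  mi <- function(v) {
    v[1] <- v[1] - box[1] * round(v[1] / box[1])
    v[2] <- v[2] - box[2] * round(v[2] / box[2])
    v
  }
  count <- 0L
  for (d in which(top$donor)) {
    for (a in which(top$acceptor)) {
      if (top$mol_id[d] == top$mol_id[a]) next
      vda <- mi(xyz[a, ] - xyz[d, ])
      if (sqrt(sum(vda^2)) > d_max) next
      for (h in top$h_ids[[d]]) {
        vdh <- xyz[h, ] - xyz[d, ]
        ang <- acos(max(-1, min(1, sum(vda * vdh) /
                                  sqrt(sum(vda^2) * sum(vdh^2))))) * 180 / pi
        if (ang <= ang_max) count <- count + 1L
      }
    }
  }
  count
}

# Brute-force connected components by repeated transitive closure of the
# adjacency matrix (independent of the union-find implementation).
brute_components <- function(adj) {
  n <- nrow(adj)
  reach <- adj | diag(n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  labels <- integer(n)
  lab <- 0L
  for (i in seq_len(n)) {
    if (labels[i] == 0L) {
      lab <- lab + 1L
      labels[reach[i, ]] <- lab
    }
  }
  labels
}

# Analytic SASA of two equal spheres (radius r, probe p, centre distance d):
# each sphere loses a spherical cap of height h = R - d/2, R = r + p.
two_sphere_sasa <- function(r, p, d) {
  R <- r + p
  if (d >= 2 * R) {
    return(2 * 4 * pi * R^2)
  }
  h <- R - d / 2
  2 * (4 * pi * R^2 - 2 * pi * R * h)
}

expect_tibble <- function(x) {
  expect_s3_class(x, "tbl_df")
}
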