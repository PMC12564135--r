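# Internal helpers shared across modules.

# Deterministic per-component sub-seeds so that the dynamics, scene and
# planting stages each consume an independent, named random stream derived
# from one user-facing seed. Kept below 2^31 - 1.
component_seed <- function(seed, component) {
  offsets <- c(dynamics = 1L, scene = 2L, planting = 3L, pulls = 4L)
  if (!component %in% names(offsets)) {
    abort(paste0("unknown random-stream component: ", component))
  }
  as.integer((as.numeric(seed) * 48271 + offsets[[component]] * 1000003) %%
    2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Minimum-image displacement in x and y only (slab geometry: z non-periodic).
# a, b: matrices n x 3; box: length-3 box edge lengths or NULL for no
# periodicity. Returns the displacement matrix b - a, wrapped.
min_image_xy <- function(d, box) {
  if (is.null(box) || anyNA(box)) {
    return(d)
  }
  for (k in 1:2) {
    L <- box[[k]]
    d[, k] <- d[, k] - L * round(d[, k] / L)
  }
  d
}

# Pairwise distances between rows of a (n x 3) and b (m x 3), minimum image
# in x/y. Returns an n x m matrix.
pair_dist_xy <- function(a, b, box) {
  n <- nrow(a)
  m <- nrow(b)
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  dz <- outer(a[, 3], b[, 3], "-")
  if (!is.null(box) && !anyNA(box)) {
    dx <- dx - box[[1]] * round(dx / box[[1]])
    dy <- dy - box[[2]] * round(dy / box[[2]])
  }
  sqrt(dx^2 + dy^2 + dz^2)
}

vnorm <- function(v) sqrt(sum(v^2))

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

stopifnot_scalar_pos <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(paste0(what, " must be a positive finite scalar"))
  }
}
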