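#' Constant-velocity pull protocol
#'
#' Protocol for a steered pull: a harmonic guide of stiffness `k_spring`
#' moves at speed `v` from `z_start` to `z_end`, dragging the solute
#' coordinate and accumulating mechanical work. The study protocol pulls at
#' 0.1 Angstrom/ns between the bilayer centre (z = 0) and its surface
#' (z = 19 Angstrom); forward (`"F"`) and reverse (`"R"`) protocols must
#' traverse the same interval in opposite senses.
#'
#' @param direction `"F"` or `"R"` -- a label used by the forward-reverse
#'   estimator; it does not by itself fix the traversal sense.
#' @param v Guide speed, Angstrom/ns (> 0).
#' @param k_spring Guide spring constant, kcal/mol/Angstrom^2. The default
#'   10 keeps the guide-particle lag below ~0.5 Angstrom at
#'   v = 0.1 Angstrom/ns for D >= 50 Angstrom^2/ns.
#' @param z_start,z_end Guide start and end positions, Angstrom.
#' @param record_stride Record every this many integration steps; `NULL`
#'   picks a stride giving about 0.05 Angstrom of guide travel per record.
#' @return An object of class `fr_pull_protocol`.
#' @export
pull_protocol <- function(direction = c("F", "R"), v = 0.1, k_spring = 10,
                          z_start = 0, z_end = 19, record_stride = NULL) {
  direction <- match.arg(direction)
  stopifnot_scalar_pos(v, "v")
  stopifnot_scalar_pos(k_spring, "k_spring")
  if (z_start == z_end) abort("z_start and z_end must differ")
  if (!is.null(record_stride) &&
      (!is_count(record_stride) || record_stride < 1)) {
    abort("record_stride must be a positive integer")
  }
  structure(
    list(direction = direction, v = v, k_spring = k_spring,
         z_start = z_start, z_end = z_end, record_stride = record_stride),
    class = "fr_pull_protocol"
  )
}

#' Simulate a steered constant-velocity pull
#'
#' Overdamped dynamics in the time-dependent potential
#' \eqn{U(z) + \tfrac{k}{2}(z - \lambda(t))^2} with the guide
#' \eqn{\lambda(t)} moving at constant speed. The spring force
#' \eqn{f = k(\lambda - z)} and the cumulative work
#' \eqn{W(t) = \int f \, \dot\lambda \, dt} (trapezoidal rule, `W[1] = 0`)
#' are recorded along the way. Unless `z0` is given, the initial position is
#' drawn from the Boltzmann distribution of the potential restrained by the
#' guide spring at `z_start` (the stiff-spring-consistent start).
#'
#' @param pot A [potential()]; the guide path must stay inside its domain.
#' @param dynamics [langevin_params()].
#' @param pull A [pull_protocol()].
#' @param seed Integer seed; identical seeds give identical traces.
#' @param z0 Optional fixed initial position.
#' @return A tibble of class `fr_work_trace` with columns `t` (ns),
#'   `lambda`, `z` (Angstrom), `f` (kcal/mol/Angstrom), `W` (kcal/mol);
#'   attributes `protocol`, `seed`, `direction`.
#' @export
simulate_smd_pull <- function(pot, dynamics, pull, seed, z0 = NULL) {
  lo <- min(pull$z_start, pull$z_end)
  hi <- max(pull$z_start, pull$z_end)
  if (lo < pot$domain[1] || hi > pot$domain[2]) {
    abort("guide path exits the potential domain")
  }
  check_stability(pot, dynamics, k_extra = pull$k_spring)
  gr <- pot_grid(pot)
  v_signed <- sign(pull$z_end - pull$z_start) * pull$v
  n_steps <- ceiling(abs(pull$z_end - pull$z_start) / (pull$v * dynamics$dt))
  stride <- pull$record_stride %||%
    max(1L, floor(0.05 / (pull$v * dynamics$dt)))
  # The restrained particle must be free to fluctuate past the guide even
  # when the guide parks on a domain edge: the gradient is continued by its
  # edge value and the reflecting walls sit a few spring lengths outside
  # the domain, so the traversal endpoints carry no wall artefact.
  margin <- 4 * sqrt(dynamics$kBT / pull$k_spring) +
    6 * sqrt(2 * dynamics$D * dynamics$dt)
  wall <- c(pot$domain[1] - margin, pot$domain[2] + margin)
  m <- with_seed(component_seed(seed, "pulls"), {
    if (is.null(z0)) {
      ks <- pull$k_spring
      zs <- pull$z_start
      z0 <- sample_boltzmann(pot, dynamics$kBT, 1,
                             extra = function(z) 0.5 * ks * (z - zs)^2,
                             range = wall)
    }
    smd_pull_cpp(z0, as.integer(n_steps), dynamics$dt, dynamics$D,
                 dynamics$kBT, wall[1], wall[2],
                 gr$z0, gr$dz, gr$grad, pull$k_spring, pull$z_start,
                 v_signed, as.integer(stride))
  })
  out <- tibble::tibble(t = m[, 1], lambda = m[, 2], z = m[, 3],
                        f = m[, 4], W = m[, 5])
  structure(out,
    class = c("fr_work_trace", class(out)),
    protocol = pull, seed = seed, direction = pull$direction,
    params = dynamics
  )
}

# Recompute the cumulative work of a trace from its recorded force samples
# (trapezoid in lambda); used as an internal consistency check in tests.
recompute_work <- function(trace) {
  f <- trace$f
  dl <- diff(trace$lambda)
  c(0, cumsum(0.5 * (f[-1] + f[-length(f)]) * dl))
}
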