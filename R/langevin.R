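#' Langevin dynamics parameters
#'
#' Parameters of the overdamped (Brownian) dynamics used for solute
#' centre-of-mass motion along the bilayer normal. The friction follows from
#' the Einstein relation \eqn{\gamma = k_B T / D}.
#'
#' @param D Diffusion coefficient, Angstrom^2/ns.
#' @param temperature Temperature in Kelvin (the study conditions are
#'   300, 310 and 320 K).
#' @param dt Integration time step in ns. The stability requirement
#'   \eqn{dt \, D \, \max|U''| / (k_B T) < 0.1} is enforced when the
#'   parameters meet a concrete potential in [simulate_langevin_1d()] /
#'   [simulate_smd_pull()]; use [suggest_dt()] to pick a safe value.
#' @return An object of class `fr_langevin_params`.
#' @export
langevin_params <- function(D, temperature = 300, dt) {
  stopifnot_scalar_pos(D, "D")
  stopifnot_scalar_pos(temperature, "temperature")
  stopifnot_scalar_pos(dt, "dt")
  structure(
    list(D = D, temperature = temperature, dt = dt,
         kB = KB_KCALMOL, kBT = KB_KCALMOL * temperature),
    class = "fr_langevin_params"
  )
}

check_stability <- function(pot, dynamics, k_extra = 0) {
  curv <- pot_grid(pot)$max_curv + k_extra
  crit <- dynamics$dt * dynamics$D * curv / dynamics$kBT
  if (crit >= 0.1) {
    abort(sprintf(
      paste0("time step fails the stability check: dt*D*max|U''|/(kB*T) = ",
             "%.3g >= 0.1; reduce dt (suggest_dt() gives %.3g ns)"),
      crit, suggest_dt(pot, dynamics$D, dynamics$temperature, k_extra)
    ))
  }
  invisible(crit)
}

#' Simulate overdamped Langevin motion on a 1-D potential
#'
#' Euler-Maruyama integration of
#' \eqn{z \leftarrow z - D\,U'(z)\,dt/(k_B T) + \sqrt{2 D\,dt}\,\eta},
#' \eqn{\eta \sim N(0,1)}, with reflecting boundaries at the potential's
#' domain edges. This is the generator standing in for the unbiased
#' all-atom dynamics of a solute near a bilayer: its stationary law is the
#' Boltzmann distribution of the supplied potential.
#'
#' @param pot A [potential()].
#' @param dynamics [langevin_params()].
#' @param n_steps Number of integration steps (>= 0).
#' @param z0 Initial position, inside the domain.
#' @param seed Integer seed; identical seeds give identical paths.
#' @param record_stride Record every this many steps (default 1).
#' @return A tibble of class `fr_path` with columns `time` (ns) and `z`
#'   (Angstrom); attributes carry the parameters and seed.
#' @examples
#' U <- potential("harmonic", c(1, 0), domain = c(-10, 10))
#' p <- simulate_langevin_1d(U, langevin_params(100, 300, 5e-4),
#'                           n_steps = 1000, z0 = 0, seed = 1)
#' var(p$z)
#' @export
simulate_langevin_1d <- function(pot, dynamics, n_steps, z0, seed,
                                 record_stride = 1L) {
  if (!is_count(n_steps)) abort("n_steps must be a nonnegative integer")
  if (!is_count(record_stride) || record_stride < 1) {
    abort("record_stride must be a positive integer")
  }
  if (z0 < pot$domain[1] || z0 > pot$domain[2]) {
    abort("z0 outside the potential domain")
  }
  check_stability(pot, dynamics)
  gr <- pot_grid(pot)
  z <- if (n_steps == 0) {
    z0
  } else {
    with_seed(component_seed(seed, "dynamics"), {
      langevin_path_cpp(z0, as.integer(n_steps), dynamics$dt, dynamics$D,
                        dynamics$kBT, pot$domain[1], pot$domain[2],
                        gr$z0, gr$dz, gr$grad, as.integer(record_stride))
    })
  }
  steps <- if (n_steps == 0) {
    0
  } else {
    st <- seq(0L, n_steps, by = record_stride)
    if (st[length(st)] != n_steps) st <- c(st, n_steps)
    st
  }
  out <- tibble::tibble(time = steps * dynamics$dt, z = z)
  structure(out,
    class = c("fr_path", class(out)),
    params = dynamics, potential = pot, seed = seed
  )
}
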