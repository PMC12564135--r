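#' Define a one-dimensional membrane potential
#'
#' A `potential` is the free-energy landscape \eqn{U(z)} (kcal/mol) a solute
#' centre of mass experiences along the bilayer normal. It is both the input
#' to the Langevin and steered-pull generators and the ground truth the
#' forward-reverse estimator is judged against.
#'
#' Available forms and their `params`:
#' \describe{
#'   \item{`flat`}{`c(u0)` constant level (default 0).}
#'   \item{`linear`}{`c(u0, slope)`: \eqn{U = u_0 + c z} with slope in
#'     kcal/mol/\eqn{\text{\AA}}.}
#'   \item{`harmonic`}{`c(kappa, z0)`: \eqn{U = \tfrac12 \kappa (z-z_0)^2}.}
#'   \item{`double_well`}{`c(h, z1, z2)`: quartic with equal minima at
#'     `z1`, `z2` (value 0) and barrier height `h` kcal/mol midway,
#'     \eqn{U = h\,[(z-c)^2-w^2]^2 / w^4} with \eqn{c=(z_1+z_2)/2},
#'     \eqn{w=(z_2-z_1)/2}.}
#'   \item{`tabulated`}{`list(z = , U = )`, interpolated with a natural cubic
#'     spline (continuously differentiable, so the gradient is available
#'     everywhere).}
#' }
#'
#' @param form One of `"flat"`, `"linear"`, `"harmonic"`, `"double_well"`,
#'   `"tabulated"`.
#' @param params Numeric coefficients (or a `list(z, U)` for `tabulated`).
#' @param domain Length-2 numeric, the `[z_min, z_max]` interval in Angstrom
#'   on which the potential is defined.
#' @return An object of class `fr_potential` with methods [pot_energy()],
#'   [pot_gradient()].
#' @examples
#' U <- potential("double_well", c(2.5, 3, 16), domain = c(0, 19))
#' pot_energy(U, c(3, 9.5, 16))
#' @export
potential <- function(form = c("flat", "linear", "harmonic", "double_well",
                               "tabulated"),
                      params = NULL, domain) {
  form <- match.arg(form)
  if (!is.numeric(domain) || length(domain) != 2L || !all(is.finite(domain)) ||
      domain[1] >= domain[2]) {
    abort("domain must be a finite increasing [z_min, z_max] pair")
  }
  spline <- NULL
  if (form == "tabulated") {
    if (!is.list(params) || is.null(params$z) || is.null(params$U)) {
      abort("tabulated potential needs params = list(z = , U = )")
    }
    if (!all(is.finite(params$U))) abort("tabulated U must be finite")
    spline <- splinefun(params$z, params$U, method = "natural")
  } else {
    params <- switch(form,
      flat = if (is.null(params)) 0 else params,
      linear = if (is.null(params)) c(0, 1) else params,
      harmonic = if (is.null(params)) c(1, 0) else params,
      double_well = if (is.null(params)) c(2.5, 3, 16) else params
    )
    if (!is.numeric(params) || !all(is.finite(params))) {
      abort("params must be finite numerics")
    }
    if (form == "double_well" && params[2] >= params[3]) {
      abort("double_well requires z1 < z2")
    }
  }
  out <- structure(
    list(form = form, params = params, domain = as.numeric(domain),
         spline = spline),
    class = "fr_potential"
  )
  if (!all(is.finite(pot_energy(out, seq(domain[1], domain[2],
                                         length.out = 101))))) {
    abort("potential is not finite on its domain")
  }
  out
}

#' Evaluate a potential and its gradient
#'
#' @param pot An [potential()] object.
#' @param z Positions (Angstrom), vectorised.
#' @return `pot_energy()`: \eqn{U(z)} in kcal/mol; `pot_gradient()`:
#'   \eqn{U'(z)} in kcal/mol/Angstrom.
#' @export
pot_energy <- function(pot, z) {
  p <- pot$params
  switch(pot$form,
    flat = rep(p[1], length(z)),
    linear = p[1] + p[2] * z,
    harmonic = 0.5 * p[1] * (z - p[2])^2,
    double_well = {
      ctr <- (p[2] + p[3]) / 2
      w <- (p[3] - p[2]) / 2
      p[1] * ((z - ctr)^2 - w^2)^2 / w^4
    },
    tabulated = pot$spline(z)
  )
}

#' @rdname pot_energy
#' @export
pot_gradient <- function(pot, z) {
  p <- pot$params
  switch(pot$form,
    flat = rep(0, length(z)),
    linear = rep(p[2], length(z)),
    harmonic = p[1] * (z - p[2]),
    double_well = {
      ctr <- (p[2] + p[3]) / 2
      w <- (p[3] - p[2]) / 2
      4 * p[1] * (z - ctr) * ((z - ctr)^2 - w^2) / w^4
    },
    tabulated = pot$spline(z, deriv = 1)
  )
}

#' @export
print.fr_potential <- function(x, ...) {
  cat("<fr_potential> form =", x$form, " domain = [",
      x$domain[1], ",", x$domain[2], "] Angstrom\n")
  invisible(x)
}

# Gradient tabulated on a fine uniform grid for the compiled integrators,
# plus the maximum |U''| used by the time-step stability bound.
pot_grid <- function(pot, n = 4001L) {
  z <- seq(pot$domain[1], pot$domain[2], length.out = n)
  g <- pot_gradient(pot, z)
  curv <- max(abs(diff(g) / diff(z)[1]))
  list(z0 = z[1], dz = z[2] - z[1], grad = g, max_curv = curv)
}

#' Suggest a stable Langevin time step
#'
#' The Euler-Maruyama scheme is kept in its stable regime by requiring
#' \eqn{dt \cdot D \cdot \max|U''| / (k_B T) < 0.1}; this helper returns a
#' time step a safety factor below that bound (an extra curvature
#' `k_extra` accounts for the guide spring during steered pulls).
#'
#' @param pot A [potential()].
#' @param D Diffusion coefficient, Angstrom^2/ns.
#' @param temperature Temperature, K.
#' @param k_extra Additional curvature (e.g. a spring constant),
#'   kcal/mol/Angstrom^2.
#' @param safety Fraction of the stability bound to use (default 0.05).
#' @return Time step in ns.
#' @export
suggest_dt <- function(pot, D, temperature, k_extra = 0, safety = 0.05) {
  kBT <- KB_KCALMOL * temperature
  curv <- pot_grid(pot)$max_curv + k_extra
  if (curv <= 0) curv <- 1e-6
  safety * kBT / (D * curv)
}

# Potential continued linearly beyond its domain (matching the clamped
# gradient the integrators use outside the tabulated grid).
pot_energy_ext <- function(pot, z) {
  zc <- pmin(pmax(z, pot$domain[1]), pot$domain[2])
  pot_energy(pot, zc) + pot_gradient(pot, zc) * (z - zc)
}

# Draw samples from exp(-(U(z) + extra(z)) / kBT) over `range` by
# inverse-CDF on a fine grid. Used for Boltzmann-distributed initial states.
sample_boltzmann <- function(pot, kBT, n = 1L, extra = NULL, ngrid = 4001L,
                             range = pot$domain) {
  z <- seq(range[1], range[2], length.out = ngrid)
  u <- pot_energy_ext(pot, z)
  if (!is.null(extra)) u <- u + extra(z)
  w <- exp(-(u - min(u)) / kBT)
  cdf <- cumsum(w)
  cdf <- cdf / cdf[length(cdf)]
  # strictly increasing for interpolation
  keep <- c(TRUE, diff(cdf) > 0)
  approx(cdf[keep], z[keep], xout = runif(n), rule = 2)$y
}
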