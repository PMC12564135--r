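#' Interpolate a work trace onto a spatial grid
#'
#' Maps the cumulative work `W(lambda)` of one pull onto uniform grid nodes
#' by linear interpolation, re-indexing traces that traverse in the
#' descending sense so that both directions share one spatial axis: for a
#' descending trace the value reported at `z` is the work expended from the
#' moment the guide passes `z` to the end of the pull, i.e. the work over
#' the same segment `[z_low, z]` that an ascending trace accumulates. This
#' is the alignment under which the forward-reverse combination
#' \eqn{\Delta U = \tfrac12 (W_F - W_R)} cancels dissipation (the
#' complementary-segment dissipations sum to a z-independent constant).
#'
#' @param trace An [simulate_smd_pull()] trace (or any tibble with
#'   `lambda`, `W` plus a `protocol` attribute).
#' @param grid Uniform ascending z grid (Angstrom), inside the traversed
#'   interval.
#' @return A tibble with `z` and `W` (kcal/mol).
#' @export
bin_work <- function(trace, grid) {
  if (length(grid) > 1 && any(abs(diff(diff(grid))) > 1e-8)) {
    abort("grid must be uniform")
  }
  lam <- trace$lambda
  lo <- min(lam)
  hi <- max(lam)
  eps <- 1e-9
  if (any(grid < lo - eps | grid > hi + eps)) {
    abort("grid node outside the traversed interval")
  }
  proto <- attr(trace, "protocol")
  descending <- if (!is.null(proto)) {
    proto$z_end < proto$z_start
  } else {
    lam[length(lam)] < lam[1]
  }
  ord <- order(lam)
  w <- approx(lam[ord], trace$W[ord], xout = pmin(pmax(grid, lo), hi),
              ties = "ordered")$y
  if (descending) w <- trace$W[which.min(lam)] - w
  tibble::tibble(z = grid, W = w)
}

#' Average pull works per direction on a grid
#'
#' Bins every trace with [bin_work()] and reports, per grid node and
#' direction label, the mean work, its standard error and the number of
#' pulls. All traces must share the same traversed interval and speed.
#'
#' @param traces List of [simulate_smd_pull()] traces, at least one per
#'   direction label (`"F"`, `"R"`).
#' @param grid Uniform z grid; defaults to 0.5 Angstrom spacing over the
#'   traversed interval.
#' @return A tibble of class `fr_meanworks` with columns `z`, `W_F`,
#'   `se_F`, `W_R`, `se_R`; attributes `n_F`, `n_R`, `v`.
#' @export
average_works <- function(traces, grid = NULL) {
  if (!length(traces)) abort("no traces supplied")
  protos <- lapply(traces, attr, "protocol")
  if (any(vapply(protos, is.null, logical(1)))) {
    abort("every trace needs a protocol attribute")
  }
  iv <- t(vapply(protos, function(p) sort(c(p$z_start, p$z_end)),
                 numeric(2)))
  vs <- vapply(protos, function(p) p$v, numeric(1))
  if (max(iv[, 1]) - min(iv[, 1]) > 1e-9 ||
      max(iv[, 2]) - min(iv[, 2]) > 1e-9 || max(vs) - min(vs) > 1e-12) {
    abort("mixed protocols: all traces must share interval and speed")
  }
  dir <- vapply(traces, function(tr) attr(tr, "direction"), character(1))
  if (!all(c("F", "R") %in% dir)) {
    abort("need at least one trace per direction (F and R)")
  }
  grid <- grid %||% seq(iv[1, 1], iv[1, 2], by = 0.5)
  wmat <- vapply(traces, function(tr) bin_work(tr, grid)$W,
                 numeric(length(grid)))
  stat <- function(d) {
    m <- wmat[, dir == d, drop = FALSE]
    list(
      mean = rowMeans(m),
      se = if (ncol(m) > 1) apply(m, 1, sd) / sqrt(ncol(m)) else
        rep(NA_real_, nrow(m)),
      n = ncol(m)
    )
  }
  f <- stat("F")
  r <- stat("R")
  out <- tibble::tibble(z = grid, W_F = f$mean, se_F = f$se,
                        W_R = r$mean, se_R = r$se)
  structure(out, class = c("fr_meanworks", class(out)),
            n_F = f$n, n_R = r$n, v = vs[1])
}

#' Forward-reverse PMF estimate
#'
#' The potential of mean force from direction-averaged non-equilibrium
#' works, \eqn{\Delta U(z) = \tfrac12 (\langle W_F \rangle - \langle W_R
#' \rangle)}, shifted so \eqn{\Delta U(\mathrm{anchor}) = 0}, with the
#' propagated standard error \eqn{\tfrac12 \sqrt{SE_F^2 + SE_R^2}}.
#'
#' @param meanworks An [average_works()] profile.
#' @param anchor Anchor position (default: the top grid node, the
#'   bulk-adjacent surface endpoint of the pull protocol).
#' @return A tibble of class `fr_pmf` with `z`, `dU`, `se`; attributes
#'   `anchor`, `n_F`, `n_R`.
#' @export
estimate_pmf <- function(meanworks, anchor = NULL) {
  anchor <- anchor %||% max(meanworks$z)
  if (anchor < min(meanworks$z) - 1e-9 || anchor > max(meanworks$z) + 1e-9) {
    abort("anchor outside the grid")
  }
  du <- 0.5 * (meanworks$W_F - meanworks$W_R)
  du0 <- approx(meanworks$z, du, xout = anchor, rule = 2)$y
  se <- 0.5 * sqrt(meanworks$se_F^2 + meanworks$se_R^2)
  out <- tibble::tibble(z = meanworks$z, dU = du - du0, se = se)
  structure(out, class = c("fr_pmf", class(out)), anchor = anchor,
            n_F = attr(meanworks, "n_F"), n_R = attr(meanworks, "n_R"),
            v = attr(meanworks, "v"))
}

#' Dissipation profile
#'
#' The dissipated work \eqn{W_d(z) = \tfrac12 (\langle W_F \rangle +
#' \langle W_R \rangle)}, which under the segment alignment of
#' [bin_work()] is the dissipation accumulated from the low end of the
#' interval: nonnegative (within noise) and nondecreasing, with slope
#' \eqn{\gamma(z)\,v}.
#'
#' @inheritParams estimate_pmf
#' @return A tibble of class `fr_dissipation` with `z`, `Wd`, `se`.
#' @export
estimate_dissipation <- function(meanworks) {
  wd <- 0.5 * (meanworks$W_F + meanworks$W_R)
  se <- 0.5 * sqrt(meanworks$se_F^2 + meanworks$se_R^2)
  out <- tibble::tibble(z = meanworks$z, Wd = wd, se = se)
  structure(out, class = c("fr_dissipation", class(out)),
            v = attr(meanworks, "v"))
}

#' Position-dependent diffusivity from dissipation (optional)
#'
#' Reconstructs \eqn{D(z) = k_B T \, v / W_d'(z)} by central differences,
#' reported only where the local slope is positive and exceeds its own
#' propagated standard error (elsewhere `NA`, never negative). The formula
#' is the overdamped linear-response relation of the forward-reverse
#' framework this estimator follows; the dissipation slope equals
#' \eqn{\gamma(z) v} with \eqn{\gamma = k_B T / D}.
#'
#' @param dissipation An [estimate_dissipation()] profile.
#' @param v Pull speed, Angstrom/ns (defaults to the profile's recorded
#'   speed).
#' @param temperature Temperature, K.
#' @return A tibble with `z`, `dWd_dz`, `D` (Angstrom^2/ns).
#' @export
estimate_friction_diffusion <- function(dissipation, v = NULL,
                                        temperature = 300) {
  v <- v %||% attr(dissipation, "v")
  if (is.null(v)) abort("pull speed v is required")
  z <- dissipation$z
  wd <- dissipation$Wd
  n <- length(z)
  if (n < 3) abort("need at least three nodes")
  slope <- rep(NA_real_, n)
  slope[2:(n - 1)] <- (wd[3:n] - wd[1:(n - 2)]) / (z[3:n] - z[1:(n - 2)])
  se_sl <- rep(NA_real_, n)
  if (!all(is.na(dissipation$se))) {
    se_sl[2:(n - 1)] <- sqrt(dissipation$se[3:n]^2 +
                               dissipation$se[1:(n - 2)]^2) /
      (z[3:n] - z[1:(n - 2)])
  }
  kBT <- KB_KCALMOL * temperature
  D <- ifelse(!is.na(slope) & slope > 0 &
                (is.na(se_sl) | slope > se_sl),
              kBT * v / slope, NA_real_)
  tibble::tibble(z = z, dWd_dz = slope, D = D)
}
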