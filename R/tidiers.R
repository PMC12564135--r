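# broom-style tidiers for fitted/estimated objects.

#' Tidy a PMF estimate
#'
#' @param x An `fr_pmf` from [estimate_pmf()].
#' @param ... Unused.
#' @return A tibble with `z`, `estimate` (kcal/mol) and `std.error`.
#' @export
tidy.fr_pmf <- function(x, ...) {
  tibble::tibble(z = x$z, estimate = x$dU, std.error = x$se)
}

#' One-row summary of a PMF estimate
#'
#' @param x An `fr_pmf`.
#' @param ... Unused.
#' @return A tibble with the grid span and spacing, pull counts, anchor,
#'   and the location/value of the profile minimum.
#' @export
glance.fr_pmf <- function(x, ...) {
  i <- which.min(x$dU)
  tibble::tibble(
    n_nodes = nrow(x), dz = x$z[2] - x$z[1],
    z_min = min(x$z), z_max = max(x$z),
    anchor = attr(x, "anchor"),
    n_pulls_F = attr(x, "n_F"), n_pulls_R = attr(x, "n_R"),
    min_z = x$z[i], min_dU = x$dU[i]
  )
}

#' Tidy direction-averaged works
#'
#' @param x An `fr_meanworks` from [average_works()].
#' @param ... Unused.
#' @return A long tibble with `z`, `direction`, `mean_work`, `std.error`.
#' @export
tidy.fr_meanworks <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(z = x$z, direction = "F", mean_work = x$W_F,
                   std.error = x$se_F),
    tibble::tibble(z = x$z, direction = "R", mean_work = x$W_R,
                   std.error = x$se_R)
  )
}

#' Tidy / summarise a work trace
#'
#' @param x An `fr_work_trace` from [simulate_smd_pull()].
#' @param ... Unused.
#' @return `tidy()`: the trace as a plain tibble; `glance()`: one row with
#'   direction, interval, speed, total work and sample count.
#' @export
tidy.fr_work_trace <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.fr_work_trace
#' @export
glance.fr_work_trace <- function(x, ...) {
  p <- attr(x, "protocol")
  tibble::tibble(
    direction = attr(x, "direction"), z_start = p$z_start, z_end = p$z_end,
    v = p$v, k_spring = p$k_spring, n_samples = nrow(x),
    total_work = x$W[nrow(x)], seed = attr(x, "seed")
  )
}

#' Tidy a cluster partition
#'
#' @param x An `fr_clusters` from [count_clusters()].
#' @param ... Unused.
#' @return `tidy()`: molecule-to-cluster assignments; `glance()`: one row
#'   per species with the normalized cluster count.
#' @export
tidy.fr_clusters <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.fr_clusters
#' @export
glance.fr_clusters <- function(x, ...) {
  out <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$species),
    n_clusters = dplyr::n_distinct(.data$cluster),
    n_molecules = dplyr::n(), .groups = "drop"
  )
  out$normalized <- out$n_clusters / out$n_molecules
  out$cutoff <- attr(x, "cutoff")
  out
}
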