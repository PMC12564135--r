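# Uniform-bin 1-D profiles (densities, distributions, PMFs share the shape).

new_profile <- function(z, value, width, mode, n_frames = 1L, se = NULL) {
  stopifnot(length(z) == length(value))
  out <- tibble::tibble(z = z, value = value)
  if (!is.null(se)) out$se <- se
  structure(out, class = c("fr_profile", class(out)),
            bin_width = width, mode = mode, n_frames = n_frames)
}

#' Bin width, normalization mode and frame count of a profile
#'
#' @param x An `fr_profile` as returned by [distance_distribution()],
#'   [number_density_profile()] or [hbond_distribution()].
#' @return `profile_bin_width()`: the uniform bin width;
#'   `profile_mode()`: `"counts"`, `"number_density"` or
#'   `"probability_density"`.
#' @export
profile_bin_width <- function(x) attr(x, "bin_width")

#' @rdname profile_bin_width
#' @export
profile_mode <- function(x) attr(x, "mode")

#' @export
print.fr_profile <- function(x, ...) {
  cat(sprintf("<fr_profile> %s, %d bins of %.3g, %d frame(s)\n",
              attr(x, "mode"), nrow(x), attr(x, "bin_width"),
              attr(x, "n_frames")))
  NextMethod()
}

# Uniform breaks covering `rng` with the given width, with bin CENTRES
# aligned on multiples of the width: values sitting exactly on a round
# position (a planted mode, an integer count) fall mid-bin instead of on an
# edge, so recovery does not depend on floating-point tie-breaking.
uniform_breaks <- function(rng, width) {
  k0 <- round(rng[1] / width)
  if ((k0 - 0.5) * width > rng[1]) k0 <- k0 - 1
  k1 <- round(rng[2] / width)
  if ((k1 + 0.5) * width < rng[2]) k1 <- k1 + 1
  if (k1 < k0) k1 <- k0
  seq((k0 - 0.5) * width, by = width, length.out = k1 - k0 + 2)
}

bin_counts <- function(x, breaks) {
  # right-open bins [b_i, b_{i+1}) with the last bin closed
  idx <- findInterval(x, breaks, rightmost.closed = TRUE)
  idx <- idx[idx >= 1 & idx <= length(breaks) - 1]
  tabulate(idx, nbins = length(breaks) - 1)
}
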