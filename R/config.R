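#' Spatial and staging configuration
#'
#' Bundles the geometric and temporal constants of the body model: the body
#' is treated as a cylinder of constant radius, birth times are minutes
#' post-fertilization, and the network is examined at a fixed ladder of
#' developmental stage times. Hatching divides births into embryonic and
#' post-embryonic phases.
#'
#' @param body_radius Cylinder radius in mm (default 0.05, i.e. 50 µm).
#' @param hatch_time Hatching time in minutes post-fertilization (default 840).
#' @param stage_times Strictly increasing developmental cutoff times in
#'   minutes (default `c(350, 400, 500, 800, 2000, 2700)`).
#' @return An object of class `spatial_config`.
#' @examples
#' cfg <- spatial_config()
#' cfg$body_radius
#' @export
spatial_config <- function(body_radius = 0.05,
                           hatch_time = 840,
                           stage_times = c(350, 400, 500, 800, 2000, 2700)) {
  stopifnot(is.numeric(body_radius), length(body_radius) == 1L,
            is.finite(body_radius), body_radius > 0)
  stopifnot(is.numeric(hatch_time), length(hatch_time) == 1L,
            is.finite(hatch_time), hatch_time > 0)
  stage_times <- as.numeric(stage_times)
  if (length(stage_times) < 1L || anyNA(stage_times) ||
      any(diff(stage_times) <= 0)) {
    stop("`stage_times` must be a strictly increasing numeric vector")
  }
  structure(
    list(body_radius = body_radius,
         hatch_time = hatch_time,
         stage_times = stage_times),
    class = "spatial_config"
  )
}

#' @export
print.spatial_config <- function(x, ...) {
  cat("Spatial configuration\n")
  cat("  body radius: ", x$body_radius, " mm\n", sep = "")
  cat("  hatch time:  ", x$hatch_time, " min\n", sep = "")
  cat("  stage times: ", paste(x$stage_times, collapse = ", "), " min\n",
      sep = "")
  invisible(x)
}

#' Wiring-length classifier
#'
#' Soma-to-soma connection lengths are divided into `n_bins` equal-width
#' bins of `bin_width` mm; the first `short_bins` bins are the short class,
#' the last `long_bins` bins the long class, and everything between is
#' medium. With the defaults (ten bins of 0.12 mm, three short, three long)
#' the class boundaries are 0.36 mm and 0.84 mm: short means d < 0.36 mm and
#' long means d >= 0.84 mm. Lengths beyond the binned range are still long.
#'
#' @param n_bins Number of length bins (default 10).
#' @param bin_width Bin width in mm (default 0.12).
#' @param short_bins Number of leading bins classed short (default 3).
#' @param long_bins Number of trailing bins classed long (default 3).
#' @return An object of class `length_classifier` with derived thresholds
#'   `short_max` and `long_min` (mm).
#' @examples
#' cl <- length_classifier()
#' c(cl$short_max, cl$long_min)
#' @export
length_classifier <- function(n_bins = 10, bin_width = 0.12,
                              short_bins = 3, long_bins = 3) {
  stopifnot(n_bins >= 1, bin_width > 0, short_bins >= 1, long_bins >= 1)
  if (short_bins + long_bins >= n_bins) {
    stop("`short_bins` + `long_bins` must be smaller than `n_bins`")
  }
  structure(
    list(n_bins = n_bins, bin_width = bin_width,
         short_bins = short_bins, long_bins = long_bins,
         short_max = short_bins * bin_width,
         long_min = (n_bins - long_bins) * bin_width),
    class = "length_classifier"
  )
}

#' @export
print.length_classifier <- function(x, ...) {
  cat("Length classifier: short < ", x$short_max, " mm <= medium < ",
      x$long_min, " mm <= long\n", sep = "")
  invisible(x)
}
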