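#' Wavenumber axis
#'
#' A strictly monotonic, uniformly spaced wavenumber grid (cm^-1).
#' Spectra are stored in the axis order; descending storage (high to low
#' wavenumber, matching acquisition) is the package default. All band
#' selection is by wavenumber interval, never by raw band index.
#'
#' @param values numeric vector of wavenumbers in cm^-1, strictly monotonic
#'   and uniformly spaced (relative tolerance 1e-6).
#' @param nominal_resolution nominal spectral resolution in cm^-1.
#' @return an object of class `wn_axis`.
#' @export
wn_axis <- function(values, nominal_resolution = abs(stats::median(diff(values)))) {
  values <- as.numeric(values)
  if (length(values) < 2L) structural_error("wavenumber axis needs >= 2 points")
  d <- diff(values)
  if (any(d == 0) || (any(d > 0) && any(d < 0)))
    structural_error("wavenumber axis must be strictly monotonic")
  if (max(abs(d - d[1])) > 1e-6 * abs(d[1]))
    structural_error("wavenumber axis spacing is not uniform (rel. tol 1e-6)")
  structure(list(values = values, nominal_resolution = nominal_resolution,
                 descending = d[1] < 0),
            class = "wn_axis")
}

#' Default acquisition axis
#'
#' The descending 2700 to 950 cm^-1 grid at 4 cm^-1 nominal step used for
#' acquisition; the last on-grid point is 952 cm^-1, giving
#' `floor((2700-950)/4)+1 = 438` bands.
#'
#' @param from,to acquisition range in cm^-1.
#' @param step grid step in cm^-1.
#' @return a `wn_axis`.
#' @export
default_axis <- function(from = 2700, to = 950, step = 4) {
  n <- floor((from - to) / step) + 1L
  wn_axis(seq(from, by = -step, length.out = n), nominal_resolution = step)
}

#' @export
length.wn_axis <- function(x) length(x$values)

#' @export
print.wn_axis <- function(x, ...) {
  cat(sprintf("<wn_axis> %d bands, %.6g to %.6g cm^-1 (step %.6g, %s)\n",
              length(x$values), x$values[1], x$values[length(x$values)],
              diff(x$values)[1], if (x$descending) "descending" else "ascending"))
  invisible(x)
}

#' Band indices inside a closed wavenumber interval
#'
#' @param axis a `wn_axis`.
#' @param window numeric length-2 wavenumber interval (any order), cm^-1.
#' @return integer indices into the axis, in storage order.
#' @export
wn_window <- function(axis, window) {
  stopifnot(inherits(axis, "wn_axis"), length(window) == 2L)
  lo <- min(window); hi <- max(window)
  if (lo < min(axis$values) - 1e-9 || hi > max(axis$values) + 1e-9)
    range_error("window [%g, %g] cm^-1 outside axis range [%g, %g]",
                lo, hi, min(axis$values), max(axis$values))
  which(axis$values >= lo - 1e-9 & axis$values <= hi + 1e-9)
}

# intersect a requested wavenumber interval with the axis range (used where
# a nominal fit range, e.g. 2300-950, may slightly overhang the stored grid)
.clip_range <- function(axis, window) {
  c(max(min(window), min(axis$values)), min(max(window), max(axis$values)))
}
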