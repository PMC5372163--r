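#' Hyperspectral absorbance image
#'
#' An absorbance cube (rows x cols x bands) with its wavenumber axis, pixel
#' geometry and a per-pixel quality-control mask. The stage position of the
#' center of 0-based pixel (r, c) is
#' `(origin_x + (c + 0.5) * pixel_width, origin_y + (r + 0.5) * pixel_height)`,
#' with stage y increasing downward; this pixel-center convention is used by
#' all geometry downstream (boundary polygons use the middle of marginal
#' pixels).
#'
#' @param cube numeric array `[rows, cols, bands]` of absorbance.
#' @param axis a [wn_axis] with as many points as the cube has bands.
#' @param pixel_size numeric length 2, pixel width and height in micrometer.
#' @param stage_origin numeric length 2, stage (x, y) in micrometer of the
#'   center of pixel (0, 0).
#' @param qc_mask logical matrix `[rows, cols]`, `TRUE` = usable; defaults
#'   to all-true.
#' @return an object of class `spectral_image`.
#' @export
spectral_image <- function(cube, axis, pixel_size = c(5.65, 5.75),
                           stage_origin = c(0, 0), qc_mask = NULL) {
  if (length(dim(cube)) != 3L) structural_error("cube must be a 3-d array")
  if (dim(cube)[3] != length(axis))
    structural_error("cube has %d bands but axis has %d entries",
                     dim(cube)[3], length(axis))
  if (any(pixel_size <= 0)) validation_error("pixel_size components must be > 0")
  if (is.null(qc_mask)) qc_mask <- matrix(TRUE, dim(cube)[1], dim(cube)[2])
  if (!identical(dim(qc_mask), dim(cube)[1:2]))
    structural_error("qc_mask shape does not match cube")
  if (any(qc_mask) && !all(is.finite(cube[rep(qc_mask, dim(cube)[3])])))
    validation_error("non-finite absorbance at QC-passing pixels")
  structure(list(cube = cube, axis = axis,
                 pixel_size = as.numeric(pixel_size),
                 stage_origin = as.numeric(stage_origin),
                 qc_mask = qc_mask),
            class = "spectral_image")
}

#' @export
dim.spectral_image <- function(x) dim(x$cube)

#' @export
print.spectral_image <- function(x, ...) {
  d <- dim(x$cube)
  cat(sprintf("<spectral_image> %d x %d pixels x %d bands, pixel %.3g x %.3g um, %d/%d QC-pass\n",
              d[1], d[2], d[3], x$pixel_size[1], x$pixel_size[2],
              sum(x$qc_mask), d[1] * d[2]))
  invisible(x)
}

#' Stage coordinates of pixel centers
#'
#' @param image a `spectral_image` (or any list with `pixel_size` and
#'   `stage_origin`).
#' @param rows,cols 1-based pixel indices.
#' @return matrix with columns `x`, `y` in micrometer.
#' @export
pixel_centers <- function(image, rows, cols) {
  cbind(x = image$stage_origin[1] + (cols - 1 + 0.5) * image$pixel_size[1],
        y = image$stage_origin[2] + (rows - 1 + 0.5) * image$pixel_size[2])
}

#' Per-pixel class label image
#'
#' Integer labels per pixel; 0 means unclassified or QC-rejected. The legend
#' maps every nonzero label to a class name and display colour, mirroring the
#' index-colour images used to present random-forest tissue classifications.
#'
#' @param labels integer matrix `[rows, cols]`, values >= 0.
#' @param legend data.frame with columns `label` (integer), `class`
#'   (character), `color` (character, hex).
#' @return an object of class `label_map`.
#' @export
label_map <- function(labels, legend) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (any(labels < 0)) validation_error("labels must be >= 0")
  legend <- as.data.frame(legend)
  need <- setdiff(c("label", "class", "color"), names(legend))
  if (length(need)) validation_error("legend lacks column(s): %s", paste(need, collapse = ", "))
  missing <- setdiff(setdiff(unique(as.vector(labels)), 0L), legend$label)
  if (length(missing))
    validation_error("label(s) %s present in map but absent from legend",
                     paste(missing, collapse = ", "))
  if (anyDuplicated(legend$label)) validation_error("duplicated label in legend")
  structure(list(labels = labels, legend = legend), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d x %d, %d classes\n",
              nrow(x$labels), ncol(x$labels), nrow(x$legend)))
  invisible(x)
}

#' Paired reference points between two coordinate frames
#'
#' Point pairs (micrometer) used to estimate the stage-to-stage transfer,
#' e.g. marks cut into the slide foil and re-located on both microscopes.
#' At least three non-collinear pairs are required for a similarity fit.
#'
#' @param source,destination numeric matrices `n x 2` of (x, y) in micrometer.
#' @param frames character length 2 naming the two frames.
#' @return an object of class `reference_points`.
#' @export
reference_points <- function(source, destination,
                             frames = c("source", "destination")) {
  source <- as.matrix(source); destination <- as.matrix(destination)
  if (!identical(dim(source), dim(destination)) || ncol(source) != 2L)
    structural_error("source and destination must be matching n x 2 matrices")
  structure(list(source = source, destination = destination,
                 frames = as.character(frames)),
            class = "reference_points")
}

#' @export
print.reference_points <- function(x, ...) {
  cat(sprintf("<reference_points> %d pairs: %s -> %s\n",
              nrow(x$source), x$frames[1], x$frames[2]))
  invisible(x)
}

# area check used before transform estimation: the largest triangle over the
# point set must be non-degenerate
.max_triangle_area <- function(pts) {
  n <- nrow(pts)
  if (n < 3L) return(0)
  best <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- abs((pts[j, 1] - pts[i, 1]) * (pts[k, 2] - pts[i, 2]) -
             (pts[k, 1] - pts[i, 1]) * (pts[j, 2] - pts[i, 2])) / 2
    if (a > best) best <- a
  }
  best
}
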