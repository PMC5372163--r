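#' Write a hyperspectral cube to a binary container with JSON sidecar
#'
#' The cube is stored as little-endian doubles in column-major order with a
#' `<path>.json` sidecar carrying the axis, pixel geometry, stage origin and
#' QC mask. A neutral container keeps the toolchain independent of vendor
#' instrument formats.
#'
#' @param image a [spectral_image].
#' @param path output path; the sidecar is written to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_cube <- function(image, path) {
  stopifnot(inherits(image, "spectral_image"))
  meta <- list(
    format = "ftirlcm-cube", version = 1L,
    dims = dim(image$cube),
    wavenumbers_cm1 = image$axis$values,
    nominal_resolution_cm1 = image$axis$nominal_resolution,
    pixel_size_um = image$pixel_size,
    stage_origin_um = image$stage_origin,
    qc_mask = as.integer(image$qc_mask))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.vector(image$cube), con, size = 8, endian = "little")
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a hyperspectral cube written by [write_cube]
#'
#' @param path path to the binary cube; `paste0(path, ".json")` must exist.
#' @return a [spectral_image]; round trips are bitwise lossless.
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) format_error("cube file not found: %s", path)
  side <- paste0(path, ".json")
  if (!file.exists(side)) format_error("missing metadata sidecar: %s", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (f in c("dims", "wavenumbers_cm1", "pixel_size_um", "stage_origin_um"))
    if (is.null(meta[[f]])) format_error("sidecar lacks field '%s'", f)
  dims <- as.integer(meta$dims)
  if (length(dims) != 3L) format_error("field 'dims' must have 3 entries")
  if (dims[3] != length(meta$wavenumbers_cm1))
    structural_error("cube declares %d bands but axis has %d entries",
                     dims[3], length(meta$wavenumbers_cm1))
  n <- prod(dims)
  con <- file(path, "rb"); on.exit(close(con))
  vals <- readBin(con, "double", n = n, size = 8, endian = "little")
  if (length(vals) != n)
    structural_error("cube payload holds %d values, dims require %d",
                     length(vals), n)
  axis <- wn_axis(meta$wavenumbers_cm1,
                  meta$nominal_resolution_cm1 %||% abs(diff(meta$wavenumbers_cm1)[1]))
  qc <- if (is.null(meta$qc_mask)) NULL else
    matrix(as.logical(meta$qc_mask), dims[1], dims[2])
  spectral_image(array(vals, dims), axis,
                 pixel_size = meta$pixel_size_um,
                 stage_origin = meta$stage_origin_um, qc_mask = qc)
}

#' Write / read an index-colour label map (paletted PNG + JSON legend)
#'
#' Labels are stored as an 8-bit grayscale PNG (so at most 255 classes) and
#' the legend as a JSON sidecar; the round trip is pixelwise lossless.
#'
#' @param map a [label_map].
#' @param path output PNG path; legend goes to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(map, path) {
  stopifnot(inherits(map, "label_map"))
  if (max(map$labels) > 255L) validation_error("more than 255 labels")
  png::writePNG(map$labels / 255, path)
  jsonlite::write_json(map$legend, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  if (!file.exists(path)) format_error("label map not found: %s", path)
  side <- paste0(path, ".json")
  if (!file.exists(side)) format_error("missing legend sidecar: %s", side)
  labels <- round(png::readPNG(path) * 255)
  legend <- jsonlite::read_json(side, simplifyVector = TRUE)
  label_map(matrix(as.integer(labels), nrow(labels), ncol(labels)), legend)
}

.check_simple_polygon <- function(p, idx) {
  if (nrow(p) < 3L)
    validation_error("shape %d is degenerate: fewer than 3 vertices", idx)
  n <- nrow(p)
  seg <- cbind(p, p[c(2:n, 1), , drop = FALSE])
  inter <- function(a, b) {
    d1 <- (b[3] - b[1]) * (a[2] - b[2]) - (b[4] - b[2]) * (a[1] - b[1])
    d2 <- (b[3] - b[1]) * (a[4] - b[2]) - (b[4] - b[2]) * (a[3] - b[1])
    d3 <- (a[3] - a[1]) * (b[2] - a[2]) - (a[4] - a[2]) * (b[1] - a[1])
    d4 <- (a[3] - a[1]) * (b[4] - a[2]) - (a[4] - a[2]) * (b[3] - a[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  if (n > 3L) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (j == i || j == i %% n + 1 || i == j %% n + 1) next
    if (inter(seg[i, ], seg[j, ]))
      validation_error("shape %d is self-intersecting (segments %d and %d)",
                       idx, i, j)
  }
  invisible(TRUE)
}

#' Export dissection shapes for laser capture microdissection
#'
#' Writes ordered vertex lists (destination-frame micrometer, 0.0001 um
#' precision) in a documented neutral dialect: `xml` (shape id + point list)
#' or `csv` (`shape_id, vertex, x_um, y_um`). Vendor-exact instrument
#' dialects are out of scope.
#'
#' @param shapes list of `n x 2` matrices, polygon vertices in micrometer;
#'   each must have at least 3 vertices and be simple.
#' @param path output path.
#' @param dialect `"xml"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
export_lcm_shapes <- function(shapes, path, dialect = c("xml", "csv")) {
  dialect <- match.arg(dialect)
  shapes <- lapply(shapes, function(p) matrix(as.numeric(as.matrix(p)), ncol = 2))
  for (i in seq_along(shapes)) .check_simple_polygon(shapes[[i]], i)
  if (dialect == "csv") {
    rows <- do.call(rbind, c(list(data.frame(shape_id = integer(), vertex = integer(),
                                             x_um = character(), y_um = character())),
      lapply(seq_along(shapes), function(i) {
        p <- shapes[[i]]
        data.frame(shape_id = i, vertex = seq_len(nrow(p)),
                   x_um = sprintf("%.4f", p[, 1]), y_um = sprintf("%.4f", p[, 2]))
      })))
    utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  } else {
    doc <- xml2::xml_new_root("lcm_shapes", unit = "um",
                              count = as.character(length(shapes)))
    for (i in seq_along(shapes)) {
      sh <- xml2::xml_add_child(doc, "shape", id = as.character(i))
      p <- shapes[[i]]
      for (k in seq_len(nrow(p)))
        xml2::xml_add_child(sh, "point", x = sprintf("%.4f", p[k, 1]),
                            y = sprintf("%.4f", p[k, 2]))
    }
    xml2::write_xml(doc, path)
  }
  invisible(path)
}

#' Re-read shapes written by [export_lcm_shapes]
#'
#' @param path file written by [export_lcm_shapes].
#' @param dialect `"xml"` or `"csv"`.
#' @return list of `n x 2` vertex matrices (micrometer).
#' @export
read_lcm_shapes <- function(path, dialect = c("xml", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) format_error("shape file not found: %s", path)
  if (dialect == "csv") {
    d <- utils::read.csv(path)
    if (nrow(d) == 0L) return(list())
    lapply(split(d, d$shape_id), function(s)
      unname(cbind(s$x_um, s$y_um)[order(s$vertex), , drop = FALSE]))
  } else {
    doc <- xml2::read_xml(path)
    lapply(xml2::xml_find_all(doc, "./shape"), function(sh) {
      pts <- xml2::xml_find_all(sh, "./point")
      cbind(as.numeric(xml2::xml_attr(pts, "x")),
            as.numeric(xml2::xml_attr(pts, "y")))
    })
  }
}

#' Write / read reference point pairs as CSV
#'
#' Columns: `src_x, src_y, dst_x, dst_y` (micrometer).
#'
#' @param pairs a [reference_points].
#' @param path CSV path.
#' @return `path` / a [reference_points].
#' @export
write_reference_points <- function(pairs, path) {
  stopifnot(inherits(pairs, "reference_points"))
  utils::write.csv(data.frame(src_x = pairs$source[, 1], src_y = pairs$source[, 2],
                              dst_x = pairs$destination[, 1], dst_y = pairs$destination[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_points
#' @export
read_reference_points <- function(path) {
  if (!file.exists(path)) format_error("reference point file not found: %s", path)
  d <- utils::read.csv(path)
  reference_points(cbind(d$src_x, d$src_y), cbind(d$dst_x, d$dst_y))
}
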