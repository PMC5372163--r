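.shift_mat <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  r_dst <- max(1, 1 + dr):min(nr, nr + dr)
  c_dst <- max(1, 1 + dc):min(nc, nc + dc)
  out[r_dst, c_dst] <- m[r_dst - dr, c_dst - dc]
  out
}

# 8-connected component labeling by iterative minimum-label propagation
.label_components8 <- function(mask) {
  lab <- matrix(Inf, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(sum(mask))
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  repeat {
    new <- lab
    for (i in seq_len(nrow(offs)))
      new <- pmin(new, .shift_mat(lab, offs$dr[i], offs$dc[i], Inf))
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  out <- matrix(0L, nrow(mask), ncol(mask))
  ids <- sort(unique(lab[mask]))
  out[mask] <- match(lab[mask], ids)
  out
}

# pixels of the region with at least one 4-neighbour outside it (or off-image)
.marginal_mask <- function(mask) {
  inside4 <- .shift_mat(mask, 1, 0, FALSE) & .shift_mat(mask, -1, 0, FALSE) &
             .shift_mat(mask, 0, 1, FALSE) & .shift_mat(mask, 0, -1, FALSE)
  mask & !inside4
}

# Moore-neighbour boundary trace (outer contour, 8-connectivity), returning
# boundary pixels in order; Jacob's stopping criterion
.trace_boundary <- function(mask) {
  rc <- which(mask, arr.ind = TRUE)
  if (nrow(rc) == 1L) return(rc)
  # clockwise Moore neighbourhood starting west
  nb <- cbind(dr = c(0, -1, -1, -1, 0, 1, 1, 1),
              dc = c(-1, -1, 0, 1, 1, 1, 0, -1))
  inside <- function(p) p[1] >= 1 && p[1] <= nrow(mask) &&
    p[2] >= 1 && p[2] <= ncol(mask) && mask[p[1], p[2]]
  ord <- order(rc[, 1], rc[, 2])
  s <- rc[ord[1], ]                       # topmost, then leftmost
  b0 <- s + nb[1L, ]                      # west of start is background
  p <- s; b <- b0
  path <- matrix(s, 1, 2)
  repeat {
    d0 <- which(nb[, 1] == b[1] - p[1] & nb[, 2] == b[2] - p[2])
    found <- FALSE
    for (k in 1:8) {
      dir <- (d0 - 1L + k) %% 8L + 1L     # clockwise from just past backtrack
      q <- p + nb[dir, ]
      if (inside(q)) {
        prev <- (dir - 2L) %% 8L + 1L     # last background examined before q
        b <- p + nb[prev, ]
        p <- q
        found <- TRUE
        break
      }
    }
    if (!found) break                     # defensive; cannot happen for n > 1
    if (all(p == s) && all(b == b0)) break
    path <- rbind(path, p)
    if (nrow(path) > 8 * sum(mask)) break # defensive bound
  }
  unname(path)
}

# ordered marginal-pixel polygon of a connected region: outer Moore contour
# restricted to 4-marginal pixels, oriented counter-clockwise in image
# coordinates (x = col, y = row), starting at the topmost-then-leftmost
# marginal pixel
.boundary_polygon_px <- function(mask) {
  marg <- .marginal_mask(mask)
  path <- .trace_boundary(mask)
  keep <- marg[cbind(path[, 1], path[, 2])]
  poly <- path[keep, , drop = FALSE]
  dup <- duplicated(paste(poly[, 1], poly[, 2]))
  poly <- poly[!dup, , drop = FALSE]
  if (nrow(poly) >= 3L) {
    x <- poly[, 2]; y <- poly[, 1]
    a2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
    if (a2 < 0) poly <- poly[nrow(poly):1, , drop = FALSE]
  }
  o <- order(poly[, 1], poly[, 2])[1]
  if (o > 1L) poly <- poly[c(o:nrow(poly), 1:(o - 1L)), , drop = FALSE]
  poly
}

.roi_new <- function(class, label, pixels, image_dim, pixel_size, stage_origin, id = NA_integer_) {
  mask <- matrix(FALSE, image_dim[1], image_dim[2])
  mask[pixels] <- TRUE
  poly_px <- .boundary_polygon_px(mask)
  geom <- list(pixel_size = pixel_size, stage_origin = stage_origin)
  structure(list(
    id = id, class = class, label = label, pixels = pixels,
    n_pixels = nrow(pixels),
    area = nrow(pixels) * pixel_size[1] * pixel_size[2],
    polygon_px = poly_px,
    polygon = pixel_centers(geom, poly_px[, 1], poly_px[, 2]),
    pixel_size = pixel_size, stage_origin = stage_origin,
    image_dim = image_dim), class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> class '%s': %d pixels, %.4g um^2, %d boundary vertices\n",
              x$class, x$n_pixels, x$area, nrow(x$polygon)))
  invisible(x)
}

#' Extract regions of interest of one class from a label map
#'
#' Regions of interest are the 8-connected components of the target class
#' with at least `min_pixels` pixels. Each carries its boundary polygon:
#' the centers of its marginal pixels (pixels with a 4-neighbour outside
#' the region), ordered counter-clockwise in image coordinates and
#' expressed in source stage micrometer. These vertex coordinates are what
#' the microdissection shapes are built from.
#'
#' @param map a [label_map].
#' @param target_class class name (or integer label) of the tissue type of
#'   interest.
#' @param min_pixels minimum component size.
#' @param pixel_size pixel (width, height) in micrometer.
#' @param stage_origin stage (x, y) of the pixel (0, 0) center, micrometer.
#' @return list of `roi` objects (empty if the class is absent).
#' @export
extract_rois <- function(map, target_class, min_pixels = 1,
                         pixel_size = c(5.65, 5.75), stage_origin = c(0, 0)) {
  stopifnot(inherits(map, "label_map"))
  if (is.character(target_class)) {
    lab <- map$legend$label[match(target_class, map$legend$class)]
    if (is.na(lab)) validation_error("class '%s' not in legend", target_class)
    cls <- target_class
  } else {
    lab <- as.integer(target_class)
    cls <- map$legend$class[match(lab, map$legend$label)]
    if (is.na(cls)) validation_error("label %d not in legend", lab)
  }
  mask <- map$labels == lab
  if (!any(mask)) return(list())
  comp <- .label_components8(mask)
  out <- list()
  for (k in seq_len(max(comp))) {
    px <- which(comp == k, arr.ind = TRUE)
    px <- px[order(px[, 1], px[, 2]), , drop = FALSE]
    if (nrow(px) < min_pixels) next
    out[[length(out) + 1L]] <- .roi_new(cls, lab, px, dim(map$labels),
                                        pixel_size, stage_origin,
                                        id = length(out) + 1L)
  }
  out
}

# deterministic principal-axis bisection of an oversized pixel set
.bisect_pixels <- function(px, max_px) {
  if (nrow(px) <= max_px) return(list(px))
  xy <- cbind(px[, 2], px[, 1])
  ctr <- sweep(xy, 2, colMeans(xy))
  cv <- crossprod(ctr) / max(1, nrow(xy) - 1)
  ev <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  proj <- ctr %*% ev
  o <- order(proj, px[, 1], px[, 2])
  half <- ceiling(nrow(px) / 2)
  a <- px[o[1:half], , drop = FALSE]
  b <- px[o[(half + 1):nrow(px)], , drop = FALSE]
  c(.bisect_pixels(a, max_px), .bisect_pixels(b, max_px))
}

#' Split an oversized region of interest into dissectable fragments
#'
#' Microdissection instruments limit the size of a cut shape, so large
#' regions are split by a distance-transform watershed: the Euclidean
#' distance map of the region interior is segmented into catchment basins
#' around its regional maxima. Adjacent basins are then merged
#' smallest-first while the merged size stays within `max_shape_area`
#' (reducing over-segmentation), and any basin still above the limit (a
#' single maximum can own an arbitrarily large basin) is bisected
#' recursively along its principal axis. The result is a partition:
#' fragments are disjoint, their union is the region, and their areas and
#' amide integrals add up exactly; this is asserted on every run.
#'
#' @param roi an `roi` from [extract_rois].
#' @param amide_map numeric matrix (image dims) of per-pixel amide I band
#'   integrals, used to annotate each fragment with its summed integral.
#' @param max_shape_area maximum fragment area in micrometer^2.
#' @return list of `fragment` objects.
#' @export
watershed_split <- function(roi, amide_map = NULL, max_shape_area = 250000) {
  stopifnot(inherits(roi, "roi"))
  px_area <- roi$pixel_size[1] * roi$pixel_size[2]
  if (max_shape_area < px_area)
    validation_error("max_shape_area smaller than one pixel")
  max_px <- floor(max_shape_area / px_area)
  mask <- matrix(FALSE, roi$image_dim[1], roi$image_dim[2])
  mask[roi$pixels] <- TRUE

  if (roi$n_pixels <= max_px) {
    frag_sets <- list(roi$pixels)
  } else {
    d <- EBImage::distmap(mask)
    w <- EBImage::watershed(d)
    w <- matrix(as.integer(w), nrow(mask), ncol(mask))
    w[!mask] <- 0L
    # watershed-line or unlabeled region pixels: attach to nearest labeled
    # neighbour by repeated 8-neighbour propagation
    while (any(mask & w == 0L)) {
      filled <- w
      offs <- expand.grid(dr = -1:1, dc = -1:1)
      for (i in seq_len(nrow(offs))) {
        sh <- .shift_mat(w, offs$dr[i], offs$dc[i], 0L)
        sel <- mask & filled == 0L & sh > 0L
        filled[sel] <- sh[sel]
      }
      if (identical(filled, w)) { w[mask & w == 0L] <- max(w) + 1L; break }
      w <- filled
    }
    labs <- sort(unique(w[mask]))
    sets <- lapply(labs, function(l) which(w == l, arr.ind = TRUE))
    # smallest-first merging of adjacent catchments under the size limit
    adj <- function(a, b) {
      any(abs(outer(a[, 1], b[, 1], `-`)) <= 1 &
          abs(outer(a[, 2], b[, 2], `-`)) <= 1)
    }
    repeat {
      sizes <- vapply(sets, nrow, 0L)
      if (length(sets) < 2L) break
      merged <- FALSE
      for (i in order(sizes)) {
        nbrs <- which(vapply(seq_along(sets), function(j)
          j != i && sizes[i] + sizes[j] <= max_px && adj(sets[[i]], sets[[j]]), TRUE))
        if (length(nbrs)) {
          j <- nbrs[which.min(sizes[nbrs])]
          sets[[i]] <- rbind(sets[[i]], sets[[j]])
          sets[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (!merged) break
    }
    frag_sets <- do.call(c, lapply(sets, .bisect_pixels, max_px = max_px))
  }

  frags <- lapply(seq_along(frag_sets), function(i) {
    px <- frag_sets[[i]]
    px <- px[order(px[, 1], px[, 2]), , drop = FALSE]
    fm <- matrix(FALSE, roi$image_dim[1], roi$image_dim[2])
    fm[px] <- TRUE
    poly_px <- .boundary_polygon_px(fm)
    geom <- list(pixel_size = roi$pixel_size, stage_origin = roi$stage_origin)
    structure(list(
      parent = roi$id, class = roi$class, fragment = i, pixels = px,
      n_pixels = nrow(px), area = nrow(px) * px_area,
      amide_integral_sum = if (is.null(amide_map)) NA_real_ else
        sum(amide_map[px]),
      polygon_px = poly_px,
      polygon = pixel_centers(geom, poly_px[, 1], poly_px[, 2])),
      class = "fragment")
  })

  # partition invariants, asserted on every run
  all_px <- do.call(rbind, lapply(frags, `[[`, "pixels"))
  key <- paste(all_px[, 1], all_px[, 2])
  stopifnot(!anyDuplicated(key),
            nrow(all_px) == roi$n_pixels,
            all(vapply(frags, function(f) f$n_pixels <= max_px, TRUE)),
            setequal(key, paste(roi$pixels[, 1], roi$pixels[, 2])))
  frags
}

#' @export
print.fragment <- function(x, ...) {
  cat(sprintf("<fragment> %d of roi %s: %d pixels, %.4g um^2, amide sum %.4g\n",
              x$fragment, x$parent, x$n_pixels, x$area, x$amide_integral_sum))
  invisible(x)
}
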