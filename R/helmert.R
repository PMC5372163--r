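#' Construct a 4-parameter planar similarity (Helmert) transform
#'
#' `x' = tx + a x - b y`, `y' = ty + b x + a y` with `a = s cos(theta)`,
#' `b = s sin(theta)`: translation, rotation and a single uniform scale, as
#' used in geodesy to map one stage coordinate frame onto another.
#'
#' @param tx,ty translation (micrometer).
#' @param s scale (> 0, dimensionless).
#' @param theta rotation (radians).
#' @param rms_residual root-mean-square fit residual (micrometer), if known.
#' @return object of class `helmert`.
#' @export
helmert <- function(tx = 0, ty = 0, s = 1, theta = 0, rms_residual = NA_real_) {
  if (s <= 0) validation_error("scale must be > 0")
  structure(list(tx = tx, ty = ty, s = s, theta = theta,
                 a = s * cos(theta), b = s * sin(theta),
                 rms_residual = rms_residual),
            class = "helmert")
}

#' @export
print.helmert <- function(x, ...) {
  cat(sprintf("<helmert> t = (%.4g, %.4g) um, s = %.8g, theta = %.6g deg, rms = %.3g um\n",
              x$tx, x$ty, x$s, x$theta * 180 / pi, x$rms_residual))
  invisible(x)
}

#' Estimate a Helmert transform from reference point pairs
#'
#' Linear least squares in the parameters `(tx, ty, a, b)` over at least
#' three non-collinear point pairs; reports `s = sqrt(a^2 + b^2)`,
#' `theta = atan2(b, a)` and the rms residual over the pairs.
#'
#' @param pairs a [reference_points].
#' @return a [helmert].
#' @export
estimate_helmert <- function(pairs) {
  stopifnot(inherits(pairs, "reference_points"))
  n <- nrow(pairs$source)
  if (n < 3L) conditioning_error("need >= 3 reference point pairs, got %d", n)
  if (.max_triangle_area(pairs$source) < 1e-9)
    conditioning_error("reference points are collinear or coincident")
  x <- pairs$source[, 1]; y <- pairs$source[, 2]
  X <- rbind(cbind(1, 0, x, -y),
             cbind(0, 1, y,  x))
  z <- c(pairs$destination[, 1], pairs$destination[, 2])
  beta <- unname(qr.coef(qr(X), z))
  res <- z - X %*% beta
  rms <- sqrt(mean(res^2) * 2)   # per-point 2-d residual norm, rms over points
  a <- beta[3]; b <- beta[4]
  helmert(tx = beta[1], ty = beta[2], s = sqrt(a^2 + b^2),
          theta = atan2(b, a), rms_residual = rms)
}

#' Apply (or invert) a Helmert transform to points
#'
#' @param transform a [helmert].
#' @param points `n x 2` matrix of (x, y) in micrometer.
#' @return transformed `n x 2` matrix.
#' @export
apply_helmert <- function(transform, points) {
  stopifnot(inherits(transform, "helmert"))
  p <- matrix(as.numeric(as.matrix(points)), ncol = 2)
  if (any(!is.finite(p))) validation_error("non-finite coordinates")
  cbind(transform$tx + transform$a * p[, 1] - transform$b * p[, 2],
        transform$ty + transform$b * p[, 1] + transform$a * p[, 2])
}

#' @rdname apply_helmert
#' @export
invert_helmert <- function(transform) {
  stopifnot(inherits(transform, "helmert"))
  s_inv <- 1 / transform$s
  th_inv <- -transform$theta
  a <- s_inv * cos(th_inv); b <- s_inv * sin(th_inv)
  helmert(tx = -(a * transform$tx - b * transform$ty),
          ty = -(b * transform$tx + a * transform$ty),
          s = s_inv, theta = th_inv,
          rms_residual = transform$rms_residual)
}

#' Calibrate optical aberration between two imaging paths
#'
#' Switching between the visible and infrared path (or between microscopes)
#' introduces anisotropic pixel scaling and a small rotation. From a grid of
#' point pairs (e.g. a 1951 USAF resolution target located in both images)
#' this fits `x' = tx + sx (x cos(phi) - y sin(phi))`,
#' `y' = ty + sy (x sin(phi) + y cos(phi))` by linear least squares and
#' reports per-axis pixel size and the rotation. Applied before the strictly
#' 4-parameter Helmert transfer.
#'
#' @param grid_pairs a [reference_points] with at least 4 pairs spanning
#'   both axes (source typically in pixel units, destination in micrometer).
#' @return object of class `aberration_calibration` with `pixel_size_x`,
#'   `pixel_size_y` (micrometer per source unit), `rotation_deg`, `tx`,
#'   `ty`, and per-point `residuals` (micrometer).
#' @export
calibrate_aberration <- function(grid_pairs) {
  stopifnot(inherits(grid_pairs, "reference_points"))
  n <- nrow(grid_pairs$source)
  if (n < 4L) conditioning_error("need >= 4 grid pairs, got %d", n)
  if (.max_triangle_area(grid_pairs$source) < 1e-9)
    conditioning_error("calibration grid points are collinear or coincident")
  x <- grid_pairs$source[, 1]; y <- grid_pairs$source[, 2]
  u <- grid_pairs$destination[, 1]; v <- grid_pairs$destination[, 2]
  # u = tx + a1 x - a2 y ; v = ty + b2 x + b1 y
  cu <- unname(qr.coef(qr(cbind(1, x, -y)), u))
  cv <- unname(qr.coef(qr(cbind(1, x, y)), v))
  a1 <- cu[2]; a2 <- cu[3]; ty <- cv[1]; b2 <- cv[2]; b1 <- cv[3]
  sx <- sqrt(a1^2 + a2^2); sy <- sqrt(b1^2 + b2^2)
  phi <- (atan2(a2, a1) + atan2(b2, b1)) / 2
  ru <- u - cbind(1, x, -y) %*% cu
  rv <- v - cbind(1, x, y) %*% cv
  structure(list(pixel_size_x = sx, pixel_size_y = sy,
                 rotation_deg = phi * 180 / pi,
                 tx = cu[1], ty = ty,
                 residuals = sqrt(ru^2 + rv^2)),
            class = "aberration_calibration")
}

#' @export
print.aberration_calibration <- function(x, ...) {
  cat(sprintf("<aberration_calibration> pixel %.6g x %.6g um, rotation %.6g deg, max residual %.3g um\n",
              x$pixel_size_x, x$pixel_size_y, x$rotation_deg, max(x$residuals)))
  invisible(x)
}

#' Select fragments so every sample pool reaches the same amide I integral
#'
#' Classically, equal dissected *areas* are pooled per sample; since the
#' amide I integral is proportional to protein concentration (Lambert-Beer),
#' pooling to a common target *integral* equalizes protein amounts instead.
#' For each sample a subset of its fragments is chosen whose summed
#' integral falls within `target +- tolerance`, by greedy largest-first
#' packing followed by single-swap refinement (exact subset-sum being
#' NP-hard).
#'
#' @param samples named list; each element either a numeric vector of
#'   fragment amide integrals or a list of `fragment` objects.
#' @param target_integral target summed integral (absorbance * cm^-1).
#' @param tolerance accepted deviation from the target; default 2% of it.
#' @return list per sample with `selected` (indices), `achieved` (summed
#'   integral), plus `spread`, the max pairwise difference of achieved
#'   integrals across samples.
#' @export
select_fragments_balanced <- function(samples, target_integral,
                                      tolerance = 0.02 * target_integral) {
  vals <- lapply(samples, function(s) {
    if (is.numeric(s)) s else vapply(s, `[[`, 0, "amide_integral_sum")
  })
  short <- names(vals)[vapply(vals, sum, 0) < target_integral - tolerance]
  if (length(short)) {
    mx <- vapply(vals[short], sum, 0)
    validation_error("target %.4g infeasible for sample(s): %s",
                     target_integral,
                     paste(sprintf("%s (max %.4g)", short, mx), collapse = ", "))
  }
  pick <- function(v) {
    o <- order(-v)
    sel <- logical(length(v))
    tot <- 0
    for (i in o) {
      if (tot + v[i] <= target_integral + tolerance) {
        sel[i] <- TRUE; tot <- tot + v[i]
        if (tot >= target_integral - tolerance) break
      }
    }
    # single-swap refinement toward the target
    repeat {
      err <- abs(tot - target_integral)
      if (err <= tolerance) break
      best <- c(0L, 0L); best_err <- err
      for (i in which(sel)) for (j in which(!sel)) {
        e <- abs(tot - v[i] + v[j] - target_integral)
        if (e < best_err - 1e-12) { best <- c(i, j); best_err <- e }
      }
      for (j in which(!sel)) {      # also consider pure additions/removals
        e <- abs(tot + v[j] - target_integral)
        if (e < best_err - 1e-12) { best <- c(0L, j); best_err <- e }
      }
      for (i in which(sel)) {
        e <- abs(tot - v[i] - target_integral)
        if (e < best_err - 1e-12) { best <- c(i, 0L); best_err <- e }
      }
      if (best_err >= err - 1e-12) break
      if (best[1]) { sel[best[1]] <- FALSE; tot <- tot - v[best[1]] }
      if (best[2]) { sel[best[2]] <- TRUE;  tot <- tot + v[best[2]] }
    }
    list(selected = which(sel), achieved = tot)
  }
  out <- lapply(vals, pick)
  ach <- vapply(out, `[[`, 0, "achieved")
  for (nm in names(out)) out[[nm]]$target <- target_integral
  attr(out, "achieved") <- ach
  attr(out, "spread") <- if (length(ach) > 1) max(ach) - min(ach) else 0
  out
}
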