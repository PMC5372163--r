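#' Quality-control parameters
#'
#' Per-pixel spectral QC rejects disrupted spectra (cracks, folds, blank
#' substrate, saturation) on two criteria: signal-to-noise ratio and the
#' amide I band integral, the latter proportional to protein content by the
#' Lambert-Beer law. Thresholds are configuration, not science; defaults are
#' chosen to reject blank and saturated pixels of the synthetic phantoms.
#'
#' @param noise_window wavenumber interval (cm^-1) for the noise estimate; a
#'   spectroscopically quiet region, default 2000-1800 cm^-1.
#' @param snr_min minimum signal-to-noise ratio.
#' @param amide_window wavenumber interval (cm^-1) of the amide I band.
#' @param amide_integral_min,amide_integral_max accepted amide I integral
#'   range (absorbance * cm^-1).
#' @return an object of class `qc_params`.
#' @export
qc_params <- function(noise_window = c(2000, 1800), snr_min = 10,
                      amide_window = c(1700, 1600),
                      amide_integral_min = 0.5, amide_integral_max = 60) {
  if (snr_min <= 0) validation_error("snr_min must be > 0")
  if (amide_integral_min >= amide_integral_max)
    validation_error("amide_integral_min must be < amide_integral_max")
  structure(list(noise_window = noise_window, snr_min = snr_min,
                 amide_window = amide_window,
                 amide_integral_min = amide_integral_min,
                 amide_integral_max = amide_integral_max),
            class = "qc_params")
}

.linear_baseline <- function(y, x) {
  # line through the first and last sample of the window (ascending x)
  n <- length(x)
  y[1] + (y[n] - y[1]) * (x - x[1]) / (x[n] - x[1])
}

#' Signal-to-noise ratio of one absorbance spectrum
#'
#' Signal is the maximum absorbance in `signal_window` above the linear
#' baseline through the window endpoints; noise is the standard deviation of
#' the residual after a linear detrend in `noise_window`. A spectrum with
#' zero noise yields `Inf` (treated as a pass downstream) unless it is
#' identically zero, which yields 0.
#'
#' @param spectrum numeric absorbance vector over `axis`.
#' @param axis a [wn_axis].
#' @param noise_window,signal_window wavenumber intervals (cm^-1).
#' @return a nonnegative (possibly infinite) ratio.
#' @export
estimate_snr <- function(spectrum, axis, noise_window = c(2000, 1800),
                         signal_window = c(1700, 1600)) {
  is_ <- wn_window(axis, signal_window)
  in_ <- wn_window(axis, noise_window)
  if (length(is_) < 2L || length(in_) < 3L)
    range_error("SNR windows must contain >= 2 (signal) / >= 3 (noise) samples")
  # ascending wavenumber inside each window
  os <- is_[order(axis$values[is_])]; on <- in_[order(axis$values[in_])]
  ys <- spectrum[os]
  sig <- max(ys - .linear_baseline(ys, axis$values[os]))
  fit <- stats::lm.fit(cbind(1, axis$values[on]), spectrum[on])
  noi <- stats::sd(fit$residuals)
  if (noi < .Machine$double.eps * 100) {
    if (max(abs(spectrum)) == 0) return(0)
    return(Inf)
  }
  max(sig, 0) / noi
}

#' Band integral of an absorbance spectrum
#'
#' Trapezoidal integral over a wavenumber window, optionally after
#' subtracting the linear baseline through the window endpoints. Linear in
#' the spectrum.
#'
#' @param spectrum numeric absorbance vector over `axis` (or a matrix with
#'   one spectrum per row).
#' @param axis a [wn_axis].
#' @param window wavenumber interval (cm^-1).
#' @param baseline `"none"` or `"linear"` (endpoint baseline).
#' @return integral(s) in absorbance * cm^-1.
#' @export
integrate_band <- function(spectrum, axis, window = c(1700, 1600),
                           baseline = c("none", "linear")) {
  baseline <- match.arg(baseline)
  idx <- wn_window(axis, window)
  if (length(idx) < 2L) range_error("integration window narrower than 2 samples")
  o <- idx[order(axis$values[idx])]
  x <- axis$values[o]
  tw <- .trapezoid_weights(x)
  one <- function(y) {
    if (baseline == "linear") y <- y - .linear_baseline(y, x)
    sum(tw * y)
  }
  if (is.matrix(spectrum)) {
    Y <- spectrum[, o, drop = FALSE]
    if (baseline == "linear") {
      n <- length(x)
      slope <- (Y[, n] - Y[, 1]) / (x[n] - x[1])
      Y <- Y - (Y[, 1] + outer(slope, x - x[1]))
    }
    as.vector(Y %*% tw)
  } else one(spectrum[o])
}

.trapezoid_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  d <- diff(x)
  w[1] <- d[1] / 2; w[n] <- d[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (d[-1] + d[-(n - 1)]) / 2
  w
}

#' Per-pixel spectral quality control of a hyperspectral image
#'
#' A pixel passes iff its SNR is at least `snr_min` and its amide I integral
#' lies in `[amide_integral_min, amide_integral_max]`. Failure codes
#' (`"amide-low"`, `"amide-high"`, `"snr"`, in that priority) are reported
#' per pixel. The mask is recomputed from the cube, so the operation is
#' idempotent.
#'
#' @param image a [spectral_image].
#' @param params a [qc_params].
#' @return list with the updated `image` (mask stored), the logical
#'   `qc_mask`, and a `report` (class `qc_report`) with counts and per-pixel
#'   codes.
#' @export
quality_control <- function(image, params = qc_params()) {
  stopifnot(inherits(image, "spectral_image"), inherits(params, "qc_params"))
  d <- dim(image$cube)
  Y <- matrix(image$cube, d[1] * d[2], d[3])
  axis <- image$axis

  amide <- integrate_band(Y, axis, params$amide_window, baseline = "none")

  is_ <- wn_window(axis, params$amide_window)
  in_ <- wn_window(axis, params$noise_window)
  os <- is_[order(axis$values[is_])]; on <- in_[order(axis$values[in_])]
  xs <- axis$values[os]; xn <- axis$values[on]
  Ys <- Y[, os, drop = FALSE]
  ns <- length(xs)
  slope <- (Ys[, ns] - Ys[, 1]) / (xs[ns] - xs[1])
  sig <- apply(Ys - (Ys[, 1] + outer(slope, xs - xs[1])), 1, max)
  X <- cbind(1, xn)
  H <- X %*% solve(crossprod(X), t(X))
  R <- Y[, on, drop = FALSE] %*% t(diag(length(on)) - H)
  noi <- sqrt(rowSums((R - rowMeans(R))^2) / (length(on) - 1))
  snr <- ifelse(noi < .Machine$double.eps * 100,
                ifelse(apply(abs(Y), 1, max) == 0, 0, Inf),
                pmax(sig, 0) / noi)

  codes <- rep("ok", nrow(Y))
  codes[snr < params$snr_min] <- "snr"
  codes[amide > params$amide_integral_max] <- "amide-high"
  codes[amide < params$amide_integral_min] <- "amide-low"
  mask <- matrix(codes == "ok", d[1], d[2])
  report <- structure(list(
    total = length(codes), n_pass = sum(codes == "ok"),
    n_fail = sum(codes != "ok"),
    by_code = table(factor(codes, levels = c("ok", "amide-low", "amide-high", "snr"))),
    codes = matrix(codes, d[1], d[2]),
    snr = matrix(snr, d[1], d[2]),
    amide_integral = matrix(amide, d[1], d[2])), class = "qc_report")
  image$qc_mask <- mask
  list(image = image, qc_mask = mask, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d/%d pixels pass (fail: %s)\n", x$n_pass, x$total,
              paste(sprintf("%s=%d", names(x$by_code)[-1], x$by_code[-1]),
                    collapse = ", ")))
  invisible(x)
}

#' Approximate Mie extinction efficiency (van de Hulst)
#'
#' `Q(rho) = 2 - (4/rho) sin(rho) + (4/rho^2)(1 - cos(rho))` with phase
#' `rho = 4 pi r nu (n - 1)` for sphere radius `r` (micrometer, converted to
#' cm) and real refractive index `n` at wavenumber `nu` (cm^-1). This
#' non-resonant approximation captures the broad oscillatory baseline that
#' sphere scattering superimposes on cellular absorbance spectra.
#'
#' @param nu wavenumbers (cm^-1).
#' @param r_um sphere radius in micrometer.
#' @param n refractive index (> 1).
#' @return extinction efficiency values.
#' @export
mie_extinction <- function(nu, r_um, n) {
  rho <- 4 * pi * (r_um * 1e-4) * nu * (n - 1)
  q <- 2 - (4 / rho) * sin(rho) + (4 / rho^2) * (1 - cos(rho))
  q[rho == 0] <- 0
  q
}

#' Principal-component basis of simulated Mie extinction curves
#'
#' Simulates van de Hulst extinction curves on a grid of sphere radii and
#' refractive indices, mean-centers them, and returns the leading
#' orthonormal principal components over the EMSC fit range. These
#' components span the family of physically plausible scattering baselines
#' and enter the EMSC design as interferent terms.
#'
#' @param axis a [wn_axis].
#' @param radius_range radius interval in micrometer.
#' @param n_range refractive-index interval.
#' @param grid_points grid points per parameter (total curves =
#'   `grid_points^2`).
#' @param k number of components to keep.
#' @param fit_range wavenumber interval of the EMSC fit (cm^-1).
#' @return object of class `mie_basis`: `components` (bands x k,
#'   orthonormal), `wavenumbers`, `mean_curve`, `explained` (fraction of
#'   variance), and the generating grid.
#' @export
build_mie_basis <- function(axis, radius_range = c(2, 8), n_range = c(1.1, 1.5),
                            grid_points = 10, k = 7, fit_range = c(2300, 950)) {
  if (any(radius_range <= 0) || any(n_range <= 1))
    validation_error("radius_range must be > 0 and n_range > 1")
  fit_range <- .clip_range(axis, fit_range)
  idx <- wn_window(axis, fit_range)
  nu <- axis$values[idx]
  rs <- seq(radius_range[1], radius_range[2], length.out = grid_points)
  ns <- seq(n_range[1], n_range[2], length.out = grid_points)
  grid <- expand.grid(r = rs, n = ns)
  if (k > nrow(grid))
    validation_error("k = %d exceeds the %d simulated curves", k, nrow(grid))
  curves <- t(mapply(function(r, n) mie_extinction(nu, r, n), grid$r, grid$n))
  mu <- colMeans(curves)
  centered <- sweep(curves, 2, mu)
  tot <- sum(centered^2)
  if (tot < 1e-20) {
    # degenerate grid: all curves identical; the common shape is the basis
    comp <- matrix(mu / sqrt(sum(mu^2)), ncol = 1)
    expl <- 1
  } else {
    pc <- stats::prcomp(curves, center = TRUE, scale. = FALSE)
    comp <- pc$rotation[, seq_len(k), drop = FALSE]
    expl <- sum(pc$sdev[seq_len(k)]^2) / sum(pc$sdev^2)
  }
  structure(list(components = comp, wavenumbers = nu, mean_curve = mu,
                 explained = expl, grid = grid, fit_range = fit_range),
            class = "mie_basis")
}

#' EMSC model for Mie / resonance-Mie scattering correction
#'
#' Extended multiplicative signal correction decomposes a measured spectrum
#' `z` over the fit range into `c * m + polynomial baseline + Mie
#' components + residual`, where `m` is a reference chemical spectrum. The
#' corrected spectrum is `(z - baseline - Mie part) / c`, i.e. the chemical
#' signal normalized to the reference scale.
#'
#' @param reference numeric reference spectrum over the full `axis`.
#' @param axis a [wn_axis].
#' @param mie_basis a [build_mie_basis] result on the same axis and fit
#'   range, or `NULL` to correct without scattering terms.
#' @param baseline_order polynomial baseline order (default 2).
#' @param fit_range wavenumber interval of the fit (cm^-1), default
#'   2300-950.
#' @param n_iterations number of reference-update iterations (>= 1). After
#'   each iteration the reference is replaced by the current corrected
#'   spectrum and the fit repeated.
#' @return object of class `emsc_model`.
#' @export
emsc_model <- function(reference, axis, mie_basis = NULL, baseline_order = 2,
                       fit_range = c(2300, 950), n_iterations = 1) {
  stopifnot(inherits(axis, "wn_axis"))
  if (length(reference) != length(axis))
    structural_error("reference length %d does not match axis length %d",
                     length(reference), length(axis))
  if (n_iterations < 1) validation_error("n_iterations must be >= 1")
  fit_range <- .clip_range(axis, fit_range)
  idx <- wn_window(axis, fit_range)
  if (!is.null(mie_basis)) {
    if (!isTRUE(all.equal(mie_basis$wavenumbers, axis$values[idx])))
      structural_error("mie_basis grid does not match the fit range of the axis")
  }
  nu <- axis$values[idx]
  nu_s <- (nu - mean(nu)) / stats::sd(nu)   # scaled for conditioning
  P <- outer(nu_s, 0:baseline_order, `^`)
  structure(list(reference = reference, axis = axis, fit_idx = idx,
                 poly = P, mie = mie_basis, baseline_order = baseline_order,
                 fit_range = fit_range, n_iterations = n_iterations),
            class = "emsc_model")
}

.emsc_design <- function(model, reference_fit) {
  G <- if (is.null(model$mie)) NULL else model$mie$components
  cbind(m = reference_fit, model$poly, G)
}

.emsc_fit_once <- function(Y, model, reference_fit, c_min) {
  D <- .emsc_design(model, reference_fit)
  qrD <- qr(D)
  B <- qr.coef(qrD, t(Y))                    # coefficients x pixels
  cc <- B[1, ]
  interf <- D[, -1, drop = FALSE] %*% B[-1, , drop = FALSE]
  corrected <- t((t(Y) - interf) / rep(cc, each = nrow(D)))
  list(corrected = corrected, coef = t(B), c = cc, degenerate = cc <= c_min)
}

#' Apply EMSC scattering correction
#'
#' Least-squares fit of each spectrum over the model's fit range; the output
#' spectra live on the fit-range grid (axis restricted accordingly). Pixels
#' whose multiplicative coefficient `c` falls at or below `c_min` are
#' flagged `"emsc-degenerate"` and, for images, removed from the QC mask
#' rather than corrected.
#'
#' @param x numeric spectrum over the model axis, a matrix with spectra in
#'   rows, or a [spectral_image].
#' @param model an [emsc_model].
#' @param c_min degeneracy threshold for the multiplicative coefficient.
#' @return for spectra: list with `corrected` (fit-range grid), `axis`,
#'   `coefficients` (c, baseline, Mie loadings) and `degenerate`; for
#'   images: list with the corrected `image` (fit-range axis, mask updated),
#'   `coefficients` and `degenerate` matrix.
#' @export
emsc_correct <- function(x, model, c_min = 1e-3) {
  UseMethod("emsc_correct")
}

#' @export
emsc_correct.default <- function(x, model, c_min = 1e-3) {
  Y <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(Y) == length(model$axis)) {
    Y <- Y[, model$fit_idx, drop = FALSE]
  } else if (ncol(Y) != length(model$fit_idx)) {
    structural_error("spectrum length %d matches neither axis (%d) nor fit range (%d)",
                     ncol(Y), length(model$axis), length(model$fit_idx))
  }
  ref <- model$reference[model$fit_idx]
  fit <- .emsc_fit_once(Y, model, ref, c_min)
  if (model$n_iterations > 1) {
    for (i in seq_len(nrow(Y))) {
      if (fit$degenerate[i]) next
      refi <- fit$corrected[i, ]
      for (it in 2:model$n_iterations) {
        f1 <- .emsc_fit_once(Y[i, , drop = FALSE], model, refi, c_min)
        if (f1$degenerate[1]) { fit$degenerate[i] <- TRUE; break }
        fit$corrected[i, ] <- f1$corrected[1, ]
        fit$coef[i, ] <- f1$coef[1, ]
        fit$c[i] <- f1$c[1]
        refi <- f1$corrected[1, ]
      }
    }
  }
  k <- if (is.null(model$mie)) 0 else ncol(model$mie$components)
  colnames(fit$coef) <- c("c", paste0("b", 0:model$baseline_order),
                          if (k) paste0("g", seq_len(k)))
  out_axis <- wn_axis(model$axis$values[model$fit_idx],
                      model$axis$nominal_resolution)
  res <- list(corrected = if (is.matrix(x)) fit$corrected else fit$corrected[1, ],
              axis = out_axis, coefficients = fit$coef, c = fit$c,
              degenerate = fit$degenerate)
  class(res) <- "emsc_result"
  res
}

#' @export
emsc_correct.spectral_image <- function(x, model, c_min = 1e-3) {
  d <- dim(x$cube)
  Y <- matrix(x$cube, d[1] * d[2], d[3])
  use <- as.vector(x$qc_mask)
  fit <- emsc_correct.default(Y[use, , drop = FALSE], model, c_min)
  nb <- length(model$fit_idx)
  cube <- array(0, c(d[1], d[2], nb))
  flat <- matrix(0, d[1] * d[2], nb)
  flat[use, ] <- fit$corrected
  cube[] <- flat
  mask <- x$qc_mask
  deg <- matrix(FALSE, d[1], d[2])
  deg[use] <- fit$degenerate
  mask[deg] <- FALSE
  cube[array(rep(deg, nb), c(d[1], d[2], nb))] <- 0
  img <- spectral_image(cube, fit$axis, pixel_size = x$pixel_size,
                        stage_origin = x$stage_origin, qc_mask = mask)
  list(image = img, coefficients = fit$coefficients, degenerate = deg)
}

#' Savitzky-Golay smoothing and derivatives
#'
#' Local polynomial least-squares filtering with the conventional 9-point
#' window. Edges are handled by reflect-padding (point-symmetric reflection
#' about the end sample, which keeps straight lines straight across the
#' boundary), so output length equals input length.
#' Derivatives are scaled by the actual wavenumber step, giving d^k A / d
#' nu^k in absorbance / (cm^-1)^k. Used for unsupervised exploration only;
#' the classifier consumes EMSC-corrected raw absorbance.
#'
#' @param spectra numeric vector, or matrix with one spectrum per row.
#' @param axis a [wn_axis] (needed to scale derivatives).
#' @param window_points odd window length (default 9).
#' @param poly_order polynomial order (default 3), `< window_points`.
#' @param deriv derivative order, 0 or 2 typical; `<= poly_order`.
#' @return transformed spectra, same shape as input.
#' @export
savitzky_golay <- function(spectra, axis, window_points = 9, poly_order = 3,
                           deriv = 0) {
  if (window_points %% 2 == 0) validation_error("window_points must be odd")
  if (poly_order >= window_points)
    validation_error("poly_order must be < window_points")
  if (deriv > poly_order) validation_error("deriv must be <= poly_order")
  F <- signal::sgolay(p = poly_order, n = window_points, m = deriv)
  h <- (window_points - 1L) / 2L
  row <- F[h + 1L, ]
  step <- diff(axis$values)[1]
  one <- function(y) {
    if (length(y) < window_points)
      validation_error("spectrum shorter than the filter window")
    B <- length(y)
    ypad <- c(2 * y[1] - y[(h + 1):2], y, 2 * y[B] - y[(B - 1):(B - h)])
    M <- stats::embed(ypad, window_points)   # row t = ypad[t+n-1], ..., ypad[t]
    as.vector(M %*% rev(row)) / step^deriv
  }
  if (is.matrix(spectra)) t(apply(spectra, 1, one)) else one(spectra)
}
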