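test_that("SNR handles degenerate spectra and calibrated noise", {
  ax <- default_axis()
  expect_equal(estimate_snr(rep(0.5, length(ax)), ax), Inf)  # constant: no noise
  expect_equal(estimate_snr(rep(0, length(ax)), ax), 0)      # blank: fails

  # Gaussian amide band of amplitude 1 with sigma = 0.01 noise: SNR near 100
  band <- exp(-(ax$values - 1654)^2 / (2 * 15^2))
  set.seed(42)
  snrs <- replicate(100, estimate_snr(band + rnorm(length(ax), 0, 0.01), ax))
  expect_gt(mean(snrs), 80)
  expect_lt(mean(snrs), 120)

  expect_error(estimate_snr(band, ax, noise_window = c(100, 200)),
               class = "ftirlcm_range_error")
})

test_that("band integration matches the analytic Gaussian integral and is linear", {
  ax <- default_axis()
  expect_equal(integrate_band(rep(0, length(ax)), ax), 0)

  a <- 1; s <- 15
  band <- a * exp(-(ax$values - 1654)^2 / (2 * s^2))
  got <- integrate_band(band, ax, c(1600, 1700))
  exact <- a * s * sqrt(2 * pi) *
    (pnorm((1700 - 1654) / s) - pnorm((1600 - 1654) / s))
  expect_lt(abs(got - exact) / exact, 0.005)

  expect_equal(integrate_band(3 * band, ax, c(1600, 1700)),
               3 * got, tolerance = 1e-14)

  # matrix input agrees with vector path
  M <- rbind(band, 2 * band)
  expect_equal(integrate_band(M, ax, c(1600, 1700)), c(got, 2 * got),
               tolerance = 1e-12)

  # endpoint baseline removes an additive offset exactly
  expect_equal(integrate_band(band + 0.2, ax, c(1600, 1700), baseline = "linear"),
               integrate_band(band, ax, c(1600, 1700), baseline = "linear"),
               tolerance = 1e-10)

  expect_error(integrate_band(band, ax, c(1654, 1655)),
               class = "ftirlcm_range_error")
})

test_that("quality control isolates exactly the planted defect pixels", {
  ph <- generate_phantom(phantom_spec(size = c(32, 32), seed = 7,
                                      n_blank = 10, n_saturated = 5))
  qc <- quality_control(ph$image)
  expect_setequal(which(qc$report$codes == "amide-low"), ph$defects$blank)
  expect_setequal(which(qc$report$codes == "amide-high"), ph$defects$saturated)
  expect_equal(qc$report$n_pass + qc$report$n_fail, qc$report$total)

  # idempotent: rerunning on the masked image reproduces the mask
  qc2 <- quality_control(qc$image)
  expect_identical(qc2$qc_mask, qc$qc_mask)

  # defect-free phantom with permissive thresholds passes everywhere
  clean <- generate_phantom(phantom_spec(size = c(16, 16), seed = 8,
                                         n_blank = 0, n_saturated = 0))
  qcc <- quality_control(clean$image,
                         qc_params(snr_min = 1, amide_integral_min = 0.01,
                                   amide_integral_max = 1e4))
  expect_true(all(qcc$qc_mask))
})

test_that("Mie basis is orthonormal and reconstructs its curves", {
  ax <- default_axis()
  basis <- build_mie_basis(ax, grid_points = 10, k = 7)
  G <- crossprod(basis$components)
  expect_lt(max(abs(G - diag(7))), 1e-10)

  # PCA reconstruction of every generated curve within 1% RMS
  curves <- t(mapply(function(r, n) mie_extinction(basis$wavenumbers, r, n),
                     basis$grid$r, basis$grid$n))
  centered <- sweep(curves, 2, basis$mean_curve)
  recon <- centered %*% basis$components %*% t(basis$components)
  err <- sqrt(rowMeans((centered - recon)^2))
  rms <- sqrt(rowMeans(curves^2))
  expect_lt(max(err / rms), 0.01)

  expect_error(build_mie_basis(ax, grid_points = 2, k = 7),
               class = "ftirlcm_validation_error")

  # degenerate single-point grid: the common shape itself, fully explained
  deg <- build_mie_basis(ax, radius_range = c(4, 4), n_range = c(1.3, 1.3),
                         grid_points = 3, k = 1)
  expect_equal(ncol(deg$components), 1)
  expect_equal(deg$explained, 1)
  q <- mie_extinction(deg$wavenumbers, 4, 1.3)
  cors <- abs(cor(deg$components[, 1], q))
  expect_gt(cors, 1 - 1e-10)
})

test_that("EMSC satisfies identity, scale and distortion-removal contracts", {
  ax <- default_axis()
  sig <- signature_spectrum(class_signatures()$epithelioid, ax)
  basis <- build_mie_basis(ax)
  mdl <- emsc_model(sig, ax, basis)

  r1 <- emsc_correct(sig, mdl)
  expect_equal(unname(r1$c), 1, tolerance = 1e-10)
  expect_lt(max(abs(r1$coefficients[1, -1])), 1e-8)
  expect_lt(max(abs(r1$corrected - sig[mdl$fit_idx])), 1e-10)

  r2 <- emsc_correct(2 * sig, mdl)
  expect_equal(unname(r2$c), 2, tolerance = 1e-10)
  expect_lt(max(abs(r2$corrected - sig[mdl$fit_idx])), 1e-8)

  # scale invariance on an arbitrary distorted spectrum
  dist <- sig + 0.3 * mie_extinction(ax$values, 4, 1.3) + 0.05
  ra <- emsc_correct(dist, mdl)
  rb <- emsc_correct(3.7 * dist, mdl)
  expect_equal(rb$corrected, ra$corrected, tolerance = 1e-9)
  expect_equal(unname(rb$c / ra$c), 3.7, tolerance = 1e-9)

  # scattering removal: at least 10x RMSE reduction vs the pure signature
  pure <- sig[mdl$fit_idx]
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(ra$corrected, pure), 0.1 * rmse(dist[mdl$fit_idx], pure))

  # 20-iteration EMSC is stationary after iteration 1 on undistorted input
  m20 <- emsc_model(sig, ax, basis, n_iterations = 20)
  r20 <- emsc_correct(sig, m20)
  expect_lt(max(abs(r20$corrected - r1$corrected)), 1e-10)

  # near-zero spectrum: degenerate c, flagged rather than corrected
  rd <- emsc_correct(rep(1e-9, length(ax)), mdl)
  expect_true(rd$degenerate)
})

test_that("EMSC on an image restricts the axis and drops degenerate pixels", {
  ph <- generate_phantom(phantom_spec(size = c(12, 12), seed = 3,
                                      n_blank = 2, n_saturated = 1))
  qc <- quality_control(ph$image)
  sig <- signature_spectrum(class_signatures()$stroma, ph$image$axis)
  mdl <- emsc_model(sig, ph$image$axis, build_mie_basis(ph$image$axis))
  res <- emsc_correct(qc$image, mdl)
  expect_equal(range(res$image$axis$values), c(952, 2300))
  expect_true(all(res$image$qc_mask <= qc$image$qc_mask))
  expect_true(all(is.finite(res$image$cube)))
})

test_that("Savitzky-Golay reproduces polynomials and Gaussian derivatives", {
  ax <- tiny_axis(200)
  nu <- ax$values

  line <- 0.3 + 0.002 * nu
  expect_lt(max(abs(savitzky_golay(line, ax, deriv = 2))), 1e-10)
  expect_equal(savitzky_golay(line, ax, deriv = 0), line, tolerance = 1e-10)

  quad <- 5e-4 * nu^2
  d2 <- savitzky_golay(quad, ax, deriv = 2)
  expect_lt(max(abs(d2[5:196] - 2 * 5e-4)) / (2 * 5e-4), 1e-8)

  g <- exp(-(nu - 1400)^2 / (2 * 30^2))
  d2g <- savitzky_golay(g, ax, deriv = 2)
  truth <- g * ((nu - 1400)^2 / 30^4 - 1 / 30^2)
  interior <- 10:190
  expect_gt(cor(d2g[interior], truth[interior]), 0.999)
  expect_lt(abs(which.min(d2g) - which.min(abs(nu - 1400))), 2)

  expect_error(savitzky_golay(g, ax, window_points = 8),
               class = "ftirlcm_validation_error")
  expect_error(savitzky_golay(g[1:5], ax),
               class = "ftirlcm_validation_error")
  expect_error(savitzky_golay(g, ax, poly_order = 1, deriv = 2),
               class = "ftirlcm_validation_error")
})
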