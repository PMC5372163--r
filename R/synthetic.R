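#' Synthetic tissue-class spectral signatures
#'
#' Each phantom tissue class is a sum of Gaussian absorbance bands plus an
#' offset. The defaults are three spectroscopically plausible but fully
#' synthetic "tissue" classes that differ in their amide I/II ratio, a
#' lipid-like 1740 cm^-1 band and a carbohydrate-like 1050 cm^-1 band;
#' every signature carries a positive amide I band near 1654 cm^-1 so that
#' quality control and the Lambert-Beer concentration proxy are meaningful.
#' No biological fidelity is claimed.
#'
#' @return named list of signatures; each has `bands` (data.frame `center`,
#'   `sigma`, `amplitude`) and `offset`.
#' @export
class_signatures <- function() {
  sig <- function(...) {
    b <- rbind(...)
    list(bands = data.frame(center = b[, 1], sigma = b[, 2], amplitude = b[, 3]),
         offset = 0)
  }
  list(
    epithelioid = sig(c(1654, 15, 0.80), c(1545, 12, 0.48), c(1740, 10, 0.10),
                      c(1240, 18, 0.18), c(1050, 20, 0.20)),
    sarcomatoid = sig(c(1654, 15, 0.80), c(1545, 12, 0.34), c(1740, 10, 0.28),
                      c(1240, 18, 0.26), c(1050, 20, 0.08)),
    stroma      = sig(c(1654, 15, 0.64), c(1545, 12, 0.42), c(1338, 14, 0.22),
                      c(1204, 12, 0.19), c(1050, 20, 0.13)))
}

#' Evaluate a class signature on a wavenumber axis
#'
#' @param signature one element of [class_signatures].
#' @param axis a [wn_axis].
#' @return absorbance vector.
#' @export
signature_spectrum <- function(signature, axis) {
  nu <- axis$values
  y <- rep(signature$offset, length(nu))
  for (i in seq_len(nrow(signature$bands))) {
    b <- signature$bands[i, ]
    y <- y + b$amplitude * exp(-(nu - b$center)^2 / (2 * b$sigma^2))
  }
  y
}

#' Phantom specification
#'
#' Describes a synthetic hyperspectral tissue image: class blobs on a
#' background, per-pixel concentration scaling (Lambert-Beer), an additive
#' Mie scattering baseline with per-pixel sphere parameters, Gaussian
#' noise, and planted defect pixels (blank and saturated) for QC tests.
#'
#' @param size image (rows, cols).
#' @param blobs named list per class: `list(count=, radius=c(min, max))` in
#'   pixels; classes are drawn in list order, later blobs overwrite.
#' @param background_class class name filling non-blob pixels, or `NULL`
#'   for empty (zero-absorbance) background.
#' @param concentration_range per-pixel concentration scaling interval.
#' @param mie_fraction amplitude of the Mie extinction baseline (0 = none).
#' @param mie_radius_range,mie_n_range per-pixel sphere parameter ranges;
#'   defaults match the correction basis grid.
#' @param noise_sd Gaussian absorbance noise standard deviation.
#' @param n_blank,n_saturated planted defect pixel counts.
#' @param seed mandatory integer seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = c(64, 64),
                         blobs = list(epithelioid = list(count = 6, radius = c(5, 10)),
                                      sarcomatoid = list(count = 6, radius = c(5, 10))),
                         background_class = "stroma",
                         concentration_range = c(0.7, 1.3),
                         mie_fraction = 0.05,
                         mie_radius_range = c(2, 8), mie_n_range = c(1.1, 1.5),
                         noise_sd = 0.005, n_blank = 10, n_saturated = 5,
                         seed) {
  if (missing(seed)) validation_error("phantom seed is mandatory")
  structure(list(size = size, blobs = blobs, background_class = background_class,
                 concentration_range = concentration_range,
                 mie_fraction = mie_fraction,
                 mie_radius_range = mie_radius_range, mie_n_range = mie_n_range,
                 noise_sd = noise_sd, n_blank = n_blank,
                 n_saturated = n_saturated, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a hyperspectral tissue phantom with known ground truth
#'
#' Per pixel the spectrum is `concentration * class signature +
#' mie_fraction * Q(nu; r, n) + noise`, with `(r, n)` drawn per pixel;
#' blank defect pixels are zeroed and saturated ones set to a constant
#' absorbance of 4. A pure function of its spec and seed.
#'
#' @param spec a [phantom_spec].
#' @param signatures named signature list, default [class_signatures].
#' @param axis a [wn_axis], default [default_axis].
#' @return list: `image` ([spectral_image], mask all-true), `truth`
#'   ([label_map], 0 at background and defects), `concentration` (matrix,
#'   zero outside tissue), `defects` (pixel index lists).
#' @export
generate_phantom <- function(spec, signatures = class_signatures(),
                             axis = default_axis()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  nr <- spec$size[1]; nc <- spec$size[2]; nb <- length(axis)
  cls_names <- names(signatures)
  used <- union(names(spec$blobs), spec$background_class)
  bad <- setdiff(used, cls_names)
  if (length(bad)) validation_error("no signature for class(es): %s",
                                    paste(bad, collapse = ", "))
  labels <- matrix(0L, nr, nc)
  if (!is.null(spec$background_class))
    labels[] <- match(spec$background_class, cls_names)
  rr <- matrix(rep(seq_len(nr), nc), nr, nc)
  cc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  for (cl in names(spec$blobs)) {
    b <- spec$blobs[[cl]]
    id <- match(cl, cls_names)
    for (i in seq_len(b$count)) {
      ctr <- c(stats::runif(1, 1, nr), stats::runif(1, 1, nc))
      rad <- stats::runif(1, b$radius[1], b$radius[2])
      labels[(rr - ctr[1])^2 + (cc - ctr[2])^2 <= rad^2] <- id
    }
  }
  conc <- matrix(stats::runif(nr * nc, spec$concentration_range[1],
                              spec$concentration_range[2]), nr, nc)
  conc[labels == 0L] <- 0

  sigs <- vapply(signatures, signature_spectrum, numeric(nb), axis = axis)
  flat <- matrix(0, nr * nc, nb)
  lv <- as.vector(labels)
  for (id in sort(unique(lv[lv > 0])))
    flat[lv == id, ] <- outer(as.vector(conc)[lv == id], sigs[, id])
  if (spec$mie_fraction > 0) {
    r <- stats::runif(nr * nc, spec$mie_radius_range[1], spec$mie_radius_range[2])
    n <- stats::runif(nr * nc, spec$mie_n_range[1], spec$mie_n_range[2])
    tissue <- lv > 0
    for (i in which(tissue))
      flat[i, ] <- flat[i, ] + spec$mie_fraction * mie_extinction(axis$values, r[i], n[i])
  }
  if (spec$noise_sd > 0)
    flat <- flat + matrix(stats::rnorm(nr * nc * nb, 0, spec$noise_sd), nr * nc, nb)

  tissue_idx <- which(lv > 0)
  n_def <- spec$n_blank + spec$n_saturated
  defects <- list(blank = integer(0), saturated = integer(0))
  if (n_def > 0) {
    if (n_def > length(tissue_idx))
      validation_error("more defects requested than tissue pixels")
    picked <- sample(tissue_idx, n_def)
    defects$blank <- sort(picked[seq_len(spec$n_blank)])
    defects$saturated <- sort(picked[spec$n_blank + seq_len(spec$n_saturated)])
    flat[defects$blank, ] <- 0
    flat[defects$saturated, ] <- 4
    lv[picked] <- 0L
    conc[picked] <- 0
  }
  truth_labels <- matrix(lv, nr, nc)
  legend <- data.frame(label = seq_along(cls_names), class = cls_names,
                       color = .class_palette(length(cls_names)))
  image <- spectral_image(array(flat, c(nr, nc, nb)), axis,
                          pixel_size = c(5.65, 5.75), stage_origin = c(0, 0))
  list(image = image,
       truth = label_map(truth_labels, legend),
       concentration = conc,
       defects = defects)
}

#' Generate reference point pairs under a known transform
#'
#' Source points are drawn uniformly (re-drawn until non-collinear);
#' destinations are the transformed sources plus isotropic Gaussian noise.
#'
#' @param true_transform a [helmert].
#' @param n number of pairs (>= 3).
#' @param noise_sd isotropic destination noise (micrometer).
#' @param seed integer seed.
#' @param extent source coordinate interval (micrometer).
#' @return a [reference_points].
#' @export
generate_reference_points <- function(true_transform, n = 3, noise_sd = 0,
                                      seed = 1, extent = c(0, 1000)) {
  stopifnot(inherits(true_transform, "helmert"), n >= 3)
  set.seed(seed)
  repeat {
    src <- cbind(stats::runif(n, extent[1], extent[2]),
                 stats::runif(n, extent[1], extent[2]))
    if (.max_triangle_area(src) > 0.01 * diff(range(extent))^2 / 100) break
  }
  dst <- apply_helmert(true_transform, src)
  if (noise_sd > 0) dst <- dst + matrix(stats::rnorm(2 * n, 0, noise_sd), n, 2)
  reference_points(src, dst, frames = c("ftir", "lcm"))
}

#' Generate a protein abundance table with planted group effects
#'
#' Log-normal baseline abundances; the first `n_de` proteins carry a
#' multiplicative group effect (positive signed effect = higher in group A,
#' negative = higher in group B); every run adds unit-mean log-normal noise
#' at the stated coefficient of variation. Technical replicates of a
#' biological sample share the sample id.
#'
#' @param n_proteins number of proteins.
#' @param n_a,n_b biological samples per group (groups "A" and "B").
#' @param replicates technical replicates per sample.
#' @param n_de number of differential proteins (0 gives a null table).
#' @param effects signed fold changes for the differential proteins
#'   (recycled).
#' @param cv run-level coefficient of variation.
#' @param frac_two_peptides fraction of proteins with >= 2 unique peptides.
#' @param seed integer seed.
#' @return list: `table` (a [protein_table]) and `truth` (data.frame
#'   `accession`, `signed_effect`).
#' @export
generate_protein_table <- function(n_proteins = 1000, n_a = 6, n_b = 4,
                                   replicates = 3, n_de = 0, effects = 4,
                                   cv = 0.1, frac_two_peptides = 0.8,
                                   seed = 1) {
  if (n_de > n_proteins) validation_error("n_de exceeds n_proteins")
  if (cv < 0 || any(abs(effects) < 1 & effects != 0))
    validation_error("cv must be >= 0 and |effects| >= 1")
  set.seed(seed)
  acc <- sprintf("SYN%04d", seq_len(n_proteins))
  genes <- sprintf("GENE%d", seq_len(n_proteins))
  up <- ifelse(stats::runif(n_proteins) < frac_two_peptides,
               sample(2:12, n_proteins, replace = TRUE), 1L)
  base <- stats::rlnorm(n_proteins, meanlog = log(1e5), sdlog = 1)
  eff <- rep_len(effects, n_de)
  samples <- c(sprintf("A%d", seq_len(n_a)), sprintf("B%d", seq_len(n_b)))
  groups <- c(rep("A", n_a), rep("B", n_b))
  design <- data.frame(
    run = as.vector(t(outer(samples, seq_len(replicates),
                            function(s, r) sprintf("%s_r%d", s, r)))),
    sample = rep(samples, each = replicates),
    group = rep(groups, each = replicates),
    replicate = rep(seq_len(replicates), length(samples)))
  sdlog <- sqrt(log(1 + cv^2))
  M <- matrix(0, n_proteins, nrow(design))
  for (j in seq_len(nrow(design))) {
    mult <- rep(1, n_proteins)
    if (n_de > 0) {
      if (design$group[j] == "A") mult[seq_len(n_de)] <- ifelse(eff > 0, abs(eff), 1)
      else mult[seq_len(n_de)] <- ifelse(eff < 0, abs(eff), 1)
    }
    noise <- stats::rlnorm(n_proteins, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    M[, j] <- base * mult * noise
  }
  colnames(M) <- design$run
  tab <- protein_table(data.frame(accession = acc, gene = genes,
                                  unique_peptides = up),
                       M, design)
  truth <- data.frame(accession = acc[seq_len(n_de)],
                      signed_effect = eff)
  list(table = tab, truth = truth)
}
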