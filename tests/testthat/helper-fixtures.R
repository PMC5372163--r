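# shared fixtures, all generated in code

# short ascending-free descending axis for cheap spectral tests
tiny_axis <- function(n = 120, from = 1800, step = 4) {
  wn_axis(seq(from, by = -step, length.out = n), nominal_resolution = step)
}

# signatures extended with a fourth, "normal"-like class for 3-level cascades
four_class_signatures <- function() {
  sigs <- class_signatures()
  sigs$normal <- list(
    bands = data.frame(center = c(1654, 1545, 1460, 1080),
                       sigma = c(15, 12, 10, 22),
                       amplitude = c(0.70, 0.40, 0.20, 0.22)),
    offset = 0)
  sigs
}

# QC + EMSC preprocessing with a fixed mean-tissue reference
preprocess_phantom <- function(ph, n_iterations = 1) {
  qc <- quality_control(ph$image)
  img <- qc$image
  flat <- matrix(img$cube, prod(dim(img$cube)[1:2]), dim(img$cube)[3])
  ref <- colMeans(flat[as.vector(img$qc_mask), , drop = FALSE])
  mdl <- emsc_model(ref, img$axis, build_mie_basis(img$axis),
                    n_iterations = n_iterations)
  emsc_correct(img, mdl)$image
}

two_level_spec <- function(ntree = 200) {
  cascade_spec(list(
    cascade_level("tissue", c("tumour", "stroma"), ntree = ntree),
    cascade_level("subtype", c("epithelioid", "sarcomatoid"),
                  parents = c("tumour", "tumour"), ntree = ntree)))
}

# truth classes of the QC-passing feature rows of a phantom
truth_classes <- function(X, truth) {
  px <- attr(X, "pixels")
  truth$legend$class[match(truth$labels[cbind(px$row, px$col)],
                           truth$legend$label)]
}

table1_fixture <- function() {
  read.csv(system.file("extdata", "table1_ranking.csv", package = "ftirlcm"),
           stringsAsFactors = FALSE)
}

# per-pixel phantom classification accuracy of a trained cascade
phantom_accuracy <- function(cascade, test_ph) {
  img <- preprocess_phantom(test_ph)
  pred <- predict_cascade(img, cascade)
  sel <- img$qc_mask & test_ph$truth$labels > 0
  pc <- pred$legend$class[match(pred$labels[sel], pred$legend$label)]
  tc <- test_ph$truth$legend$class[match(test_ph$truth$labels[sel],
                                         test_ph$truth$legend$label)]
  mean(pc == tc)
}
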