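#' Specification of a hierarchical classifier cascade
#'
#' Tissue annotation proceeds through an ordered sequence of random-forest
#' classifiers: the first separates coarse (e.g. pathologic vs. normal)
#' regions, each later level refines one parent class of the previous level
#' into finer classes (tumour classes, then tumour subtypes). The hierarchy
#' is data-configured, not hard-coded to any one tumour entity.
#'
#' @param levels list of levels built with [cascade_level].
#' @return object of class `cascade_spec`.
#' @export
cascade_spec <- function(levels) {
  stopifnot(length(levels) >= 1L)
  for (l in seq_along(levels)) {
    lv <- levels[[l]]
    if (!inherits(lv, "cascade_level")) validation_error("level %d is not a cascade_level", l)
    if (l == 1L) {
      if (!is.null(lv$parents)) validation_error("level 1 must not declare parents")
    } else {
      prev <- levels[[l - 1L]]$classes
      bad <- setdiff(unique(lv$parents), prev)
      if (length(bad))
        validation_error("level %d parent(s) not in level %d classes: %s",
                         l, l - 1L, paste(bad, collapse = ", "))
    }
    if (anyDuplicated(lv$classes))
      validation_error("duplicate class label within level %d", l)
  }
  all_cls <- unlist(lapply(levels, `[[`, "classes"))
  if (anyDuplicated(all_cls)) validation_error("class labels must be unique across levels")
  structure(list(levels = levels), class = "cascade_spec")
}

#' @rdname cascade_spec
#' @param name level name.
#' @param classes character vector of class labels at this level.
#' @param parents character vector parallel to `classes`, the parent class
#'   of each (previous level); `NULL` for level 1.
#' @param ntree,mtry random-forest hyperparameters (`mtry` default
#'   `floor(sqrt(bands))`).
#' @param feature_range wavenumber interval of classifier features, default
#'   the 1800-950 cm^-1 fingerprint region.
#' @export
cascade_level <- function(name, classes, parents = NULL, ntree = 200,
                          mtry = NULL, feature_range = c(1800, 950)) {
  if (!is.null(parents) && length(parents) != length(classes))
    validation_error("parents must parallel classes")
  structure(list(name = name, classes = classes, parents = parents,
                 ntree = ntree, mtry = mtry, feature_range = feature_range),
            class = "cascade_level")
}

# classes never refined at a later level are terminal (carry final labels)
.terminal_classes <- function(spec) {
  refined <- unlist(lapply(spec$levels[-1], `[[`, "parents"))
  unlist(lapply(spec$levels, function(lv) setdiff(lv$classes, refined)))
}

# ancestor of terminal class `cls` at level `l` (NA if its branch starts deeper)
.ancestor <- function(spec, cls, l) {
  lev_of <- function(x) which(vapply(spec$levels, function(lv) x %in% lv$classes, TRUE))
  cur_l <- lev_of(cls); cur <- cls
  if (!length(cur_l) || cur_l < l) return(NA_character_)
  while (cur_l > l) {
    lv <- spec$levels[[cur_l]]
    cur <- lv$parents[match(cur, lv$classes)]
    cur_l <- cur_l - 1L
  }
  cur
}

#' Extract the per-pixel classifier feature matrix
#'
#' Rows are the QC-passing pixels in row-major order (an index back-map is
#' attached); columns are the bands inside `range` in descending wavenumber
#' order. The image must already be scattering-corrected.
#'
#' @param image a [spectral_image] (EMSC-corrected).
#' @param range wavenumber interval, default the fingerprint region.
#' @return numeric matrix with attributes `pixels` (data.frame `row`,
#'   `col`) and `wavenumbers`.
#' @export
extract_features <- function(image, range = c(1800, 950)) {
  stopifnot(inherits(image, "spectral_image"))
  if (!any(image$qc_mask)) stopf("no usable pixels (empty QC mask)")
  idx <- wn_window(image$axis, .clip_range(image$axis, range))
  idx <- idx[order(-image$axis$values[idx])]
  rc <- which(image$qc_mask, arr.ind = TRUE)
  rc <- rc[order(rc[, 1], rc[, 2]), , drop = FALSE]
  d <- dim(image$cube)
  flat <- matrix(image$cube, d[1] * d[2], d[3])
  lin <- (rc[, 2] - 1L) * d[1] + rc[, 1]
  X <- flat[lin, idx, drop = FALSE]
  colnames(X) <- format(image$axis$values[idx], trim = TRUE)
  attr(X, "pixels") <- data.frame(row = rc[, 1], col = rc[, 2])
  attr(X, "wavenumbers") <- image$axis$values[idx]
  X
}

#' Train a random-forest classifier cascade
#'
#' One forest is fitted per refinement node: level 1 gets one forest over
#' its classes; at deeper levels each refined parent class gets a forest
#' over its children, trained only on pixels whose ancestry passes through
#' that parent. Class imbalance is handled by balanced per-class
#' subsampling within each forest. Training is deterministic given `seed`.
#'
#' @param training either a feature matrix (from [extract_features]) with a
#'   parallel `labels` vector, or a list of `list(features=, labels=)`
#'   pairs that are concatenated.
#' @param labels character vector of terminal class labels per feature row
#'   (ignored when `training` is a list of pairs).
#' @param spec a [cascade_spec].
#' @param seed integer master seed.
#' @param min_train_pixels minimum training examples per class.
#' @return object of class `trained_cascade`.
#' @export
train_cascade <- function(training, labels = NULL, spec, seed = 1,
                          min_train_pixels = 100) {
  if (is.list(training) && !is.matrix(training)) {
    X <- do.call(rbind, lapply(training, `[[`, "features"))
    y <- unlist(lapply(training, `[[`, "labels"))
    wns <- attr(training[[1]]$features, "wavenumbers")
  } else {
    X <- training; y <- labels
    wns <- attr(training, "wavenumbers")
  }
  if (is.null(wns)) wns <- as.numeric(colnames(X))
  stopifnot(inherits(spec, "cascade_spec"), length(y) == nrow(X))
  terminals <- .terminal_classes(spec)
  bad <- setdiff(unique(y), terminals)
  if (length(bad))
    validation_error("label(s) present in data but absent from cascade spec: %s",
                     paste(bad, collapse = ", "))

  forests <- list(); counts <- list()
  for (l in seq_along(spec$levels)) {
    lv <- spec$levels[[l]]
    anc <- vapply(terminals, .ancestor, "", spec = spec, l = l)
    ylev <- unname(anc[match(y, terminals)])
    groups <- if (l == 1L) list(`<root>` = lv$classes) else
      split(lv$classes, lv$parents)
    for (parent in names(groups)) {
      cls <- groups[[parent]]
      sel <- if (l == 1L) !is.na(ylev) else
        !is.na(ylev) & ylev %in% cls
      key <- sprintf("L%d:%s", l, parent)
      if (length(cls) < 2L) { forests[[key]] <- list(level = l, parent = parent, classes = cls, forest = NULL); next }
      ysub <- factor(ylev[sel], levels = cls)
      tab <- table(ysub)
      low <- names(tab)[tab < min_train_pixels]
      if (length(low))
        validation_error("class(es) with fewer than %d training pixels: %s",
                         min_train_pixels, paste(low, collapse = ", "))
      Xsub <- X[sel, , drop = FALSE]
      idx <- which(wns >= min(lv$feature_range) & wns <= max(lv$feature_range))
      set.seed(derive_seed(seed, key))
      rf <- randomForest::randomForest(
        x = Xsub[, idx, drop = FALSE], y = ysub,
        ntree = lv$ntree,
        mtry = lv$mtry %||% max(1L, floor(sqrt(length(idx)))),
        strata = ysub, sampsize = rep(min(tab), length(tab)))
      forests[[key]] <- list(level = l, parent = parent, classes = cls,
                             forest = rf, grid = wns[idx])
      counts[[key]] <- tab
    }
  }
  code <- seq_along(terminals)
  names(code) <- terminals
  structure(list(spec = spec, forests = forests, terminal_classes = terminals,
                 codes = code, grid = wns, seed = seed,
                 class_counts = counts),
            class = "trained_cascade")
}

#' @export
print.trained_cascade <- function(x, ...) {
  cat(sprintf("<trained_cascade> %d level(s), %d forest(s), terminal classes: %s\n",
              length(x$spec$levels),
              sum(!vapply(x$forests, function(f) is.null(f$forest), TRUE)),
              paste(x$terminal_classes, collapse = ", ")))
  invisible(x)
}

.class_palette <- function(n) {
  pal <- c("#1f77b4", "#2ca02c", "#d62728", "#ff7f0e", "#9467bd", "#8c564b",
           "#e377c2", "#7f7f7f", "#bcbd22", "#17becf")
  rep_len(pal, n)
}

#' Classify every usable pixel of an image with a trained cascade
#'
#' QC-failed pixels receive label 0. Each passing pixel descends the
#' hierarchy: its level-1 class is predicted first, and deeper forests are
#' applied only to pixels whose previous-level class is the parent they
#' refine, so no pixel can carry a leaf label whose parent it was not
#' assigned. The feature grid must match the training grid exactly; there
#' is no silent resampling.
#'
#' @param image a preprocessed (QC + EMSC) [spectral_image].
#' @param cascade a [train_cascade] result.
#' @return a [label_map] with the terminal-class legend.
#' @export
predict_cascade <- function(image, cascade) {
  stopifnot(inherits(cascade, "trained_cascade"))
  rng <- range(cascade$grid)
  X <- extract_features(image, rng)
  wns <- attr(X, "wavenumbers")
  if (length(wns) != length(cascade$grid) ||
      max(abs(wns - cascade$grid)) > 1e-9)
    structural_error("image wavenumber grid does not match the training grid")
  px <- attr(X, "pixels")
  cur <- rep(NA_character_, nrow(X))
  level_labels <- matrix(NA_character_, nrow(X), length(cascade$spec$levels))
  for (l in seq_along(cascade$spec$levels)) {
    keys <- names(cascade$forests)[vapply(cascade$forests, function(f) f$level == l, TRUE)]
    for (key in keys) {
      f <- cascade$forests[[key]]
      sel <- if (l == 1L) rep(TRUE, nrow(X)) else !is.na(cur) & cur == f$parent
      if (!any(sel)) next
      if (is.null(f$forest)) { cur[sel] <- f$classes } else {
        sub <- which(wns >= min(f$grid) & wns <= max(f$grid))
        cur[sel] <- as.character(stats::predict(f$forest, X[sel, sub, drop = FALSE]))
      }
      level_labels[sel, l] <- cur[sel]
    }
  }
  labels <- matrix(0L, nrow(image$qc_mask), ncol(image$qc_mask))
  labels[cbind(px$row, px$col)] <- unname(cascade$codes[cur])
  legend <- data.frame(label = unname(cascade$codes),
                       class = names(cascade$codes),
                       color = .class_palette(length(cascade$codes)))
  map <- label_map(labels, legend)
  # per-level assignment trail of each classified pixel, for auditing the
  # cascade-restriction property
  colnames(level_labels) <- paste0("L", seq_along(cascade$spec$levels))
  attr(map, "level_labels") <- cbind(px, as.data.frame(level_labels))
  map
}

#' Binary classification metrics against reference calls
#'
#' Computes the confusion matrix and accuracy, sensitivity and specificity
#' (percent, full precision retained; rounded to the nearest integer for
#' display).
#'
#' @param predicted,truth equal-length vectors of per-sample calls.
#' @param positive_class the class counted as positive.
#' @return object of class `eval_report` with `confusion`, `accuracy`,
#'   `sensitivity`, `specificity` (percent).
#' @export
evaluate <- function(predicted, truth, positive_class) {
  if (length(predicted) == 0L || length(predicted) != length(truth))
    validation_error("predicted and truth must be equal-length, non-empty")
  pp <- predicted == positive_class
  tp <- sum(pp & truth == positive_class)
  tn <- sum(!pp & truth != positive_class)
  fp <- sum(pp & truth != positive_class)
  fn <- sum(!pp & truth == positive_class)
  conf <- matrix(c(tp, fp, fn, tn), 2, 2,
                 dimnames = list(truth = c("positive", "negative"),
                                 predicted = c("positive", "negative")))
  structure(list(confusion = conf,
                 accuracy = 100 * (tp + tn) / length(truth),
                 sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %d%% (sensitivity %d%%, specificity %d%%)\n",
              round(x$accuracy), round(x$sensitivity), round(x$specificity)))
  print(x$confusion)
  invisible(x)
}

#' Sample-level diagnosis from a pixel-level label map
#'
#' Returns the candidate class with the largest pixel count and its
#' fraction of all candidate-class pixels. When a `mixed_pair` is given
#' (e.g. the epithelioid and sarcomatoid subtypes) and both members reach
#' `mixed_threshold`, the sample is called by `mixed_label` ("biphasic")
#' with the majority member reported.
#'
#' @param map a [label_map].
#' @param candidate_classes class names competing for the call.
#' @param mixed_pair optional length-2 class names whose co-occurrence
#'   defines a mixed diagnosis.
#' @param mixed_threshold minimum fraction of each pair member, default 0.20.
#' @param mixed_label call emitted for a mixed sample.
#' @return list with `call`, `majority_class`, `fraction`, and the full
#'   `fractions` vector.
#' @export
majority_sample_call <- function(map, candidate_classes, mixed_pair = NULL,
                                 mixed_threshold = 0.20,
                                 mixed_label = "biphasic") {
  stopifnot(inherits(map, "label_map"))
  ids <- map$legend$label[match(candidate_classes, map$legend$class)]
  if (anyNA(ids)) validation_error("candidate class(es) absent from legend: %s",
                                   paste(candidate_classes[is.na(ids)], collapse = ", "))
  counts <- vapply(ids, function(i) sum(map$labels == i), 0L)
  names(counts) <- candidate_classes
  if (sum(counts) == 0L) validation_error("no candidate-class pixels in map")
  fr <- counts / sum(counts)
  maj <- candidate_classes[which.max(counts)]
  call <- maj
  if (!is.null(mixed_pair) && all(mixed_pair %in% candidate_classes) &&
      all(fr[mixed_pair] >= mixed_threshold))
    call <- mixed_label
  list(call = call, majority_class = maj, fraction = unname(fr[maj]),
       fractions = fr)
}
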