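#' Inverse hyperbolic sine transform of protein abundances
#'
#' `y = ln(x + sqrt(x^2 + 1))`, a variance-stabilizing transform for
#' nonnegative label-free abundances (behaves like `log(2x)` for large `x`
#' while being defined at zero). Monotonic and invertible by `sinh`.
#'
#' @param x a [protein_table] or a nonnegative numeric vector/matrix.
#' @return same shape as the input, transformed; a `protein_table` keeps
#'   its design.
#' @export
arcsinh_transform <- function(x) {
  if (inherits(x, "protein_table")) {
    x$abundance <- asinh(x$abundance)
    attr(x, "transformed") <- TRUE
    return(x)
  }
  if (any(x < 0)) validation_error("negative abundance values")
  asinh(x)
}

#' Average technical replicates into one value per biological sample
#'
#' @param table a [protein_table] (transformed or raw).
#' @return list: `values` (proteins x samples matrix), `samples`
#'   (data.frame `sample`, `group`).
#' @export
average_replicates <- function(table) {
  stopifnot(inherits(table, "protein_table"))
  ds <- table$design
  samples <- unique(ds$sample)
  empty <- setdiff(samples, ds$sample[!is.na(ds$replicate)])
  if (length(empty)) validation_error("sample(s) without replicates: %s",
                                      paste(empty, collapse = ", "))
  V <- vapply(samples, function(s)
    rowMeans(table$abundance[, ds$sample == s, drop = FALSE]),
    numeric(nrow(table$abundance)))
  colnames(V) <- samples
  grp <- ds$group[match(samples, ds$sample)]
  list(values = V, samples = data.frame(sample = samples, group = grp))
}

#' Per-protein equal-variance two-sample t-test
#'
#' Classical pooled-variance Student t with `n1 + n2 - 2` degrees of
#' freedom, two-sided, applied per protein to replicate-averaged
#' (transformed-scale) sample values. Zero pooled variance yields p = 1 if
#' the group means agree and a degenerate flag with a vanishing p
#' otherwise.
#'
#' @param values proteins x samples matrix (transformed scale).
#' @param groups character vector per column of `values`.
#' @param group_a,group_b the two group labels (defaults: first two).
#' @return data.frame `t`, `p_value`, `degenerate` per protein.
#' @export
differential_test <- function(values, groups,
                              group_a = unique(groups)[1],
                              group_b = unique(groups)[2]) {
  ia <- which(groups == group_a); ib <- which(groups == group_b)
  if (length(ia) < 2L || length(ib) < 2L)
    validation_error("each group needs >= 2 biological samples")
  res <- t(apply(values, 1, function(v) {
    a <- v[ia]; b <- v[ib]
    sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
      (length(a) + length(b) - 2)
    if (sp2 < .Machine$double.eps * max(1, mean(v)^2)) {
      if (isTRUE(all.equal(mean(a), mean(b)))) return(c(0, 1, 0))
      return(c(Inf * sign(mean(a) - mean(b)), .Machine$double.xmin, 1))
    }
    ht <- stats::t.test(a, b, var.equal = TRUE)
    c(ht$statistic, ht$p.value, 0)
  }))
  data.frame(t = res[, 1], p_value = res[, 2], degenerate = res[, 3] > 0,
             row.names = rownames(values))
}

#' Per-protein fold change between two groups
#'
#' Computed on the untransformed normalized-abundance scale from
#' replicate-averaged sample values (the `"back-transformed"` alternative
#' applies `sinh` to transformed-scale means first). `fold_change` is the
#' ratio of group means folded to `>= 1`; `signed_fc` carries the
#' direction as a sign (`-fc` when group B is higher), matching the
#' "fold change >= 2 or <= -2" reporting convention.
#'
#' @param values proteins x samples matrix on the scale selected by
#'   `scale`.
#' @param groups character vector per column.
#' @param group_a,group_b group labels.
#' @param scale `"normalized"` (values already untransformed) or
#'   `"back-transformed"` (`sinh` applied first).
#' @return data.frame `ratio`, `fold_change`, `direction`, `signed_fc`,
#'   `excluded` (zero group mean).
#' @export
fold_change <- function(values, groups,
                        group_a = unique(groups)[1],
                        group_b = unique(groups)[2],
                        scale = c("normalized", "back-transformed")) {
  scale <- match.arg(scale)
  if (scale == "back-transformed") values <- sinh(values)
  ia <- which(groups == group_a); ib <- which(groups == group_b)
  ma <- rowMeans(values[, ia, drop = FALSE])
  mb <- rowMeans(values[, ib, drop = FALSE])
  excluded <- ma <= 0 | mb <= 0
  r <- ifelse(excluded, NA_real_, ma / mb)
  fc <- pmax(r, 1 / r)
  dirn <- ifelse(r >= 1, paste0(group_a, "-higher"), paste0(group_b, "-higher"))
  data.frame(ratio = r, fold_change = fc, direction = dirn,
             signed_fc = ifelse(r >= 1, fc, -fc), excluded = excluded,
             row.names = rownames(values))
}

#' Euclidean ranking distance in the volcano plane
#'
#' `d = sqrt((log10 p)^2 + (log10 FC)^2)`: the distance of a protein from
#' the origin of the volcano plane (signed log10 fold change against
#' -log10 p), combining effect size and significance into a single ranking
#' score. Monotonic: decreasing p or increasing fold change never
#' decreases d.
#'
#' @param p_value p-values in (0, 1].
#' @param fc unsigned fold changes, >= 1.
#' @return nonnegative distances.
#' @export
euclidean_rank <- function(p_value, fc) {
  if (any(p_value <= 0 | p_value > 1, na.rm = TRUE))
    validation_error("p-values must lie in (0, 1]")
  if (any(fc < 1, na.rm = TRUE))
    validation_error("fold changes must be >= 1 (unsigned)")
  sqrt(log10(p_value)^2 + log10(fc)^2)
}

#' Significance filter for differential abundance
#'
#' A protein is significant iff it was quantified with at least
#' `min_unique_peptides` unique peptides, `|signed fold change| >=
#' min_fold_change`, and `p <= max_p`.
#'
#' @param records data.frame with `p_value`, `fold_change`,
#'   `unique_peptides` (and optionally `direction`).
#' @param min_unique_peptides,min_fold_change,max_p thresholds.
#' @return `records` with a logical `significant` column; attribute
#'   `counts` holds significant counts by direction.
#' @export
significance_filter <- function(records, min_unique_peptides = 2,
                                min_fold_change = 2, max_p = 0.05) {
  records$significant <- records$unique_peptides >= min_unique_peptides &
    !is.na(records$fold_change) & records$fold_change >= min_fold_change &
    records$p_value <= max_p
  if (!is.null(records$direction))
    attr(records, "counts") <- table(records$direction[records$significant])
  records
}

#' Volcano-plane export with Euclidean-distance contour tiers
#'
#' Emits per-record volcano coordinates and the highest contour level the
#' record reaches (closed boundary: a record exactly at a level belongs to
#' it), plus the contour arcs themselves: origin-centered circles of the
#' given radii in the `(log10 FC, -log10 p)` plane.
#'
#' @param records data.frame with `p_value`, `fold_change`, `signed_fc`
#'   and `d_eucl` (e.g. from [de_analysis]).
#' @param contour_levels circle radii, default `c(1, 1.5, 2)`.
#' @return list: `table` (records + `log10_fc_signed`, `neg_log10_p`,
#'   `tier`, sorted by `d_eucl` descending) and `contours` (data.frame
#'   `level`, `x`, `y`).
#' @export
volcano_export <- function(records, contour_levels = c(1, 1.5, 2)) {
  if (nrow(records) == 0L)
    return(list(table = records, contours = data.frame(level = numeric(),
                                                       x = numeric(), y = numeric())))
  tab <- records
  tab$log10_fc_signed <- sign(tab$signed_fc) * log10(tab$fold_change)
  tab$neg_log10_p <- -log10(tab$p_value)
  tab$tier <- vapply(tab$d_eucl, function(d) {
    below <- contour_levels[contour_levels <= d + 1e-12]
    if (length(below)) max(below) else 0
  }, 0)
  o <- order(-tab$d_eucl, tab$p_value,
             if (!is.null(tab$accession)) tab$accession else seq_len(nrow(tab)))
  tab <- tab[o, ]
  theta <- seq(0, pi, length.out = 181)   # upper half plane (p <= 1)
  contours <- do.call(rbind, lapply(contour_levels, function(l)
    data.frame(level = l, x = l * cos(theta), y = l * sin(theta))))
  list(table = tab, contours = contours)
}

#' Full differential-abundance analysis of a protein table
#'
#' The fixed pipeline: arcsinh transform, technical-replicate averaging on
#' the transformed scale, equal-variance two-sided t-test on the
#' transformed sample means, fold change on the untransformed normalized
#' scale (replicate-averaged), the significance filter (two unique
#' peptides, |FC| >= 2, p <= 0.05 by default), and Euclidean-distance
#' ranking. A Benjamini-Hochberg adjusted column (`bh_q`) is included for
#' information only; it plays no role in the significance call. Proteins
#' with a zero group mean are excluded from the ranking. Ties are broken
#' by smaller p, then accession.
#'
#' @param table a [protein_table] of raw normalized abundances.
#' @param group_a,group_b group labels (defaults: first two in the design).
#' @param fc_scale fold-change scale, see [fold_change].
#' @param min_unique_peptides,min_fold_change,max_p filter thresholds.
#' @return data.frame (class `de_table`) with one row per protein:
#'   accession, gene, unique_peptides, t, p_value, fold_change, direction,
#'   signed_fc, significant, d_eucl, bh_q; sorted by `d_eucl` descending.
#' @export
de_analysis <- function(table, group_a = NULL, group_b = NULL,
                        fc_scale = c("normalized", "back-transformed"),
                        min_unique_peptides = 2, min_fold_change = 2,
                        max_p = 0.05) {
  stopifnot(inherits(table, "protein_table"))
  fc_scale <- match.arg(fc_scale)
  groups <- unique(table$design$group)
  group_a <- group_a %||% groups[1]; group_b <- group_b %||% groups[2]

  tr <- arcsinh_transform(table)
  avg_t <- average_replicates(tr)
  tt <- differential_test(avg_t$values, avg_t$samples$group, group_a, group_b)

  if (fc_scale == "normalized") {
    avg_r <- average_replicates(table)
    fc <- fold_change(avg_r$values, avg_r$samples$group, group_a, group_b)
  } else {
    fc <- fold_change(avg_t$values, avg_t$samples$group, group_a, group_b,
                      scale = "back-transformed")
  }

  rec <- data.frame(accession = table$proteins$accession,
                    gene = table$proteins$gene,
                    unique_peptides = table$proteins$unique_peptides,
                    t = tt$t, p_value = tt$p_value,
                    fold_change = fc$fold_change, direction = fc$direction,
                    signed_fc = fc$signed_fc, excluded = fc$excluded,
                    stringsAsFactors = FALSE)
  rec <- significance_filter(rec, min_unique_peptides, min_fold_change, max_p)
  rec$d_eucl <- ifelse(rec$excluded, NA_real_,
                       euclidean_rank(rec$p_value, rec$fold_change))
  rec$bh_q <- stats::p.adjust(rec$p_value, method = "BH")
  o <- order(-rec$d_eucl, rec$p_value, rec$accession, na.last = TRUE)
  rec <- rec[o, ]
  rownames(rec) <- NULL
  class(rec) <- c("de_table", "data.frame")
  rec
}
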