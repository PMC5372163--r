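test_that("arcsinh transform matches its closed form and inverts", {
  expect_equal(arcsinh_transform(0), 0)
  expect_equal(arcsinh_transform(10), log(10 + sqrt(101)))
  set.seed(12)
  x <- rlnorm(200, 10, 2)
  expect_equal(sinh(arcsinh_transform(x)), x, tolerance = 1e-12)
  expect_error(arcsinh_transform(c(1, -2)), class = "ftirlcm_validation_error")
})

test_that("replicate averaging is a per-sample mean, order-invariant", {
  g <- generate_protein_table(n_proteins = 8, seed = 2)
  tab <- g$table
  avg <- average_replicates(tab)
  expect_equal(ncol(avg$values), 10)
  p1 <- tab$abundance[1, tab$design$sample == "A1"]
  expect_equal(unname(avg$values[1, "A1"]), mean(p1))
  expect_equal(unname(avg$values[1, "A1"]),
               mean(c(p1[3], p1[1], p1[2])))   # permutation invariance

  tab$abundance[2, tab$design$sample == "B2"] <- 7   # identical replicates
  expect_equal(unname(average_replicates(tab)$values[2, "B2"]), 7)
})

test_that("the pooled t-test matches the closed-form oracle", {
  v <- matrix(c(1, 2, 3, 11, 12.5, 13), 1)
  colnames(v) <- paste0("s", 1:6)
  groups <- c("A", "A", "A", "B", "B", "B")
  got <- differential_test(v, groups)

  # independent textbook computation
  a <- c(1, 2, 3); b <- c(11, 12.5, 13)
  sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
               (length(a) + length(b) - 2))
  t_oracle <- (mean(a) - mean(b)) / (sp * sqrt(1 / length(a) + 1 / length(b)))
  p_oracle <- 2 * pt(-abs(t_oracle), df = length(a) + length(b) - 2)
  expect_equal(got$t, t_oracle, tolerance = 1e-12)
  expect_equal(got$p_value, p_oracle, tolerance = 1e-12)

  same <- matrix(rep(c(1, 2, 3), 2), 1); colnames(same) <- paste0("s", 1:6)
  r0 <- differential_test(same, groups)
  expect_equal(r0$t, 0); expect_equal(r0$p_value, 1)

  const <- matrix(c(1, 1, 1, 2, 2, 2), 1); colnames(const) <- paste0("s", 1:6)
  rd <- differential_test(const, groups)
  expect_true(rd$degenerate)
  expect_lt(rd$p_value, 1e-300)

  expect_error(differential_test(v, c("A", rep("B", 5))),
               class = "ftirlcm_validation_error")
})

test_that("fold changes report ratio, direction and sign correctly", {
  v <- matrix(c(8, 8, 2, 2,
                3, 3, 3, 3), 2, byrow = TRUE)
  colnames(v) <- c("a1", "a2", "b1", "b2")
  fc <- fold_change(v, c("A", "A", "B", "B"))
  expect_equal(fc$fold_change, c(4, 1))
  expect_equal(fc$signed_fc, c(4, 1))
  expect_equal(fc$direction[1], "A-higher")

  v2 <- v[, c(3, 4, 1, 2)]; colnames(v2) <- c("a1", "a2", "b1", "b2")
  fc2 <- fold_change(v2, c("A", "A", "B", "B"))
  expect_equal(fc2$signed_fc[1], -4)
  expect_equal(fc2$direction[1], "B-higher")

  vz <- rbind(c(0, 0, 1, 1)); colnames(vz) <- colnames(v)
  expect_true(fold_change(vz, c("A", "A", "B", "B"))$excluded)
})

test_that("a planted 4-fold effect is estimated within [3.5, 4.5]", {
  hits <- vapply(1:500, function(s) {
    g <- generate_protein_table(n_proteins = 5, n_a = 6, n_b = 4, n_de = 1,
                                effects = 4, cv = 0.05,
                                frac_two_peptides = 1, seed = s)
    avg <- average_replicates(g$table)
    fc <- fold_change(avg$values, avg$samples$group, "A", "B")
    fc$fold_change[1] >= 3.5 && fc$fold_change[1] <= 4.5
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("Euclidean ranking reproduces Table-style values and is monotonic", {
  expect_equal(euclidean_rank(1, 1), 0)
  expect_equal(euclidean_rank(0.0004, 22.4), 3.66, tolerance = 0.005)
  expect_equal(euclidean_rank(0.0148, 110.5), 2.74, tolerance = 0.005)
  expect_equal(euclidean_rank(0.0120, 3.8), 2.01, tolerance = 0.005)

  # monotonic in both arguments
  set.seed(9)
  p <- runif(50, 1e-6, 1); f <- runif(50, 1, 100)
  expect_true(all(euclidean_rank(p * 0.5, f) >= euclidean_rank(p, f)))
  expect_true(all(euclidean_rank(p, f * 2) >= euclidean_rank(p, f)))
  expect_true(all(euclidean_rank(p, f) >= abs(log10(p))))
  expect_true(all(euclidean_rank(p, f) >= abs(log10(f))))

  expect_error(euclidean_rank(0, 2), class = "ftirlcm_validation_error")
  expect_error(euclidean_rank(0.5, 0.5), class = "ftirlcm_validation_error")
})

test_that("the significance filter applies the threshold triple exactly", {
  rec <- data.frame(
    accession = c("KRT8-like", "late", "weak", "single-peptide"),
    p_value = c(0.0484, 0.06, 0.001, 0.01),
    fold_change = c(6.9, 3, 1.5, 8),
    unique_peptides = c(2, 2, 5, 1),
    direction = c("A-higher", "A-higher", "B-higher", "A-higher"))
  out <- significance_filter(rec)
  expect_equal(out$significant, c(TRUE, FALSE, FALSE, FALSE))
  # boundary cases are inclusive
  b <- significance_filter(data.frame(p_value = 0.05, fold_change = 2,
                                      unique_peptides = 2))
  expect_true(b$significant)
})

test_that("volcano export tiers records against the contour levels", {
  t1 <- table1_fixture()
  rec <- data.frame(accession = t1$accession, p_value = t1$p_value,
                    fold_change = t1$fold_change,
                    signed_fc = ifelse(t1$more_abundant_in == "sarcomatoid",
                                       -t1$fold_change, t1$fold_change))
  rec$d_eucl <- euclidean_rank(rec$p_value, rec$fold_change)
  out <- volcano_export(rec)
  expect_equal(sum(out$table$tier >= 2), 7)   # all but the two weakest rows
  expect_setequal(out$table$accession[out$table$tier < 2],
                  c("P05787", "P12109"))
  expect_equal(out$table$d_eucl, sort(rec$d_eucl, decreasing = TRUE))

  at15 <- volcano_export(data.frame(accession = "x", p_value = 10^-1.5,
                                    fold_change = 1, signed_fc = 1,
                                    d_eucl = 1.5))
  expect_equal(at15$table$tier, 1.5)          # closed boundary

  empty <- volcano_export(data.frame(p_value = numeric(),
                                     fold_change = numeric(),
                                     signed_fc = numeric(),
                                     d_eucl = numeric())[0, ])
  expect_equal(nrow(empty$table), 0)
})

test_that("the full pipeline computes each stage on its declared scale", {
  g <- generate_protein_table(n_proteins = 30, n_de = 3, effects = 4,
                              cv = 0.05, frac_two_peptides = 1, seed = 14)
  de <- de_analysis(g$table)
  expect_s3_class(de, "de_table")
  expect_true(all(diff(de$d_eucl[!is.na(de$d_eucl)]) <= 1e-12))

  # hand-recompute one protein end to end
  acc <- g$table$proteins$accession[1]
  i <- match(acc, g$table$proteins$accession)
  tr <- asinh(g$table$abundance[i, ])
  ds <- g$table$design
  sm <- tapply(tr, ds$sample, mean)
  grp <- ds$group[match(names(sm), ds$sample)]
  tt <- t.test(sm[grp == "A"], sm[grp == "B"], var.equal = TRUE)
  raw_sm <- tapply(g$table$abundance[i, ], ds$sample, mean)
  ratio <- mean(raw_sm[grp == "A"]) / mean(raw_sm[grp == "B"])
  row <- de[de$accession == acc, ]
  expect_equal(row$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(row$fold_change, max(ratio, 1 / ratio), tolerance = 1e-12)
  expect_equal(row$d_eucl,
               sqrt(log10(row$p_value)^2 + log10(row$fold_change)^2))
  # BH column is informational and matches p.adjust on the same p-values
  expect_equal(de$bh_q, p.adjust(de$p_value, "BH"))
})
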