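test_that("cube round trips are bitwise lossless and carry metadata", {
  set.seed(10)
  ax <- tiny_axis(50)
  cube <- array(rnorm(6 * 7 * 50), c(6, 7, 50))
  mask <- matrix(runif(42) > 0.2, 6, 7)
  cube[array(rep(!mask, 50), c(6, 7, 50))] <- 0
  img <- spectral_image(cube, ax, pixel_size = c(5.65, 5.75),
                        stage_origin = c(-100, 40), qc_mask = mask)
  path <- tempfile(fileext = ".bin")
  write_cube(img, path)
  back <- read_cube(path)
  expect_identical(back$cube, img$cube)
  expect_identical(back$qc_mask, img$qc_mask)
  expect_equal(back$axis$values, ax$values)
  expect_equal(back$pixel_size, c(5.65, 5.75))
  expect_equal(back$stage_origin, c(-100, 40))
})

test_that("cube reader validates structure and metadata", {
  ax <- tiny_axis(20)
  img <- spectral_image(array(0, c(3, 3, 20)), ax)
  path <- tempfile(fileext = ".bin")
  write_cube(img, path)

  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  meta$wavenumbers_cm1 <- meta$wavenumbers_cm1[-1]   # 19 entries vs 20 bands
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  expect_error(read_cube(path), "bands", class = "ftirlcm_structural_error")

  meta$wavenumbers_cm1 <- NULL
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  expect_error(read_cube(path), "wavenumbers_cm1", class = "ftirlcm_format_error")

  expect_error(read_cube(tempfile()), "not found", class = "ftirlcm_format_error")

  # absent qc_mask defaults to all-true
  write_cube(img, path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  meta$qc_mask <- NULL
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  expect_true(all(read_cube(path)$qc_mask))
})

test_that("acquisition-range phantom declares 438 bands and round trips", {
  ph <- generate_phantom(phantom_spec(size = c(8, 8), seed = 1,
                                      n_blank = 2, n_saturated = 1))
  expect_length(ph$image$axis$values, 438)
  expect_equal(range(ph$image$axis$values), c(952, 2700))
  path <- tempfile(fileext = ".bin")
  write_cube(ph$image, path)
  expect_identical(read_cube(path)$cube, ph$image$cube)
})

test_that("label maps round trip losslessly and validate their legend", {
  checker <- matrix(rep(c(1L, 2L), 18), 6, 6)
  legend <- data.frame(label = 1:2, class = c("a", "b"),
                       color = c("#ff0000", "#00ff00"))
  map <- label_map(checker, legend)
  path <- tempfile(fileext = ".png")
  write_label_map(map, path)
  back <- read_label_map(path)
  expect_identical(back$labels, map$labels)
  expect_equal(back$legend$class, legend$class)

  bad <- checker; bad[2, 2] <- 7L
  expect_error(label_map(bad, legend), "7", class = "ftirlcm_validation_error")

  ph <- generate_phantom(phantom_spec(size = c(16, 16), seed = 1,
                                      n_blank = 2, n_saturated = 1))
  write_label_map(ph$truth, path)
  expect_identical(read_label_map(path)$labels, ph$truth$labels)
})

test_that("LCM shape export preserves shapes at 0.01 um precision", {
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  for (dialect in c("xml", "csv")) {
    path <- tempfile(fileext = paste0(".", dialect))
    export_lcm_shapes(list(square), path, dialect)
    back <- read_lcm_shapes(path, dialect)
    expect_length(back, 1)
    expect_equal(nrow(back[[1]]), 4)
    expect_lt(max(abs(back[[1]] - square)), 0.01)
  }
  # empty document is valid
  path <- tempfile(fileext = ".xml")
  export_lcm_shapes(list(), path, "xml")
  expect_length(read_lcm_shapes(path, "xml"), 0)
  # degenerate / self-intersecting polygons are rejected with their index
  expect_error(export_lcm_shapes(list(square, rbind(c(0, 0), c(1, 1))),
                                 tempfile(), "xml"),
               "shape 2", class = "ftirlcm_validation_error")
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(export_lcm_shapes(list(bowtie), tempfile(), "xml"),
               "self-intersecting", class = "ftirlcm_validation_error")
})

test_that("a 3x3 ROI boundary polygon exports with 8 vertices at pixel centers", {
  lab <- matrix(0L, 8, 8); lab[3:5, 4:6] <- 1L
  map <- label_map(lab, data.frame(label = 1L, class = "t", color = "#000000"))
  roi <- extract_rois(map, "t", pixel_size = c(1, 1))[[1]]
  path <- tempfile(fileext = ".xml")
  export_lcm_shapes(list(roi$polygon), path, "xml")
  back <- read_lcm_shapes(path, "xml")[[1]]
  expect_equal(nrow(back), 8)
  expect_lt(max(abs(back - roi$polygon)), 0.01)
})

test_that("protein tables parse with design validation", {
  t1 <- table1_fixture()
  set.seed(2)
  runs <- as.vector(outer(c("A1", "A2", "B1", "B2"), 1:3,
                          function(s, r) paste0(s, "_r", r)))
  ab <- matrix(rlnorm(9 * 12, log(1e5), 1), 9, 12, dimnames = list(NULL, runs))
  design <- data.frame(run = runs,
                       sample = sub("_r[0-9]$", "", runs),
                       group = substr(runs, 1, 1),
                       replicate = as.integer(sub(".*_r", "", runs)))
  tab_path <- tempfile(fileext = ".csv"); des_path <- tempfile(fileext = ".csv")
  df <- cbind(data.frame(accession = t1$accession, gene = t1$gene,
                         unique_peptides = c(8, 2, 5, 3, 2, 4, 2, 6, 3)),
              as.data.frame(ab))
  write.csv(df, tab_path, row.names = FALSE, quote = FALSE)
  write.csv(design, des_path, row.names = FALSE, quote = FALSE)
  tab <- read_protein_table(tab_path, des_path)
  expect_s3_class(tab, "protein_table")
  expect_equal(nrow(tab$abundance), 9)
  expect_equal(tab$proteins$accession[1], "P22676")

  dup <- df; dup$accession[2] <- "P22676"
  write.csv(dup, tab_path, row.names = FALSE, quote = FALSE)
  expect_error(read_protein_table(tab_path, des_path), "P22676",
               class = "ftirlcm_validation_error")

  write.csv(df, tab_path, row.names = FALSE, quote = FALSE)
  write.csv(design[-1, ], des_path, row.names = FALSE, quote = FALSE)
  expect_error(read_protein_table(tab_path, des_path), "not in design",
               class = "ftirlcm_validation_error")

  neg <- df; neg[3, 5] <- -1
  write.csv(neg, tab_path, row.names = FALSE, quote = FALSE)
  write.csv(design, des_path, row.names = FALSE, quote = FALSE)
  expect_error(read_protein_table(tab_path, des_path), "egative",
               class = "ftirlcm_validation_error")
})

test_that("reference point files round trip", {
  rp <- generate_reference_points(helmert(tx = 5, ty = -3, s = 1.1, theta = 0.2),
                                  n = 5, noise_sd = 0.5, seed = 4)
  path <- tempfile(fileext = ".csv")
  write_reference_points(rp, path)
  back <- read_reference_points(path)
  expect_equal(back$source, rp$source, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$destination, rp$destination, tolerance = 1e-12,
               ignore_attr = TRUE)
})
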