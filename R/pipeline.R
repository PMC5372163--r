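.config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}

.provenance <- function(stage, config, inputs, outputs, seed) {
  list(stage = stage,
       package_version = as.character(utils::packageVersion("ftirlcm")),
       seed = seed,
       config_hash = .config_hash(config),
       input_md5 = if (length(inputs)) as.list(tools::md5sum(unlist(inputs))) else list(),
       outputs = unlist(outputs))
}

#' Run one pipeline stage with provenance
#'
#' File-level glue over the package functions. Every stage validates its
#' inputs, writes its outputs plus a `provenance.json` (config hash, input
#' hashes, package version, seed) into `out_dir`, and is deterministic:
#' rerunning with identical config and inputs reproduces identical output
#' bytes.
#'
#' Stages and their inputs/outputs:
#' \describe{
#'   \item{simulate}{config: [phantom_spec] arguments incl. `seed`. Writes
#'     `cube.bin(+.json)`, `truth.png(+.json)`, `concentration.csv`.}
#'   \item{preprocess}{inputs: `cube`. Config: [qc_params] arguments,
#'     `emsc = TRUE/FALSE`, `n_iterations`. Writes `corrected.bin`,
#'     `qc_report.json`, `amide.csv`.}
#'   \item{train}{inputs: `cube` (corrected), `truth`. Config: `cascade`
#'     (a [cascade_spec]), `seed`. Writes `cascade.rds`.}
#'   \item{classify}{inputs: `cube` (corrected), `cascade`. Writes
#'     `labels.png(+.json)`.}
#'   \item{rois}{inputs: `labels`, `amide` (csv). Config: `target_class`,
#'     `min_pixels`, `max_shape_area`. Writes `shapes.xml`,
#'     `fragments.csv`.}
#'   \item{transfer}{inputs: `shapes`, `points` (reference CSV). Writes
#'     `shapes_lcm.xml`, `transform.json`.}
#'   \item{pool}{inputs: one or more `fragments` CSVs (named by sample).
#'     Config: `target_integral`, `tolerance`. Writes `pooling.csv`.}
#'   \item{stats}{inputs: `proteins`, `design`. Config: filter thresholds.
#'     Writes `de_table.csv`.}
#' }
#'
#' @param stage stage name.
#' @param config named list of stage parameters.
#' @param inputs named list of input file paths.
#' @param out_dir output directory (created if needed).
#' @return named list of output paths (invisibly, with the provenance
#'   record as attribute `provenance`).
#' @export
run_stage <- function(stage, config = list(), inputs = list(),
                      out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(inputs))
    if (!file.exists(inputs[[nm]]))
      format_error("stage '%s': missing input '%s': %s", stage, nm, inputs[[nm]])
  out <- switch(stage,
    simulate = {
      spec <- do.call(phantom_spec, config[setdiff(names(config), "signatures")])
      ph <- generate_phantom(spec, config$signatures %||% class_signatures())
      cube <- file.path(out_dir, "cube.bin")
      truth <- file.path(out_dir, "truth.png")
      conc <- file.path(out_dir, "concentration.csv")
      write_cube(ph$image, cube)
      write_label_map(ph$truth, truth)
      utils::write.csv(ph$concentration, conc, row.names = FALSE)
      list(cube = cube, truth = truth, concentration = conc)
    },
    preprocess = {
      img <- read_cube(inputs$cube)
      qp <- do.call(qc_params, config$qc %||% list())
      qc <- quality_control(img, qp)
      img <- qc$image
      amide <- qc$report$amide_integral
      if (isTRUE(config$emsc %||% TRUE)) {
        ref <- colMeans(matrix(img$cube, prod(dim(img$cube)[1:2]),
                               dim(img$cube)[3])[as.vector(img$qc_mask), , drop = FALSE])
        basis <- build_mie_basis(img$axis)
        mdl <- emsc_model(ref, img$axis, basis,
                          n_iterations = config$n_iterations %||% 1)
        img <- emsc_correct(img, mdl)$image
      }
      cube <- file.path(out_dir, "corrected.bin")
      rep_path <- file.path(out_dir, "qc_report.json")
      amide_path <- file.path(out_dir, "amide.csv")
      write_cube(img, cube)
      jsonlite::write_json(list(total = qc$report$total, pass = qc$report$n_pass,
                                by_code = as.list(qc$report$by_code)),
                           rep_path, auto_unbox = TRUE)
      utils::write.csv(amide, amide_path, row.names = FALSE)
      list(cube = cube, qc_report = rep_path, amide = amide_path)
    },
    train = {
      img <- read_cube(inputs$cube)
      truth <- read_label_map(inputs$truth)
      X <- extract_features(img, config$feature_range %||% c(1800, 950))
      px <- attr(X, "pixels")
      codes <- truth$labels[cbind(px$row, px$col)]
      y <- truth$legend$class[match(codes, truth$legend$label)]
      keep <- !is.na(y)
      cascade <- train_cascade(X[keep, , drop = FALSE], y[keep],
                               spec = config$cascade,
                               seed = config$seed %||% 1,
                               min_train_pixels = config$min_train_pixels %||% 100)
      path <- file.path(out_dir, "cascade.rds")
      saveRDS(cascade, path, version = 2)
      list(cascade = path)
    },
    classify = {
      img <- read_cube(inputs$cube)
      cascade <- readRDS(inputs$cascade)
      map <- predict_cascade(img, cascade)
      path <- file.path(out_dir, "labels.png")
      write_label_map(map, path)
      list(labels = path)
    },
    rois = {
      map <- read_label_map(inputs$labels)
      amide <- as.matrix(utils::read.csv(inputs$amide))
      rois <- extract_rois(map, config$target_class,
                           min_pixels = config$min_pixels %||% 4,
                           pixel_size = config$pixel_size %||% c(5.65, 5.75))
      frags <- do.call(c, lapply(rois, watershed_split, amide_map = amide,
                                 max_shape_area = config$max_shape_area %||% 250000))
      shp <- file.path(out_dir, "shapes.xml")
      man <- file.path(out_dir, "fragments.csv")
      export_lcm_shapes(lapply(frags, `[[`, "polygon"), shp, "xml")
      utils::write.csv(data.frame(
        roi = vapply(frags, `[[`, 0L, "parent"),
        fragment = vapply(frags, `[[`, 0L, "fragment"),
        class = vapply(frags, `[[`, "", "class"),
        n_pixels = vapply(frags, `[[`, 0L, "n_pixels"),
        area_um2 = vapply(frags, `[[`, 0, "area"),
        amide_integral = vapply(frags, `[[`, 0, "amide_integral_sum")),
        man, row.names = FALSE)
      list(shapes = shp, fragments = man)
    },
    transfer = {
      shapes <- read_lcm_shapes(inputs$shapes, "xml")
      pairs <- read_reference_points(inputs$points)
      h <- estimate_helmert(pairs)
      out_shapes <- lapply(shapes, apply_helmert, transform = h)
      shp <- file.path(out_dir, "shapes_lcm.xml")
      tj <- file.path(out_dir, "transform.json")
      export_lcm_shapes(out_shapes, shp, "xml")
      jsonlite::write_json(list(tx = h$tx, ty = h$ty, s = h$s, theta = h$theta,
                                rms_residual_um = h$rms_residual),
                           tj, auto_unbox = TRUE, digits = NA)
      list(shapes = shp, transform = tj)
    },
    pool = {
      mans <- lapply(inputs, function(p) utils::read.csv(p)$amide_integral)
      sel <- select_fragments_balanced(mans, config$target_integral,
                                       config$tolerance %||% 0.02 * config$target_integral)
      path <- file.path(out_dir, "pooling.csv")
      utils::write.csv(do.call(rbind, lapply(names(sel), function(nm)
        data.frame(sample = nm, fragment = sel[[nm]]$selected,
                   achieved = sel[[nm]]$achieved))),
        path, row.names = FALSE)
      list(pooling = path)
    },
    stats = {
      tab <- read_protein_table(inputs$proteins, inputs$design)
      de <- de_analysis(tab,
                        min_unique_peptides = config$min_unique_peptides %||% 2,
                        min_fold_change = config$min_fold_change %||% 2,
                        max_p = config$max_p %||% 0.05)
      path <- file.path(out_dir, "de_table.csv")
      utils::write.csv(as.data.frame(de), path, row.names = FALSE)
      list(de_table = path)
    },
    stopf("unknown stage '%s'", stage))
  prov <- .provenance(stage, config, inputs, out, config$seed %||% NA)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  attr(out, "provenance") <- prov
  invisible(out)
}

#' Run the full phantom-to-statistics pipeline in one call
#'
#' Simulates a phantom, preprocesses it (QC + EMSC), trains and applies the
#' classifier cascade on the phantom truth, extracts and splits regions of
#' interest, transfers their shapes through a Helmert transform estimated
#' from generated reference points, and runs the differential-abundance
#' statistics on a generated protein table. Intended as an end-to-end smoke
#' test and usage example; all stages derive their seeds from `seed`.
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @return named list of stage output lists.
#' @export
run_pipeline <- function(out_dir, seed = 1) {
  d <- function(...) file.path(out_dir, ...)
  sim <- run_stage("simulate",
                   config = list(size = c(48, 48), seed = derive_seed(seed, "phantom"),
                                 n_blank = 5, n_saturated = 3),
                   out_dir = d("sim"))
  pre <- run_stage("preprocess", inputs = list(cube = sim$cube),
                   out_dir = d("pre"))
  spec <- cascade_spec(list(
    cascade_level("tissue", c("tumour", "stroma")),
    cascade_level("subtype", c("epithelioid", "sarcomatoid"),
                  parents = c("tumour", "tumour"))))
  tr <- run_stage("train",
                  config = list(cascade = spec, seed = derive_seed(seed, "train"),
                                min_train_pixels = 50),
                  inputs = list(cube = pre$cube, truth = sim$truth),
                  out_dir = d("train"))
  cls <- run_stage("classify", inputs = list(cube = pre$cube, cascade = tr$cascade),
                   out_dir = d("classify"))
  rois <- run_stage("rois",
                    config = list(target_class = "epithelioid",
                                  max_shape_area = 10000),
                    inputs = list(labels = cls$labels, amide = pre$amide),
                    out_dir = d("rois"))
  pts_path <- d("points.csv")
  write_reference_points(
    generate_reference_points(helmert(tx = -250, ty = 310, s = 1.0, theta = 12 * pi / 180),
                              n = 3, seed = derive_seed(seed, "points")),
    pts_path)
  trf <- run_stage("transfer", inputs = list(shapes = rois$shapes, points = pts_path),
                   out_dir = d("transfer"))
  prot <- generate_protein_table(n_proteins = 200, n_de = 10,
                                 seed = derive_seed(seed, "proteins"))
  pt <- d("proteins.csv"); pd <- d("design.csv")
  write_protein_table(prot$table, pt, pd)
  st <- run_stage("stats", inputs = list(proteins = pt, design = pd),
                  out_dir = d("stats"))
  list(simulate = sim, preprocess = pre, train = tr, classify = cls,
       rois = rois, transfer = trf, stats = st)
}

# The DMM cascade of the study, as a configured (not hard-coded) example:
# level 1 separates pathologic from normal regions, level 2 the tumour
# classes within pathologic tissue, level 3 the DMM subtypes.
#' Example three-level cascade specification
#'
#' @return a [cascade_spec] with pathologic-region, tumour-class and
#'   tumour-subtype levels.
#' @export
dmm_cascade_spec <- function() {
  cascade_spec(list(
    cascade_level("region", c("pathologic", "normal")),
    cascade_level("tumour_class", c("mesothelioma", "other_tumour"),
                  parents = c("pathologic", "pathologic")),
    cascade_level("subtype", c("epithelioid", "sarcomatoid"),
                  parents = c("mesothelioma", "mesothelioma"))))
}
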