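#' Normalized protein abundance table with run design
#'
#' Holds per-protein normalized abundances across LC-MS runs together with
#' the design mapping each run (column) to a biological sample, a group and
#' a technical replicate index. This is the contract for the export of an
#' upstream label-free quantification tool; the package never touches raw
#' MS data.
#'
#' @param proteins data.frame with columns `accession` (unique), `gene`,
#'   `unique_peptides` (integer >= 0).
#' @param abundance numeric matrix, proteins x runs, nonnegative; column
#'   names are run ids.
#' @param design data.frame with columns `run`, `sample`, `group`,
#'   `replicate`; one row per abundance column.
#' @return an object of class `protein_table`.
#' @export
protein_table <- function(proteins, abundance, design) {
  proteins <- as.data.frame(proteins)
  design <- as.data.frame(design)
  abundance <- as.matrix(abundance)
  need <- setdiff(c("accession", "gene", "unique_peptides"), names(proteins))
  if (length(need)) validation_error("proteins lacks column(s): %s", paste(need, collapse = ", "))
  need <- setdiff(c("run", "sample", "group", "replicate"), names(design))
  if (length(need)) validation_error("design lacks column(s): %s", paste(need, collapse = ", "))
  dup <- proteins$accession[duplicated(proteins$accession)]
  if (length(dup)) validation_error("duplicated accession: %s", paste(unique(dup), collapse = ", "))
  if (nrow(abundance) != nrow(proteins))
    structural_error("abundance has %d rows but %d proteins declared",
                     nrow(abundance), nrow(proteins))
  unmapped <- setdiff(colnames(abundance), design$run)
  if (length(unmapped))
    validation_error("abundance column(s) not in design: %s", paste(unmapped, collapse = ", "))
  extra <- setdiff(design$run, colnames(abundance))
  if (length(extra))
    validation_error("design run(s) missing from table: %s", paste(extra, collapse = ", "))
  if (anyDuplicated(design$run)) validation_error("design maps a run twice")
  if (any(abundance < 0)) validation_error("negative abundance values present")
  design <- design[match(colnames(abundance), design$run), ]
  rownames(abundance) <- proteins$accession
  structure(list(proteins = proteins, abundance = abundance, design = design),
            class = "protein_table")
}

#' @export
print.protein_table <- function(x, ...) {
  cat(sprintf("<protein_table> %d proteins x %d runs (%d samples, groups: %s)\n",
              nrow(x$abundance), ncol(x$abundance),
              length(unique(x$design$sample)),
              paste(unique(x$design$group), collapse = "/")))
  invisible(x)
}

#' Read a quantified protein table plus its run design
#'
#' The table CSV/TSV must carry `accession`, `gene`, `unique_peptides` and
#' one abundance column per run; the design CSV maps every run column to
#' `(sample, group, replicate)`.
#'
#' @param path delimited protein table (CSV, or TSV if the name ends in
#'   `.tsv`).
#' @param design_path CSV with columns `run, sample, group, replicate`.
#' @return a [protein_table].
#' @export
read_protein_table <- function(path, design_path) {
  for (p in c(path, design_path))
    if (!file.exists(p)) format_error("file not found: %s", p)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                         stringsAsFactors = FALSE)
  design <- utils::read.csv(design_path, stringsAsFactors = FALSE)
  need <- setdiff(c("accession", "gene", "unique_peptides"), names(d))
  if (length(need)) format_error("table lacks column(s): %s", paste(need, collapse = ", "))
  runs <- setdiff(names(d), c("accession", "gene", "unique_peptides"))
  ab <- as.matrix(d[, runs, drop = FALSE])
  storage.mode(ab) <- "double"
  protein_table(d[, c("accession", "gene", "unique_peptides")], ab, design)
}

#' Write a protein table and its design to CSV
#'
#' @param table a [protein_table].
#' @param path,design_path output CSV paths.
#' @return `path`, invisibly.
#' @export
write_protein_table <- function(table, path, design_path) {
  stopifnot(inherits(table, "protein_table"))
  out <- cbind(table$proteins, as.data.frame(table$abundance, check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(table$design, design_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
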