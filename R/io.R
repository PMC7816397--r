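# Reading and writing the standard on-disk formats: 10x-style MTX triplets,
# tag-count CSVs, whitelists, annotation and ground-truth tables.

#' Write counts in 10x-style sparse format
#'
#' Emits `matrix.mtx`, `features.tsv`, and `barcodes.tsv` into a directory.
#'
#' @param counts gene x cell count matrix.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_tenx <- function(counts, dir) {
  counts <- as_count_matrix(counts)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(counts, file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(rownames(counts)),
                     file.path(dir, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(data.frame(colnames(counts)),
                     file.path(dir, "barcodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(dir)
}

#' Read counts from a 10x-style directory
#'
#' Expects `matrix.mtx`, `features.tsv` (gene ids in the first column), and
#' `barcodes.tsv`.
#'
#' @param dir directory containing the three files.
#' @return sparse gene x cell count matrix.
#' @export
read_tenx <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort("missing input file(s): %s", paste(missing, collapse = ", "))
  }
  m <- Matrix::readMM(paths[1])
  feats <- utils::read.table(paths[2], sep = "\t", stringsAsFactors = FALSE)
  bcs <- utils::read.table(paths[3], sep = "\t", stringsAsFactors = FALSE)
  if (nrow(feats) != nrow(m) || nrow(bcs) != ncol(m)) {
    abort("matrix.mtx dimensions (%d x %d) do not match features (%d) / barcodes (%d)",
          nrow(m), ncol(m), nrow(feats), nrow(bcs))
  }
  dimnames(m) <- list(feats[[1]], bcs[[1]])
  as_count_matrix(m)
}

#' Write a tag x cell count matrix as CSV
#' @param tags tag x cell matrix.
#' @param path output file.
#' @export
write_tag_csv <- function(tags, path) {
  utils::write.csv(as.matrix(tags), path, quote = FALSE)
  invisible(path)
}

#' Read a tag x cell count matrix from CSV (tags in rows)
#' @param path CSV with tag ids in the first column, cells as columns.
#' @return numeric matrix.
#' @export
read_tag_csv <- function(path) {
  if (!file.exists(path)) abort("missing input file: %s", path)
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Read a barcode whitelist CSV (columns donor, sequence)
#' @param path CSV file.
#' @param correction_radius Hamming correction radius.
#' @return a [barcode_whitelist()].
#' @export
read_whitelist_csv <- function(path, correction_radius = 1L) {
  if (!file.exists(path)) abort("missing input file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("donor", "sequence") %in% names(df))) {
    abort("%s must have columns `donor` and `sequence`", path)
  }
  barcode_whitelist(df, correction_radius)
}

#' Read external per-cell reference calls (columns cell, donor)
#' @param path CSV file.
#' @return named character vector of calls.
#' @export
read_reference_calls <- function(path) {
  if (!file.exists(path)) abort("missing input file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("cell", "donor") %in% names(df))) {
    abort("%s must have columns `cell` and `donor`", path)
  }
  stats::setNames(df$donor, df$cell)
}

#' Write simulation outputs to disk
#'
#' Writes the 10x-style count triplet, the tag-count CSV, the ground-truth
#' annotation CSV, and (optionally) a read-level tag TSV.
#'
#' @param sim an `allomix_sim` from [generate_counts()].
#' @param dir output directory.
#' @param tag_reads also emit a read-level tag TSV (cell, read).
#' @param seed seed for read-level simulation.
#' @return the directory, invisibly.
#' @export
write_sim <- function(sim, dir, tag_reads = FALSE, seed = 1L) {
  stopifnot(inherits(sim, "allomix_sim"))
  write_tenx(sim$counts, dir)
  write_tag_csv(sim$tags, file.path(dir, "tag_counts.csv"))
  utils::write.csv(sim$truth$cells, file.path(dir, "ground_truth.csv"),
                   quote = FALSE, row.names = FALSE)
  utils::write.csv(
    data.frame(donor = names(sim$truth$whitelist),
               sequence = unname(sim$truth$whitelist)),
    file.path(dir, "whitelist.csv"), quote = FALSE, row.names = FALSE)
  if (tag_reads) {
    reads <- simulate_tag_reads(sim$truth$cells, sim$truth$config$tag_params,
                                sim$truth$whitelist, seed)
    utils::write.table(reads, file.path(dir, "tag_reads.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Build a generator configuration from a YAML file
#'
#' Top-level YAML keys map to [generator_config()] arguments; `allo_effect`
#' and `tag_params` sub-maps are forwarded to their constructors.
#'
#' @param path YAML file.
#' @return a [generator_config()].
#' @export
generator_config_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) abort("config %s must set a seed", path)
  if (!is.null(cfg$allo_effect)) {
    cfg$allo_effect <- do.call(allo_effect_spec, cfg$allo_effect)
  }
  if (!is.null(cfg$tag_params)) {
    cfg$tag_params <- do.call(tag_params, cfg$tag_params)
  }
  if (!is.null(cfg$celltype_proportions)) {
    cfg$celltype_proportions <- unlist(cfg$celltype_proportions)
  }
  if (!is.null(cfg$cd4_subtype_proportions)) {
    cfg$cd4_subtype_proportions <- unlist(cfg$cd4_subtype_proportions)
  }
  do.call(generator_config, cfg)
}
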