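# Plain-text readers and writers for the pipeline's file formats. All
# writers accept paths ending in ".gz" (routed through a gzip connection).

open_write <- function(path) if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")

write_tsv <- function(df, path, row_names = FALSE) {
  con <- open_write(path)
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}

#' Write an AOI matrix as TSV (genes x AOIs) plus metadata TSV
#'
#' @param m an [aoi_matrix()].
#' @param counts_path,meta_path output paths (".gz" allowed).
#' @export
write_aoi_matrix <- function(m, counts_path, meta_path) {
  stopifnot(inherits(m, "aoi_matrix"))
  df <- data.frame(gene_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, counts_path)
  write_tsv(m$meta, meta_path)
}

#' Read an AOI matrix from TSV counts and metadata
#'
#' @param counts_path TSV with a `gene_id` column then one column per AOI.
#' @param meta_path TSV of per-AOI metadata.
#' @param transformed whether the values are stabilized expression.
#' @return An [aoi_matrix()].
#' @export
read_aoi_matrix <- function(counts_path, meta_path, transformed = FALSE) {
  df <- read_tsv(counts_path, check.names = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  aoi_matrix(v, read_tsv(meta_path), transformed = transformed)
}

#' Write an AOI matrix in MatrixMarket form
#'
#' Writes the sparse counts as MTX with row (gene) and column (AOI) name
#' sidecar files, the exchange format commonly used for large count
#' matrices.
#'
#' @param m an [aoi_matrix()].
#' @param prefix path prefix; writes `<prefix>.mtx`, `<prefix>.rownames`,
#'   `<prefix>.colnames`.
#' @export
write_aoi_mtx <- function(m, prefix) {
  stopifnot(inherits(m, "aoi_matrix"))
  if (!requireNamespace("Matrix", quietly = TRUE)) {
    stopf("MTX output needs the Matrix package")
  }
  sm <- Matrix::Matrix(m$values, sparse = TRUE)
  Matrix::writeMM(sm, paste0(prefix, ".mtx"))
  writeLines(rownames(m$values), paste0(prefix, ".rownames"))
  writeLines(colnames(m$values), paste0(prefix, ".colnames"))
}

#' Write / read locus counts as 4-column TSV
#'
#' Columns: locus_id, chrom, pos0, count.
#'
#' @param s a [locus_counts()].
#' @param path output path.
#' @export
write_locus_counts <- function(s, path) {
  stopifnot(inherits(s, "locus_counts"))
  write_tsv(data.frame(s$loci, count = s$counts), path)
}

#' @rdname write_locus_counts
#' @param sample_id sample id to attach on read.
#' @return `read_locus_counts()` returns a [locus_counts()].
#' @export
read_locus_counts <- function(path, sample_id = basename(path)) {
  df <- read_tsv(path)
  locus_counts(sample_id, df[, c("locus_id", "chrom", "pos0")], df$count)
}

#' Read a directory of panel member TSVs as a reference panel
#'
#' @param dir directory of locus-count TSV files (one per member).
#' @return A [reference_panel()].
#' @export
read_panel_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv(\\.gz)?$", full.names = TRUE))
  if (!length(files)) stopf("no panel TSV files in '%s'", dir)
  reference_panel(lapply(files, function(f) {
    read_locus_counts(f, sample_id = sub("\\.tsv(\\.gz)?$", "", basename(f)))
  }))
}

#' Write a genome model as BED-like TSVs
#'
#' Arms and cytobands as (chrom, start, end, name) tables.
#'
#' @param genome a [genome_model()].
#' @param arms_path,cytobands_path output paths.
#' @export
write_genome_bed <- function(genome, arms_path, cytobands_path) {
  arms <- genome$arms[, c("chrom", "start", "end", "name")]
  write_tsv(arms, arms_path)
  write_tsv(genome$cytobands[, c("chrom", "start", "end", "name")], cytobands_path)
}

#' Write a full cohort bundle to a directory
#'
#' Emits counts + metadata TSVs (and MTX when the Matrix package is
#' present), the sample table, per-patient locus counts, the panel, the
#' genome tables, gene coordinates, and the truth labels.
#'
#' @param bundle a `cohort_bundle` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param gzip gzip the larger tables.
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(bundle, dir, gzip = FALSE) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  z <- if (gzip) ".gz" else ""
  p <- function(...) file.path(dir, paste0(...))
  write_aoi_matrix(bundle$expr, p("counts.tsv", z), p("aoi_meta.tsv"))
  if (requireNamespace("Matrix", quietly = TRUE)) {
    write_aoi_mtx(bundle$expr, file.path(dir, "counts"))
  }
  write_tsv(bundle$samples, p("samples.tsv"))
  dna_dir <- file.path(dir, "dna")
  dir.create(dna_dir, showWarnings = FALSE)
  for (nm in names(bundle$dna)) {
    write_locus_counts(bundle$dna[[nm]], file.path(dna_dir, paste0(nm, ".tsv", z)))
  }
  panel_dir <- file.path(dir, "panel")
  dir.create(panel_dir, showWarnings = FALSE)
  for (m in bundle$panel$members) {
    write_locus_counts(m, file.path(panel_dir, paste0(m$sample_id, ".tsv", z)))
  }
  write_genome_bed(bundle$genome, p("arms.tsv"), p("cytobands.tsv"))
  write_tsv(bundle$gene_coords, p("gene_coords.tsv"))
  truth <- data.frame(patient = names(bundle$truth$subtype),
                      subtype = unname(bundle$truth$subtype))
  write_tsv(truth, p("truth_subtypes.tsv"))
  sig <- data.frame(
    subtype = rep(names(bundle$truth$signatures),
                  lengths(bundle$truth$signatures)),
    gene_id = unlist(bundle$truth$signatures, use.names = FALSE)
  )
  write_tsv(sig, p("truth_signatures.tsv"))
  invisible(list.files(dir, recursive = TRUE, full.names = TRUE))
}
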