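# S3 containers shared across the pipeline stages.

#' AOI expression matrix with per-AOI metadata
#'
#' The expression substrate of the pipeline: a genes x AOIs matrix (raw
#' nonnegative counts, or stabilized expression once transformed) together
#' with one metadata record per AOI (compartment, diagnosis, batch/run,
#' patient).
#'
#' @param values numeric genes x AOIs matrix with row and column names.
#' @param meta data.frame with one row per AOI; must contain `aoi_id`,
#'   `compartment`, `diagnosis`, `batch`, `patient`.
#' @param transformed logical; FALSE for raw counts, TRUE for stabilized
#'   expression.
#' @return An object of class `aoi_matrix`.
#' @export
aoi_matrix <- function(values, meta, transformed = FALSE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("aoi_matrix values need gene rownames and AOI colnames")
  }
  if (anyDuplicated(rownames(values))) stopf("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stopf("duplicate AOI ids")
  need <- c("aoi_id", "compartment", "diagnosis", "batch", "patient")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stopf("meta lacks columns: %s", paste(miss, collapse = ", "))
  if (!setequal(meta$aoi_id, colnames(values)) ||
      nrow(meta) != ncol(values)) {
    stopf("meta must cover every AOI exactly once")
  }
  meta <- meta[match(colnames(values), meta$aoi_id), , drop = FALSE]
  rownames(meta) <- NULL
  if (!transformed && any(values < 0)) stopf("raw counts must be nonnegative")
  structure(list(values = values, meta = meta, transformed = transformed),
            class = "aoi_matrix")
}

#' @export
print.aoi_matrix <- function(x, ...) {
  cat(sprintf("aoi_matrix: %d genes x %d AOIs (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$transformed) "transformed" else "raw counts"))
  cat("  diagnoses:", paste(names(table(x$meta$diagnosis)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.aoi_matrix <- function(x) dim(x$values)

#' Per-locus genome-wide read counts for one DNA sample
#'
#' @param sample_id sample identifier.
#' @param loci data.frame with `locus_id`, `chrom`, `pos0` (0-based),
#'   sorted by (chrom, pos0).
#' @param counts nonnegative integer vector, one entry per locus.
#' @return An object of class `locus_counts` with a `total` field.
#' @export
locus_counts <- function(sample_id, loci, counts) {
  stopifnot(all(c("locus_id", "chrom", "pos0") %in% names(loci)))
  if (length(counts) != nrow(loci)) stopf("counts/loci length mismatch")
  if (any(counts < 0) || any(counts != floor(counts))) {
    stopf("counts must be nonnegative integers")
  }
  ord <- order(loci$chrom, loci$pos0)
  loci <- loci[ord, , drop = FALSE]
  counts <- counts[ord]
  rownames(loci) <- NULL
  total <- sum(counts)
  if (total <= 0) stopf("sample '%s' has zero total reads", sample_id)
  structure(list(sample_id = sample_id, loci = loci,
                 counts = as.numeric(counts), total = total),
            class = "locus_counts")
}

#' @export
print.locus_counts <- function(x, ...) {
  cat(sprintf("locus_counts '%s': %d loci, %.3g reads\n",
              x$sample_id, nrow(x$loci), x$total))
  invisible(x)
}

#' Euploid reference panel
#'
#' A set of euploid DNA samples profiled over the identical locus list; the
#' comparator against which experimental samples are scored. Panel matching
#' selects a most-similar subset, so the panel must be strictly larger than
#' the match size (default 7), and at least 8 members are required.
#'
#' @param members list of [locus_counts()] over identical loci.
#' @return An object of class `reference_panel`.
#' @export
reference_panel <- function(members) {
  if (length(members) < 8L) {
    stopf("reference panel needs >= 8 members (got %d); matching a subset of 7 would be impossible",
          length(members))
  }
  ids <- members[[1]]$loci$locus_id
  for (m in members[-1]) {
    if (!identical(m$loci$locus_id, ids)) {
      stopf("panel members disagree on the locus list (e.g. sample '%s')", m$sample_id)
    }
  }
  structure(list(members = members, size = length(members)),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("reference_panel: %d euploid samples, %d loci\n",
              x$size, nrow(x$members[[1]]$loci)))
  invisible(x)
}
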