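# Shared fixtures. Heavy objects are built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small 4-subtype cohort: fast enough for module tests, structured enough
# for recovery checks.
small_cohort <- function() {
  cached("small_cohort", {
    generate_cohort(synth_config(
      n_patients_per_subtype = c(proliferative = 10, immunoreactive = 10,
                                 mixed = 10, dormant = 10),
      n_nft = 8, n_hgsc = 6, n_meso = 4,
      n_genes = 600, n_signature_per_subtype = 25,
      n_loci = 6000, seed = 107
    ))
  })
}

# The small cohort taken through variance stabilization + batch removal.
small_corrected <- function() {
  cached("small_corrected", {
    remove_batch_effects(variance_stabilize(small_cohort()$expr))
  })
}

# Lesion-only nonnegative expression matrix plus the matching truth labels.
small_lesion_matrix <- function() {
  cached("small_lesion_matrix", {
    bc <- small_corrected()
    lesion <- bc$meta$diagnosis == "STIC"
    X <- nonneg_shift_clip(aoi_matrix(bc$values[, lesion, drop = FALSE],
                                      bc$meta[lesion, , drop = FALSE],
                                      transformed = TRUE))$values
    truth <- small_cohort()$truth$aoi_subtype[colnames(X)]
    list(X = X, truth = truth)
  })
}

# Transformed aoi_matrix built directly from a numeric matrix, one batch.
as_transformed_aoi <- function(values, batch = "run1") {
  n <- ncol(values)
  if (is.null(colnames(values))) colnames(values) <- sprintf("A%03d", seq_len(n))
  if (is.null(rownames(values))) rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  meta <- data.frame(aoi_id = colnames(values), compartment = "epithelial",
                     diagnosis = "STIC", batch = rep_len(batch, n),
                     patient = colnames(values), stringsAsFactors = FALSE)
  aoi_matrix(values, meta, transformed = TRUE)
}

# Hand-built locus set on the toy genome: n loci per chromosome, evenly
# spaced, for constructing exact panel/sample fixtures.
grid_loci <- function(genome, per_chrom = 10) {
  do.call(rbind, lapply(seq_len(nrow(genome$chromosomes)), function(i) {
    L <- genome$chromosomes$length[i]
    data.frame(chrom = genome$chromosomes$chrom[i],
               pos0 = floor(seq(0, L - 1, length.out = per_chrom)),
               stringsAsFactors = FALSE)
  })) -> df
  df <- df[order(df$chrom, df$pos0), ]
  df$locus_id <- sprintf("L%05d", seq_len(nrow(df)))
  rownames(df) <- NULL
  df[, c("locus_id", "chrom", "pos0")]
}

# Bin table constructed directly (bypassing bin_log2_ratios) for CBS tests.
make_bins <- function(log2, chrom = "chr1", bin_bp = 50000) {
  starts <- (seq_along(log2) - 1) * bin_bp
  b <- data.frame(chrom = chrom, start = starts, end = starts + bin_bp,
                  n_loci = 1L, log2 = log2, stringsAsFactors = FALSE)
  attr(b, "bin_bp") <- bin_bp
  b
}

# Expand a counts matrix (categories x groups) into per-record rows.
records_from_counts <- function(counts, row_var = "level", col_var = "group") {
  out <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    do.call(rbind, lapply(seq_len(ncol(counts)), function(j) {
      if (counts[i, j] == 0) return(NULL)
      data.frame(a = rep(rownames(counts)[i], counts[i, j]),
                 b = rep(colnames(counts)[j], counts[i, j]),
                 stringsAsFactors = FALSE)
    }))
  }))
  names(out) <- c(row_var, col_var)
  out
}
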