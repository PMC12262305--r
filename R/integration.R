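# RNA-DNA integration: molecular-distance scoring against reference
# centroids and per-gene expression vs copy-number correlation through
# cytoband-mapped segment log2 ratios.

#' Reference expression centroids
#'
#' Per-gene mean stabilized expression over the AOIs of each reference
#' group (histologically unremarkable tubal epithelium, HGSC, ovarian
#' mesothelium), restricted to the signature gene union when given.
#'
#' @param m transformed [aoi_matrix()].
#' @param groups diagnosis labels to build centroids for.
#' @param signature_genes optional gene restriction (the usual distance
#'   subspace); default all genes.
#' @return Named list of named numeric vectors.
#' @export
reference_centroids <- function(m, groups = c("NFT", "HGSC", "mesothelium"),
                                signature_genes = NULL) {
  stopifnot(inherits(m, "aoi_matrix"))
  v <- m$values
  if (!is.null(signature_genes)) {
    miss <- setdiff(signature_genes, rownames(v))
    if (length(miss)) stopf("unknown signature gene(s): %s",
                            paste(utils::head(miss, 3), collapse = ", "))
    v <- v[signature_genes, , drop = FALSE]
  }
  out <- lapply(groups, function(g) {
    j <- which(m$meta$diagnosis == g)
    if (!length(j)) stopf("no AOIs with diagnosis '%s'", g)
    rowMeans(v[, j, drop = FALSE])
  })
  stats::setNames(out, groups)
}

#' Molecular distance between an expression profile and a centroid
#'
#' Euclidean distance over the union of subtype signature genes (at most
#' 4 x 50 genes under the defaults), on the stabilized log2 scale without
#' z-scoring.
#'
#' @param sample_expr named numeric vector (or single-column slice) of
#'   stabilized expression.
#' @param centroid named numeric vector.
#' @param signature_genes nonempty gene subset present in both vectors.
#' @return Scalar Euclidean distance.
#' @export
molecular_distance <- function(sample_expr, centroid, signature_genes) {
  if (!length(signature_genes)) stopf("empty signature gene set")
  if (anyNA(match(signature_genes, names(sample_expr))) ||
      anyNA(match(signature_genes, names(centroid)))) {
    stopf("signature genes missing from sample or centroid")
  }
  sqrt(sum((sample_expr[signature_genes] - centroid[signature_genes])^2))
}

#' Map genes to cytobands
#'
#' Assigns each gene to the cytoband containing its start coordinate
#' (0-based, half-open intervals: a gene at a band's end boundary belongs
#' to the next band). Genes outside every band are reported unmapped.
#'
#' @param gene_coords data.frame with `gene_id`, `chrom`, `pos0`.
#' @param genome a [genome_model()].
#' @return list of class `cytoband_map`: `genes` (data.frame gene_id,
#'   chrom, pos0, cytoband), `band_genes` (named list), `unmapped`.
#' @export
map_genes_to_cytobands <- function(gene_coords, genome) {
  need <- c("gene_id", "chrom", "pos0")
  if (!all(need %in% names(gene_coords))) {
    stopf("gene_coords needs columns: %s", paste(need, collapse = ", "))
  }
  if (any(!is.finite(gene_coords$pos0)) || any(gene_coords$pos0 < 0)) {
    stopf("malformed gene coordinates")
  }
  cb <- genome$cytobands
  band <- rep(NA_character_, nrow(gene_coords))
  for (k in seq_len(nrow(cb))) {
    hit <- gene_coords$chrom == cb$chrom[k] &
      gene_coords$pos0 >= cb$start[k] & gene_coords$pos0 < cb$end[k]
    band[hit] <- cb$name[k]
  }
  genes <- data.frame(gene_coords[, need], cytoband = band,
                      stringsAsFactors = FALSE)
  mapped <- genes[!is.na(genes$cytoband), , drop = FALSE]
  structure(list(
    genes = genes,
    band_genes = split(mapped$gene_id, mapped$cytoband),
    unmapped = genes$gene_id[is.na(genes$cytoband)]
  ), class = "cytoband_map")
}

# seg_log2 value at a genomic position: the overlapping segment; on ties
# (shared boundaries) the longest-overlapping, i.e. covering, segment.
segment_value_at <- function(segments, chrom, pos) {
  hits <- segments[segments$chrom == chrom & segments$start <= pos &
                     segments$end > pos, , drop = FALSE]
  if (!nrow(hits)) return(NA_real_)
  hits$seg_log2[which.max(hits$end - hits$start)]
}

#' Per-gene expression vs copy-number correlation
#'
#' For each mapped gene, pairs per-patient mean stabilized expression
#' (epithelial AOIs of the patient averaged) with the log2 ratio of the
#' DNA segment overlapping the gene's position in that patient's profile,
#' and reports the Pearson correlation with a two-sided p-value and BH q
#' across genes. Genes with fewer than `min_n` matched patients, no
#' overlapping segment, or constant DNA values are excluded with a
#' warning count.
#'
#' @param expr transformed [aoi_matrix()].
#' @param segs named list of segment tables ([cbs_segment()] output), one
#'   per patient.
#' @param map a `cytoband_map` from [map_genes_to_cytobands()].
#' @param min_n minimum matched patients per gene (default 3).
#' @return data.frame of class `correlation_result`: `gene`, `cytoband`,
#'   `r`, `p`, `q`, `n`.
#' @export
expression_cn_correlation <- function(expr, segs, map, min_n = 3) {
  stopifnot(inherits(expr, "aoi_matrix"), inherits(map, "cytoband_map"))
  patients <- intersect(unique(expr$meta$patient), names(segs))
  if (length(patients) < min_n) {
    stopf("need >= %d patients with both expression and DNA", min_n)
  }
  # per-patient mean expression over that patient's epithelial AOIs
  pexp <- vapply(patients, function(p) {
    j <- which(expr$meta$patient == p & expr$meta$compartment == "epithelial")
    rowMeans(expr$values[, j, drop = FALSE])
  }, numeric(nrow(expr$values)))
  mapped <- map$genes[!is.na(map$genes$cytoband), , drop = FALSE]
  mapped <- mapped[mapped$gene_id %in% rownames(expr$values), , drop = FALSE]
  # genes x patients matrix of segment log2 values (vectorized interval
  # lookup per patient; CBS segments are non-overlapping within chromosome)
  dna_mat <- vapply(patients, function(p) {
    sg <- segs[[p]]
    out <- rep(NA_real_, nrow(mapped))
    for (cn in unique(mapped$chrom)) {
      gi <- which(mapped$chrom == cn)
      sc <- sg[sg$chrom == cn, , drop = FALSE]
      if (!nrow(sc)) next
      sc <- sc[order(sc$start), , drop = FALSE]
      ix <- findInterval(mapped$pos0[gi], sc$start)
      hit <- ix >= 1 & mapped$pos0[gi] < sc$end[pmax(ix, 1)]
      out[gi[hit]] <- sc$seg_log2[ix[hit]]
    }
    out
  }, numeric(nrow(mapped)))
  n_dropped <- 0L
  rows <- lapply(seq_len(nrow(mapped)), function(i) {
    g <- mapped$gene_id[i]
    dna <- dna_mat[i, ]
    ok <- !is.na(dna)
    if (sum(ok) < min_n || stats::sd(dna[ok]) == 0) {
      n_dropped <<- n_dropped + 1L
      return(NULL)
    }
    ct <- stats::cor.test(pexp[g, ok], dna[ok])
    data.frame(gene = g, cytoband = mapped$cytoband[i],
               r = unname(ct$estimate), p = ct$p.value, q = NA_real_,
               n = sum(ok), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stopf("no gene admitted a correlation")
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  if (n_dropped) {
    warnf("%d gene(s) excluded (too few matched samples or constant DNA)", n_dropped)
  }
  class(out) <- c("correlation_result", "data.frame")
  out
}
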