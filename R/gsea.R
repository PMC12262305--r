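# Preranked gene-set enrichment: weighted Kolmogorov-Smirnov running-sum
# enrichment scores with a seeded gene-set resampling null.

#' Read gene sets from a GMT file
#'
#' Tab-separated: set name, description, then member genes. Empty gene
#' fields are dropped; single-gene sets are kept but warned about, since
#' their enrichment statistics are unstable.
#'
#' @param path GMT file path (plain or gzip).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stopf("malformed GMT line: '%s'", substr(l, 1, 40))
    genes <- parts[-(1:2)]
    genes[nzchar(genes)]
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  small <- names(sets)[lengths(sets) < 2]
  if (length(small)) {
    warnf("gene set(s) with < 2 genes: %s", paste(small, collapse = ", "))
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional per-set description strings.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
}

# Weighted KS running-sum enrichment score for hit positions in a ranking
# sorted by decreasing score. Hits step up by |score|^weight (normalized),
# misses step down uniformly; ES is the extreme excursion (signed).
running_sum_es <- function(hit, weights_abs, weight) {
  N <- length(hit)
  nh <- sum(hit)
  if (nh == 0 || nh == N) return(0)
  w <- if (weight == 0) rep(1, N) else weights_abs^weight
  inc <- numeric(N)
  wh <- w[hit]
  if (sum(wh) == 0) wh <- rep(1, nh)  # degenerate all-zero scores
  inc[hit] <- wh / sum(wh)
  inc[!hit] <- -1 / (N - nh)
  rs <- cumsum(inc)
  rs[which.max(abs(rs))]
}

#' Preranked gene-set enrichment analysis
#'
#' Computes the weighted Kolmogorov-Smirnov running-sum enrichment score of
#' each gene set against a ranking (genes sorted by decreasing score; hits
#' weighted by |score|^weight, misses by a uniform decrement). The null is
#' seeded resampling of random gene sets of equal size from the universe;
#' p = (1 + #same-sign null |ES| >= |ES|) / (n_perm + 1); NES is ES divided
#' by the mean |ES| of the same-sign null scores; q is Benjamini-Hochberg
#' across sets.
#'
#' Gene-set resampling (rather than phenotype permutation) keeps the null
#' well-defined for small contrast groups.
#'
#' @param ranking named numeric vector of per-gene scores.
#' @param gene_sets named list of character vectors (a single set may be
#'   passed as a character vector).
#' @param weight score weight exponent (0 = classic KS, 1 = weighted).
#' @param n_perm resampling permutations.
#' @param seed permutation seed.
#' @return data.frame of class `enrichment_result`: `set`, `size`, `es`,
#'   `nes`, `p`, `q`, `leading_edge` (comma-separated).
#' @export
gsea_preranked <- function(ranking, gene_sets, weight = 1, n_perm = 1000,
                           seed = 1L) {
  if (is.null(names(ranking))) stopf("ranking must be a named vector")
  if (is.character(gene_sets)) gene_sets <- list(set = gene_sets)
  ord <- order(ranking, decreasing = TRUE)
  genes <- names(ranking)[ord]
  scores_abs <- abs(ranking[ord])
  N <- length(genes)
  rows <- lapply(names(gene_sets), function(nm) {
    members <- intersect(gene_sets[[nm]], genes)
    k <- length(members)
    if (k == 0) stopf("gene set '%s' has empty intersection with the ranking", nm)
    if (k >= N) {
      return(data.frame(set = nm, size = k, es = 0, nes = NA_real_, p = 1,
                        q = NA_real_, leading_edge = "", stringsAsFactors = FALSE))
    }
    hit <- genes %in% members
    es <- running_sum_es(hit, scores_abs, weight)
    null_es <- with_seed(child_seed(seed, "gsea"), {
      vapply(seq_len(n_perm), function(i) {
        h <- logical(N)
        h[sample.int(N, k)] <- TRUE
        running_sum_es(h, scores_abs, weight)
      }, numeric(1))
    })
    same_sign <- null_es[sign(null_es) == sign(es) | null_es == 0]
    p <- (1 + sum(abs(same_sign) >= abs(es))) / (n_perm + 1)
    denom <- mean(abs(same_sign))
    nes <- if (is.finite(denom) && denom > 0) es / denom else NA_real_
    # leading edge: hits at or before the extreme of the running sum
    w <- if (weight == 0) rep(1, N) else scores_abs^weight
    inc <- numeric(N)
    inc[hit] <- (w[hit] / sum(w[hit]))
    inc[!hit] <- -1 / (N - k)
    rs <- cumsum(inc)
    peak <- which.max(abs(rs))
    le <- if (es >= 0) genes[seq_len(peak)][hit[seq_len(peak)]] else
      genes[peak:N][hit[peak:N]]
    data.frame(set = nm, size = k, es = es, nes = nes, p = p, q = NA_real_,
               leading_edge = paste(le, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$p)
  out$q[ok] <- bh_adjust(out$p[ok])
  class(out) <- c("enrichment_result", "data.frame")
  out
}
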