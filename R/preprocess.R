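# Preprocessing of AOI expression: variance stabilization, least-squares
# batch-effect removal, a kBET-style batch-mixing rejection rate, and a
# deterministic PCA embedding.

#' Variance-stabilizing transformation
#'
#' Upper-quartile size normalization per AOI followed by log2(x + 1): each
#' AOI's counts are divided by the ratio of its upper quartile (over its
#' nonzero counts) to the median upper quartile across AOIs, so rescaling a
#' single AOI's counts cancels out and identical AOIs get a unit size
#' factor.
#'
#' @param m an [aoi_matrix()] of raw counts (`transformed = FALSE`).
#' @return The transformed [aoi_matrix()] (`transformed = TRUE`).
#' @export
variance_stabilize <- function(m) {
  stopifnot(inherits(m, "aoi_matrix"))
  if (m$transformed) stopf("matrix is already transformed")
  totals <- colSums(m$values)
  if (any(totals == 0)) {
    stopf("AOI(s) with all-zero counts: %s",
          paste(colnames(m$values)[totals == 0], collapse = ", "))
  }
  uq <- apply(m$values, 2, function(x) stats::quantile(x[x > 0], 0.75))
  size_factor <- uq / stats::median(uq)
  v <- log2(sweep(m$values, 2, size_factor, "/") + 1)
  aoi_matrix(v, m$meta, transformed = TRUE)
}

#' Remove run-level batch effects
#'
#' Per gene, subtracts each batch's mean deviation from the grand mean
#' (one-way least-squares batch-effect removal). Preserves the per-gene
#' grand mean exactly and is idempotent. Applied after variance
#' stabilization, where errors are approximately additive.
#'
#' @param m transformed [aoi_matrix()].
#' @param batch_key metadata column naming the batch (default "batch").
#' @return Batch-corrected [aoi_matrix()]. Values may be negative; shift and
#'   clip with [nonneg_shift_clip()] before nonnegative factorization.
#' @export
remove_batch_effects <- function(m, batch_key = "batch") {
  stopifnot(inherits(m, "aoi_matrix"))
  if (!m$transformed) stopf("apply variance_stabilize() first")
  batch <- factor(m$meta[[batch_key]])
  if (nlevels(batch) < 2L) {
    warnf("single batch: nothing to remove")
    return(m)
  }
  sizes <- table(batch)
  if (any(sizes < 2L)) {
    stopf("batch(es) with a single AOI: %s",
          paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  grand <- rowMeans(m$values)
  v <- m$values
  for (b in levels(batch)) {
    j <- which(batch == b)
    dev <- rowMeans(v[, j, drop = FALSE]) - grand
    v[, j] <- v[, j] - dev
  }
  out <- aoi_matrix(v, m$meta, transformed = TRUE)
  out
}

#' Shift-and-clip repair of negative expression values
#'
#' Batch correction can push stabilized expression below zero; nonnegative
#' factorization requires nonnegative input. Shifts the whole matrix up by
#' the global minimum when negative, then clips any residual negatives at 0.
#'
#' @param m transformed [aoi_matrix()].
#' @return Nonnegative [aoi_matrix()].
#' @export
nonneg_shift_clip <- function(m) {
  stopifnot(inherits(m, "aoi_matrix"))
  v <- m$values
  mn <- min(v)
  if (mn < 0) v <- v - mn
  v[v < 0] <- 0
  aoi_matrix(v, m$meta, transformed = m$transformed)
}

#' Centered PCA embedding
#'
#' Principal components of the AOIs (genes as features). Component signs
#' are fixed by making the largest-magnitude loading entry of each
#' component positive, so repeated runs give identical coordinates.
#'
#' @param m transformed [aoi_matrix()].
#' @param k number of components, at most min(genes, AOIs).
#' @return list of class `embedding` with `coordinates` (AOIs x k) and
#'   `explained_variance` (fraction per component, nonincreasing).
#' @export
pca_embed <- function(m, k = 10) {
  stopifnot(inherits(m, "aoi_matrix"))
  if (!m$transformed) stopf("apply variance_stabilize() first")
  if (!is_count(k)) stopf("k must be a positive integer")
  n <- ncol(m$values); p <- nrow(m$values)
  if (k > min(n, p)) stopf("k exceeds min(genes, AOIs)")
  pc <- stats::prcomp(t(m$values), center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  coords <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      coords[, j] <- -coords[, j]
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(coordinates = coords,
                 explained_variance = ev[seq_len(k)]),
            class = "embedding")
}

#' kBET-style batch-mixing rejection rate
#'
#' For `n_draws` randomly chosen anchor AOIs, tests the batch composition
#' of the anchor's k-nearest-neighborhood (Euclidean, in the embedding)
#' against the global batch frequencies with a chi-square goodness-of-fit
#' test, and reports the fraction of anchors rejected at level `alpha`.
#' 0 means perfectly mixed batches; values near 1 indicate batch
#' separation.
#'
#' @param e an `embedding` (or coordinate matrix, AOIs x k).
#' @param batches batch label per AOI.
#' @param k neighborhood size (anchor included); must exceed the number of
#'   batches and be below the number of AOIs.
#' @param alpha test level.
#' @param n_draws number of anchors.
#' @param seed anchor-sampling seed.
#' @return Rejection rate in [0, 1].
#' @export
batch_mixing_score <- function(e, batches, k = 25, alpha = 0.05,
                               n_draws = 100, seed = 1L) {
  coords <- if (inherits(e, "embedding")) e$coordinates else as.matrix(e)
  n <- nrow(coords)
  batches <- factor(batches)
  if (nlevels(batches) < 2L) stopf("need >= 2 batches")
  if (k >= n) stopf("k must be below the number of AOIs")
  if (k <= nlevels(batches)) stopf("k must exceed the number of batches")
  global <- as.numeric(table(batches)) / n
  with_seed(seed, {
    anchors <- sample.int(n, min(n_draws, n), replace = n_draws > n)
    rejected <- vapply(anchors, function(i) {
      d <- sqrt(colSums((t(coords) - coords[i, ])^2))
      nb <- order(d)[seq_len(k)]
      obs <- as.numeric(table(batches[nb]))
      stat <- sum((obs - k * global)^2 / (k * global))
      p <- stats::pchisq(stat, df = nlevels(batches) - 1L, lower.tail = FALSE)
      p < alpha
    }, logical(1))
    mean(rejected)
  })
}
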