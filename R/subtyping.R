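# Consensus non-negative matrix factorization for molecular subtype
# discovery, with rank selection by cophenetic correlation, dispersion and
# silhouette width.

#' Non-negative matrix factorization by multiplicative updates
#'
#' Minimizes the Frobenius reconstruction error ||X - WH||_F by the
#' classical multiplicative update rules, which never increase the loss.
#' Stops when the relative loss change drops below `tol` or after
#' `max_iter` iterations. Initialization is uniform random, so the result
#' is deterministic given `seed`.
#'
#' @param X nonnegative numeric matrix (genes x AOIs). All-zero rows are
#'   dropped with a warning before factorization (their basis weights are
#'   identically zero anyway).
#' @param r factorization rank, at least 1.
#' @param seed integer seed for the random initialization.
#' @param max_iter,tol stopping controls.
#' @param init `"runif"` (default) uses uniform random entries;
#'   `"exemplar"` seeds each basis column with one distinct random data
#'   column; `"acol"` averages a few random columns.
#' @return list of class `nmf_factors`: `W` (genes x r), `H` (r x AOIs),
#'   `loss` (final Frobenius error), `loss_trace`, `n_iter`, `seed`,
#'   `kept_rows`.
#' @export
nmf_factorize <- function(X, r, seed = 1L, max_iter = 500, tol = 1e-6,
                          init = c("runif", "exemplar", "acol")) {
  init <- match.arg(init)
  X <- as.matrix(X)
  if (any(X < 0)) stopf("X must be nonnegative; shift/clip upstream (see nonneg_shift_clip)")
  if (!is_count(r)) stopf("rank r must be a positive integer")
  zr <- rowSums(X) == 0
  if (any(zr)) {
    warnf("dropping %d all-zero row(s) before factorization", sum(zr))
    X <- X[!zr, , drop = FALSE]
  }
  zc <- colSums(X) == 0
  if (any(zc)) {
    warnf("dropping %d all-zero column(s) before factorization", sum(zc))
    X <- X[, !zc, drop = FALSE]
  }
  n <- nrow(X); p <- ncol(X)
  if (r > min(n, p)) stopf("rank r exceeds matrix dimensions")
  eps <- .Machine$double.eps
  with_seed(seed, {
    scale0 <- sqrt(mean(X) / r)
    if (init == "exemplar") {
      W <- X[, sample.int(p, r), drop = FALSE] + eps
    } else if (init == "acol") {
      W <- vapply(seq_len(r), function(k) {
        rowMeans(X[, sample.int(p, min(5L, p)), drop = FALSE])
      }, numeric(n)) + eps
      W <- matrix(W, n, r)
    } else {
      W <- matrix(stats::runif(n * r, min = eps, max = 1) * scale0, n, r)
    }
    H <- matrix(stats::runif(r * p, min = eps, max = 1) * scale0, r, p)
    loss_trace <- numeric(0)
    normX2 <- sum(X^2)
    prev <- Inf
    it <- 0L
    repeat {
      it <- it + 1L
      # H half-step, with the loss of (W, H_new) from the same intermediates
      WtX <- crossprod(W, X)
      WtW <- crossprod(W)
      H <- H * (WtX / (WtW %*% H + eps))
      loss2 <- normX2 - 2 * sum(WtX * H) + sum(WtW * tcrossprod(H))
      loss <- sqrt(max(loss2, 0))
      loss_trace <- c(loss_trace, loss)
      # W half-step
      HHt <- tcrossprod(H)
      W <- W * (X %*% t(H)) / (W %*% HHt + eps)
      if (it >= max_iter) break
      if (is.finite(prev) && prev > 0 && (prev - loss) / prev < tol) break
      prev <- loss
    }
    # final loss consistent with the returned (W, H)
    loss <- sqrt(sum((X - W %*% H)^2))
    # fix the diagonal scaling ambiguity: unit-norm basis columns, scale
    # absorbed into H, so per-AOI argmax reflects loadings, not factor norms
    d <- sqrt(colSums(W^2))
    d[d == 0] <- 1
    W <- sweep(W, 2, d, "/")
    H <- H * d
    structure(list(W = W, H = H, loss = loss, loss_trace = loss_trace,
                   n_iter = it, seed = as.integer(seed), kept_rows = !zr),
              class = "nmf_factors")
  })
}

#' @export
print.nmf_factors <- function(x, ...) {
  cat(sprintf("nmf_factors: rank %d, %d iterations, Frobenius loss %.4g\n",
              ncol(x$W), x$n_iter, x$loss))
  invisible(x)
}

# cluster AOIs by the dominant basis component of each H column;
# ties break toward the lower component index (which.max convention).
cluster_from_H <- function(H) apply(H, 2, which.max)

#' Consensus NMF clustering
#'
#' Runs `n_runs` seeded factorizations (run i uses seed + i), clusters AOIs
#' by the argmax of their H column in each run, and records the fraction of
#' runs in which each AOI pair is co-assigned (the consensus matrix). Final
#' labels come from average-linkage hierarchical clustering of
#' 1 - consensus cut at `r`; the stability metrics (cophenetic correlation,
#' dispersion, mean silhouette width) are computed on the consensus.
#'
#' @param X nonnegative matrix (genes x AOIs).
#' @param r rank / cluster count, at least 2 and below the AOI count.
#' @param n_runs number of factorization runs (>= 2).
#' @param seed base seed.
#' @param max_iter,tol per-run stopping controls. Consensus stability is
#'   only meaningful between converged runs: half-converged factorizations
#'   blur the argmax assignments at the true rank while extra factors at
#'   over-fitted ranks absorb the blur reproducibly, which inverts the
#'   stability ordering. Keep runs close to convergence.
#' @return list of class `consensus_result`: `rank`, `consensus`,
#'   `cophenetic`, `dispersion`, `silhouette`, `labels`, `n_runs`.
#' @export
consensus_nmf <- function(X, r, n_runs = 100, seed = 1L,
                          max_iter = 400, tol = 1e-6) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (!is_count(r) || r < 2) stopf("rank r must be an integer >= 2")
  if (r >= p) stopf("rank r must be below the number of AOIs")
  if (!is_count(n_runs) || n_runs < 2) stopf("n_runs must be >= 2")
  if (any(colSums(X) == 0)) stopf("all-zero AOI column(s); cannot cluster them")
  co <- matrix(0, p, p)
  for (i in seq_len(n_runs)) {
    f <- suppressWarnings(
      nmf_factorize(X, r, seed = as.integer(seed) + i,
                    max_iter = max_iter, tol = tol)
    )
    lab <- cluster_from_H(f$H)
    co <- co + outer(lab, lab, "==")
  }
  consensus <- co / n_runs
  dimnames(consensus) <- list(colnames(X), colnames(X))
  d <- stats::as.dist(1 - consensus)
  hc <- stats::hclust(d, method = "average")
  labels <- stats::cutree(hc, k = r)
  sil <- if (length(unique(labels)) > 1L) {
    mean(cluster::silhouette(labels, d)[, "sil_width"])
  } else {
    NA_real_
  }
  structure(list(
    rank = r, consensus = consensus,
    cophenetic = cophenetic_correlation(consensus),
    dispersion = mean(4 * (consensus - 0.5)^2),
    silhouette = sil,
    labels = labels, n_runs = n_runs
  ), class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf(
    "consensus_result: rank %d over %d runs | cophenetic %.3f, dispersion %.3f, silhouette %.3f\n",
    x$rank, x$n_runs, x$cophenetic, x$dispersion, x$silhouette))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Cophenetic correlation of a consensus matrix
#'
#' Pearson correlation between the consensus distances (1 - consensus) and
#' the cophenetic distances of their average-linkage dendrogram; 1 for
#' perfectly stable clustering. A constant distance matrix carries no
#' disagreement between the two and returns 1 with a warning.
#'
#' @param consensus symmetric matrix of co-clustering frequencies in [0,1].
#' @return Scalar in [-1, 1].
#' @export
cophenetic_correlation <- function(consensus) {
  consensus <- as.matrix(consensus)
  if (any(consensus < -1e-9) || any(consensus > 1 + 1e-9) ||
      any(abs(consensus - t(consensus)) > 1e-9)) {
    stopf("consensus must be a symmetric matrix with entries in [0,1]")
  }
  d <- stats::as.dist(1 - consensus)
  if (stats::sd(d) == 0) {
    warnf("constant consensus distances; cophenetic correlation set to 1")
    return(1)
  }
  hc <- stats::hclust(d, method = "average")
  coph <- stats::cophenetic(hc)
  if (stats::sd(coph) == 0) {
    warnf("constant cophenetic distances; correlation set to 1")
    return(1)
  }
  stats::cor(as.numeric(d), as.numeric(coph))
}

#' Select the factorization rank
#'
#' Among candidate consensus results, picks the rank maximizing the
#' cophenetic correlation; ties break toward higher silhouette width, then
#' toward the smaller rank. Because the cophenetic correlation is a Monte
#' Carlo estimate over a finite number of consensus runs, candidates whose
#' cophenetic values lie within `tie_eps` of the maximum are treated as
#' tied and resolved by the silhouette (then smaller-rank) rule; an exact
#' floating-point tie would otherwise almost never trigger. Returns the
#' full metric table for inspection, since published practice tempers the
#' quantitative choice with interpretability.
#'
#' @param results list of `consensus_result` (>= 2 candidate ranks).
#' @param tie_eps stability-resolution tolerance on the cophenetic
#'   correlation (default 0.005, about the run-to-run noise of a
#'   100-run consensus).
#' @return list with `rank` (the selected r*) and `metrics` (data.frame of
#'   rank, cophenetic, dispersion, silhouette).
#' @export
select_rank <- function(results, tie_eps = 0.005) {
  if (length(results) < 2L) stopf("need >= 2 candidate ranks")
  metrics <- do.call(rbind, lapply(results, function(x) {
    data.frame(rank = x$rank, cophenetic = x$cophenetic,
               dispersion = x$dispersion, silhouette = x$silhouette)
  }))
  metrics <- metrics[order(metrics$rank), , drop = FALSE]
  rownames(metrics) <- NULL
  near_best <- metrics$cophenetic >= max(metrics$cophenetic) - tie_eps
  cand <- metrics[near_best, , drop = FALSE]
  ord <- order(-cand$silhouette, cand$rank)
  list(rank = cand$rank[ord[1]], metrics = metrics)
}
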