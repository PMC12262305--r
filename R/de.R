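# Moderated differential expression: per-gene two-group linear models with
# empirical-Bayes variance shrinkage (method-of-moments prior fit),
# Benjamini-Hochberg correction, and the unique-signature extraction used
# for molecular-distance scoring.

#' Moderated two-group differential expression
#'
#' Fits a per-gene two-group comparison on stabilized (log2) expression.
#' Residual variances are shrunk toward a pooled prior: assuming the usual
#' hierarchical model (per-gene variance sampled around a prior scale s0^2
#' with d0 prior degrees of freedom), d0 and s0^2 are estimated by matching
#' the mean and variance of the observed residual variances to the moments
#' of the implied scaled F distribution. The moderated t uses the posterior
#' variance (d0 s0^2 + d s^2) / (d0 + d) with d0 + d degrees of freedom. In
#' the d0 -> Inf limit this reduces to an ordinary t with the common pooled
#' variance.
#'
#' @param m transformed [aoi_matrix()].
#' @param group_a,group_b AOI ids (or logical/integer selectors on columns)
#'   of the two groups; log2 fold changes are mean(A) - mean(B). Each group
#'   needs >= 2 AOIs.
#' @param lfc_threshold,alpha significance thresholds: a gene is flagged
#'   significant when adjusted p < `alpha` and |log2fc| > `lfc_threshold`.
#' @param prior_df optional fixed prior degrees of freedom overriding the
#'   moment estimate; `Inf` forces the fully pooled common variance.
#' @return data.frame of class `de_result`: `gene`, `log2fc`, `mean_expr`,
#'   `t`, `p`, `adj_p`, `significant`; prior df and scale in attributes.
#' @export
fit_de <- function(m, group_a, group_b, lfc_threshold = 0.5, alpha = 0.05,
                   prior_df = NULL) {
  stopifnot(inherits(m, "aoi_matrix"))
  if (!m$transformed) stopf("fit_de expects transformed expression")
  ja <- if (is.character(group_a)) match(group_a, colnames(m$values)) else
    if (is.logical(group_a)) which(group_a) else as.integer(group_a)
  jb <- if (is.character(group_b)) match(group_b, colnames(m$values)) else
    if (is.logical(group_b)) which(group_b) else as.integer(group_b)
  if (anyNA(ja) || anyNA(jb)) stopf("unknown AOI id(s) in group selection")
  na <- length(ja); nb <- length(jb)
  if (na < 2 || nb < 2) stopf("each group needs >= 2 AOIs (got %d and %d)", na, nb)
  A <- m$values[, ja, drop = FALSE]
  B <- m$values[, jb, drop = FALSE]
  ma <- rowMeans(A); mb <- rowMeans(B)
  log2fc <- ma - mb
  d <- na + nb - 2
  s2 <- (rowSums((A - ma)^2) + rowSums((B - mb)^2)) / d
  prior <- if (is.null(prior_df)) {
    fit_variance_prior(s2, d)
  } else {
    list(d0 = prior_df, s0_2 = mean(s2))
  }
  s2_post <- if (is.infinite(prior$d0)) {
    rep(prior$s0_2, length(s2))
  } else {
    (prior$d0 * prior$s0_2 + d * s2) / (prior$d0 + d)
  }
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  tstat <- log2fc / se
  df_total <- d + prior$d0
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  adj <- bh_adjust(p)
  out <- data.frame(
    gene = rownames(m$values), log2fc = log2fc,
    mean_expr = (ma * na + mb * nb) / (na + nb),
    t = tstat, p = p, adj_p = adj,
    significant = adj < alpha & abs(log2fc) > lfc_threshold,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("de_result", "data.frame")
  attr(out, "prior_df") <- prior$d0
  attr(out, "prior_scale") <- prior$s0_2
  attr(out, "residual_df") <- d
  out
}

# Method-of-moments fit of the variance prior: under the hierarchical
# model, s2 / s0^2 ~ F(d, d0). Matching the squared coefficient of
# variation of the observed s2 to that of the F distribution gives d0;
# the mean gives s0^2. cv^2 * d <= 2 means no excess dispersion beyond
# chi-square sampling noise: d0 = Inf (fully pooled variance).
fit_variance_prior <- function(s2, d) {
  m1 <- mean(s2)
  if (m1 <= 0) return(list(d0 = Inf, s0_2 = m1))
  cv2 <- stats::var(s2) / m1^2
  if (!is.finite(cv2) || cv2 * d <= 2) {
    return(list(d0 = Inf, s0_2 = m1))
  }
  d0 <- (4 * cv2 * d + 2 * d - 4) / (cv2 * d - 2)
  if (!is.finite(d0) || d0 <= 4) d0 <- 4.01  # moment fit valid for d0 > 4
  s0_2 <- m1 * (d0 - 2) / d0
  list(d0 = d0, s0_2 = s0_2)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control with monotone enforcement, capped
#' at 1; a validating front end over the standard step-up implementation.
#'
#' @param pvals numeric p-values in [0, 1].
#' @return Adjusted p-values (same order as the input).
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Top uniquely upregulated genes per subtype
#'
#' From one subtype-vs-rest DE result per subtype, takes the significantly
#' upregulated genes (significant flag and positive log2fc), removes any
#' gene that is significantly upregulated in two or more subtypes, ranks
#' the remainder by moderated t descending, and truncates each list to `n`
#' -- the gene filter used for molecular-distance scoring.
#'
#' @param de_per_subtype named list of [fit_de()] results over a shared
#'   gene universe.
#' @param n list length per subtype (default 50).
#' @return Named list of character vectors; lists shorter than `n` trigger
#'   a warning.
#' @export
top_upregulated_unique <- function(de_per_subtype, n = 50) {
  stopifnot(length(de_per_subtype) >= 1)
  universe <- de_per_subtype[[1]]$gene
  for (d in de_per_subtype) {
    if (!identical(sort(d$gene), sort(universe))) {
      stopf("DE results must share one gene universe")
    }
  }
  up <- lapply(de_per_subtype, function(d) d$gene[d$significant & d$log2fc > 0])
  tally <- table(unlist(up))
  shared <- names(tally)[tally >= 2]
  out <- lapply(names(de_per_subtype), function(s) {
    d <- de_per_subtype[[s]]
    eligible <- setdiff(up[[s]], shared)
    dd <- d[d$gene %in% eligible, , drop = FALSE]
    sig <- dd$gene[order(-dd$t)]
    if (length(sig) < n) {
      warnf("subtype '%s': only %d eligible unique genes (< %d)", s, length(sig), n)
    }
    utils::head(sig, n)
  })
  stats::setNames(out, names(de_per_subtype))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
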