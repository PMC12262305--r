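# RealSeqS-style aneuploidy inference from genome-wide locus counts:
# reference-panel matching, per-arm Z statistics with |Z| > 5 calls on the
# 39 non-acrocentric autosome arms, 50-kb bin log2 ratios, circular binary
# segmentation, focal amplification calls at target cytobands, and the
# aneuploidy index.

#' Normalize locus counts to genome-wide fractions
#'
#' @param s a [locus_counts()] sample.
#' @return Numeric vector of locus fractions summing to 1.
#' @export
normalize_loci <- function(s) {
  stopifnot(inherits(s, "locus_counts"))
  if (s$total <= 0) stopf("total read count must be positive")
  s$counts / s$total
}

#' Match a sample to its most similar reference-panel subset
#'
#' Selects the `n_match` panel members whose locus-fraction vectors are
#' closest to the sample's in Euclidean distance (the amplicon-distribution
#' matching step performed before arm-level scoring). Ties break by panel
#' member order.
#'
#' @param s a [locus_counts()] sample.
#' @param panel a [reference_panel()] over the same loci.
#' @param n_match subset size (study convention: 7 of 30); must be below
#'   the panel size.
#' @return A [reference_panel()]-like list restricted to the matched
#'   members (class `matched_panel`, with `distances` for all members).
#' @export
match_reference <- function(s, panel, n_match = 7) {
  stopifnot(inherits(s, "locus_counts"), inherits(panel, "reference_panel"))
  if (n_match >= panel$size) {
    stopf("n_match (%d) must be below the panel size (%d)", n_match, panel$size)
  }
  if (!identical(s$loci$locus_id, panel$members[[1]]$loci$locus_id)) {
    both <- intersect(s$loci$locus_id, panel$members[[1]]$loci$locus_id)
    bad <- setdiff(union(s$loci$locus_id, panel$members[[1]]$loci$locus_id), both)
    stopf("sample and panel disagree on loci (e.g. %s)",
          paste(utils::head(bad, 3), collapse = ", "))
  }
  f <- normalize_loci(s)
  d <- vapply(panel$members, function(m) {
    sqrt(sum((f - normalize_loci(m))^2))
  }, numeric(1))
  sel <- order(d)[seq_len(n_match)]
  structure(list(members = panel$members[sel], size = n_match,
                 selected = sel,
                 distances = stats::setNames(d, vapply(panel$members,
                                                       `[[`, "", "sample_id"))),
            class = c("matched_panel", "reference_panel"))
}

# Per-arm fraction statistic: sum of locus fractions within the arm, over
# the genome model's scoreable arms.
arm_fractions <- function(fractions, loci, genome, arm = NULL) {
  if (is.null(arm)) arm <- assign_arm(loci$chrom, loci$pos0, genome)
  arms <- genome$scoreable_arms$name
  keep <- !is.na(arm) & arm %in% arms
  sums <- rowsum(fractions[keep], arm[keep])
  out <- stats::setNames(numeric(length(arms)), arms)
  out[rownames(sums)] <- sums[, 1]
  out
}

#' Arm-level aneuploidy Z-scores
#'
#' For each of the 39 scoreable (non-acrocentric autosome) arms, the
#' observed statistic is the sample's summed locus fraction in the arm;
#' mu and sigma are the mean and SD (n-1 denominator) of the same statistic
#' across the matched panel members; Z = (observed - mu) / sigma. An arm is
#' called gained if Z > threshold, lost if Z < -threshold, neutral
#' otherwise (threshold 5 by convention).
#'
#' @param s a [locus_counts()] sample.
#' @param matched a matched [reference_panel()] (see [match_reference()]).
#' @param genome a [genome_model()].
#' @param threshold call threshold on |Z|.
#' @return data.frame of class `arm_z_profile` with columns `arm`,
#'   `observed`, `mu`, `sigma`, `z`, `call`; arms with zero panel SD are
#'   called neutral and listed in `attr(, "warnings")`.
#' @export
arm_zscores <- function(s, matched, genome, threshold = 5) {
  stopifnot(inherits(s, "locus_counts"), inherits(matched, "reference_panel"))
  if (!identical(s$loci$locus_id, matched$members[[1]]$loci$locus_id)) {
    stopf("sample and matched panel disagree on loci")
  }
  arm_of <- assign_arm(s$loci$chrom, s$loci$pos0, genome)
  obs <- arm_fractions(normalize_loci(s), s$loci, genome, arm = arm_of)
  if (any(obs == 0)) {
    # scoreable arms must carry at least one locus to be testable
    empty <- setdiff(names(obs), unique(arm_of))
    if (length(empty)) stopf("arm(s) without loci: %s", paste(empty, collapse = ", "))
  }
  panel_stats <- vapply(matched$members, function(m) {
    arm_fractions(normalize_loci(m), m$loci, genome, arm = arm_of)
  }, numeric(length(obs)))
  mu <- rowMeans(panel_stats)
  sigma <- apply(panel_stats, 1, stats::sd)
  z <- (obs - mu) / sigma
  # zero panel SD: z is 0/0 when the sample agrees with the panel exactly
  # (define as 0), undefined otherwise (flagged, called neutral)
  exact <- sigma == 0 & obs == mu
  z[exact] <- 0
  flagged <- names(obs)[sigma == 0 & obs != mu]
  z[sigma == 0 & obs != mu] <- NA_real_
  call <- ifelse(is.na(z), "neutral",
                 ifelse(z > threshold, "gain",
                        ifelse(z < -threshold, "loss", "neutral")))
  out <- data.frame(arm = names(obs), observed = obs, mu = mu, sigma = sigma,
                    z = z, call = call, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("arm_z_profile", "data.frame")
  attr(out, "threshold") <- threshold
  attr(out, "warnings") <- if (length(flagged)) {
    sprintf("zero panel SD on arm(s): %s", paste(flagged, collapse = ", "))
  } else {
    character(0)
  }
  out
}

#' Per-bin log2 copy-number ratios
#'
#' Partitions each chromosome into non-overlapping `bin_bp` intervals
#' (0-based half-open; a trailing partial bin is kept when it contains at
#' least one locus), sums locus fractions per bin for the sample and for
#' the matched-panel mean, and reports
#' log2((sample + p) / (panel mean + p)) with pseudocount
#' p = pseudo / n_loci. Bins without loci get NA and are excluded
#' downstream.
#'
#' @param s a [locus_counts()] sample.
#' @param matched matched [reference_panel()].
#' @param genome a [genome_model()].
#' @param bin_bp bin width in bp (default 50 kb).
#' @param pseudo pseudocount numerator.
#' @return data.frame with `chrom`, `start`, `end`, `n_loci`, `log2`;
#'   `attr(, "bin_bp")` records the bin width.
#' @export
bin_log2_ratios <- function(s, matched, genome, bin_bp = 50000, pseudo = 0.5) {
  stopifnot(inherits(s, "locus_counts"))
  f_s <- normalize_loci(s)
  f_p <- rowMeans(vapply(matched$members, normalize_loci,
                         numeric(nrow(s$loci))))
  p <- pseudo / nrow(s$loci)
  bins <- do.call(rbind, lapply(seq_len(nrow(genome$chromosomes)), function(i) {
    cn <- genome$chromosomes$chrom[i]
    L <- genome$chromosomes$length[i]
    starts <- seq(0, L - 1, by = bin_bp)
    data.frame(chrom = cn, start = starts,
               end = pmin(starts + bin_bp, L), stringsAsFactors = FALSE)
  }))
  key_bin <- paste(bins$chrom, bins$start %/% bin_bp)
  key_loc <- paste(s$loci$chrom, s$loci$pos0 %/% bin_bp)
  ix <- match(key_loc, key_bin)
  sum_by <- function(v) {
    out <- numeric(nrow(bins))
    agg <- tapply(v, ix, sum)
    out[as.integer(names(agg))] <- agg
    out
  }
  bins$n_loci <- sum_by(rep(1, nrow(s$loci)))
  bin_s <- sum_by(f_s)
  bin_p <- sum_by(f_p)
  bins$log2 <- ifelse(bins$n_loci > 0, log2((bin_s + p) / (bin_p + p)), NA_real_)
  attr(bins, "bin_bp") <- bin_bp
  bins
}

#' Circular binary segmentation of per-bin log2 ratios
#'
#' Recursive change-point partitioning per chromosome: the circular arc
#' maximizing the standardized mean-difference statistic is accepted as a
#' split if its permutation p-value (over `n_perm` seeded shuffles of the
#' bins) is below `alpha`, and the procedure recurses into the resulting
#' segments. Missing bins are excluded; segments partition the non-missing
#' bins of each chromosome.
#'
#' @param bins output of [bin_log2_ratios()].
#' @param alpha split acceptance level.
#' @param n_perm permutations per candidate split.
#' @param min_width minimum bins per segment.
#' @param seed permutation seed.
#' @return data.frame with `chrom`, `start`, `end`, `n_bins`, `seg_log2`;
#'   `attr(, "bin_bp")` is propagated from `bins`.
#' @export
cbs_segment <- function(bins, alpha = 0.01, n_perm = 1000, min_width = 2,
                        seed = 1L) {
  bin_bp <- attr(bins, "bin_bp")
  segs <- with_seed(seed, {
    out <- list()
    for (cn in unique(bins$chrom)) {
      b <- bins[bins$chrom == cn & !is.na(bins$log2), , drop = FALSE]
      if (!nrow(b)) next
      x <- b$log2
      pieces <- cbs_recurse(x, alpha, n_perm, min_width)
      for (pc in pieces) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = cn, start = b$start[pc[1]], end = b$end[pc[2]],
          n_bins = pc[2] - pc[1] + 1L,
          seg_log2 = mean(x[pc[1]:pc[2]]), stringsAsFactors = FALSE
        )
      }
    }
    if (length(out)) do.call(rbind, out) else
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 n_bins = integer(), seg_log2 = numeric())
  })
  attr(segs, "bin_bp") <- bin_bp
  segs
}

# Recursive splitter on a vector of bin values; returns a list of
# c(first, last) index pairs partitioning 1..length(x).
cbs_recurse <- function(x, alpha, n_perm, min_width) {
  n <- length(x)
  whole <- list(c(1L, n))
  if (n < 2L * min_width) return(whole)
  sp <- cbs_split_cpp(x, as.integer(n_perm), as.integer(min_width), alpha)
  if (is.na(sp$stat) || sp$p >= alpha) return(whole)
  i <- sp$i; j <- sp$j  # arc is (i, j] in 0-based prefix indices
  cuts <- c(if (i > 0) i, if (j < n) j)
  if (!length(cuts)) return(whole)
  bounds <- c(0L, as.integer(cuts), n)
  out <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    lo <- bounds[k] + 1L
    hi <- bounds[k + 1L]
    sub <- cbs_recurse(x[lo:hi], alpha, n_perm, min_width)
    for (pc in sub) out[[length(out) + 1L]] <- pc + lo - 1L
  }
  out
}

#' Call focal amplifications at target cytobands
#'
#' A target band is called amplified when some segment overlaps it, has
#' seg_log2 above `log2_min`, and spans less than `max_arm_frac` of its
#' chromosome arm (the sub-chromosomal requirement: whole-arm gains do not
#' qualify as focal events).
#'
#' @param segments output of [cbs_segment()].
#' @param genome a [genome_model()].
#' @param targets cytoband names to interrogate.
#' @param log2_min amplification threshold (default 0.25).
#' @param max_arm_frac maximum fraction of the arm a qualifying segment may
#'   span (default 0.9).
#' @return data.frame with `target`, `called`, `seg_log2` (log2 of the
#'   best qualifying segment, NA when none).
#' @export
call_focal_amplifications <- function(segments, genome,
                                      targets = c("19q12", "19q13.2", "8q24"),
                                      log2_min = 0.25, max_arm_frac = 0.9) {
  rows <- lapply(targets, function(tg) {
    iv <- cytoband_interval(genome, tg)
    arm_name <- assign_arm(iv$chrom, iv$start, genome)
    arm <- genome$arms[genome$arms$name == arm_name, ]
    arm_len <- arm$end - arm$start
    hits <- segments[segments$chrom == iv$chrom &
                       segments$end > iv$start & segments$start < iv$end, ,
                     drop = FALSE]
    ok <- hits[hits$seg_log2 > log2_min &
                 (hits$end - hits$start) < max_arm_frac * arm_len, ,
               drop = FALSE]
    if (nrow(ok)) {
      best <- ok[which.max(pmin(ok$end, iv$end) - pmax(ok$start, iv$start)), ]
      data.frame(target = tg, called = TRUE, seg_log2 = best$seg_log2,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(target = tg, called = FALSE, seg_log2 = NA_real_,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Aneuploidy index
#'
#' Total binned base pairs at copy-number gain or loss: the summed widths
#' of bins whose assigned log2 ratio exceeds `log2_gain` or falls below
#' `log2_loss`. By default the segment-level log2 is assigned to every bin
#' of the segment; `level = "bin"` uses the raw per-bin values instead.
#'
#' @param segments output of [cbs_segment()] (used for `level = "segment"`
#'   and to recover the bin width).
#' @param bins output of [bin_log2_ratios()] (required for `level = "bin"`).
#' @param log2_gain,log2_loss thresholds (defaults +0.25 / -0.25).
#' @param level `"segment"` (default) or `"bin"`.
#' @return Scalar base-pair count.
#' @export
aneuploidy_index <- function(segments, bins = NULL,
                             log2_gain = 0.25, log2_loss = -0.25,
                             level = c("segment", "bin")) {
  level <- match.arg(level)
  if (level == "bin") {
    if (is.null(bins)) stopf("bin-level index needs the bins table")
    keep <- !is.na(bins$log2) &
      (bins$log2 > log2_gain | bins$log2 < log2_loss)
    return(sum(bins$end[keep] - bins$start[keep]))
  }
  bin_bp <- attr(segments, "bin_bp")
  if (is.null(bin_bp)) stopf("segments lack a bin_bp attribute")
  keep <- segments$seg_log2 > log2_gain | segments$seg_log2 < log2_loss
  sum(segments$n_bins[keep]) * bin_bp
}

#' Full aneuploidy profile for one sample
#'
#' Convenience wrapper chaining panel matching, arm Z-scores, bin log2
#' ratios, CBS, focal amplification calls and the aneuploidy index.
#'
#' @param s a [locus_counts()] sample.
#' @param panel a [reference_panel()].
#' @param genome a [genome_model()].
#' @param n_match matched subset size.
#' @param threshold arm-call threshold on |Z|.
#' @param bin_bp,alpha,n_perm,min_width,seed segmentation controls.
#' @param targets focal amplification target cytobands.
#' @return list with `arm_z`, `bins`, `segments`, `focal`, `index`.
#' @export
aneuploidy_profile <- function(s, panel, genome, n_match = 7, threshold = 5,
                               bin_bp = 50000, alpha = 0.01, n_perm = 1000,
                               min_width = 2, seed = 1L,
                               targets = c("19q12", "19q13.2", "8q24")) {
  matched <- match_reference(s, panel, n_match = n_match)
  arm_z <- arm_zscores(s, matched, genome, threshold = threshold)
  bins <- bin_log2_ratios(s, matched, genome, bin_bp = bin_bp)
  segments <- cbs_segment(bins, alpha = alpha, n_perm = n_perm,
                          min_width = min_width, seed = seed)
  focal <- call_focal_amplifications(segments, genome, targets = targets)
  list(arm_z = arm_z, bins = bins, segments = segments, focal = focal,
       index = aneuploidy_index(segments))
}
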