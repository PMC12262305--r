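toy <- toy_genome()

test_that("locus normalization yields fractions with scale invariance", {
  loci <- grid_loci(toy, 1)[1:4, ]
  s <- locus_counts("s", loci, c(2, 2, 2, 2))
  expect_equal(normalize_loci(s), rep(0.25, 4))
  s10 <- locus_counts("s10", loci, c(20, 20, 20, 20))
  expect_equal(normalize_loci(s10), normalize_loci(s))
  set.seed(3)
  sr <- locus_counts("sr", grid_loci(toy, 5), rpois(110, 40))
  expect_equal(sum(normalize_loci(sr)), 1, tolerance = 1e-12)
  expect_error(locus_counts("z", loci, c(0, 0, 0, 0)), "zero total")
})

test_that("panel matching is exact nearest-neighbor selection", {
  loci <- grid_loci(toy, 4)
  set.seed(9)
  members <- lapply(1:30, function(i) {
    locus_counts(sprintf("m%02d", i), loci, rpois(nrow(loci), 50) + 1)
  })
  panel <- reference_panel(members)
  s <- locus_counts("sample", loci, members[[17]]$counts * 3L)

  m <- match_reference(s, panel, n_match = 7)
  expect_equal(m$selected[1], 17L)  # exact copy at distance 0
  expect_equal(unname(m$distances["m17"]), 0)

  # brute-force nearest-7 oracle
  f <- s$counts / sum(s$counts)
  d <- vapply(members, function(mm) {
    sqrt(sum((f - mm$counts / sum(mm$counts))^2))
  }, numeric(1))
  expect_equal(sort(m$selected), sort(order(d)[1:7]))

  expect_error(match_reference(s, panel, n_match = 30), "below the panel size")
  bad <- locus_counts("bad", loci[-1, ], s$counts[-1])
  expect_error(match_reference(bad, panel), "disagree on loci")
})

test_that("arm Z-scores follow the panel-reference equation and call rule", {
  loci <- grid_loci(toy, 12)
  set.seed(21)
  base <- rpois(nrow(loci), 200) + 1

  # sample identical to every matched member: all z = 0, all neutral
  members <- lapply(1:8, function(i) locus_counts(sprintf("m%d", i), loci, base))
  matched <- structure(list(members = members[1:7], size = 7),
                       class = c("matched_panel", "reference_panel"))
  s_same <- locus_counts("s", loci, base)
  z_same <- arm_zscores(s_same, matched, toy)
  expect_equal(z_same$z, rep(0, 39))
  expect_true(all(z_same$call == "neutral"))
  expect_length(attr(z_same, "warnings"), 0)

  # an arm placed analytically at mu + 6 sigma scores z = 6 and is a gain
  members2 <- lapply(1:7, function(i) {
    cnt <- base + rpois(length(base), 20)
    locus_counts(sprintf("v%d", i), loci, cnt)
  })
  matched2 <- structure(list(members = members2, size = 7),
                        class = c("matched_panel", "reference_panel"))
  arm_of <- sticatlas:::assign_arm(loci$chrom, loci$pos0, toy)
  target <- "4q"
  stat <- vapply(members2, function(m) {
    f <- m$counts / sum(m$counts)
    sum(f[!is.na(arm_of) & arm_of == target])
  }, numeric(1))
  mu <- mean(stat); sg <- sd(stat)
  # craft a sample whose 4q fraction is mu + 6 sigma (scale 4q counts)
  s_cnt <- base
  in_arm <- !is.na(arm_of) & arm_of == target
  f0 <- sum(s_cnt[in_arm]) / sum(s_cnt)
  want <- mu + 6 * sg
  # solve scale a: a*x / (T - x + a*x) = want, with x arm counts, T total
  x <- sum(s_cnt[in_arm]); T <- sum(s_cnt)
  a <- want * (T - x) / (x * (1 - want))
  s_cnt[in_arm] <- round(s_cnt[in_arm] * a)
  z <- arm_zscores(locus_counts("s6", loci, s_cnt), matched2, toy)
  got <- z[z$arm == target, ]
  expect_equal(got$z, 6, tolerance = 0.05)
  expect_equal(got$call, "gain")
  # all entries agree with a direct recomputation of the equation
  f_s <- s_cnt / sum(s_cnt)
  obs_all <- vapply(z$arm, function(a2) sum(f_s[!is.na(arm_of) & arm_of == a2]),
                    numeric(1))
  expect_equal(z$z, unname((obs_all - z$mu) / z$sigma), tolerance = 1e-12)
})

test_that("a simulated single-arm loss is called on the right arm", {
  ev <- list(dormant = data.frame(region = "6q", log2 = -1))
  cfg <- synth_config(
    n_patients_per_subtype = c(proliferative = 1, immunoreactive = 1,
                               mixed = 1, dormant = 20),
    n_nft = 1, n_hgsc = 1, n_meso = 1, n_genes = 60,
    n_signature_per_subtype = 10, n_loci = 8000,
    cn_events = ev, seed = 37
  )
  b <- generate_cohort(cfg)
  pts <- names(b$truth$subtype)[b$truth$subtype == "dormant"]
  hits <- 0; fp <- 0; n_other <- 0
  for (p in pts) {
    z <- arm_zscores(b$dna[[p]], match_reference(b$dna[[p]], b$panel), b$genome)
    hits <- hits + (z$z[z$arm == "6q"] < -5)
    o <- z[z$arm != "6q", ]
    fp <- fp + sum(abs(o$z) > 5, na.rm = TRUE)
    n_other <- n_other + nrow(o)
  }
  expect_equal(hits, 20)
  expect_lte(fp / n_other, 0.02)
})

test_that("bin log2 ratios are centered, doubled bins read ~1, pseudocount shrinks", {
  loci <- grid_loci(toy, 40)  # one locus per 250 kb
  set.seed(5)
  base <- rpois(nrow(loci), 500) + 1
  members <- lapply(1:7, function(i) locus_counts(sprintf("m%d", i), loci, base))
  matched <- structure(list(members = members, size = 7),
                       class = c("matched_panel", "reference_panel"))

  s_eq <- locus_counts("eq", loci, base)
  b_eq <- bin_log2_ratios(s_eq, matched, toy)
  expect_true(all(abs(b_eq$log2[b_eq$n_loci > 0]) < 1e-9))
  expect_true(all(is.na(b_eq$log2[b_eq$n_loci == 0])))

  # double the counts in one occupied bin
  cnt <- base
  i_bin <- which(b_eq$n_loci > 0)[3]
  in_bin <- loci$chrom == b_eq$chrom[i_bin] &
    loci$pos0 >= b_eq$start[i_bin] & loci$pos0 < b_eq$end[i_bin]
  cnt[in_bin] <- cnt[in_bin] * 2L
  # negligible pseudocount so the doubling reads as one log2 unit
  b_dbl <- bin_log2_ratios(locus_counts("dbl", loci, cnt), matched, toy,
                           pseudo = 0.001)
  expect_equal(b_dbl$log2[i_bin], 1, tolerance = 0.02)

  # larger pseudocounts shrink every bin toward zero
  set.seed(6)
  s_r <- locus_counts("r", loci, rpois(nrow(loci), 500) + 1)
  b1 <- bin_log2_ratios(s_r, matched, toy, pseudo = 0.5)
  b2 <- bin_log2_ratios(s_r, matched, toy, pseudo = 5)
  occ <- b1$n_loci > 0
  expect_true(all(abs(b2$log2[occ]) <= abs(b1$log2[occ]) + 1e-12))
})

test_that("CBS finds noiseless breakpoints exactly and leaves flat signal whole", {
  step <- make_bins(c(rep(0, 100), rep(1, 100)))
  segs <- cbs_segment(step, seed = 4)
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$n_bins, c(100L, 100L))
  expect_equal(segs$end[1], 100 * 50000)
  expect_equal(segs$seg_log2, c(0, 1))

  flat <- make_bins(rep(0.3, 150))
  segs_flat <- cbs_segment(flat, seed = 4)
  expect_equal(nrow(segs_flat), 1L)
  expect_equal(segs_flat$n_bins, 150L)

  # segment means reconstruct bin means; segments partition the bins
  set.seed(7)
  noisy <- make_bins(c(rnorm(80, 0, 0.2), rnorm(60, 0.8, 0.2), rnorm(60, 0, 0.2)))
  sg <- cbs_segment(noisy, seed = 8)
  expect_equal(sum(sg$n_bins), 200L)
  for (k in seq_len(nrow(sg))) {
    ix <- noisy$start >= sg$start[k] & noisy$start < sg$end[k]
    expect_equal(sg$seg_log2[k], mean(noisy$log2[ix]), tolerance = 1e-9)
  }
})

test_that("noisy step breakpoints land within two bins of the truth", {
  hits <- 0
  for (i in 1:20) {
    set.seed(900 + i)
    b <- make_bins(c(rnorm(100, 0, 0.2), rnorm(100, 0.58, 0.2)))
    sg <- cbs_segment(b, seed = 900 + i)
    bp <- sg$end[-nrow(sg)] / 50000
    hits <- hits + (length(bp) >= 1 && min(abs(bp - 100)) <= 2)
  }
  expect_gte(hits, 19)
})

test_that("focal amplification calls require amplitude and focality", {
  g <- toy
  arm_19q <- g$arms[g$arms$name == "19q", ]
  seg <- function(chrom, start, end, log2) {
    s <- data.frame(chrom = chrom, start = start, end = end,
                    n_bins = as.integer((end - start) / 50000), seg_log2 = log2)
    attr(s, "bin_bp") <- 50000
    s
  }
  # whole-arm gain covering 19q12: amplitude fine, not sub-chromosomal
  whole <- seg("chr19", arm_19q$start, arm_19q$end, 0.6)
  f1 <- call_focal_amplifications(whole, g)
  expect_false(f1$called[f1$target == "19q12"])

  # 1-Mb segment over 19q12 at 0.5: called
  iv <- g$cytobands[g$cytobands$name == "19q12", ]
  focal <- seg("chr19", iv$start, iv$start + 1e6, 0.5)
  f2 <- call_focal_amplifications(focal, g)
  expect_true(f2$called[f2$target == "19q12"])
  expect_equal(f2$seg_log2[f2$target == "19q12"], 0.5)

  # below the log2 threshold: not called
  weak <- seg("chr19", iv$start, iv$start + 1e6, 0.2)
  f3 <- call_focal_amplifications(weak, g)
  expect_false(f3$called[f3$target == "19q12"])

  expect_error(call_focal_amplifications(focal, g, targets = "99z99"),
               "unknown cytoband")
})

test_that("the aneuploidy index counts altered binned base pairs", {
  seg <- function(log2, n_bins = 40) {
    s <- data.frame(chrom = "chr1", start = 0, end = n_bins * 50000,
                    n_bins = n_bins, seg_log2 = log2)
    attr(s, "bin_bp") <- 50000
    s
  }
  expect_equal(aneuploidy_index(seg(0)), 0)
  expect_equal(aneuploidy_index(seg(0.5)), 2e6)
  expect_equal(aneuploidy_index(seg(-0.5)), 2e6)
  expect_equal(aneuploidy_index(seg(0.25)), 0)  # strict inequality

  # threshold monotonicity on random segment profiles
  set.seed(12)
  for (i in 1:10) {
    n <- 30
    s <- data.frame(chrom = "chr1", start = (0:(n - 1)) * 50000,
                    end = (1:n) * 50000, n_bins = 1L,
                    seg_log2 = rnorm(n, 0, 0.4))
    attr(s, "bin_bp") <- 50000
    expect_lte(aneuploidy_index(s, log2_gain = 0.3, log2_loss = -0.3),
               aneuploidy_index(s))
  }

  # bin-level variant agrees on segment-constant data
  b <- make_bins(rep(0.5, 40))
  expect_equal(aneuploidy_index(seg(0.5), bins = b, level = "bin"), 2e6)
})
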