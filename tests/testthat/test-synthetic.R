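tiny_cfg <- function(seed = 11, ...) {
  args <- utils::modifyList(list(
    n_patients_per_subtype = c(proliferative = 4, immunoreactive = 4,
                               mixed = 4, dormant = 4),
    n_nft = 3, n_hgsc = 3, n_meso = 2,
    n_genes = 120, n_signature_per_subtype = 10,
    n_loci = 800, seed = seed
  ), list(...))
  do.call(synth_config, args)
}

test_that("the generator is a pure function of its configuration", {
  b1 <- generate_cohort(tiny_cfg())
  b2 <- generate_cohort(tiny_cfg())
  expect_identical(b1, b2)
  b3 <- generate_cohort(tiny_cfg(seed = 12))
  expect_false(identical(b1$expr$values, b3$expr$values))
})

test_that("expression counts are nonnegative integers and DNA depth is honored", {
  b <- generate_cohort(tiny_cfg())
  v <- b$expr$values
  expect_true(all(v >= 0))
  expect_true(all(v == floor(v)))
  depth <- b$truth$config$depth
  totals <- vapply(b$dna, `[[`, 0, "total")
  expect_true(all(abs(totals - depth) < 5 * sqrt(depth)))
})

test_that("configuration errors are caught", {
  expect_error(tiny_cfg(n_genes = 30), "signature gene demand")
  bad_probs <- default_clinpath_probs()
  bad_probs$atypia[1, 1] <- 0.9
  expect_error(tiny_cfg(clinpath_probs = bad_probs), "sum to 1")
  expect_error(
    synth_config(n_patients_per_subtype = c(4, 4, 4, 4)),
    "named"
  )
  expect_error(tiny_cfg(cn_events = list(nosuch = data.frame(region = "1p", log2 = 1))),
               "unknown subtype")
})

test_that("reference panel generation enforces its preconditions", {
  g <- toy_genome()
  expect_error(generate_reference_panel(g, n = 7), ">= 8")
  expect_error(generate_reference_panel(g, n = 30, depth = 0), "positive")
  p <- generate_reference_panel(g, n = 10, depth = 1e4, seed = 3, n_loci = 500)
  expect_s3_class(p, "reference_panel")
  expect_equal(p$size, 10L)
  expect_identical(p, generate_reference_panel(g, n = 10, depth = 1e4,
                                               seed = 3, n_loci = 500))
})

test_that("held-out euploid samples are called neutral on nearly every arm", {
  g <- toy_genome()
  big <- generate_reference_panel(g, n = 50, depth = 2e5, seed = 31, n_loci = 8000)
  panel <- reference_panel(big$members[1:30])
  held <- big$members[31:50]
  calls <- vapply(held, function(s) {
    z <- arm_zscores(s, match_reference(s, panel), g)
    c(sum(z$call != "neutral"), nrow(z))
  }, numeric(2))
  expect_lte(sum(calls[1, ]) / sum(calls[2, ]), 0.01)
})

test_that("a configured arm gain shifts the arm fraction by the configured dose", {
  ev <- list(dormant = data.frame(region = "5q", log2 = 0.58))
  cfg <- synth_config(
    n_patients_per_subtype = c(proliferative = 1, immunoreactive = 1,
                               mixed = 1, dormant = 50),
    n_nft = 1, n_hgsc = 1, n_meso = 1, n_genes = 60,
    n_signature_per_subtype = 10, n_loci = 8000,
    cn_events = ev, cn_presence_prob = 1, seed = 23
  )
  b <- generate_cohort(cfg)
  g <- b$genome
  arm_frac <- function(s) {
    f <- normalize_loci(s)
    arm <- sticatlas:::assign_arm(s$loci$chrom, s$loci$pos0, g)
    sum(f[!is.na(arm) & arm == "5q"])
  }
  pts <- names(b$truth$subtype)[b$truth$subtype == "dormant"]
  mean_evt <- mean(vapply(b$dna[pts], arm_frac, numeric(1)))
  mean_eu <- mean(vapply(b$panel$members, arm_frac, numeric(1)))
  expect_lt(abs(mean_evt / mean_eu / 2^0.58 - 1), 0.02)
})

test_that("clinicopathological covariates follow their subtype-conditional laws", {
  # determinism and unknown-label error
  s1 <- generate_clinpath(c("dormant", "mixed"), seed = 4)
  s2 <- generate_clinpath(c("dormant", "mixed"), seed = 4)
  expect_identical(s1, s2)
  expect_error(generate_clinpath("nosuch", seed = 1), "unknown subtype")

  # large-sample recovery of a dependent structure
  labels <- rep(c("dormant", "mixed", "immunoreactive", "proliferative"),
                each = 10000)
  big <- generate_clinpath(labels, seed = 9)
  ct <- contingency_table(big, "atypia", "subtype")
  expect_lt(chi_square_test(ct)$p, 1e-6)
})

test_that("under subtype-independent covariates the chi-square p is uniform", {
  probs <- default_clinpath_probs()["atypia"]
  probs$atypia[] <- 0.5  # same law in every subtype
  labels <- rep(c("dormant", "mixed", "immunoreactive", "proliferative"),
                each = 100)
  pvals <- vapply(1:200, function(i) {
    s <- generate_clinpath(labels, probs, seed = 1000 + i)
    chi_square_test(contingency_table(s, "atypia", "subtype"))$p
  }, numeric(1))
  # chi-square p-values on discrete tables carry occasional exact ties
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("null simulations yield no differential expression beyond chance", {
  n_with_discovery <- 0L
  for (i in 1:100) {
    cfg <- synth_config(
      n_patients_per_subtype = c(proliferative = 6, immunoreactive = 6,
                                 mixed = 6, dormant = 6),
      n_nft = 2, n_hgsc = 2, n_meso = 2,
      n_genes = 150, n_signature_per_subtype = 10,
      signature_log2fc = 0, batch_sd = 0, cn_events = list(),
      n_loci = 200, seed = 5000 + i
    )
    b <- generate_cohort(cfg)
    v <- variance_stabilize(b$expr)
    lab <- b$truth$aoi_subtype
    a <- names(lab)[!is.na(lab) & lab == "proliferative"]
    bb <- names(lab)[!is.na(lab) & lab == "dormant"]
    de <- fit_de(v, a, bb)
    if (any(de$significant)) n_with_discovery <- n_with_discovery + 1L
  }
  # BH controls the global-null familywise rate at ~5%; allow binomial noise
  expect_lte(n_with_discovery, 11L)
})

test_that("cohort bundles round-trip through the on-disk formats", {
  b <- generate_cohort(tiny_cfg())
  dir <- withr::local_tempdir()
  write_cohort(b, dir)
  expr2 <- read_aoi_matrix(file.path(dir, "counts.tsv"),
                           file.path(dir, "aoi_meta.tsv"))
  expect_equal(expr2$values, b$expr$values)
  expect_equal(expr2$meta, b$expr$meta)
  panel2 <- read_panel_dir(file.path(dir, "panel"))
  expect_equal(panel2$size, 30L)
  expect_equal(panel2$members[[1]]$counts, b$panel$members[[1]]$counts)
  s2 <- read_locus_counts(file.path(dir, "dna", paste0(names(b$dna)[1], ".tsv")),
                          sample_id = names(b$dna)[1])
  expect_equal(s2$counts, b$dna[[1]]$counts)
})
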