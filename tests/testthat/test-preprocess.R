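test_that("variance stabilization normalizes sizes and preserves shape", {
  # identical AOIs: unit size factors, output log2(c + 1)
  v <- matrix(8, nrow = 10, ncol = 4)
  m <- as_transformed_aoi(v)
  m$transformed <- FALSE
  out <- variance_stabilize(m)
  expect_true(out$transformed)
  expect_equal(unname(out$values), matrix(log2(9), 10, 4))

  # doubling every count of one AOI cancels through its size factor
  # (choose an AOI whose quartile sits above the median reference, so the
  # median is untouched and the cancellation is exact)
  set.seed(1)
  v <- matrix(rpois(50 * 7, 30), 50, 7)
  m <- as_transformed_aoi(v)
  m$transformed <- FALSE
  base <- variance_stabilize(m)
  uq <- apply(v, 2, function(x) quantile(x[x > 0], 0.75))
  j <- which.max(uq)
  v2 <- v
  v2[, j] <- v[, j] * 2
  m2 <- as_transformed_aoi(v2)
  m2$transformed <- FALSE
  out2 <- variance_stabilize(m2)
  expect_equal(out2$values[, j], base$values[, j], tolerance = 1e-12)

  # matches an independent reimplementation on a mixed matrix
  oracle <- {
    uq <- apply(v, 2, function(x) quantile(x[x > 0], 0.75))
    sf <- uq / median(uq)
    log2(sweep(v, 2, sf, "/") + 1)
  }
  expect_equal(unname(base$values), unname(oracle), tolerance = 1e-12)

  expect_identical(dimnames(base$values), dimnames(m$values))
  m0 <- m
  m0$values[, 2] <- 0
  expect_error(variance_stabilize(m0), "A002")
})

test_that("batch removal recenters batch means and preserves the grand mean", {
  # gene with batch means 5 and 9, equal sizes -> both recentered to 7
  v <- rbind(g1 = c(5, 5, 9, 9), g2 = c(1, 3, 2, 4))
  m <- as_transformed_aoi(v, batch = c("b1", "b1", "b2", "b2"))
  out <- remove_batch_effects(m)
  expect_equal(unname(out$values["g1", ]), c(7, 7, 7, 7))
  expect_equal(rowMeans(out$values), rowMeans(v), tolerance = 1e-9)

  # identical batch means: no-op
  v_eq <- rbind(c(1, 3, 1, 3), c(2, 2, 2, 2))
  m_eq <- as_transformed_aoi(v_eq, batch = c("b1", "b1", "b2", "b2"))
  expect_equal(remove_batch_effects(m_eq)$values, m_eq$values)

  # idempotent
  out2 <- remove_batch_effects(out)
  expect_equal(out2$values, out$values, tolerance = 1e-9)

  # degenerate batch structures
  expect_warning(remove_batch_effects(as_transformed_aoi(v, batch = "b1")),
                 "single batch")
  expect_error(remove_batch_effects(
    as_transformed_aoi(v, batch = c("b1", "b1", "b1", "b2"))),
    "single AOI")
})

test_that("PCA embedding is deterministic with honest variance fractions", {
  # rank-1 data: first component carries all variance
  set.seed(2)
  t_vals <- rnorm(30)
  v <- outer(c(1, 2, 3), t_vals)  # 3 genes x 30 AOIs on a line
  e <- pca_embed(as_transformed_aoi(v), k = 2)
  expect_equal(e$explained_variance[1], 1, tolerance = 1e-9)
  expect_true(all(diff(e$explained_variance) <= 1e-12))

  # isotropic noise: near-uniform spectrum
  set.seed(3)
  v <- matrix(rnorm(5 * 10000), nrow = 5)
  e2 <- pca_embed(as_transformed_aoi(v), k = 5)
  expect_lt(max(e2$explained_variance) - min(e2$explained_variance), 0.1)

  # rerun gives identical coordinates (sign convention fixed)
  e3 <- pca_embed(as_transformed_aoi(v), k = 5)
  expect_identical(e2$coordinates, e3$coordinates)

  expect_error(pca_embed(as_transformed_aoi(v), k = 0), "positive integer")
  expect_error(pca_embed(as_transformed_aoi(v), k = 6), "exceeds")
})

test_that("the batch-mixing score separates mixed from split batches", {
  # two batches perfectly interleaved on a line
  n <- 120
  coords <- cbind(seq_len(n), 0)
  batches <- rep(c("a", "b"), n / 2)
  r_mixed <- batch_mixing_score(coords, batches, k = 10, n_draws = 100, seed = 5)
  expect_lte(r_mixed, 0.05 + 0.05)

  # two fully separated clusters by batch
  coords2 <- rbind(cbind(rnorm(60), rnorm(60)),
                   cbind(rnorm(60) + 100, rnorm(60)))
  batches2 <- rep(c("a", "b"), each = 60)
  expect_equal(batch_mixing_score(coords2, batches2, k = 10,
                                  n_draws = 50, seed = 5), 1.0)

  # invariant to batch relabeling
  relabeled <- ifelse(batches == "a", "x", "y")
  expect_equal(batch_mixing_score(coords, relabeled, k = 10,
                                  n_draws = 100, seed = 5), r_mixed)

  expect_error(batch_mixing_score(coords, rep("a", n), k = 10), ">= 2 batches")
  expect_error(batch_mixing_score(coords, batches, k = 2), "exceed")
  expect_error(batch_mixing_score(coords, batches, k = n), "below"
  )
})

test_that("batch correction collapses an injected run effect", {
  b <- generate_cohort(synth_config(
    n_patients_per_subtype = c(proliferative = 10, immunoreactive = 10,
                               mixed = 10, dormant = 10),
    n_nft = 4, n_hgsc = 4, n_meso = 2,
    n_genes = 300, n_signature_per_subtype = 20,
    batch_sd = 1, n_loci = 500, seed = 77
  ))
  v <- variance_stabilize(b$expr)
  before <- batch_mixing_score(pca_embed(v, k = 10), v$meta$batch,
                               k = 15, n_draws = 100, seed = 9)
  corrected <- remove_batch_effects(v)
  after <- batch_mixing_score(pca_embed(corrected, k = 10), corrected$meta$batch,
                              k = 15, n_draws = 100, seed = 9)
  expect_gt(before, 0.8)
  expect_lt(after, 0.2)
})
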