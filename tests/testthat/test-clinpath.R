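t1 <- table1_counts()

test_that("cross-tabulation reproduces entered records in any order", {
  rec <- data.frame(x = c("a", "a", "b", "b"), y = c("u", "v", "u", "v"))
  ct <- contingency_table(rec, "x", "y")
  expect_equal(unname(ct$counts), matrix(1L, 2, 2))
  expect_equal(ct$grand_total, 4L)

  # published stromal-lymphocyte table rebuilt from per-patient records
  rec_lym <- records_from_counts(t1$lymphocytes, "lymphocytes", "subtype")
  set.seed(3)
  rec_lym <- rec_lym[sample(nrow(rec_lym)), ]
  ct_lym <- contingency_table(rec_lym, "lymphocytes", "subtype",
                              row_levels = rownames(t1$lymphocytes),
                              col_levels = colnames(t1$lymphocytes))
  expect_equal(unname(ct_lym$counts),
               matrix(c(39, 42, 19, 43, 2, 10, 7, 4), 2, byrow = TRUE))

  # missing records are excluded and counted
  rec$y[1] <- NA
  ct_m <- contingency_table(rec, "x", "y")
  expect_equal(ct_m$n_missing, 1L)
  expect_equal(ct_m$grand_total, 3L)
  expect_error(contingency_table(rec, "x", "nope"), "not found")
})

test_that("expected counts follow the margin product rule", {
  uni <- matrix(5L, 2, 2)
  expect_equal(expected_counts(uni), matrix(5, 2, 2), ignore_attr = TRUE)
  e_lym <- expected_counts(t1$lymphocytes)
  expect_equal(min(e_lym), 26 * 23 / 166, tolerance = 1e-12)
  expect_equal(sum(e_lym), sum(t1$lymphocytes))
})

test_that("test selection follows the expected-count rule", {
  expect_equal(choose_test(matrix(100L, 2, 2)), "chi_square")
  expect_equal(choose_test(t1$lymphocytes), "fisher_exact")  # min E ~ 3.6
  expect_equal(choose_test(t1$atypia), "chi_square")
})

test_that("the chi-square statistic matches the direct O/E oracle", {
  # table equal to its expected values: statistic 0, p = 1
  flat <- matrix(6L, 3, 2)
  r0 <- chi_square_test(flat)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  expect_equal(r0$df, 2L)

  # random tables against stats::chisq.test (no correction)
  set.seed(41)
  for (i in 1:100) {
    tab <- matrix(rpois(6, 20) + 1L, 2, 3)
    got <- chi_square_test(tab)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$p, ref$p.value, tolerance = 1e-9)
  }
  expect_error(chi_square_test(matrix(c(1L, 0L, 2L, 0L), 2)), "zero margin")
})

test_that("Fisher's exact p equals hypergeometric enumeration on 2x2 tables", {
  # brute-force oracle: enumerate all tables with the observed margins,
  # two-sided by probability ordering
  fisher_oracle_2x2 <- function(m) {
    r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
    lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
    probs <- vapply(lo:hi, function(a) {
      stats::dhyper(a, c1, n - c1, r1)
    }, numeric(1))
    p_obs <- stats::dhyper(m[1, 1], c1, n - c1, r1)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  tabs <- list(matrix(c(3L, 1L, 1L, 3L), 2),
               matrix(c(10L, 2L, 3L, 9L), 2),
               matrix(c(1L, 8L, 5L, 2L), 2))
  for (m in tabs) {
    expect_equal(fisher_exact_rxc(m)$p, fisher_oracle_2x2(m), tolerance = 1e-9)
  }
  # a 1 x c table is fully determined by its margins
  expect_equal(fisher_exact_rxc(matrix(c(2L, 5L, 3L), 1))$p, 1)
})

test_that("Monte Carlo Fisher agrees with enumeration on an r x c table", {
  tab <- t1$myc_gain
  exact <- fisher_exact_rxc(tab)
  mc <- fisher_exact_rxc(tab, max_enum_total = 0, n_mc = 1e6, seed = 11)
  expect_match(mc$note, "Monte Carlo")
  expect_lt(abs(exact$p - mc$p), 0.002)
  # seeded: identical on rerun
  expect_equal(mc$p, fisher_exact_rxc(tab, max_enum_total = 0, n_mc = 1e6,
                                      seed = 11)$p)
})

test_that("column percentages round as cohort tables print them", {
  pct <- percent_summary(t1$atypia)
  expect_equal(pct["High-grade", "Proliferative"], 91.5)
  expect_equal(unname(colSums(percent_summary(t1$ki67))),
               rep(100, 4), tolerance = 0.1)
  z <- matrix(c(0L, 10L), 2)
  expect_equal(percent_summary(z)[1, 1], 0.0)
  expect_error(percent_summary(matrix(c(0L, 0L, 1L, 1L), 2)), "zero column")
})

test_that("the H-score is the intensity-weighted percentage sum", {
  expect_equal(h_score(c(0, 0, 0, 100)), 300)
  expect_equal(h_score(c(100, 0, 0, 0)), 0)
  expect_equal(h_score(c(50, 0, 50, 0)), 100)
  # linear in each argument: moving 10% from intensity 0 to 3 adds 30
  expect_equal(h_score(c(40, 10, 20, 30)) - h_score(c(50, 10, 20, 20)), 30)
  expect_error(h_score(c(50, 10, 20, 30)), "sum to 100")
  expect_error(h_score(c(-10, 50, 30, 30)), "nonnegative")
})

test_that("Ki67 categories use the published cutpoints", {
  expect_equal(ki67_category(51.9), "High")
  expect_equal(ki67_category(4.5), "Low")
  expect_equal(ki67_category(5.0), "Intermediate")
  expect_equal(ki67_category(20.0), "Intermediate")
  expect_equal(ki67_category(20.1), "High")
  expect_error(ki67_category(150), "\\[0, 100\\]")
})

test_that("the association wrapper reports both tests per covariate", {
  labels <- rep(c("dormant", "mixed", "immunoreactive", "proliferative"),
                times = c(41, 52, 26, 47))
  s <- generate_clinpath(labels, seed = 13)
  res <- associate_subtypes(s, c("atypia", "lymphocytes"))
  expect_equal(res$variable, c("atypia", "lymphocytes"))
  expect_true(all(res$method %in% c("chi_square", "fisher_exact")))
  expect_true(all(res$p_selected > 0 & res$p_selected <= 1))
  expect_true(all(is.finite(res$p_chi_square)))
})
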