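# Clinicopathological association machinery: contingency tables, test
# selection by expected counts, chi-square and r x c Fisher exact tests,
# column-percentage summaries, the immunohistochemistry H-score, and Ki67
# index categorization.

#' Published clinicopathological counts for the four STIC subtypes
#'
#' The cross-tabulated patient counts per molecular subtype (columns
#' Dormant, Mixed, Immunoreactive, Proliferative) for each
#' clinicopathological variable, as printed in the source study's cohort
#' table. Copy-number gain rows are restricted to the patients with
#' evaluable DNA. These counts serve two roles: the worked-example surface
#' for the association statistics, and the default subtype-conditional
#' category probabilities of the synthetic cohort generator.
#'
#' @return Named list of integer matrices (categories x subtypes).
#' @export
table1_counts <- function() {
  subs <- c("Dormant", "Mixed", "Immunoreactive", "Proliferative")
  m <- function(x, rows) matrix(x, nrow = length(rows), byrow = TRUE,
                                dimnames = list(rows, subs))
  list(
    n_patients = m(c(41, 52, 26, 47), "Patients"),
    age = m(c(0, 0, 1, 0,
              3, 0, 5, 0,
              28, 15, 9, 9,
              9, 9, 4, 20,
              1, 28, 7, 13),
            c("30-39", "40-49", "50-59", "60-69", "70-79")),
    brca = m(c(30, 36, 12, 41,
               0, 6, 8, 2,
               6, 6, 5, 2,
               5, 4, 1, 2),
             c("Negative", "BRCA1", "BRCA2", "Other")),
    atypia = m(c(32, 24, 4, 4,
                 9, 28, 22, 43),
               c("Low-grade", "High-grade")),
    architecture = m(c(39, 39, 19, 26,
                       2, 13, 7, 21),
                     c("Flat", "BLAD")),
    lymphocytes = m(c(39, 42, 19, 43,
                      2, 10, 7, 4),
                    c("Non-enriched", "Enriched")),
    ki67 = m(c(13, 19, 5, 3,
               22, 16, 8, 15,
               5, 17, 13, 29),
             c("Low", "Intermediate", "High")),
    p53 = m(c(32, 44, 24, 35,
              8, 8, 2, 11,
              1, 0, 0, 1),
            c("Missense", "Loss/null", "Wildtype")),
    ccne1_gain = m(c(0, 2, 1, 10,
                     9, 6, 4, 7),
                   c("Gain", "No gain")),
    myc_gain = m(c(1, 3, 3, 7,
                   8, 5, 2, 10),
                 c("Gain", "No gain"))
  )
}

#' Default subtype-conditional clinicopathological probabilities
#'
#' Empirical per-subtype category proportions of the published cohort table
#' for BRCA germline status, nuclear atypia, lesion architecture, stromal
#' lymphocytes, and Ki67 category, with subtype names in the generator's
#' lower-case convention.
#'
#' @return Named list of probability matrices (categories x subtypes).
#' @export
default_clinpath_probs <- function() {
  t1 <- table1_counts()
  vars <- c("brca", "atypia", "architecture", "lymphocytes", "ki67")
  out <- lapply(t1[vars], function(m) {
    p <- sweep(m, 2, colSums(m), "/")
    colnames(p) <- tolower(colnames(p))
    p
  })
  out
}

#' Cross-tabulate two categorical variables
#'
#' @param table data.frame of per-sample records.
#' @param row_var,col_var column names to cross-tabulate.
#' @param row_levels,col_levels optional explicit level order; default is
#'   order of first appearance.
#' @return A `contingency_table`: counts with row/column/grand totals and a
#'   count of excluded records with missing values.
#' @export
contingency_table <- function(table, row_var, col_var,
                              row_levels = NULL, col_levels = NULL) {
  r <- table[[row_var]]
  cc <- table[[col_var]]
  if (is.null(r) || is.null(cc)) stopf("variable not found in table")
  keep <- !is.na(r) & !is.na(cc)
  n_missing <- sum(!keep)
  r <- as.character(r[keep]); cc <- as.character(cc[keep])
  if (!length(r)) stopf("no complete records to tabulate")
  if (is.null(row_levels)) row_levels <- unique(r)
  if (is.null(col_levels)) col_levels <- unique(cc)
  counts <- table(factor(r, levels = row_levels), factor(cc, levels = col_levels))
  counts <- matrix(as.integer(counts), nrow = length(row_levels),
                   dimnames = list(row_levels, col_levels))
  as_contingency(counts, n_missing = n_missing)
}

as_contingency <- function(counts, n_missing = 0L) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stopf("contingency counts must be nonnegative integers")
  }
  structure(list(
    counts = counts,
    row_totals = rowSums(counts), col_totals = colSums(counts),
    grand_total = sum(counts), n_missing = n_missing
  ), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("contingency_table %dx%d (N = %d%s)\n",
              nrow(x$counts), ncol(x$counts), x$grand_total,
              if (x$n_missing) sprintf(", %d missing excluded", x$n_missing) else ""))
  print(x$counts)
  invisible(x)
}

#' Expected cell counts under independence
#'
#' E[i,j] = row_i x col_j / N, the quantity that drives chi-square vs
#' Fisher test selection.
#'
#' @param t a `contingency_table` or count matrix.
#' @return Matrix of expected counts.
#' @export
expected_counts <- function(t) {
  t <- as_ct(t)
  if (t$grand_total <= 0) stopf("grand total must be positive")
  outer(t$row_totals, t$col_totals) / t$grand_total
}

as_ct <- function(t) if (inherits(t, "contingency_table")) t else as_contingency(t)

#' Select chi-square or Fisher's exact test by expected counts
#'
#' The classical rule: Fisher's exact test whenever any expected cell count
#' falls below 5, otherwise the Pearson chi-square test.
#'
#' @param t a `contingency_table` or count matrix.
#' @param min_expected cutoff (default 5).
#' @return `"chi_square"` or `"fisher_exact"`.
#' @export
choose_test <- function(t, min_expected = 5) {
  e <- expected_counts(as_ct(t))
  if (any(e < min_expected)) "fisher_exact" else "chi_square"
}

#' Pearson chi-square test of independence
#'
#' Classic Sum (O-E)^2 / E statistic with (r-1)(c-1) degrees of freedom and
#' no continuity correction.
#'
#' @param t a `contingency_table` or count matrix.
#' @return list with `method`, `statistic`, `df`, `p`.
#' @export
chi_square_test <- function(t) {
  t <- as_ct(t)
  if (any(t$row_totals == 0) || any(t$col_totals == 0)) {
    stopf("zero margin: chi-square undefined, use fisher_exact_rxc()")
  }
  e <- expected_counts(t)
  stat <- sum((t$counts - e)^2 / e)
  df <- (nrow(t$counts) - 1L) * (ncol(t$counts) - 1L)
  list(method = "chi_square", statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE), note = "")
}

#' Fisher's exact test for r x c tables
#'
#' Exact conditional test with fixed margins and the probability-ordering
#' two-sided p-value: full enumeration (network algorithm) when the grand
#' total is at most `max_enum_total`, otherwise a seeded Monte Carlo
#' estimate flagged in the `note` field.
#'
#' @param t a `contingency_table` or count matrix.
#' @param max_enum_total largest grand total handled exactly.
#' @param n_mc Monte Carlo replicates beyond `max_enum_total`.
#' @param seed Monte Carlo seed.
#' @return list with `method`, `p`, `note`.
#' @export
fisher_exact_rxc <- function(t, max_enum_total = 500, n_mc = 1e6, seed = 1L) {
  t <- as_ct(t)
  keep_r <- t$row_totals > 0
  keep_c <- t$col_totals > 0
  m <- t$counts[keep_r, keep_c, drop = FALSE]
  if (nrow(m) < 2L || ncol(m) < 2L) {
    # margins determine the table completely
    return(list(method = "fisher_exact", p = 1, note = "degenerate table"))
  }
  if (t$grand_total <= max_enum_total) {
    p <- tryCatch(
      stats::fisher.test(m, workspace = 2e7)$p.value,
      error = function(e) {
        with_seed(seed, stats::fisher.test(m, simulate.p.value = TRUE,
                                           B = n_mc)$p.value)
      }
    )
    list(method = "fisher_exact", p = min(p, 1), note = "exact enumeration")
  } else {
    p <- with_seed(seed, stats::fisher.test(m, simulate.p.value = TRUE,
                                            B = n_mc)$p.value)
    list(method = "fisher_exact", p = min(p, 1),
         note = sprintf("Monte Carlo, B = %g, seed = %d", n_mc, as.integer(seed)))
  }
}

#' Column-percentage summary of a contingency table
#'
#' 100 x count / column total, rounded to one decimal -- the "n (percent)"
#' convention of clinical cohort tables.
#'
#' @param t a `contingency_table` or count matrix.
#' @return Matrix of percentages.
#' @export
percent_summary <- function(t) {
  t <- as_ct(t)
  if (any(t$col_totals == 0)) stopf("zero column total")
  round(sweep(t$counts, 2, t$col_totals, "/") * 100, 1)
}

#' Immunohistochemistry H-score
#'
#' Sum over intensity categories 0..3 of intensity times the percentage of
#' epithelial cells at that intensity; range 0-300.
#'
#' @param pct_by_intensity numeric length-4 vector of percentages for
#'   intensities 0, 1, 2, 3; must sum to 100.
#' @return Scalar H-score.
#' @export
h_score <- function(pct_by_intensity) {
  if (length(pct_by_intensity) != 4L || any(pct_by_intensity < 0)) {
    stopf("need 4 nonnegative percentages (intensities 0..3)")
  }
  if (abs(sum(pct_by_intensity) - 100) > 0.01) {
    stopf("percentages must sum to 100 (got %.3f)", sum(pct_by_intensity))
  }
  sum((0:3) * pct_by_intensity)
}

#' Categorize a Ki67 labeling index
#'
#' Low below 5 percent, Intermediate from 5 to 20 percent inclusive, High
#' above 20 percent.
#'
#' @param index_pct Ki67 labeling index in percent, in [0, 100].
#' @return `"Low"`, `"Intermediate"`, or `"High"` (vectorized).
#' @export
ki67_category <- function(index_pct) {
  if (any(index_pct < 0 | index_pct > 100)) {
    stopf("Ki67 index must be within [0, 100]")
  }
  ifelse(index_pct < 5, "Low", ifelse(index_pct <= 20, "Intermediate", "High"))
}

#' Association tests for every covariate against subtype
#'
#' Builds the subtype cross-tab for each requested covariate and reports
#' the expected-count-selected test alongside both the chi-square and the
#' Fisher p-value, mirroring cohort-table association columns. When the
#' selection is borderline (any expected count < 5) both p-values matter,
#' since published tables do not always state the per-row choice.
#'
#' @param samples data.frame with a `subtype` column and covariates.
#' @param vars covariate column names.
#' @return data.frame with method, statistic, df, and p-values per variable.
#' @export
associate_subtypes <- function(samples, vars) {
  rows <- lapply(vars, function(v) {
    ct <- contingency_table(samples, v, "subtype")
    method <- choose_test(ct)
    chi <- tryCatch(chi_square_test(ct), error = function(e) NULL)
    fis <- fisher_exact_rxc(ct)
    data.frame(
      variable = v, method = method,
      statistic = if (is.null(chi)) NA_real_ else chi$statistic,
      df = if (is.null(chi)) NA_integer_ else chi$df,
      p_chi_square = if (is.null(chi)) NA_real_ else chi$p,
      p_fisher = fis$p,
      p_selected = if (method == "chi_square" && !is.null(chi)) chi$p else fis$p,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
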