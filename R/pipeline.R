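# End-to-end orchestration: simulate -> preprocess -> subtype -> aneuploidy
# -> differential expression / enrichment -> integrate -> clinicopathological
# statistics, with a manifest of parameters, seeds and output checksums.

#' Default pipeline configuration
#'
#' One-command demo settings: the default synthetic cohort, variance
#' stabilization followed by batch removal, consensus NMF over ranks 2-6,
#' full aneuploidy profiling of every DNA sample, cluster-vs-rest DE with
#' unique signatures, RNA-DNA integration, and the covariate association
#' table. Stage blocks mirror each module's defaults and can be overridden
#' field by field.
#'
#' @param seed global seed; stage-specific streams are derived from it.
#' @param out_dir output directory.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L, out_dir = tempfile("stic_run_")) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = c(simulate = TRUE, preprocess = TRUE, subtype = TRUE,
               aneuploidy = TRUE, de = TRUE, gsea = FALSE,
               integrate = TRUE, clinpath = TRUE),
    simulate = list(),   # overrides for synth_config()
    preprocess = list(order = "vst_first", kbet_k = 25, kbet_draws = 100),
    subtype = list(ranks = 2:6, n_runs = 100, max_iter = 400, tol = 1e-6),
    aneuploidy = list(n_match = 7, threshold = 5, bin_bp = 50000,
                      alpha = 0.01, n_perm = 1000, min_width = 2),
    de = list(n_signature = 50, lfc_threshold = 0.5, alpha = 0.05),
    gsea = list(gmt = NULL, weight = 1, n_perm = 1000),
    integrate = list(min_n = 3)
  )
}

#' Run the full pipeline
#'
#' Executes the enabled stages in dependency order on a synthetic cohort
#' and writes per-stage outputs plus a manifest (parameters, seeds, output
#' checksums) under `config$out_dir`. Rerunning with an identical
#' configuration reproduces identical outputs.
#'
#' @param config a configuration list, see [default_pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  stages <- config$stages
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(name) {
    message(sprintf("[stic-atlas] %s (t+%.1fs)", name,
                    proc.time()[["elapsed"]] - t0))
  }

  if (!stages[["simulate"]]) stopf("pipeline currently starts from the simulate stage")
  log_stage("simulate")
  sim_args <- utils::modifyList(list(seed = config$seed), config$simulate)
  bundle <- generate_cohort(do.call(synth_config, sim_args))
  res$bundle <- bundle
  write_cohort(bundle, file.path(config$out_dir, "cohort"))

  expr_corrected <- NULL
  if (stages[["preprocess"]]) {
    log_stage("preprocess")
    pp <- config$preprocess
    if (identical(pp$order, "batch_first")) {
      # literal published order: correct raw counts first, then stabilize
      logged <- aoi_matrix(log2(bundle$expr$values + 1), bundle$expr$meta,
                           transformed = TRUE)
      corrected <- remove_batch_effects(logged)
      back <- pmax(2^corrected$values - 1, 0)
      expr_corrected <- variance_stabilize(
        aoi_matrix(back, bundle$expr$meta, transformed = FALSE))
    } else {
      vst <- variance_stabilize(bundle$expr)
      expr_corrected <- remove_batch_effects(vst)
    }
    emb <- pca_embed(expr_corrected, k = min(10, ncol(expr_corrected$values) - 1))
    kbet_after <- batch_mixing_score(
      emb, expr_corrected$meta$batch, k = pp$kbet_k,
      n_draws = pp$kbet_draws, seed = child_seed(config$seed, "kbet"))
    res$preprocess <- list(expr = expr_corrected, embedding = emb,
                           kbet_after = kbet_after)
    write_aoi_matrix(expr_corrected, file.path(config$out_dir, "norm.tsv"),
                     file.path(config$out_dir, "norm_meta.tsv"))
  }

  if (stages[["subtype"]]) {
    if (is.null(expr_corrected)) stopf("subtype stage needs preprocess output")
    log_stage("subtype")
    st <- config$subtype
    lesion <- expr_corrected$meta$diagnosis == "STIC" &
      expr_corrected$meta$compartment == "epithelial"
    X <- nonneg_shift_clip(
      aoi_matrix(expr_corrected$values[, lesion, drop = FALSE],
                 expr_corrected$meta[lesion, , drop = FALSE],
                 transformed = TRUE))$values
    results <- lapply(st$ranks, function(r) {
      consensus_nmf(X, r, n_runs = st$n_runs,
                    seed = child_seed(config$seed, "nmf") + 1000L * r,
                    max_iter = st$max_iter, tol = st$tol)
    })
    sel <- select_rank(results)
    best <- results[[match(sel$rank, vapply(results, `[[`, 0, "rank"))]]
    labels <- stats::setNames(best$labels, colnames(X))
    res$subtype <- list(results = results, rank = sel$rank,
                        metrics = sel$metrics, labels = labels,
                        consensus = best$consensus)
    write_tsv(sel$metrics, file.path(config$out_dir, "rank_metrics.tsv"))
    write_tsv(data.frame(aoi_id = names(labels), cluster = labels),
              file.path(config$out_dir, "subtype_labels.tsv"))
  }

  if (stages[["aneuploidy"]]) {
    log_stage("aneuploidy")
    an <- config$aneuploidy
    profiles <- lapply(names(bundle$dna), function(pt) {
      aneuploidy_profile(bundle$dna[[pt]], bundle$panel, bundle$genome,
                         n_match = an$n_match, threshold = an$threshold,
                         bin_bp = an$bin_bp, alpha = an$alpha,
                         n_perm = an$n_perm, min_width = an$min_width,
                         seed = child_seed(config$seed, "cbs"))
    })
    names(profiles) <- names(bundle$dna)
    res$aneuploidy <- profiles
    idx <- data.frame(
      patient = names(profiles),
      aneuploidy_index = vapply(profiles, `[[`, 0, "index")
    )
    write_tsv(idx, file.path(config$out_dir, "aneuploidy_index.tsv"))
    focal <- do.call(rbind, lapply(names(profiles), function(p) {
      data.frame(patient = p, profiles[[p]]$focal)
    }))
    write_tsv(focal, file.path(config$out_dir, "focal_calls.tsv"))
  }

  signatures <- NULL
  if (stages[["de"]]) {
    if (is.null(res$subtype)) stopf("de stage needs subtype output")
    log_stage("de")
    de_cfg <- config$de
    labels <- res$subtype$labels
    sizes <- table(labels)
    usable <- as.integer(names(sizes)[sizes >= 2])
    if (length(usable) < length(sizes)) {
      warnf("skipping DE for %d singleton cluster(s)",
            length(sizes) - length(usable))
    }
    de_list <- lapply(usable, function(cl) {
      fit_de(res$preprocess$expr,
             names(labels)[labels == cl], names(labels)[labels != cl],
             lfc_threshold = de_cfg$lfc_threshold, alpha = de_cfg$alpha)
    })
    names(de_list) <- paste0("cluster", usable)
    signatures <- suppressWarnings(
      top_upregulated_unique(de_list, n = de_cfg$n_signature))
    res$de <- list(results = de_list, signatures = signatures)
    sig_df <- data.frame(cluster = rep(names(signatures), lengths(signatures)),
                         gene_id = unlist(signatures, use.names = FALSE))
    write_tsv(sig_df, file.path(config$out_dir, "signatures.tsv"))
  }

  if (stages[["gsea"]] && !is.null(config$gsea$gmt)) {
    log_stage("gsea")
    sets <- read_gmt(config$gsea$gmt)
    first_de <- res$de$results[[1]]
    ranking <- stats::setNames(first_de$t, first_de$gene)
    res$gsea <- gsea_preranked(ranking, sets, weight = config$gsea$weight,
                               n_perm = config$gsea$n_perm,
                               seed = child_seed(config$seed, "gsea"))
    write_tsv(res$gsea[, setdiff(names(res$gsea), "leading_edge")],
              file.path(config$out_dir, "gsea.tsv"))
  }

  if (stages[["integrate"]]) {
    if (is.null(signatures)) stopf("integrate stage needs de output")
    log_stage("integrate")
    sig_union <- unique(unlist(signatures))
    cents <- reference_centroids(res$preprocess$expr,
                                 signature_genes = sig_union)
    lesion <- res$preprocess$expr$meta$diagnosis == "STIC"
    dist_df <- do.call(rbind, lapply(which(lesion), function(j) {
      v <- res$preprocess$expr$values[, j]
      data.frame(
        aoi_id = colnames(res$preprocess$expr$values)[j],
        d_nft = molecular_distance(v, cents$NFT, sig_union),
        d_hgsc = molecular_distance(v, cents$HGSC, sig_union),
        d_meso = molecular_distance(v, cents$mesothelium, sig_union)
      )
    }))
    out_int <- list(centroids = cents, distances = dist_df)
    if (!is.null(res$aneuploidy)) {
      map <- map_genes_to_cytobands(bundle$gene_coords, bundle$genome)
      segs <- lapply(res$aneuploidy, `[[`, "segments")
      out_int$cn_correlation <- suppressWarnings(
        expression_cn_correlation(res$preprocess$expr, segs, map,
                                  min_n = config$integrate$min_n))
      write_tsv(out_int$cn_correlation,
                file.path(config$out_dir, "cn_correlation.tsv"))
    }
    res$integrate <- out_int
    write_tsv(dist_df, file.path(config$out_dir, "molecular_distance.tsv"))
  }

  if (stages[["clinpath"]]) {
    log_stage("clinpath")
    samples <- bundle$samples
    if (!is.null(res$subtype)) {
      # associate covariates with the discovered clusters, not the truth
      lab_by_pt <- res$subtype$labels
      pt <- res$preprocess$expr$meta$patient[
        match(names(lab_by_pt), res$preprocess$expr$meta$aoi_id)]
      cl <- stats::setNames(paste0("cluster", lab_by_pt), pt)
      samples$cluster <- cl[samples$patient]
      samples$subtype <- samples$cluster
    }
    vars <- intersect(c("brca", "atypia", "architecture", "lymphocytes", "ki67"),
                      names(samples))
    res$clinpath <- associate_subtypes(samples, vars)
    write_tsv(res$clinpath, file.path(config$out_dir, "associations.tsv"))
  }

  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    seed = config$seed,
    stages = names(stages)[stages],
    parameters = config[setdiff(names(config), c("stages", "out_dir"))],
    elapsed_s = proc.time()[["elapsed"]] - t0,
    checksums = as.list(tools::md5sum(files))
  )
  res$manifest <- manifest
  writeLines(utils::capture.output(utils::str(manifest, give.attr = FALSE)),
             file.path(config$out_dir, "manifest.txt"))
  invisible(res)
}

#' Validate pipeline input files
#'
#' Structural checks on the on-disk formats: counts/metadata TSV headers,
#' GMT structure (warning on single-gene sets), BED-like sortedness, and
#' locus concordance between a sample and a panel directory. Returns a
#' machine-readable report rather than erroring.
#'
#' @param paths named list; recognized entries: `counts`, `meta`, `gmt`,
#'   `bed`, `sample`, `panel_dir`.
#' @return data.frame with `check`, `path`, `ok`, `message`.
#' @export
validate_inputs <- function(paths) {
  report <- list()
  add <- function(check, path, ok, message = "") {
    report[[length(report) + 1L]] <<- data.frame(
      check = check, path = path %||% "", ok = ok, message = message,
      stringsAsFactors = FALSE)
  }
  if (!is.null(paths$counts)) {
    ok <- file.exists(paths$counts)
    msg <- ""
    if (ok) {
      hdr <- strsplit(readLines(paths$counts, n = 1), "\t")[[1]]
      ok <- identical(hdr[1], "gene_id") && length(hdr) > 1
      if (!ok) msg <- "first column must be gene_id with >= 1 AOI column"
    } else {
      msg <- "missing file"
    }
    add("counts_tsv", paths$counts, ok, msg)
  }
  if (!is.null(paths$meta)) {
    ok <- file.exists(paths$meta)
    msg <- ""
    if (ok) {
      hdr <- strsplit(readLines(paths$meta, n = 1), "\t")[[1]]
      need <- c("aoi_id", "compartment", "diagnosis", "batch", "patient")
      miss <- setdiff(need, hdr)
      ok <- !length(miss)
      if (!ok) msg <- paste("missing columns:", paste(miss, collapse = ", "))
    } else {
      msg <- "missing file"
    }
    add("meta_tsv", paths$meta, ok, msg)
  }
  if (!is.null(paths$gmt)) {
    ok <- file.exists(paths$gmt)
    msg <- ""
    if (ok) {
      sets <- tryCatch(suppressWarnings(read_gmt(paths$gmt)), error = function(e) e)
      if (inherits(sets, "error")) {
        ok <- FALSE
        msg <- conditionMessage(sets)
      } else if (any(lengths(sets) < 2)) {
        msg <- sprintf("warning: %d set(s) with < 2 genes (enrichment unstable)",
                       sum(lengths(sets) < 2))
      }
    } else {
      msg <- "missing file"
    }
    add("gmt", paths$gmt, ok, msg)
  }
  if (!is.null(paths$bed)) {
    ok <- file.exists(paths$bed)
    msg <- ""
    if (ok) {
      bed <- tryCatch(read_tsv(paths$bed), error = function(e) NULL)
      ok <- !is.null(bed) && all(c("chrom", "start", "end") %in% names(bed))
      if (ok) {
        sorted <- !is.unsorted(order(bed$chrom, bed$start))
        by_chrom <- split(bed$start, bed$chrom)
        sorted <- all(vapply(by_chrom, function(s) !is.unsorted(s), logical(1)))
        if (!sorted) {
          ok <- FALSE
          msg <- "intervals not sorted within chromosome"
        }
      } else {
        msg <- "need chrom/start/end columns"
      }
    } else {
      msg <- "missing file"
    }
    add("bed", paths$bed, ok, msg)
  }
  if (!is.null(paths$sample) && !is.null(paths$panel_dir)) {
    ok <- file.exists(paths$sample) && dir.exists(paths$panel_dir)
    msg <- ""
    if (ok) {
      s <- tryCatch(read_locus_counts(paths$sample), error = function(e) NULL)
      panel <- tryCatch(read_panel_dir(paths$panel_dir), error = function(e) NULL)
      if (is.null(s) || is.null(panel)) {
        ok <- FALSE
        msg <- "unreadable sample or panel"
      } else if (!identical(s$loci$locus_id, panel$members[[1]]$loci$locus_id)) {
        ok <- FALSE
        both <- intersect(s$loci$locus_id, panel$members[[1]]$loci$locus_id)
        msg <- sprintf("locus mismatch: %d shared of %d/%d", length(both),
                       nrow(s$loci), nrow(panel$members[[1]]$loci))
      }
    } else {
      msg <- "missing sample file or panel directory"
    }
    add("locus_concordance", paths$sample, ok, msg)
  }
  do.call(rbind, report)
}
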