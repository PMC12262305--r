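# Synthetic cohort generator: emulates the data structure of a spatial
# profiling study of tubal precancerous lesions -- AOI-level expression for
# four STIC molecular subtypes plus NFT / HGSC / mesothelium reference
# groups with run-level batch effects, RealSeqS-style locus counts with
# arm-level gains/losses and focal amplifications, a euploid reference
# panel, and subtype-conditional clinicopathological covariates.

#' Configuration for the synthetic cohort generator
#'
#' Defaults define the standard study conditions used throughout the test
#' suite: 40 lesion AOIs per molecular subtype (160 total), 2,000 genes with
#' 50 uniquely upregulated signature genes per subtype at a mean effect of
#' 2.0 log2 units, four simulated runs as batches, a 22-autosome toy genome
#' with 20,000 loci, and DNA depth of 500,000 reads per sample. Copy-number
#' events per subtype follow the qualitative pattern reported for STIC
#' subtypes: chromosome 13/17/22 arm losses in all subtypes, plus focal
#' 19q12 / 19q13.2 / 8q24 amplifications concentrated in the proliferative
#' subtype.
#'
#' A "progression axis" places subtype centroids on a line through the
#' proliferative signature: the dormant subtype sits at 0 (closest to NFT),
#' the proliferative subtype at 1, and HGSC beyond it, so that Euclidean
#' molecular distances reproduce the dormant-nearest-NFT /
#' proliferative-nearest-HGSC ordering by construction.
#'
#' @param n_patients_per_subtype named integer vector, patients (one lesion
#'   AOI each) per subtype.
#' @param n_nft,n_hgsc,n_meso reference group sizes.
#' @param n_genes total genes.
#' @param n_signature_per_subtype uniquely upregulated genes per subtype.
#' @param signature_log2fc mean signature effect size (log2).
#' @param batch_count,batch_sd number of simulated runs and SD of the
#'   per-gene, per-run log2 shift.
#' @param genome_mode "toy" or "hg".
#' @param n_loci number of RealSeqS-style loci.
#' @param depth mean total DNA reads per sample.
#' @param amplicon_jitter_sdlog SD (log scale) of the per-sample
#'   amplicon-efficiency jitter applied to locus weights; models the
#'   between-sample amplicon-distribution variability that reference-panel
#'   matching is designed to absorb.
#' @param rna_depth mean library size per AOI.
#' @param dispersion_meanlog,dispersion_sdlog log-normal parameters of the
#'   per-gene negative-binomial size.
#' @param cn_events named list (by subtype) of data.frames with columns
#'   `region` (arm or cytoband name) and `log2`; `list()` disables events.
#' @param cn_presence_prob probability that a configured event is realized
#'   in a given patient. The default 1 makes events a deterministic property
#'   of the subtype; lower values introduce within-subtype copy-number
#'   substructure (which consensus clustering will then legitimately find).
#' @param dosage_coupling couple expression of genes inside realized events
#'   to the DNA log2 shift (gene dosage).
#' @param progression_levels named numeric, position of each subtype on the
#'   proliferative progression axis.
#' @param within_subtype_cv per-AOI coefficient of variation of the
#'   signature effect, and SD of the per-AOI progression-level jitter.
#'   0 (the default) gives four well-separated homogeneous subtypes;
#'   positive values add continuous within-subtype heterogeneity, which
#'   consensus clustering will then partially resolve as substructure.
#' @param hgsc_level,meso_log2fc HGSC position on the progression axis and
#'   the mesothelium lineage effect size.
#' @param clinpath_probs subtype-conditional category probabilities (see
#'   [default_clinpath_probs()]).
#' @param seed integer; fully determines all generator output.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_patients_per_subtype = c(proliferative = 40, immunoreactive = 40,
                                                    mixed = 40, dormant = 40),
                         n_nft = 20, n_hgsc = 15, n_meso = 10,
                         n_genes = 2000, n_signature_per_subtype = 50,
                         signature_log2fc = 2.0,
                         batch_count = 4, batch_sd = 0.3,
                         genome_mode = c("toy", "hg"),
                         n_loci = 20000, depth = 5e5,
                         amplicon_jitter_sdlog = 0.2,
                         rna_depth = 1.5e5,
                         dispersion_meanlog = log(10), dispersion_sdlog = 0.5,
                         cn_events = default_cn_events(),
                         cn_presence_prob = 1,
                         dosage_coupling = TRUE,
                         progression_levels = c(dormant = 0, mixed = 0.5,
                                                immunoreactive = 0.75, proliferative = 1.0),
                         within_subtype_cv = 0,
                         hgsc_level = 2.2, meso_log2fc = 2.0,
                         clinpath_probs = default_clinpath_probs(),
                         seed = 1L) {
  genome_mode <- match.arg(genome_mode)
  subtypes <- names(n_patients_per_subtype)
  if (is.null(subtypes) || any(!nzchar(subtypes))) {
    stopf("n_patients_per_subtype must be a named vector")
  }
  counts <- c(n_patients_per_subtype, n_nft = n_nft, n_hgsc = n_hgsc,
              n_meso = n_meso, n_genes = n_genes,
              n_loci = n_loci, depth = depth, batch_count = batch_count)
  if (any(counts <= 0)) stopf("all sizes and depths must be positive")
  n_blocks <- length(subtypes) + 1L  # + mesothelium lineage block
  if (n_blocks * n_signature_per_subtype > n_genes) {
    stopf("signature gene demand (%d) exceeds n_genes (%d)",
          n_blocks * n_signature_per_subtype, n_genes)
  }
  if (length(cn_events)) {
    bad <- setdiff(names(cn_events), subtypes)
    if (length(bad)) stopf("cn_events for unknown subtype: %s", paste(bad, collapse = ", "))
  }
  for (v in names(clinpath_probs)) {
    pm <- clinpath_probs[[v]]
    if (any(abs(colSums(pm) - 1) > 1e-8) || any(pm < 0)) {
      stopf("clinpath_probs[['%s']] columns must be nonnegative and sum to 1", v)
    }
  }
  if (!setequal(names(progression_levels), subtypes)) {
    stopf("progression_levels must name every subtype")
  }
  structure(list(
    subtypes = subtypes,
    n_patients_per_subtype = n_patients_per_subtype,
    n_nft = n_nft, n_hgsc = n_hgsc, n_meso = n_meso,
    n_genes = n_genes, n_signature_per_subtype = n_signature_per_subtype,
    signature_log2fc = signature_log2fc,
    batch_count = batch_count, batch_sd = batch_sd,
    genome_mode = genome_mode, n_loci = n_loci, depth = depth,
    amplicon_jitter_sdlog = amplicon_jitter_sdlog,
    rna_depth = rna_depth,
    dispersion_meanlog = dispersion_meanlog, dispersion_sdlog = dispersion_sdlog,
    cn_events = cn_events, cn_presence_prob = cn_presence_prob,
    dosage_coupling = dosage_coupling,
    progression_levels = progression_levels,
    within_subtype_cv = within_subtype_cv,
    hgsc_level = hgsc_level, meso_log2fc = meso_log2fc,
    clinpath_probs = clinpath_probs,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' Default per-subtype copy-number events
#'
#' Arm losses of chromosomes 13, 17 and 22 across subtypes, single-copy in
#' log2 units (-1), with focal single-copy gains (+1) of 19q12, 19q13.2 and
#' 8q24 plus a 3q gain (+0.58) concentrated in the proliferative subtype and
#' a 19q12 gain in the immunoreactive subtype.
#'
#' @return Named list of data.frames with columns `region`, `log2`.
#' @export
default_cn_events <- function() {
  ev <- function(region, log2) data.frame(region = region, log2 = log2,
                                          stringsAsFactors = FALSE)
  list(
    dormant = ev(c("13q", "17p", "17q"), c(-1, -1, -1)),
    mixed = ev(c("13q", "17p", "17q", "22q"), c(-1, -1, -1, -1)),
    immunoreactive = ev(c("13q", "17p", "17q", "22q", "19q12"),
                        c(-1, -1, -1, -1, 1)),
    proliferative = ev(c("13q", "17p", "17q", "19q12", "19q13.2", "8q24", "3q"),
                       c(-1, -1, -1, 1, 1, 1, 0.58))
  )
}

# log2 copy-number shift per locus implied by a set of events; regions may
# be arm names (e.g. "17p") or cytoband names (e.g. "19q12").
region_log2_by_position <- function(events, chrom, pos, genome) {
  shift <- numeric(length(pos))
  if (is.null(events) || !nrow(events)) return(shift)
  for (k in seq_len(nrow(events))) {
    reg <- events$region[k]
    i <- match(reg, genome$arms$name)
    if (!is.na(i)) {
      iv <- genome$arms[i, ]
    } else {
      iv <- cytoband_interval(genome, reg)
    }
    hit <- chrom == iv$chrom & pos >= iv$start & pos < iv$end
    shift[hit] <- shift[hit] + events$log2[k]
  }
  shift
}

# Loci placed uniformly at random over the genome, sorted by (chrom, pos0).
make_loci <- function(genome, n_loci) {
  lens <- genome$chromosomes$length
  chrom_idx <- sample.int(nrow(genome$chromosomes), n_loci, replace = TRUE,
                          prob = lens / sum(lens))
  chrom <- genome$chromosomes$chrom[chrom_idx]
  pos0 <- floor(stats::runif(n_loci) * lens[chrom_idx])
  df <- data.frame(chrom = chrom, pos0 = pos0, stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos0), ]
  df$locus_id <- sprintf("locus%06d", seq_len(n_loci))
  rownames(df) <- NULL
  df[, c("locus_id", "chrom", "pos0")]
}

# One DNA sample: multinomial draw over locus weights, optionally shifted by
# copy-number events. Per-sample log-normal amplicon-efficiency jitter makes
# panel members genuinely differ in their amplicon distributions -- the
# reason subset matching exists at all.
draw_locus_sample <- function(sample_id, loci, base_weights, depth,
                              events = NULL, genome = NULL,
                              jitter_sdlog = 0.2) {
  w <- base_weights
  if (jitter_sdlog > 0) {
    w <- w * stats::rlnorm(length(w), meanlog = -jitter_sdlog^2 / 2,
                           sdlog = jitter_sdlog)
  }
  if (!is.null(events) && nrow(events)) {
    shift <- region_log2_by_position(events, loci$chrom, loci$pos0, genome)
    w <- w * 2^shift
  }
  total <- stats::rpois(1, depth)
  counts <- as.numeric(stats::rmultinom(1, total, w / sum(w)))
  locus_counts(sample_id, loci, counts)
}

#' Generate a euploid reference panel
#'
#' Draws `n` euploid DNA samples over a shared locus list with per-sample
#' totals Poisson-distributed around `depth`. At least 8 members are
#' required so that matching a subset of 7 remains possible.
#'
#' @param genome a [genome_model()].
#' @param n panel size (study convention: 30).
#' @param depth mean total reads per sample.
#' @param seed integer seed.
#' @param loci,base_weights optional locus table and per-locus propensity
#'   weights; generated from the seed when omitted. Supply these to share
#'   loci with a cohort.
#' @param n_loci number of loci when `loci` is generated internally.
#' @param jitter_sdlog per-sample amplicon-efficiency jitter (log-scale SD).
#' @return A [reference_panel()].
#' @export
generate_reference_panel <- function(genome, n = 30, depth = 5e5, seed = 1L,
                                     loci = NULL, base_weights = NULL,
                                     n_loci = 20000, jitter_sdlog = 0.2) {
  if (!is_count(n) || n < 8) stopf("panel size must be >= 8 (got %s)", format(n))
  if (!is.numeric(depth) || depth <= 0) stopf("depth must be positive")
  with_seed(seed, {
    if (is.null(loci)) loci <- make_loci(genome, n_loci)
    if (is.null(base_weights)) {
      base_weights <- stats::rgamma(nrow(loci), shape = 1) + 0.1
    }
    members <- lapply(seq_len(n), function(i) {
      draw_locus_sample(sprintf("ref%02d", i), loci, base_weights, depth,
                        jitter_sdlog = jitter_sdlog)
    })
    reference_panel(members)
  })
}

#' Generate subtype-conditional clinicopathological covariates
#'
#' Draws one record per patient, each covariate from its subtype-conditional
#' multinomial.
#'
#' @param subtype_labels character vector, one subtype per patient.
#' @param clinpath_probs named list of probability matrices
#'   (categories x subtypes), see [default_clinpath_probs()].
#' @param seed integer seed.
#' @return data.frame with `patient`, `subtype` and one column per covariate.
#' @export
generate_clinpath <- function(subtype_labels,
                              clinpath_probs = default_clinpath_probs(),
                              seed = 1L) {
  subs <- colnames(clinpath_probs[[1]])
  unknown <- setdiff(unique(subtype_labels), subs)
  if (length(unknown)) {
    stopf("unknown subtype label(s): %s", paste(unknown, collapse = ", "))
  }
  with_seed(seed, {
    out <- data.frame(
      patient = sprintf("pt%04d", seq_along(subtype_labels)),
      subtype = subtype_labels, stringsAsFactors = FALSE
    )
    for (v in names(clinpath_probs)) {
      pm <- clinpath_probs[[v]]
      out[[v]] <- vapply(subtype_labels, function(s) {
        sample(rownames(pm), 1, prob = pm[, s])
      }, character(1), USE.NAMES = FALSE)
    }
    out
  })
}

#' Generate a full synthetic cohort
#'
#' Produces every input the downstream stages consume, alongside the truth
#' used by recovery tests: an AOI expression count matrix with batch
#' effects, a per-patient sample table with clinicopathological covariates,
#' per-patient DNA locus counts carrying the configured copy-number events,
#' a euploid reference panel over the same loci, the genome model, gene
#' coordinates, and truth labels (subtype per AOI, signature gene lists,
#' realized events per patient).
#'
#' Expression counts are negative-binomial with gene-specific dispersion;
#' subtype signature genes carry a mean log2 shift, the proliferative
#' signature additionally carries the progression-axis shift, and genes
#' inside realized copy-number events are dosage-coupled to the DNA log2
#' shift. Per-run batch effects are additive per-gene shifts on the log2
#' scale. All output is a pure function of the configuration (including its
#' seed).
#'
#' @param config a [synth_config()].
#' @return A list of class `cohort_bundle` with elements `expr`
#'   ([aoi_matrix()]), `samples` (data.frame), `dna` (named list of
#'   [locus_counts()] per lesion patient), `panel` ([reference_panel()]),
#'   `genome`, `gene_coords`, and `truth`.
#' @export
generate_cohort <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  genome <- if (config$genome_mode == "toy") toy_genome() else hg_genome()
  with_seed(config$seed, {
    subs <- config$subtypes
    nsig <- config$n_signature_per_subtype
    lfc <- config$signature_log2fc

    ## --- patients / AOIs -------------------------------------------------
    lesion_subtype <- rep(subs, config$n_patients_per_subtype)
    n_lesion <- length(lesion_subtype)
    lesion_pt <- sprintf("pt%04d", seq_len(n_lesion))
    ref_groups <- c(rep("NFT", config$n_nft), rep("HGSC", config$n_hgsc),
                    rep("mesothelium", config$n_meso))
    ref_pt <- sprintf("ref_pt%04d", seq_along(ref_groups))
    diagnosis <- c(rep("STIC", n_lesion), ref_groups)
    patient <- c(lesion_pt, ref_pt)
    n_aoi <- length(patient)
    aoi_id <- sprintf("AOI%04d", seq_len(n_aoi))
    batch <- sprintf("run%d", (seq_len(n_aoi) - 1L) %% config$batch_count + 1L)

    ## --- gene universe ----------------------------------------------------
    gene_id <- sprintf("g%04d", seq_len(config$n_genes))
    base_log2 <- stats::rnorm(config$n_genes, mean = 5, sd = 1.5)
    size_g <- stats::rlnorm(config$n_genes, config$dispersion_meanlog,
                            config$dispersion_sdlog)
    lens <- genome$chromosomes$length
    g_chrom_idx <- sample.int(nrow(genome$chromosomes), config$n_genes,
                              replace = TRUE, prob = lens / sum(lens))
    gene_coords <- data.frame(
      gene_id = gene_id,
      chrom = genome$chromosomes$chrom[g_chrom_idx],
      pos0 = floor(stats::runif(config$n_genes) * lens[g_chrom_idx]),
      stringsAsFactors = FALSE
    )
    blocks <- split(seq_len((length(subs) + 1L) * nsig),
                    rep(seq_len(length(subs) + 1L), each = nsig))
    signatures <- stats::setNames(lapply(blocks[seq_along(subs)],
                                         function(ix) gene_id[ix]), subs)
    meso_sig <- gene_id[blocks[[length(subs) + 1L]]]

    ## --- DNA: loci, panel, per-patient samples ---------------------------
    loci <- make_loci(genome, config$n_loci)
    base_weights <- stats::rgamma(nrow(loci), shape = 1) + 0.1
    panel <- {
      members <- lapply(seq_len(30), function(i) {
        draw_locus_sample(sprintf("ref%02d", i), loci, base_weights,
                          config$depth,
                          jitter_sdlog = config$amplicon_jitter_sdlog)
      })
      reference_panel(members)
    }
    realized_events <- stats::setNames(vector("list", n_lesion), lesion_pt)
    dna <- stats::setNames(vector("list", n_lesion), lesion_pt)
    for (i in seq_len(n_lesion)) {
      ev <- config$cn_events[[lesion_subtype[i]]]
      if (!is.null(ev) && nrow(ev)) {
        keep <- stats::runif(nrow(ev)) < config$cn_presence_prob
        ev <- ev[keep, , drop = FALSE]
      } else {
        ev <- data.frame(region = character(), log2 = numeric())
      }
      realized_events[[i]] <- ev
      dna[[i]] <- draw_locus_sample(lesion_pt[i], loci, base_weights,
                                    config$depth, ev, genome,
                                    jitter_sdlog = config$amplicon_jitter_sdlog)
    }

    ## --- expression -------------------------------------------------------
    mu <- matrix(base_log2, nrow = config$n_genes, ncol = n_aoi)
    rownames(mu) <- gene_id
    prog_sig_idx <- match(signatures[["proliferative"]], gene_id)
    cv <- config$within_subtype_cv
    for (j in seq_len(n_aoi)) {
      if (j <= n_lesion) {
        s <- lesion_subtype[j]
        # continuous within-subtype heterogeneity: each lesion expresses its
        # program at its own strength and sits at its own point on the
        # progression axis
        lfc_j <- lfc * max(stats::rnorm(1, 1, cv), 0.3)
        prog_j <- config$progression_levels[[s]] + stats::rnorm(1, 0, cv / 2)
        mu[match(signatures[[s]], gene_id), j] <-
          mu[match(signatures[[s]], gene_id), j] + lfc_j
        mu[prog_sig_idx, j] <- mu[prog_sig_idx, j] + prog_j * lfc
        if (config$dosage_coupling) {
          ev <- realized_events[[j]]
          gshift <- region_log2_by_position(ev, gene_coords$chrom,
                                            gene_coords$pos0, genome)
          mu[, j] <- mu[, j] + gshift
        }
      } else if (diagnosis[j] == "HGSC") {
        mu[prog_sig_idx, j] <- mu[prog_sig_idx, j] + config$hgsc_level * lfc
      } else if (diagnosis[j] == "mesothelium") {
        mu[match(meso_sig, gene_id), j] <-
          mu[match(meso_sig, gene_id), j] + config$meso_log2fc
      }
    }
    batch_shift <- matrix(stats::rnorm(config$n_genes * config$batch_count,
                                       sd = config$batch_sd),
                          nrow = config$n_genes)
    mu <- mu + batch_shift[, as.integer(factor(batch,
                                               levels = sprintf("run%d", seq_len(config$batch_count))))]
    lib <- stats::rlnorm(n_aoi, meanlog = log(config$rna_depth) - 0.02,
                         sdlog = 0.2)
    prop <- 2^mu
    prop <- sweep(prop, 2, colSums(prop), "/")
    mean_mat <- sweep(prop, 2, lib, "*")
    counts <- matrix(stats::rnbinom(length(mean_mat), mu = mean_mat,
                                    size = size_g),
                     nrow = config$n_genes, dimnames = list(gene_id, aoi_id))

    meta <- data.frame(
      aoi_id = aoi_id, compartment = "epithelial", diagnosis = diagnosis,
      batch = batch, patient = patient, stringsAsFactors = FALSE
    )
    expr <- aoi_matrix(counts, meta, transformed = FALSE)

    ## --- clinicopathological covariates ----------------------------------
    samples <- generate_clinpath(lesion_subtype, config$clinpath_probs,
                                 seed = child_seed(config$seed, "clinpath"))
    samples$patient <- lesion_pt

    structure(list(
      expr = expr, samples = samples, dna = dna, panel = panel,
      genome = genome, gene_coords = gene_coords,
      truth = list(
        subtype = stats::setNames(lesion_subtype, lesion_pt),
        aoi_subtype = stats::setNames(
          c(lesion_subtype, rep(NA_character_, length(ref_groups))), aoi_id),
        signatures = signatures, meso_signature = meso_sig,
        realized_events = realized_events,
        config = config
      )
    ), class = "cohort_bundle")
  })
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf(
    "cohort_bundle: %d genes x %d AOIs, %d DNA samples, panel of %d, %d loci\n",
    nrow(x$expr$values), ncol(x$expr$values), length(x$dna), x$panel$size,
    nrow(x$dna[[1]]$loci)
  ))
  print(table(subtype = x$truth$subtype))
  invisible(x)
}
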