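# Genome models: chromosome/arm/cytoband coordinate tables used by the
# aneuploidy and integration stages. Coordinates are 0-based, half-open.

#' Construct a genome model
#'
#' A genome model bundles chromosome lengths, p/q arm boundaries, the set of
#' acrocentric p arms excluded from arm-level scoring, and named cytoband
#' intervals. Arm-level aneuploidy statistics are computed on the autosomal
#' arms that remain after excluding acrocentric p arms; the model must leave
#' exactly 39 such arms, matching genome-wide arm-level calling on the 22
#' autosomes with the five acrocentric p arms (13p, 14p, 15p, 21p, 22p)
#' removed.
#'
#' @param chromosomes data.frame with columns `chrom`, `length`.
#' @param arms data.frame with columns `chrom`, `arm` ("p"/"q"), `start`,
#'   `end` (0-based half-open).
#' @param acrocentric_p_arms character vector of excluded arm names, e.g.
#'   `"13p"`.
#' @param cytobands data.frame with columns `chrom`, `start`, `end`, `name`.
#' @return An object of class `genome_model`.
#' @seealso [toy_genome()], [hg_genome()]
#' @export
genome_model <- function(chromosomes, arms, acrocentric_p_arms, cytobands) {
  stopifnot(all(c("chrom", "length") %in% names(chromosomes)))
  stopifnot(all(c("chrom", "arm", "start", "end") %in% names(arms)))
  stopifnot(all(c("chrom", "start", "end", "name") %in% names(cytobands)))
  arms$name <- paste0(sub("^chr", "", arms$chrom), arms$arm)
  len <- stats::setNames(chromosomes$length, chromosomes$chrom)
  if (any(arms$end > len[arms$chrom] | arms$start < 0)) {
    stopf("arm boundaries fall outside their chromosome")
  }
  if (any(cytobands$start < 0 | cytobands$end > len[cytobands$chrom] |
          cytobands$start >= cytobands$end)) {
    stopf("malformed cytoband intervals")
  }
  scoreable <- setdiff(arms$name, acrocentric_p_arms)
  if (length(scoreable) != 39L) {
    stopf("genome model must leave 39 scoreable arms, got %d", length(scoreable))
  }
  structure(
    list(
      chromosomes = chromosomes,
      arms = arms,
      acrocentric_p_arms = acrocentric_p_arms,
      cytobands = cytobands,
      scoreable_arms = arms[arms$name %in% scoreable, , drop = FALSE]
    ),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf(
    "genome_model: %d chromosomes, %.1f Mb, %d scoreable arms, %d cytobands\n",
    nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6,
    nrow(x$scoreable_arms), nrow(x$cytobands)
  ))
  invisible(x)
}

#' Miniature 22-autosome genome for desk-scale simulation
#'
#' Twenty-two 10-Mb autosomes with the p/q boundary at 4 Mb and acrocentric
#' p arms on chromosomes 13, 14, 15, 21 and 22, so that exactly 39 scoreable
#' arms exist by construction. Every arm carries named cytobands; the q arms
#' of chromosomes 8 and 19 carry the amplification targets 8q24, 19q12 and
#' 19q13.2 at fixed positions so that focal-call logic can be exercised.
#'
#' @param chrom_mb chromosome length in Mb (default 10).
#' @return A [genome_model()].
#' @export
toy_genome <- function(chrom_mb = 10) {
  mb <- 1e6
  L <- chrom_mb * mb
  split_at <- round(0.4 * L)
  chroms <- data.frame(
    chrom = paste0("chr", 1:22), length = L, stringsAsFactors = FALSE
  )
  arms <- do.call(rbind, lapply(1:22, function(i) {
    data.frame(
      chrom = paste0("chr", i), arm = c("p", "q"),
      start = c(0, split_at), end = c(split_at, L),
      stringsAsFactors = FALSE
    )
  }))
  band <- function(chrom, start, end, name) {
    data.frame(chrom = chrom, start = start, end = end, name = name,
               stringsAsFactors = FALSE)
  }
  scale <- L / (10 * mb)
  cyto <- do.call(rbind, lapply(1:22, function(i) {
    cn <- paste0("chr", i)
    if (i == 19L) {
      rbind(
        band(cn, 0, split_at / 2, "19p12"),
        band(cn, split_at / 2, split_at, "19p11"),
        band(cn, split_at, 6.0 * mb * scale, "19q11"),
        band(cn, 6.0 * mb * scale, 7.5 * mb * scale, "19q12"),
        band(cn, 7.5 * mb * scale, 8.5 * mb * scale, "19q13.1"),
        band(cn, 8.5 * mb * scale, 9.5 * mb * scale, "19q13.2"),
        band(cn, 9.5 * mb * scale, L, "19q13.3")
      )
    } else if (i == 8L) {
      rbind(
        band(cn, 0, split_at / 2, "8p12"),
        band(cn, split_at / 2, split_at, "8p11"),
        band(cn, split_at, 6 * mb * scale, "8q11"),
        band(cn, 6 * mb * scale, 7 * mb * scale, "8q21"),
        band(cn, 7 * mb * scale, 8 * mb * scale, "8q22"),
        band(cn, 8 * mb * scale, 9 * mb * scale, "8q23"),
        band(cn, 9 * mb * scale, L, "8q24")
      )
    } else {
      rbind(
        band(cn, 0, split_at / 2, paste0(i, "p12")),
        band(cn, split_at / 2, split_at, paste0(i, "p11")),
        band(cn, split_at, 6 * mb * scale, paste0(i, "q11")),
        band(cn, 6 * mb * scale, 8 * mb * scale, paste0(i, "q12")),
        band(cn, 8 * mb * scale, L, paste0(i, "q13"))
      )
    }
  }))
  genome_model(chroms, arms,
               acrocentric_p_arms = c("13p", "14p", "15p", "21p", "22p"),
               cytobands = cyto)
}

#' Human-scaled genome model from the bundled arm/cytoband table
#'
#' Loads a static, approximate hg-scaled arm table (22 autosomes with
#' realistic lengths and centromere positions, plus the 8q24 / 19q12 /
#' 19q13.2 target bands and coarse per-arm bands). Intended for runs where
#' genomic proportions should resemble the human autosomes; band boundaries
#' are coarse-grained, not a full ideogram.
#'
#' @return A [genome_model()].
#' @export
hg_genome <- function() {
  path <- system.file("extdata", "hg_arms_synthetic.tsv", package = "sticatlas")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  chroms <- unique(tab[tab$kind == "chrom", c("chrom", "end")])
  names(chroms) <- c("chrom", "length")
  arms <- tab[tab$kind == "arm", c("chrom", "name", "start", "end")]
  arms$arm <- sub("^[0-9]+", "", arms$name)
  cyto <- tab[tab$kind == "band", c("chrom", "start", "end", "name")]
  genome_model(chroms, arms[, c("chrom", "arm", "start", "end")],
               acrocentric_p_arms = c("13p", "14p", "15p", "21p", "22p"),
               cytobands = cyto)
}

# Map 0-based positions to arm names; NA where no arm covers the position.
assign_arm <- function(chrom, pos, genome) {
  arms <- genome$arms
  out <- rep(NA_character_, length(pos))
  for (k in seq_len(nrow(arms))) {
    hit <- chrom == arms$chrom[k] & pos >= arms$start[k] & pos < arms$end[k]
    out[hit] <- arms$name[k]
  }
  out
}

# Locate a named cytoband; errors on unknown names.
cytoband_interval <- function(genome, name) {
  i <- match(name, genome$cytobands$name)
  if (is.na(i)) stopf("unknown cytoband '%s'", name)
  genome$cytobands[i, , drop = FALSE]
}
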