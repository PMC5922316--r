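merged_width <- function(gr) sum(GenomicRanges::width(GenomicRanges::reduce(gr, ignore.strand = TRUE)))

#' Observed vs expected mutation load per genomic region
#'
#' For each sample and region set, counts the SNVs falling inside the
#' intersection of the region with that sample's surveyed (callable) loci.
#' The expected count assumes a uniform rate over surveyed bases:
#' `expected = n_total * surveyed_region_bases / surveyed_total_bases`, where
#' `n_total` counts only SNVs inside the surveyed loci. Restricting both the
#' numerator and the denominator to surveyed bases prevents coverage gaps
#' from masquerading as mutation depletion. Regions and surveyed sets are
#' merged (union) before intersection so double-covered bases count once.
#'
#' @param catalogues A `mut_catalogue` or list of them.
#' @param surveyed_per_sample A `GRanges` of surveyed loci, or a named list
#'   with one `GRanges` per sample (a single unnamed `GRanges` is recycled).
#' @param region_sets Named list of `GRanges` region sets.
#' @return data.frame with one row per sample x region: `sample`, `region`,
#'   `observed`, `n_total`, `surveyed_region_bases`, `surveyed_total_bases`,
#'   `expected`, `log2_ratio`.
#' @export
genomic_distribution <- function(catalogues, surveyed_per_sample, region_sets) {
  catalogues <- as_catalogue_list(catalogues)
  if (inherits(surveyed_per_sample, "GRanges")) {
    surveyed_per_sample <- setNames(
      rep(list(surveyed_per_sample), length(catalogues)), names(catalogues))
  }
  if (!is.list(region_sets) || is.null(names(region_sets))) {
    region_sets <- setNames(list(region_sets), "region")
  }
  rows <- list()
  for (s in names(catalogues)) {
    surveyed <- surveyed_per_sample[[s]]
    if (is.null(surveyed)) stop("missing surveyed loci for sample: ", s)
    surveyed <- GenomicRanges::reduce(surveyed, ignore.strand = TRUE)
    gr <- snv_granges(catalogues[[s]]$snvs)
    in_surv <- IRanges::overlapsAny(gr, surveyed, ignore.strand = TRUE)
    n_total <- sum(in_surv)
    total_bases <- sum(GenomicRanges::width(surveyed))
    for (rn in names(region_sets)) {
      region <- GenomicRanges::reduce(region_sets[[rn]], ignore.strand = TRUE)
      inter <- GenomicRanges::intersect(surveyed, region, ignore.strand = TRUE)
      region_bases <- sum(GenomicRanges::width(inter))
      observed <- sum(in_surv & IRanges::overlapsAny(gr, inter, ignore.strand = TRUE))
      expected <- if (total_bases > 0) n_total * region_bases / total_bases else 0
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, region = rn, observed = observed, n_total = n_total,
        surveyed_region_bases = region_bases,
        surveyed_total_bases = total_bases,
        expected = expected,
        log2_ratio = ifelse(observed > 0 & expected > 0,
                            log2(observed / expected), NA_real_),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-sided binomial enrichment/depletion test of regional mutation load
#'
#' With `n = n_total` surveyed mutations and region probability
#' `pi = surveyed_region_bases / surveyed_total_bases`, the observed count is
#' compared to `Binomial(n, pi)`: when `observed >= expected` the direction
#' is `enrichment` with `p = P[X >= observed]`, otherwise `depletion` with
#' `p = P[X <= observed]`. Tests can be pooled per sample group via `by`
#' (counts and base totals are summed within groups). Significance is
#' flagged at raw `p < alpha`; a BH-adjusted column is included.
#'
#' @param loads Output of [genomic_distribution()].
#' @param by Optional named vector mapping samples to groups (default: each
#'   sample is its own group).
#' @param alpha Significance level (default 0.05).
#' @return data.frame with one row per group x region: pooled counts and
#'   bases, `expected`, `log2_ratio`, `direction`, `p_value`, `p_adjust`,
#'   `significant`.
#' @export
enrichment_depletion_test <- function(loads, by = NULL, alpha = 0.05) {
  if (is.null(by)) {
    by <- setNames(unique(loads$sample), unique(loads$sample))
  }
  if (is.null(names(by))) names(by) <- unique(loads$sample)
  loads$group <- as.character(by[loads$sample])
  if (anyNA(loads$group)) stop("sample missing from 'by' grouping")
  rows <- list()
  for (g in unique(loads$group)) {
    for (rn in unique(loads$region)) {
      sub <- loads[loads$group == g & loads$region == rn, , drop = FALSE]
      observed <- sum(sub$observed)
      n <- sum(sub$n_total)
      region_bases <- sum(sub$surveyed_region_bases)
      total_bases <- sum(sub$surveyed_total_bases)
      pi <- if (total_bases > 0) region_bases / total_bases else 0
      expected <- n * pi
      if (n == 0) {
        direction <- "none"; p <- 1
      } else if (observed >= expected) {
        direction <- "enrichment"
        p <- pbinom(observed - 1, n, pi, lower.tail = FALSE)
      } else {
        direction <- "depletion"
        p <- pbinom(observed, n, pi)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, region = rn, observed = observed, n_total = n,
        surveyed_region_bases = region_bases,
        surveyed_total_bases = total_bases, expected = expected,
        log2_ratio = ifelse(observed > 0 & expected > 0,
                            log2(observed / expected), NA_real_),
        direction = direction, p_value = p, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjust <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < alpha & out$direction != "none"
  rownames(out) <- NULL
  out
}

#' Intermutation distances (rainfall series)
#'
#' For each chromosome, the genomic distance of every SNV to the previous SNV
#' on the same chromosome; the first SNV of each chromosome has no distance
#' (`NA`). Each point carries its 6-category substitution type, the usual
#' colouring of a rainfall plot; runs of very small distances indicate
#' localized hypermutation (kataegis).
#'
#' @param catalogue A `mut_catalogue` (sorted by construction).
#' @return data.frame with one row per SNV: `chrom`, `pos`, `distance`
#'   (NA for the first SNV of each chromosome), `type`.
#' @export
intermutation_distances <- function(catalogue) {
  s <- catalogue$snvs
  if (nrow(s) == 0) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      distance = numeric(0), type = character(0),
                      stringsAsFactors = FALSE))
  }
  dist <- ave(as.numeric(s$pos), s$chrom,
              FUN = function(p) c(NA_real_, diff(p)))
  data.frame(chrom = s$chrom, pos = s$pos, distance = dist,
             type = classify_substitution(s$ref, s$alt),
             stringsAsFactors = FALSE)
}
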