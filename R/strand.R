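# reduce intervals per strand; returns list(plus = GRanges, minus = GRanges)
reduced_stranded <- function(intervals) {
  st <- as.character(GenomicRanges::strand(intervals))
  if (length(intervals) == 0) stop("empty interval set")
  if (any(st == "*")) stop("intervals must be stranded for strand assignment")
  list(plus = GenomicRanges::reduce(intervals[st == "+"]),
       minus = GenomicRanges::reduce(intervals[st == "-"]))
}

snv_granges <- function(snvs) {
  GenomicRanges::GRanges(snvs$chrom, IRanges::IRanges(snvs$pos, snvs$pos))
}

#' Assign a transcriptional or replicative strand to each SNV
#'
#' Every SNV is viewed in the pyrimidine reference frame: its "pyrimidine
#' strand" is `+` when the reference base is C or T, otherwise `-`. Gene
#' annotations report the coding (untranscribed) strand, so an SNV whose
#' pyrimidine strand equals the overlapping gene's strand is labelled
#' `untranscribed`, and `transcribed` otherwise. In replication mode the
#' interval strand encodes fork direction (`+` = right-moving), and the
#' labels are `leading` (pyrimidine strand equals the fork strand) and
#' `lagging`. SNVs outside all intervals are `outside`; SNVs covered by
#' intervals on both strands are `ambiguous`. Same-strand overlaps are merged
#' before assignment.
#'
#' @param catalogue A `mut_catalogue`.
#' @param intervals Stranded `GRanges` (genes or replication-direction
#'   domains).
#' @param mode `"transcription"` or `"replication"`.
#' @return Character vector, one label per SNV in catalogue order.
#' @export
assign_strand <- function(catalogue, intervals, mode = c("transcription", "replication")) {
  mode <- match.arg(mode)
  red <- reduced_stranded(intervals)
  gr <- snv_granges(catalogue$snvs)
  on_plus <- IRanges::overlapsAny(gr, red$plus, ignore.strand = TRUE)
  on_minus <- IRanges::overlapsAny(gr, red$minus, ignore.strand = TRUE)
  pyr_plus <- catalogue$snvs$ref %in% c("C", "T")
  labels1 <- if (mode == "transcription") c("untranscribed", "transcribed")
             else c("leading", "lagging")
  out <- rep("outside", nrow(catalogue$snvs))
  amb <- on_plus & on_minus
  out[amb] <- "ambiguous"
  only_plus <- on_plus & !on_minus
  only_minus <- on_minus & !on_plus
  # same-strand as annotation -> untranscribed / leading
  same <- (only_plus & pyr_plus) | (only_minus & !pyr_plus)
  diff <- (only_plus & !pyr_plus) | (only_minus & pyr_plus)
  out[same] <- labels1[1]
  out[diff] <- labels1[2]
  out
}

strand_levels <- function(mode) {
  if (mode == "transcription") c("transcribed", "untranscribed")
  else c("leading", "lagging")
}

#' Build a stranded 192-channel mutation count matrix
#'
#' Classifies SNVs into the 96 trinucleotide channels crossed with the
#' transcriptional (or replicative) strand. Rows are channel-major with the
#' two strand rows adjacent, strand 1 (`transcribed` / `leading`) first. SNVs
#' outside the annotation, with ambiguous strand, or unclassifiable by
#' context are excluded and tallied in the `"excluded"` attribute.
#'
#' @inheritParams build_mut_matrix
#' @param intervals Stranded `GRanges` annotation.
#' @param mode `"transcription"` or `"replication"`.
#' @return Integer 192 x S matrix.
#' @export
build_mut_matrix_stranded <- function(catalogues, genome, intervals,
                                      mode = c("transcription", "replication")) {
  mode <- match.arg(mode)
  catalogues <- as_catalogue_list(catalogues)
  labs <- channel_labels(stranded = TRUE, mode = mode)
  lev <- strand_levels(mode)
  m <- matrix(0L, 192, length(catalogues), dimnames = list(labs, names(catalogues)))
  excl <- matrix(0L, 3, length(catalogues),
                 dimnames = list(c("outside", "ambiguous", "unclassifiable"),
                                 names(catalogues)))
  for (j in seq_along(catalogues)) {
    cat_j <- catalogues[[j]]
    ch <- snv_channels(genome, cat_j$snvs)
    st <- assign_strand(cat_j, intervals, mode)
    excl["outside", j] <- sum(st == "outside")
    excl["ambiguous", j] <- sum(st == "ambiguous")
    excl["unclassifiable", j] <- sum(is.na(ch$index) & st %in% lev)
    keep <- !is.na(ch$index) & st %in% lev
    if (any(keep)) {
      row_idx <- 2L * ch$index[keep] + match(st[keep], lev)  # 1-based
      t <- tabulate(row_idx, nbins = 192)
      m[, j] <- t
    }
  }
  attr(m, "excluded") <- excl
  m
}

#' Collapse a 192-channel stranded matrix over strands
#'
#' @param matrix192 192 x S matrix from [build_mut_matrix_stranded()].
#' @return 96 x S matrix in canonical channel order.
#' @export
collapse_strands <- function(matrix192) {
  stopifnot(nrow(matrix192) == 192)
  out <- matrix192[seq(1, 192, 2), , drop = FALSE] +
    matrix192[seq(2, 192, 2), , drop = FALSE]
  rownames(out) <- channels_96()
  out
}

# Exact conditional test of equal Poisson rates: given n = n1 + n2, n1 is
# Binomial(n, 1/2) under the null; two-sided p doubles the smaller tail.
binom_equal_rates_p <- function(n1, n2) {
  n <- n1 + n2
  if (n == 0) return(1)
  lo <- pbinom(n1, n, 0.5)
  hi <- pbinom(n1 - 1, n, 0.5, lower.tail = FALSE)
  min(1, 2 * min(lo, hi))
}

strand_bias_table <- function(ids, type, n1, n2, strand_names, alpha) {
  p <- mapply(binom_equal_rates_p, n1, n2)
  ratio <- ifelse(n1 > 0 & n2 > 0, log2(n1 / n2), NA_real_)
  out <- data.frame(group = ids, type = type, stringsAsFactors = FALSE)
  out[[strand_names[1]]] <- n1
  out[[strand_names[2]]] <- n2
  out$log2_ratio <- ratio
  out$p_value <- p
  out$p_adjust <- p.adjust(p, method = "BH")
  out$significant <- out$p_value < alpha
  out
}

#' Test strand asymmetry per group and substitution type
#'
#' For each sample group and each of the 6 substitution types, the counts on
#' the two strands are compared with an exact conditional test of equal
#' Poisson rates: conditional on the total `n = n1 + n2`, `n1` follows
#' `Binomial(n, 1/2)` under the null, and the two-sided p-value doubles the
#' smaller tail (capped at 1). The effect size is `log2(n1 / n2)` (strand 1 =
#' transcribed / leading), finite only when both counts are positive.
#' Significance is reported at raw `p < alpha`; a Benjamini-Hochberg adjusted
#' column is always included.
#'
#' @param matrix192 192 x S stranded count matrix.
#' @param by Optional grouping of samples (named vector or vector matching
#'   columns); defaults to one group per sample.
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @return data.frame with one row per group x type: counts per strand,
#'   `log2_ratio`, `p_value`, `p_adjust`, `significant`.
#' @export
strand_bias_test <- function(matrix192, by = NULL, alpha = 0.05) {
  stopifnot(nrow(matrix192) == 192)
  samples <- colnames(matrix192) %||% as.character(seq_len(ncol(matrix192)))
  if (is.null(by)) by <- setNames(samples, samples)
  if (is.null(names(by))) names(by) <- samples
  by <- as.character(by[samples])
  mode <- if (grepl("transcribed", rownames(matrix192)[1])) "transcription" else "replication"
  lev <- strand_levels(mode)
  types <- rep(channel_types(), each = 2)
  strands <- rep(lev, times = 96)
  rows <- list()
  for (g in unique(by)) {
    sub <- matrix192[, by == g, drop = FALSE]
    tot <- rowSums(sub)
    n1 <- vapply(SUBSTITUTION_TYPES, function(ty) sum(tot[types == ty & strands == lev[1]]), 0)
    n2 <- vapply(SUBSTITUTION_TYPES, function(ty) sum(tot[types == ty & strands == lev[2]]), 0)
    rows[[g]] <- strand_bias_table(g, SUBSTITUTION_TYPES, n1, n2, lev, alpha)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Test strand asymmetry of 192-channel signatures
#'
#' A stranded signature is a probability distribution over the 192 channels;
#' to test its asymmetry the per-strand masses of each substitution type
#' (summed over the 16 contexts) are scaled by the signature's attributed
#' mutation total and rounded to pseudo-counts, then tested exactly as in
#' [strand_bias_test()].
#'
#' @param signatures192 192 x K non-negative signature matrix.
#' @param total_per_signature Numeric vector of attributed mutation totals,
#'   one per signature (e.g. row sums of a contribution matrix).
#' @param alpha Significance level (default 0.05).
#' @return data.frame as in [strand_bias_test()], `group` = signature name.
#' @export
signature_strand_bias <- function(signatures192, total_per_signature, alpha = 0.05) {
  signatures192 <- as.matrix(signatures192)
  stopifnot(nrow(signatures192) == 192)
  if (any(signatures192 < 0)) stop("negative signature entries")
  if (length(total_per_signature) != ncol(signatures192)) {
    stop("one total per signature required")
  }
  mode <- if (grepl("transcribed", rownames(signatures192)[1] %||% "transcribed"))
    "transcription" else "replication"
  lev <- strand_levels(mode)
  types <- rep(channel_types(), each = 2)
  strands <- rep(lev, times = 96)
  sig_names <- colnames(signatures192) %||% paste0("signature", seq_len(ncol(signatures192)))
  rows <- list()
  for (k in seq_len(ncol(signatures192))) {
    v <- signatures192[, k] / sum(signatures192[, k])
    n1 <- vapply(SUBSTITUTION_TYPES, function(ty)
      round(total_per_signature[k] * sum(v[types == ty & strands == lev[1]])), 0)
    n2 <- vapply(SUBSTITUTION_TYPES, function(ty)
      round(total_per_signature[k] * sum(v[types == ty & strands == lev[2]])), 0)
    rows[[k]] <- strand_bias_table(sig_names[k], SUBSTITUTION_TYPES, n1, n2, lev, alpha)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
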