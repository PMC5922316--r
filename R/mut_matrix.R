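# Vectorised channel classification for a catalogue against a genome.
# Returns a data.frame with one row per SNV: index (0-based canonical channel,
# NA when unclassifiable), label, and the plus-strand trinucleotide context.
snv_channels <- function(genome, snvs) {
  gchars <- as_genome_chars(genome)
  lens <- nchar(gchars)
  missing_chrom <- setdiff(unique(snvs$chrom), names(gchars))
  if (length(missing_chrom)) {
    stop("catalogue references chromosome absent from genome: ",
         missing_chrom[1])
  }
  if (nrow(snvs) == 0) {
    return(data.frame(index = integer(0), label = character(0),
                      context = character(0), stringsAsFactors = FALSE))
  }
  chrom_len <- lens[snvs$chrom]
  if (any(snvs$pos < 1 | snvs$pos > chrom_len)) {
    bad <- which(snvs$pos < 1 | snvs$pos > chrom_len)[1]
    stop(sprintf("SNV position out of chromosome bounds: %s:%d",
                 snvs$chrom[bad], snvs$pos[bad]))
  }
  center <- substr_by_chrom(gchars, snvs$chrom, snvs$pos, snvs$pos)
  mism <- center != snvs$ref
  if (any(mism)) {
    b <- which(mism)[1]
    stop(sprintf(paste0("reference mismatch at %s:%d (genome %s, VCF ref %s);",
                        " check that the VCF matches the reference build"),
                 snvs$chrom[b], snvs$pos[b], center[b], snvs$ref[b]))
  }
  at_edge <- snvs$pos == 1L | snvs$pos == chrom_len
  ctx <- rep(NA_character_, nrow(snvs))
  ctx[!at_edge] <- substr_by_chrom(gchars, snvs$chrom[!at_edge],
                                   snvs$pos[!at_edge] - 1L, snvs$pos[!at_edge] + 1L)
  has_n <- !is.na(ctx) & grepl("N", ctx, fixed = TRUE)
  ok <- !at_edge & !has_n
  idx <- rep(NA_integer_, nrow(snvs))
  lab <- rep(NA_character_, nrow(snvs))
  if (any(ok)) {
    ref <- snvs$ref[ok]; alt <- snvs$alt[ok]; cx <- ctx[ok]
    purine <- ref %in% c("A", "G")
    p5 <- ifelse(purine, complement_base(substr(cx, 3, 3)), substr(cx, 1, 1))
    p3 <- ifelse(purine, complement_base(substr(cx, 1, 1)), substr(cx, 3, 3))
    ty <- classify_substitution(ref, alt)
    idx[ok] <- channel_index(ty, p5, p3)
    lab[ok] <- sprintf("%s[%s]%s", p5, ty, p3)
  }
  data.frame(index = idx, label = lab, context = ctx, stringsAsFactors = FALSE)
}

# vectorised substr across chromosomes
substr_by_chrom <- function(gchars, chrom, start, stop) {
  out <- character(length(chrom))
  for (cn in unique(chrom)) {
    i <- chrom == cn
    out[i] <- substring(gchars[[cn]], start[i], stop[i])
  }
  out
}

#' Trinucleotide channel of a single SNV
#'
#' Extracts the plus-strand trinucleotide around the variant from the genome
#' and maps it to the canonical 96-channel system (pyrimidine reference
#' frame; purine-reference variants are reverse-complemented). SNVs at a
#' chromosome terminus or with an `N` in their context are unclassifiable.
#'
#' @param genome A `DNAStringSet` or named character vector.
#' @param chrom,pos,ref,alt The SNV (1-based position).
#' @return A list with `label` (e.g. `"A[C>T]G"`), `index` (0-based canonical
#'   index) and `context` (plus-strand triplet), or `NULL` when the SNV is
#'   unclassifiable.
#' @export
#' @examples
#' channel_96(c(chr1 = "TACGA"), "chr1", 3, "C", "T")
channel_96 <- function(genome, chrom, pos, ref, alt) {
  res <- snv_channels(genome, data.frame(chrom = chrom, pos = as.integer(pos),
                                         ref = toupper(ref), alt = toupper(alt),
                                         stringsAsFactors = FALSE))
  if (is.na(res$index[1])) return(NULL)
  list(label = res$label[1], index = res$index[1], context = res$context[1])
}

as_catalogue_list <- function(catalogues) {
  if (inherits(catalogues, "mut_catalogue")) catalogues <- list(catalogues)
  if (!length(catalogues) || !all(vapply(catalogues, inherits, TRUE, "mut_catalogue"))) {
    stop("expected a mut_catalogue or a list of them")
  }
  nm <- names(catalogues)
  ids <- vapply(catalogues, `[[`, "", "sample_id")
  if (is.null(nm)) names(catalogues) <- ids else {
    names(catalogues) <- ifelse(nm == "" | is.na(nm), ids, nm)
  }
  catalogues
}

#' Build a 96-channel mutation count matrix
#'
#' Classifies every SNV of every catalogue into the 96 trinucleotide channels
#' and tabulates counts per sample. Unclassifiable SNVs (chromosome edge or
#' `N` context) are excluded and tallied in the `"unclassifiable"` attribute.
#' A warning is emitted for samples with fewer than 200 classifiable SNVs,
#' below which a 96-channel profile is usually too noisy to be representative.
#'
#' @param catalogues A `mut_catalogue` or (optionally named) list of them.
#' @param genome A `DNAStringSet` or named character vector.
#' @return Integer 96 x S matrix, canonical channel row labels, one column
#'   per sample.
#' @export
build_mut_matrix <- function(catalogues, genome) {
  catalogues <- as_catalogue_list(catalogues)
  labs <- channels_96()
  m <- matrix(0L, 96, length(catalogues),
              dimnames = list(labs, names(catalogues)))
  unclass_tally <- setNames(integer(length(catalogues)), names(catalogues))
  for (j in seq_along(catalogues)) {
    ch <- snv_channels(genome, catalogues[[j]]$snvs)
    unclass_tally[j] <- sum(is.na(ch$index))
    t <- tabulate(ch$index[!is.na(ch$index)] + 1L, nbins = 96)
    m[, j] <- t
    if (sum(t) < 200) {
      warning(sprintf(paste0("sample '%s' has only %d classifiable SNVs; ",
                             "at least 200 are typically required for a ",
                             "representative 96-channel profile"),
                      names(catalogues)[j], sum(t)), call. = FALSE)
    }
  }
  attr(m, "unclassifiable") <- unclass_tally
  m
}

#' Collapse a 96-channel matrix to the 6 (or 7) substitution-type spectrum
#'
#' Sums the 16 context channels of each substitution type. With
#' `split_cpg = TRUE` the C>T type is split into C>T at CpG sites (3' base G,
#' the deamination-associated context) and C>T at other sites.
#'
#' @param matrix96 96 x S matrix in canonical row order.
#' @param split_cpg Split C>T by CpG context?
#' @return 6 x S (or 7 x S) matrix of type counts.
#' @export
spectrum_by_type <- function(matrix96, split_cpg = FALSE) {
  stopifnot(nrow(matrix96) == 96)
  if (!is.null(rownames(matrix96)) && !identical(rownames(matrix96), channels_96())) {
    stop("matrix rows are not in canonical channel order")
  }
  types <- channel_types()
  if (!split_cpg) {
    out <- rowsum(matrix96, group = factor(types, levels = SUBSTITUTION_TYPES))
    rownames(out) <- SUBSTITUTION_TYPES
    return(out)
  }
  p3 <- substr(channels_96(), 7, 7)  # "A[C>T]G" -> 7th char is the 3' base
  cat7 <- ifelse(types == "C>T",
                 ifelse(p3 == "G", "C>T at CpG", "C>T other"), types)
  lev <- c("C>A", "C>G", "C>T at CpG", "C>T other", "T>A", "T>C", "T>G")
  out <- rowsum(matrix96, group = factor(cat7, levels = lev))
  rownames(out) <- lev
  out
}

#' Per-group mean type spectrum with standard deviations
#'
#' Each sample's type spectrum is normalised to sum 1 (all-zero samples are
#' excluded with a notice); per group, the arithmetic mean and sample
#' standard deviation of each category are reported together with the group's
#' total mutation count.
#'
#' @param matrix_typed Type x S matrix (output of [spectrum_by_type()]).
#' @param groups Named character vector or factor mapping every sample
#'   (column) to a group label.
#' @return A data.frame with columns `group`, `category`, `mean`, `sd`,
#'   `n_samples`, `total_mutations`.
#' @export
group_spectrum <- function(matrix_typed, groups) {
  samples <- colnames(matrix_typed)
  if (is.null(names(groups))) {
    if (length(groups) != length(samples)) stop("groups must be named or match columns")
    names(groups) <- samples
  }
  missing <- setdiff(samples, names(groups))
  if (length(missing)) stop("sample missing from groups: ", missing[1])
  groups <- as.character(groups[samples])
  totals <- colSums(matrix_typed)
  zero <- totals == 0
  if (any(zero)) {
    message("excluding ", sum(zero), " all-zero sample(s) from group spectrum")
  }
  keep <- !zero
  rel <- sweep(matrix_typed[, keep, drop = FALSE], 2, totals[keep], "/")
  out <- list()
  for (g in unique(groups)) {
    j <- keep & groups == g
    sub <- rel[, groups[keep] == g, drop = FALSE]
    if (ncol(sub) == 0) next
    if (ncol(sub) == 1) {
      message("group '", g, "' has a single sample; sd reported as 0")
      sdv <- rep(0, nrow(sub))
    } else {
      sdv <- apply(sub, 1, sd)
    }
    out[[g]] <- data.frame(
      group = g, category = rownames(matrix_typed),
      mean = rowMeans(sub), sd = sdv,
      n_samples = ncol(sub), total_mutations = sum(totals[j]),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  do.call(rbind, out)
}

#' Compare two mutation profiles
#'
#' Both profiles are normalised to sum 1; the difference vector, the residual
#' sum of squares (RSS) between the normalised profiles and their cosine
#' similarity are returned.
#'
#' @param p1,p2 Non-negative numeric vectors of equal length.
#' @return A list with `difference` (`p1 - p2`, normalised scale), `rss` and
#'   `cosine`.
#' @export
compare_profiles <- function(p1, p2) {
  if (length(p1) != length(p2)) stop("profiles must have equal length")
  if (any(p1 < 0) || any(p2 < 0)) stop("profiles must be non-negative")
  if (sum(p1) == 0 || sum(p2) == 0) stop("all-zero profile")
  q1 <- p1 / sum(p1); q2 <- p2 / sum(p2)
  list(difference = q1 - q2,
       rss = sum((q1 - q2)^2),
       cosine = cos_sim(p1, p2))
}
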