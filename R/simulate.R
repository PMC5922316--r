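#' Simulate a toy reference genome
#'
#' Chromosomes are i.i.d. base sequences at the requested GC fraction —
#' deliberately free of the repeat and isochore structure of real genomes,
#' which keeps every trinucleotide context abundant and the generative
#' distribution of simulated catalogues exact.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths (each
#'   >= 1000).
#' @param gc GC fraction in (0, 1) (default 0.42, the human-like value).
#' @param seed RNG seed.
#' @param fasta_path Optional path; when given the genome is also written as
#'   FASTA.
#' @return A `DNAStringSet`.
#' @export
make_genome <- function(chrom_lengths = c(chr1 = 120000, chr2 = 100000, chr3 = 80000),
                        gc = 0.42, seed = 1, fasta_path = NULL) {
  if (!(gc > 0 && gc < 1)) stop("GC fraction must be in (0, 1)")
  if (any(chrom_lengths < 1000)) stop("chromosome lengths must be >= 1000")
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seqs <- with_seed(seed, {
    vapply(chrom_lengths, function(L) {
      paste(sample(BASES, L, replace = TRUE, prob = prob), collapse = "")
    }, character(1))
  })
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- names(chrom_lengths)
  if (!is.null(fasta_path)) Biostrings::writeXStringSet(g, fasta_path)
  g
}

#' Simulate stranded gene annotations and surveyed loci
#'
#' Genes are packed without overlap by slotting: each chromosome is divided
#' into equal slots, one gene per slot at a random offset, leaving room for
#' its promoter. Strands are random. Promoters are fixed-width windows
#' immediately 5' of each gene (upstream of the start for `+` genes, of the
#' end for `-` genes). Surveyed loci cover the genome minus a few small
#' random gaps, mimicking callable-loci output.
#'
#' @param genome A `DNAStringSet` or named character vector.
#' @param n_genes Total number of genes (allocated across chromosomes in
#'   proportion to length).
#' @param gene_length,promoter_length Interval widths in bases.
#' @param gap_fraction Fraction of the genome left unsurveyed (default 0.02).
#' @param seed RNG seed.
#' @return List of `GRanges`: `genes` (stranded, named), `promoters`
#'   (stranded), `surveyed` (unstranded).
#' @export
make_annotations <- function(genome, n_genes = 40, gene_length = 5000,
                             promoter_length = 1000, gap_fraction = 0.02,
                             seed = 1) {
  lens <- genome_lengths(genome)
  alloc <- round(n_genes * lens / sum(lens))
  alloc[1] <- alloc[1] + (n_genes - sum(alloc))
  with_seed(seed, {
    g_chrom <- character(0); g_start <- integer(0); g_strand <- character(0)
    for (ci in seq_along(lens)) {
      ng <- alloc[ci]
      if (ng == 0) next
      slot <- floor(lens[ci] / ng)
      room <- slot - gene_length - promoter_length
      if (room < 1) stop("infeasible packing: slots too small for gene + promoter")
      for (k in seq_len(ng)) {
        offset <- promoter_length + sample.int(room, 1)
        g_chrom <- c(g_chrom, names(lens)[ci])
        g_start <- c(g_start, (k - 1L) * slot + offset)
        g_strand <- c(g_strand, sample(c("+", "-"), 1))
      }
    }
    genes <- GenomicRanges::GRanges(
      g_chrom, IRanges::IRanges(g_start, width = gene_length),
      strand = g_strand)
    names(genes) <- paste0("gene", seq_along(genes))
    plus <- as.character(GenomicRanges::strand(genes)) == "+"
    p_start <- ifelse(plus, GenomicRanges::start(genes) - promoter_length,
                      GenomicRanges::end(genes) + 1L)
    promoters <- GenomicRanges::GRanges(
      g_chrom, IRanges::IRanges(pmax(1L, as.integer(p_start)), width = promoter_length),
      strand = g_strand)
    names(promoters) <- paste0("promoter", seq_along(promoters))
    # surveyed: whole genome minus random gaps totalling ~gap_fraction
    gap_total <- round(gap_fraction * sum(lens))
    n_gaps <- max(1L, round(gap_total / 2000))
    gap_chrom <- sample(names(lens), n_gaps, replace = TRUE, prob = lens / sum(lens))
    gap_len <- rep(floor(gap_total / n_gaps), n_gaps)
    gap_start <- vapply(seq_len(n_gaps), function(i) {
      sample.int(lens[gap_chrom[i]] - gap_len[i], 1)
    }, 0L)
    gaps <- GenomicRanges::GRanges(gap_chrom, IRanges::IRanges(gap_start, width = gap_len))
    whole <- GenomicRanges::GRanges(names(lens), IRanges::IRanges(1L, lens))
    surveyed <- GenomicRanges::setdiff(whole, gaps, ignore.strand = TRUE)
    list(genes = genes, promoters = promoters, surveyed = surveyed)
  })
}

#' Simulate a set of synthetic mutational signatures
#'
#' Each signature is a 96-channel probability vector drawn from a symmetric
#' Dirichlet; a low concentration yields peaked, well-separated signatures.
#' For `k > 1` the draw is repeated (deterministically) until all pairwise
#' cosines fall below `max_pairwise_cosine`, and the achieved cosines are
#' attached as an attribute.
#'
#' @param k Number of signatures.
#' @param seed RNG seed.
#' @param concentration Dirichlet concentration (default 0.05).
#' @param max_pairwise_cosine Separation requirement (default 0.5).
#' @return 96 x k column-stochastic matrix with canonical row labels.
#' @export
make_signature_set <- function(k, seed = 1, concentration = 0.05,
                               max_pairwise_cosine = 0.5) {
  stopifnot(k >= 1)
  draw <- function(s) with_seed(s, {
    m <- matrix(rgamma(96 * k, shape = concentration), 96, k)
    m[m < 1e-300] <- 1e-300
    sweep(m, 2, colSums(m), "/")
  })
  for (attempt in 0:99) {
    m <- draw(seed + 1000L * attempt)
    cs <- if (k > 1) cos_sim_matrix(m, m) else matrix(0, 1, 1)
    off <- cs[upper.tri(cs)]
    if (k == 1 || all(off < max_pairwise_cosine)) {
      dimnames(m) <- list(channels_96(), paste0("TrueSig", seq_len(k)))
      attr(m, "pairwise_cosine") <- off
      attr(m, "attempt") <- attempt
      return(m)
    }
  }
  stop("could not draw ", k, " signatures with pairwise cosine < ",
       max_pairwise_cosine)
}

#' Simulate a mutation count matrix from signature mixtures
#'
#' Draws each sample's channel counts from a multinomial over the mixture
#' `signatures %*% weights[, j]` — the matrix-level generative model, with no
#' genome placement involved.
#'
#' @param signatures 96 x K column-stochastic matrix.
#' @param weights K x S matrix of mixture weights (columns normalised to 1
#'   internally).
#' @param n_per_sample Mutations per sample (scalar or length-S vector).
#' @param seed RNG seed.
#' @return 96 x S count matrix.
#' @export
simulate_mut_matrix <- function(signatures, weights, n_per_sample, seed = 1) {
  weights <- as.matrix(weights)
  ns <- ncol(weights)
  n_per_sample <- rep_len(n_per_sample, ns)
  with_seed(seed, {
    m <- vapply(seq_len(ns), function(j) {
      p <- as.numeric(signatures %*% (weights[, j] / sum(weights[, j])))
      rmultinom(1, n_per_sample[j], p)[, 1]
    }, numeric(96))
  })
  dimnames(m) <- list(rownames(signatures) %||% channels_96(),
                      colnames(weights) %||% paste0("sample", seq_len(ns)))
  m
}

# Index of every interior genome position by its pyrimidine-frame context.
# Returns a data.frame: chrom, pos, ctx (pyrimidine-frame trinucleotide),
# pyr_plus (is the pyrimidine frame the plus strand?).
context_index <- function(genome) {
  gchars <- as_genome_chars(genome)
  out <- vector("list", length(gchars))
  for (ci in seq_along(gchars)) {
    s <- strsplit(gchars[[ci]], "", fixed = TRUE)[[1]]
    L <- length(s)
    if (L < 3) next
    center <- s[2:(L - 1)]
    p5 <- s[1:(L - 2)]
    p3 <- s[3:L]
    ok <- center %in% BASES & p5 %in% BASES & p3 %in% BASES
    pyr <- center %in% c("C", "T")
    ctx <- ifelse(pyr, paste0(p5, center, p3),
                  paste0(chartr("ACGT", "TGCA", p3), chartr("ACGT", "TGCA", center),
                         chartr("ACGT", "TGCA", p5)))
    out[[ci]] <- data.frame(
      chrom = names(gchars)[ci], pos = which(ok) + 1L,
      ctx = ctx[ok], pyr_plus = pyr[ok], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate a somatic SNV catalogue from a signature mixture
#'
#' The generative model is context-conditional: each mutation first draws a
#' 96-channel from the sample's mixture distribution, then a genome position
#' uniformly among all positions whose pyrimidine-frame trinucleotide matches
#' the channel's context, and is emitted in plus-strand VCF coordinates. This
#' makes the generating 96-distribution exact regardless of genome
#' composition. Two optional effects are planted by rejection:
#'
#' * `strand_bias` (with `genes`): mutations inside a single-strand gene keep
#'   a placement whose pyrimidine strand equals the gene strand (label
#'   "untranscribed") with probability `strand_bias`, otherwise with
#'   `1 - strand_bias`; because the toy genome is strand-symmetric on
#'   average, the untranscribed:transcribed ratio converges to
#'   `strand_bias / (1 - strand_bias)`.
#' * `region_multipliers` (with `regions`): a named vector of relative rates;
#'   placements are accepted with probability `multiplier / max(multiplier)`
#'   for the region they fall in (background multiplier 1 unless a `"background"`
#'   entry is supplied).
#'
#' Duplicate (chrom, pos, alt) draws are rejected and redrawn; each mutation
#' is retried at most 100 rounds before the simulation errors out.
#'
#' @param genome A `DNAStringSet` or named character vector.
#' @param signatures 96 x K column-stochastic matrix (canonical row order).
#' @param weights Mixture weights, length K (normalised internally).
#' @param n Number of mutations.
#' @param seed RNG seed.
#' @param sample_id Sample name for the catalogue.
#' @param genes Optional stranded `GRanges` (required for `strand_bias`).
#' @param strand_bias Optional in-gene pyrimidine-on-gene-strand probability
#'   in (0, 1).
#' @param regions Optional named list of `GRanges` for rate multipliers.
#' @param region_multipliers Optional named numeric vector parallel to
#'   `regions`.
#' @param vcf_path Optional path; when given the catalogue is also written
#'   as VCF.
#' @param ctx_index Optional precomputed [context_index()] of `genome`,
#'   to amortise indexing across samples.
#' @return A `mut_catalogue`; attribute `"truth"` records the generating
#'   weights and planted effects.
#' @export
simulate_catalogue <- function(genome, signatures, weights, n, seed = 1,
                               sample_id = "sim", genes = NULL,
                               strand_bias = NULL, regions = NULL,
                               region_multipliers = NULL, vcf_path = NULL,
                               ctx_index = NULL) {
  if (!is.null(strand_bias)) {
    if (is.null(genes)) stop("strand_bias requires gene annotations")
    if (!(strand_bias > 0 && strand_bias < 1)) stop("strand_bias must be in (0, 1)")
  }
  weights <- weights / sum(weights)
  mix <- as.numeric(as.matrix(signatures) %*% weights)
  mix <- mix / sum(mix)
  labs <- parse_channel_label(channels_96())
  chan_ctx <- paste0(labs$five_prime, labs$ref, labs$three_prime)
  chan_alt <- labs$alt
  if (is.null(ctx_index)) ctx_index <- context_index(genome)
  pools <- split(seq_len(nrow(ctx_index)), ctx_index$ctx)
  missing_ctx <- setdiff(unique(chan_ctx[mix > 0]), names(pools))
  if (length(missing_ctx)) {
    stop("no genomic instance of context ", missing_ctx[1],
         " (channel ", channels_96()[match(missing_ctx[1], chan_ctx)], ")")
  }
  # per-position annotations used by the rejection steps
  pos_gr <- GenomicRanges::GRanges(ctx_index$chrom,
                                   IRanges::IRanges(ctx_index$pos, ctx_index$pos))
  gene_state <- NULL
  if (!is.null(strand_bias)) {
    red <- reduced_stranded(genes)
    onp <- IRanges::overlapsAny(pos_gr, red$plus, ignore.strand = TRUE)
    onm <- IRanges::overlapsAny(pos_gr, red$minus, ignore.strand = TRUE)
    gene_state <- ifelse(onp & onm, "ambiguous",
                         ifelse(onp, "+", ifelse(onm, "-", "outside")))
  }
  region_prob <- NULL
  if (!is.null(region_multipliers)) {
    if (is.null(regions)) stop("region_multipliers requires regions")
    bg <- if ("background" %in% names(region_multipliers))
      region_multipliers[["background"]] else 1
    mult <- rep(bg, nrow(ctx_index))
    for (rn in setdiff(names(region_multipliers), "background")) {
      hit <- IRanges::overlapsAny(pos_gr, regions[[rn]], ignore.strand = TRUE)
      mult[hit] <- region_multipliers[[rn]]
    }
    region_prob <- mult / max(mult)
  }
  with_seed(seed, {
    acc_chrom <- character(0); acc_pos <- integer(0)
    acc_ref <- character(0); acc_alt <- character(0); acc_key <- character(0)
    needed <- n
    for (round in seq_len(100)) {
      if (needed == 0) break
      ch <- sample.int(96, needed, replace = TRUE, prob = mix)
      ctxs <- chan_ctx[ch]
      idx <- integer(needed)
      for (cx in unique(ctxs)) {
        sel <- ctxs == cx
        pool <- pools[[cx]]
        idx[sel] <- pool[sample.int(length(pool), sum(sel), replace = TRUE)]
      }
      keep <- rep(TRUE, needed)
      if (!is.null(gene_state)) {
        st <- gene_state[idx]
        pyr_plus <- ctx_index$pyr_plus[idx]
        in_gene <- st %in% c("+", "-")
        untr <- in_gene & ((st == "+") == pyr_plus)
        p_acc <- ifelse(!in_gene, 1, ifelse(untr, strand_bias, 1 - strand_bias))
        keep <- keep & (runif(needed) < p_acc)
      }
      if (!is.null(region_prob)) {
        keep <- keep & (runif(needed) < region_prob[idx])
      }
      pyr_plus <- ctx_index$pyr_plus[idx]
      ref <- ifelse(pyr_plus, substr(chan_ctx[ch], 2, 2),
                    complement_base(substr(chan_ctx[ch], 2, 2)))
      alt <- ifelse(pyr_plus, chan_alt[ch], complement_base(chan_alt[ch]))
      key <- paste0(ctx_index$chrom[idx], ":", ctx_index$pos[idx], ":", alt)
      keep <- keep & !duplicated(key) & !(key %in% acc_key)
      acc_chrom <- c(acc_chrom, ctx_index$chrom[idx][keep])
      acc_pos <- c(acc_pos, ctx_index$pos[idx][keep])
      acc_ref <- c(acc_ref, ref[keep]); acc_alt <- c(acc_alt, alt[keep])
      acc_key <- c(acc_key, key[keep])
      needed <- n - length(acc_key)
    }
    if (needed > 0) {
      stop("simulation could not place ", needed,
           " mutation(s) within the retry cap")
    }
    snvs <- data.frame(chrom = acc_chrom, pos = acc_pos, ref = acc_ref,
                       alt = acc_alt, stringsAsFactors = FALSE)
    cat_out <- new_catalogue(sample_id, snvs)
    attr(cat_out, "truth") <- list(weights = weights, n = n,
                                   strand_bias = strand_bias,
                                   region_multipliers = region_multipliers,
                                   seed = seed)
    if (!is.null(vcf_path)) write_snvs(cat_out, vcf_path)
    cat_out
  })
}

#' Simulate a full study: genome, annotations, signatures and catalogues
#'
#' Drives the individual generators from one specification list and
#' (optionally) writes every artefact — FASTA, per-sample VCFs, BED
#' annotations, the true signature matrix and a truth TSV of generating
#' weights — under an output directory. All randomness derives from
#' `spec$seed`; sample `i` uses `seed + i`.
#'
#' @param spec List with components `seed`, `chrom_lengths`, `gc`,
#'   `n_samples`, `k_signatures`, `n_mutations` (scalar or vector),
#'   `concentration`, and optional `strand_bias`, `region_multipliers`,
#'   `n_genes`, `gene_length`. Missing components take the defaults of the
#'   underlying generators.
#' @param out_dir Optional output directory (created if needed).
#' @return List: `genome`, `annotations`, `signatures`, `weights` (K x S),
#'   `catalogues` (list of `mut_catalogue`).
#' @export
simulate_study <- function(spec, out_dir = NULL) {
  defaults <- list(seed = 1, chrom_lengths = c(chr1 = 120000, chr2 = 100000, chr3 = 80000),
                   gc = 0.42, n_samples = 6, k_signatures = 3,
                   n_mutations = 2000, concentration = 0.05,
                   n_genes = 40, gene_length = 5000,
                   strand_bias = NULL, region_multipliers = NULL)
  spec <- modifyList(defaults, spec[!vapply(spec, is.null, TRUE)])
  genome <- make_genome(spec$chrom_lengths, spec$gc, seed = spec$seed)
  ann <- make_annotations(genome, n_genes = spec$n_genes,
                          gene_length = spec$gene_length, seed = spec$seed)
  sigs <- make_signature_set(spec$k_signatures, seed = spec$seed,
                             concentration = spec$concentration)
  weights <- with_seed(spec$seed, {
    w <- matrix(rgamma(spec$k_signatures * spec$n_samples, shape = 1),
                spec$k_signatures, spec$n_samples)
    sweep(w, 2, colSums(w), "/")
  })
  dimnames(weights) <- list(colnames(sigs),
                            sprintf("sample%02d", seq_len(spec$n_samples)))
  regions <- NULL
  if (!is.null(spec$region_multipliers)) {
    regions <- list(genes = ann$genes, promoters = ann$promoters)
    regions <- regions[intersect(names(regions),
                                 setdiff(names(spec$region_multipliers), "background"))]
  }
  ctx <- context_index(genome)
  n_mut <- rep_len(spec$n_mutations, spec$n_samples)
  catalogues <- lapply(seq_len(spec$n_samples), function(i) {
    simulate_catalogue(genome, sigs, weights[, i], n_mut[i],
                       seed = spec$seed + i,
                       sample_id = colnames(weights)[i],
                       genes = ann$genes, strand_bias = spec$strand_bias,
                       regions = regions,
                       region_multipliers = spec$region_multipliers,
                       ctx_index = ctx)
  })
  names(catalogues) <- colnames(weights)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    Biostrings::writeXStringSet(genome, file.path(out_dir, "genome.fasta"))
    write_intervals(ann$genes, file.path(out_dir, "genes.bed"))
    write_intervals(ann$promoters, file.path(out_dir, "promoters.bed"))
    write_intervals(ann$surveyed, file.path(out_dir, "surveyed.bed"))
    write_matrix_tsv(sigs, file.path(out_dir, "true_signatures.tsv"))
    write_matrix_tsv(weights, file.path(out_dir, "true_weights.tsv"),
                     label_header = "signature")
    for (i in seq_along(catalogues)) {
      write_snvs(catalogues[[i]],
                 file.path(out_dir, paste0(names(catalogues)[i], ".vcf")))
    }
  }
  list(genome = genome, annotations = ann, signatures = sigs,
       weights = weights, catalogues = catalogues)
}
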