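#' Read a reference genome from FASTA
#'
#' Sequences are uppercased (soft-masked lowercase becomes uppercase) and
#' record order is preserved. Chromosome names are taken from the first
#' whitespace-delimited word of each header.
#'
#' @param fasta_path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
read_reference <- function(fasta_path) {
  if (!file.exists(fasta_path)) stop("no such file: ", fasta_path)
  g <- Biostrings::readDNAStringSet(fasta_path)
  if (length(g) == 0) stop("empty FASTA: ", fasta_path)
  nm <- sub("\\s.*$", "", names(g))
  if (any(nm == "")) stop("empty chromosome name in FASTA")
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome name in FASTA: ", nm[duplicated(nm)][1])
  }
  names(g) <- nm
  # DNAStringSet already normalises case on read; enforce for safety
  g
}

#' Chromosome lengths of a genome
#' @param genome A `DNAStringSet` (or named character vector of sequences).
#' @return Named integer vector of chromosome lengths.
#' @export
genome_lengths <- function(genome) {
  if (is.character(genome)) return(setNames(nchar(genome), names(genome)))
  setNames(Biostrings::width(genome), names(genome))
}

# genome as a plain named character vector of uppercase sequences
as_genome_chars <- function(genome) {
  if (is.character(genome)) return(toupper(genome))
  setNames(toupper(as.character(genome)), names(genome))
}

new_catalogue <- function(sample_id, snvs, skipped = integer(0)) {
  ord <- order(snvs$chrom, snvs$pos, snvs$alt)
  snvs <- snvs[ord, , drop = FALSE]
  rownames(snvs) <- NULL
  structure(
    list(sample_id = sample_id, snvs = snvs, skipped = skipped),
    class = "mut_catalogue"
  )
}

#' @export
print.mut_catalogue <- function(x, ...) {
  cat(sprintf("<mut_catalogue> sample '%s': %d SNVs on %d chromosome(s)\n",
              x$sample_id, nrow(x$snvs), length(unique(x$snvs$chrom))))
  if (length(x$skipped) && sum(x$skipped) > 0) {
    cat("  skipped at import:",
        paste(sprintf("%s=%d", names(x$skipped), x$skipped), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of SNVs in a catalogue
#' @param catalogue A `mut_catalogue`.
#' @return Integer count.
#' @export
n_snvs <- function(catalogue) nrow(catalogue$snvs)

empty_snv_frame <- function() {
  data.frame(chrom = character(0), pos = integer(0),
             ref = character(0), alt = character(0), stringsAsFactors = FALSE)
}

#' Import somatic SNVs from a VCF file
#'
#' Retains only biallelic single-nucleotide substitutions. Indels, MNVs,
#' symbolic/breakend alleles, records with `ref == alt` and (by default)
#' non-PASS records are excluded and tallied in the `skipped` field by reason.
#' Multi-allelic records are split into one SNV per alternate allele.
#' Duplicate (chrom, pos, alt) entries are dropped with a tally. Genotype
#' columns are ignored: every retained record belongs to the file's sample.
#'
#' @param vcf_path Path to a VCF file (plain text or bgzip/gzip).
#' @param sample_filter Optional sample name for the catalogue; defaults to
#'   the file name without its `.vcf`/`.vcf.gz` extension.
#' @param keep_filtered If `TRUE`, keep records whose FILTER is not PASS/"."
#'   (default drops them, the usual convention for somatic call sets).
#' @return A `mut_catalogue` sorted by chromosome then position.
#' @export
read_snvs <- function(vcf_path, sample_filter = NULL, keep_filtered = FALSE) {
  if (!file.exists(vcf_path)) stop("no such file: ", vcf_path)
  sample_id <- if (!is.null(sample_filter)) sample_filter else
    sub("\\.vcf(\\.b?gz)?$", "", basename(vcf_path))
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0) {
    return(new_catalogue(sample_id, empty_snv_frame()))
  }
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos)) {
    stop("malformed VCF record (non-numeric POS) at body line ",
         which(is.na(pos))[1])
  }
  chrom <- fix[, "CHROM"]
  ref <- toupper(fix[, "REF"])
  alt_field <- fix[, "ALT"]
  filt <- fix[, "FILTER"]
  filt[is.na(filt)] <- "."
  skipped <- c(indel = 0L, mnv = 0L, symbolic = 0L, ref_equals_alt = 0L,
               non_canonical = 0L, filtered = 0L, duplicate = 0L)

  keep_chrom <- character(0); keep_pos <- integer(0)
  keep_ref <- character(0); keep_alt <- character(0)
  for (i in seq_len(nrow(fix))) {
    if (!keep_filtered && !(filt[i] %in% c("PASS", "."))) {
      skipped["filtered"] <- skipped["filtered"] + 1L
      next
    }
    alts <- toupper(strsplit(alt_field[i], ",", fixed = TRUE)[[1]])
    if (length(alts) == 0 || (length(alts) == 1 && alts %in% c(".", ""))) next
    for (a in alts) {
      if (grepl("<|>|\\[|\\]", a) || a == "*") {
        skipped["symbolic"] <- skipped["symbolic"] + 1L
      } else if (nchar(ref[i]) != nchar(a)) {
        skipped["indel"] <- skipped["indel"] + 1L
      } else if (nchar(ref[i]) > 1) {
        skipped["mnv"] <- skipped["mnv"] + 1L
      } else if (!(ref[i] %in% BASES) || !(a %in% BASES)) {
        skipped["non_canonical"] <- skipped["non_canonical"] + 1L
      } else if (ref[i] == a) {
        skipped["ref_equals_alt"] <- skipped["ref_equals_alt"] + 1L
      } else {
        keep_chrom <- c(keep_chrom, chrom[i]); keep_pos <- c(keep_pos, pos[i])
        keep_ref <- c(keep_ref, ref[i]); keep_alt <- c(keep_alt, a)
      }
    }
  }
  snvs <- data.frame(chrom = keep_chrom, pos = keep_pos, ref = keep_ref,
                     alt = keep_alt, stringsAsFactors = FALSE)
  dup <- duplicated(snvs[, c("chrom", "pos", "alt")])
  skipped["duplicate"] <- sum(dup)
  snvs <- snvs[!dup, , drop = FALSE]
  new_catalogue(sample_id, snvs, skipped[skipped > 0])
}

#' Write a mutation catalogue to a minimal VCF file
#'
#' Emits a VCFv4.2 file with one record per SNV (FILTER PASS), suitable for
#' round-tripping through [read_snvs()].
#'
#' @param catalogue A `mut_catalogue`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_snvs <- function(catalogue, path) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=somaticsigs;sample=%s", catalogue$sample_id),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  s <- catalogue$snvs
  body <- if (nrow(s)) sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                               s$chrom, s$pos, s$ref, s$alt) else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read genomic intervals from a BED file
#'
#' BED's 0-based half-open coordinates are converted to the internal 1-based
#' inclusive convention (the `GRanges` convention). Zero-width BED records
#' (`end <= start`) are rejected.
#'
#' @param bed_path Path to a BED3/BED6 file.
#' @param label Free-text label recorded on the result (e.g. "genes").
#' @param stranded If `FALSE`, strand information is discarded (set to `*`).
#' @return A [GenomicRanges::GRanges]; `metadata(x)$label` carries the label.
#' @export
read_intervals <- function(bed_path, label = basename(bed_path), stranded = TRUE) {
  if (!file.exists(bed_path)) stop("no such file: ", bed_path)
  gr <- rtracklayer::import(bed_path, format = "BED")
  if (any(GenomicRanges::width(gr) == 0)) {
    stop("BED interval with end <= start in ", bed_path)
  }
  if (!stranded) GenomicRanges::strand(gr) <- "*"
  S4Vectors::metadata(gr)$label <- label
  gr
}

#' Write intervals to BED
#'
#' @param intervals A `GRanges`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_intervals <- function(intervals, path) {
  rtracklayer::export(intervals, path, format = "BED")
  invisible(path)
}

#' Read a signature matrix from delimited text
#'
#' Expects 96 data rows keyed by channel label (e.g. `"A[C>A]A"`) in the first
#' column and one numeric column per signature. Rows are reordered into the
#' canonical channel order; any column whose sum deviates from 1 by more than
#' `1e-6` is renormalised to sum 1 (with a notice), so both probability
#' profiles and raw loadings are accepted.
#'
#' @param path Path to a TSV/CSV file.
#' @return Numeric 96 x K matrix, rows in canonical channel order, columns
#'   summing to 1.
#' @export
read_signature_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.delim(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  want <- channels_96()
  if (anyDuplicated(labels)) stop("duplicated channel label: ",
                                  labels[duplicated(labels)][1])
  if (nrow(m) != 96 || !setequal(labels, want)) {
    missing <- setdiff(want, labels)
    stop("expected 96 channels; ",
         if (length(missing)) paste0("missing e.g. ", missing[1])
         else paste0("got ", nrow(m), " rows"))
  }
  if (any(m < 0)) stop("negative entry in signature matrix")
  rownames(m) <- labels
  m <- m[want, , drop = FALSE]
  cs <- colSums(m)
  if (any(cs == 0)) stop("all-zero signature column")
  off <- abs(cs - 1) > 1e-6
  if (any(off)) {
    message("renormalising ", sum(off), " signature column(s) to sum 1")
    m <- sweep(m, 2, cs, "/")
  }
  m
}

#' Read / write channel-labelled count matrices
#'
#' The on-disk dialect is a TSV whose first column holds the channel labels
#' (96 or 192, canonical order) and whose remaining columns are samples or
#' signatures.
#'
#' @param path File path.
#' @return For `read_matrix_tsv`, a numeric matrix with row names.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' @rdname read_matrix_tsv
#' @param m Matrix with row names (channels) and column names.
#' @param label_header Header for the first (label) column.
#' @export
write_matrix_tsv <- function(m, path, label_header = "channel") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(label_header, colnames(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
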