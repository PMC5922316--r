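#' @importFrom rlang .data
#' @importFrom stats pbinom p.adjust sd cor hclust dist as.dendrogram rgamma
#'   runif rmultinom setNames cutree
#' @importFrom utils read.delim write.table head modifyList
NULL

BASES <- c("A", "C", "G", "T")
SUBSTITUTION_TYPES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Canonical 96-channel labels
#'
#' Channels follow the community (COSMIC) convention: substitution type in the
#' pyrimidine reference frame (C>A, C>G, C>T, T>A, T>C, T>G), crossed with the
#' 5' and 3' flanking bases, each ordered A, C, G, T. Channel `i` (0-based)
#' satisfies `i = 16 * type_rank + 4 * rank(5') + rank(3')` and renders as
#' e.g. `"A[C>T]G"`.
#'
#' @param stranded If `TRUE`, return the 192 stranded labels: each channel is
#'   expanded into two adjacent rows, strand 1 (`transcribed`/`leading`) first.
#' @param mode For stranded labels, `"transcription"` (suffixes `-transcribed`
#'   and `-untranscribed`) or `"replication"` (`-leading`, `-lagging`).
#' @return Character vector of 96 (or 192) labels in canonical order.
#' @export
#' @examples
#' head(channel_labels())
channel_labels <- function(stranded = FALSE, mode = c("transcription", "replication")) {
  labs <- as.vector(vapply(SUBSTITUTION_TYPES, function(ty) {
    unlist(lapply(BASES, function(p5) sprintf("%s[%s]%s", p5, ty, BASES)))
  }, character(16)))
  if (!stranded) return(labs)
  mode <- match.arg(mode)
  sfx <- if (mode == "transcription") c("transcribed", "untranscribed") else c("leading", "lagging")
  as.vector(rbind(paste0(labs, "-", sfx[1]), paste0(labs, "-", sfx[2])))
}

channels_96 <- function() channel_labels(stranded = FALSE)

base_rank <- function(b) match(b, BASES) - 1L

complement_base <- function(b) chartr("ACGT", "TGCA", b)

reverse_complement <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Classify a base substitution in the pyrimidine reference frame
#'
#' Substitutions whose reference base is a purine (A or G) are complemented so
#' that every substitution is reported from the strand carrying the pyrimidine
#' reference base; e.g. G>A becomes C>T.
#'
#' @param ref,alt Single reference and alternate bases (A/C/G/T), vectorised.
#' @return Character vector of substitution types among
#'   `c("C>A","C>G","C>T","T>A","T>C","T>G")`.
#' @export
#' @examples
#' classify_substitution("G", "A")  # "C>T"
classify_substitution <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (length(ref) != length(alt)) stop("ref and alt must have equal length")
  if (!all(ref %in% BASES) || !all(alt %in% BASES)) {
    stop("ref and alt must be single canonical bases (A/C/G/T)")
  }
  if (any(ref == alt)) stop("ref and alt must differ")
  purine <- ref %in% c("A", "G")
  r <- ifelse(purine, complement_base(ref), ref)
  a <- ifelse(purine, complement_base(alt), alt)
  ty <- paste0(r, ">", a)
  stopifnot(all(ty %in% SUBSTITUTION_TYPES))
  ty
}

# 0-based canonical channel index from pyrimidine-frame components
channel_index <- function(type, five_prime, three_prime) {
  16L * (match(type, SUBSTITUTION_TYPES) - 1L) +
    4L * base_rank(five_prime) + base_rank(three_prime)
}

# Parse a channel label "A[C>T]G" into its components
parse_channel_label <- function(label) {
  m <- regmatches(label, regexec("^([ACGT])\\[([ACGT])>([ACGT])\\]([ACGT])$", label))
  bad <- vapply(m, length, integer(1)) != 5L
  if (any(bad)) stop("malformed channel label: ", label[bad][1])
  data.frame(
    five_prime = vapply(m, `[`, "", 2L),
    ref = vapply(m, `[`, "", 3L),
    alt = vapply(m, `[`, "", 4L),
    three_prime = vapply(m, `[`, "", 5L),
    stringsAsFactors = FALSE
  )
}

# substitution type of each of the 96 channels, in canonical order
channel_types <- function() rep(SUBSTITUTION_TYPES, each = 16L)

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
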