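# Shared fixtures and independent oracles used across the suite.

# --- tiny on-disk fixtures (built in code, never stored) ----------------

write_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  out <- character(0)
  for (nm in names(seqs)) out <- c(out, paste0(">", nm), seqs[[nm]])
  writeLines(out, path)
  path
}

write_vcf <- function(records, path = tempfile(fileext = ".vcf"),
                      header_extra = character(0)) {
  writeLines(c("##fileformat=VCFv4.2", header_extra,
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", records), path)
  path
}

vcf_rec <- function(chrom, pos, ref, alt, filter = "PASS") {
  sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t.", chrom, pos, ref, alt, filter)
}

write_bed <- function(lines, path = tempfile(fileext = ".bed")) {
  writeLines(lines, path)
  path
}

gr <- function(chrom, start, end, strand = "*") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand)
}

# a small fixed genome + signature set reused by several files
toy_genome <- function(seed = 101) make_genome(c(chr1 = 20000, chr2 = 12000),
                                               gc = 0.5, seed = seed)
toy_signatures <- function(k = 2, seed = 202) make_signature_set(k, seed = seed)

random_stochastic_matrix <- function(n, k) {
  m <- matrix(rgamma(n * k, 0.3) + 1e-12, n, k)
  sweep(m, 2, colSums(m), "/")
}

# --- independent oracles -------------------------------------------------

# exact two-sided equal-rates p-value by explicit enumeration of the
# conditional Binomial(n, 1/2) distribution (exact rational arithmetic is
# unnecessary: dbinom at p = 1/2 is exact in double for n <= 1000)
enum_equal_rates_p <- function(n1, n2) {
  n <- n1 + n2
  if (n == 0) return(1)
  probs <- choose(n, 0:n) / 2^n
  lo <- sum(probs[seq_len(n1 + 1)])
  hi <- sum(probs[(n1 + 1):(n + 1)])
  min(1, 2 * min(lo, hi))
}

# one-sided binomial tails by explicit term-wise summation
enum_binom_upper <- function(obs, n, p) {
  if (obs > n) return(0)
  k <- obs:n
  sum(exp(lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)))
}
enum_binom_lower <- function(obs, n, p) {
  k <- 0:obs
  sum(exp(lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)))
}

# exhaustive simplex-grid NNLS oracle: minimises ||S x - d||^2 over x on the
# grid {x >= 0, sum(x) = total, x_i multiples of step * total}; the quadratic
# form trick (G = S'S, b = S'd) makes full enumeration cheap
grid_nnls_oracle <- function(S, d, total = sum(d), step = 1e-3) {
  k <- ncol(S)
  G <- crossprod(S)
  b <- as.numeric(crossprod(S, d))
  N <- round(1 / step)
  if (k == 2) {
    i <- 0:N
    W <- cbind(i, N - i) / N * total
  } else if (k == 3) {
    i <- rep(0:N, times = N + 1)
    j <- rep(0:N, each = N + 1)
    keep <- i + j <= N
    i <- i[keep]; j <- j[keep]
    W <- cbind(i, j, N - i - j) / N * total
  } else stop("oracle supports K <= 3")
  obj <- rowSums((W %*% G) * W) - 2 * as.numeric(W %*% b) + sum(d^2)
  W[which.min(obj), ]
}

nnls_objective <- function(S, x, d) sum((as.numeric(S %*% x) - d)^2)
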