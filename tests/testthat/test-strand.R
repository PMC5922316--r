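mk_cat <- function(chrom, pos, ref, alt, id = "s") {
  somaticsigs:::new_catalogue(id, data.frame(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    stringsAsFactors = FALSE))
}

test_that("strand labels follow the pyrimidine-on-annotation-strand convention", {
  gene_plus <- gr("chr1", 1, 10, "+")
  # pyrimidine ref on the gene (coding, untranscribed) strand
  expect_equal(assign_strand(mk_cat("chr1", 3, "C", "T"), gene_plus),
               "untranscribed")
  # G>A: the pyrimidine C sits on the minus strand -> transcribed
  expect_equal(assign_strand(mk_cat("chr1", 3, "G", "A"), gene_plus),
               "transcribed")
  # overlap of both strands -> ambiguous; outside -> outside
  both <- c(gr("chr1", 1, 10, "+"), gr("chr1", 5, 15, "-"))
  expect_equal(assign_strand(mk_cat("chr1", 7, "C", "T"), both), "ambiguous")
  expect_equal(assign_strand(mk_cat("chr1", 50, "C", "T"), both), "outside")
  # replication mode relabels the same geometry
  expect_equal(assign_strand(mk_cat("chr1", 3, "C", "T"), gene_plus,
                             mode = "replication"), "leading")
  expect_equal(assign_strand(mk_cat("chr1", 3, "G", "A"), gene_plus,
                             mode = "replication"), "lagging")
  expect_error(assign_strand(mk_cat("chr1", 3, "C", "T"), gr("chr1", 1, 10, "*")),
               "stranded")
})

test_that("strand labels partition the catalogue and swap with annotation strand", {
  g <- toy_genome()
  ann <- make_annotations(g, n_genes = 8, gene_length = 1500,
                          promoter_length = 300, seed = 44)
  cat1 <- simulate_catalogue(g, toy_signatures(), c(0.5, 0.5), 400, seed = 45)
  st <- assign_strand(cat1, ann$genes)
  expect_equal(length(st), n_snvs(cat1))
  expect_true(all(st %in% c("transcribed", "untranscribed", "outside", "ambiguous")))

  flipped <- ann$genes
  sv <- as.character(GenomicRanges::strand(flipped))
  GenomicRanges::strand(flipped) <- ifelse(sv == "+", "-", "+")
  st2 <- assign_strand(cat1, flipped)
  expect_equal(sum(st == "transcribed"), sum(st2 == "untranscribed"))
  expect_equal(sum(st == "untranscribed"), sum(st2 == "transcribed"))
  expect_equal(st == "outside", st2 == "outside")
})

test_that("stranded 192-channel matrices collapse to the in-gene 96 matrix", {
  g <- c(chr1 = "TTACGATT")
  gene <- gr("chr1", 1, 8, "+")
  cat1 <- mk_cat("chr1", 4, "C", "T")
  m <- build_mut_matrix_stranded(cat1, g, gene)
  expect_equal(nrow(m), 192)
  expect_equal(sum(m), 1)
  expect_equal(m["A[C>T]G-untranscribed", 1], 1)

  # marginalising strands reproduces the 96-channel counts of in-gene,
  # unambiguous SNVs
  g2 <- toy_genome()
  ann <- make_annotations(g2, n_genes = 8, gene_length = 1500,
                          promoter_length = 300, seed = 46)
  cat2 <- simulate_catalogue(g2, toy_signatures(), c(0.3, 0.7), 400, seed = 47)
  m192 <- build_mut_matrix_stranded(cat2, g2, ann$genes)
  st <- assign_strand(cat2, ann$genes)
  keep <- st %in% c("transcribed", "untranscribed")
  sub <- somaticsigs:::new_catalogue("in", cat2$snvs[keep, ])
  m96 <- suppressWarnings(build_mut_matrix(sub, g2))
  expect_equal(unname(collapse_strands(m192)[, 1]), unname(m96[, 1]))

  expect_error(build_mut_matrix_stranded(cat1, g, GenomicRanges::GRanges()),
               "empty")
})

test_that("the exact conditional strand test matches enumeration for all totals <= 20", {
  for (n in 0:20) for (n1 in 0:n) {
    expect_equal(somaticsigs:::binom_equal_rates_p(n1, n - n1),
                 enum_equal_rates_p(n1, n - n1), tolerance = 1e-12)
  }
  # worked cases: doubling of the smaller tail
  expect_equal(somaticsigs:::binom_equal_rates_p(8, 2), 0.109375)
  expect_equal(somaticsigs:::binom_equal_rates_p(5, 5), 1)
  expect_equal(somaticsigs:::binom_equal_rates_p(0, 10), 2 / 1024)
})

test_that("strand bias tables report counts, log2 ratios and BH-adjusted p-values", {
  m <- matrix(0, 192, 1, dimnames = list(channel_labels(stranded = TRUE), "s"))
  m["A[C>A]A-transcribed", 1] <- 8
  m["A[C>A]A-untranscribed", 1] <- 2
  m["A[T>C]A-transcribed", 1] <- 5
  m["A[T>C]A-untranscribed", 1] <- 5
  res <- strand_bias_test(m)
  ca <- res[res$type == "C>A", ]
  expect_equal(ca$log2_ratio, 2)
  expect_equal(ca$p_value, 0.109375)
  tc <- res[res$type == "T>C", ]
  expect_equal(tc$log2_ratio, 0)
  expect_equal(tc$p_value, 1)
  # empty type: p = 1, ratio undefined
  cg <- res[res$type == "C>G", ]
  expect_equal(cg$p_value, 1)
  expect_true(is.na(cg$log2_ratio))
  expect_true(all(res$p_adjust >= res$p_value - 1e-12))
})

test_that("signature strand bias scales masses to pseudo-counts before testing", {
  m <- matrix(0, 192, 2, dimnames = list(channel_labels(stranded = TRUE),
                                         c("skewed", "flat")))
  # all C>T mass on the transcribed strand
  m["A[C>T]A-transcribed", "skewed"] <- 1
  m["A[C>T]A-transcribed", "flat"] <- 0.5
  m["A[C>T]A-untranscribed", "flat"] <- 0.5
  res <- signature_strand_bias(m, total_per_signature = c(100, 100))
  sk <- res[res$group == "skewed" & res$type == "C>T", ]
  expect_equal(sk$p_value, min(1, 2 * 2^-100))
  fl <- res[res$group == "flat" & res$type == "C>T", ]
  expect_equal(fl$log2_ratio, 0)
  expect_equal(fl$p_value, 1)
  expect_error(signature_strand_bias(-m, c(1, 1)), "negative")

  # a larger attributed total cannot weaken evidence for a fixed asymmetry
  m2 <- matrix(0, 192, 1, dimnames = list(channel_labels(stranded = TRUE), "s"))
  m2["A[C>A]A-transcribed", 1] <- 0.7
  m2["A[C>A]A-untranscribed", 1] <- 0.3
  p_small <- signature_strand_bias(m2, 50)
  p_big <- signature_strand_bias(m2, 100)
  expect_lte(p_big[p_big$type == "C>A", "p_value"],
             p_small[p_small$type == "C>A", "p_value"])
})

test_that("a planted 3:1 transcriptional bias is recovered with significance", {
  g <- make_genome(seed = 50)
  ann <- make_annotations(g, seed = 50)
  sigs <- make_signature_set(3, seed = 50)
  cat1 <- simulate_catalogue(g, sigs, c(0.4, 0.4, 0.2), 2000, seed = 51,
                             genes = ann$genes, strand_bias = 0.75)
  m192 <- build_mut_matrix_stranded(cat1, g, ann$genes)
  res <- strand_bias_test(m192)
  n_untr <- sum(res$untranscribed); n_tr <- sum(res$transcribed)
  pooled_log2 <- log2(n_untr / n_tr)
  expect_lt(abs(pooled_log2 - log2(3)), 0.15)
  expect_lt(somaticsigs:::binom_equal_rates_p(n_untr, n_tr), 0.05)
})
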