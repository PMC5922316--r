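whole_genome_gr <- function(g) {
  lens <- genome_lengths(g)
  GenomicRanges::GRanges(names(lens), IRanges::IRanges(1, lens))
}

test_that("expected counts follow the surveyed-base rate formula", {
  # n_total = 100 over 1 Mb surveyed; 10 kb of region surveyed -> expected 1
  surveyed <- gr("chr1", 1, 1e6)
  region <- gr("chr1", 1, 1e4)
  set.seed(60)
  pos <- sort(sample(15000:1e6, 99))
  cat1 <- somaticsigs:::new_catalogue("s", data.frame(
    chrom = "chr1", pos = c(5000L, pos), ref = "C", alt = "T",
    stringsAsFactors = FALSE))
  loads <- genomic_distribution(cat1, surveyed, list(reg = region))
  expect_equal(loads$n_total, 100)
  expect_equal(loads$surveyed_region_bases, 1e4)
  expect_equal(loads$expected, 1)
  expect_equal(loads$observed, 1)
})

test_that("a region equal to the surveyed set conserves counts, partitions add up", {
  g <- toy_genome()
  cat1 <- simulate_catalogue(g, toy_signatures(), c(0.5, 0.5), 300, seed = 61)
  surveyed <- whole_genome_gr(g)
  all_loads <- genomic_distribution(cat1, surveyed, list(all = surveyed))
  expect_equal(all_loads$observed, n_snvs(cat1))
  expect_equal(all_loads$expected, all_loads$n_total)

  # random partition of the surveyed set: expecteds sum to n_total
  lens <- genome_lengths(g)
  cut1 <- gr("chr1", 1, 8000)
  cut2 <- gr("chr1", 8001, lens["chr1"])
  cut3 <- gr("chr2", 1, lens["chr2"])
  loads <- genomic_distribution(cat1, surveyed,
                                list(a = cut1, b = cut2, c = cut3))
  expect_equal(sum(loads$expected), unique(loads$n_total))
  expect_equal(sum(loads$observed), n_snvs(cat1))
})

test_that("mutations outside surveyed loci are excluded from totals", {
  surveyed <- gr("chr1", 1, 1000)
  cat1 <- somaticsigs:::new_catalogue("s", data.frame(
    chrom = "chr1", pos = c(100L, 500L, 5000L), ref = "C", alt = "T",
    stringsAsFactors = FALSE))
  loads <- genomic_distribution(cat1, surveyed, list(reg = gr("chr1", 1, 200)))
  expect_equal(loads$n_total, 2)   # the SNV at 5000 is unsurveyed
  expect_equal(loads$observed, 1)
  expect_error(genomic_distribution(cat1, list(other = surveyed),
                                    list(reg = surveyed)),
               "missing surveyed")
})

test_that("enrichment/depletion p-values match exhaustive enumeration for n <= 25", {
  for (n in c(0, 1, 5, 12, 25)) for (obs in unique(c(0, 1, n %/% 2, n))) {
    pi <- 0.23
    loads <- data.frame(sample = "s", region = "r", observed = obs,
                        n_total = n, surveyed_region_bases = 23,
                        surveyed_total_bases = 100,
                        expected = n * pi, log2_ratio = NA)
    res <- enrichment_depletion_test(loads)
    if (n == 0) {
      expect_equal(res$p_value, 1)
      expect_equal(res$direction, "none")
    } else if (obs >= n * pi) {
      expect_equal(res$direction, "enrichment")
      expect_equal(res$p_value, enum_binom_upper(obs, n, pi), tolerance = 1e-12)
    } else {
      expect_equal(res$direction, "depletion")
      expect_equal(res$p_value, enum_binom_lower(obs, n, pi), tolerance = 1e-12)
    }
  }
})

test_that("enrichment worked example and closed forms hold", {
  mk_loads <- function(obs, n, region_bases, total_bases) {
    data.frame(sample = "s", region = "r", observed = obs, n_total = n,
               surveyed_region_bases = region_bases,
               surveyed_total_bases = total_bases,
               expected = n * region_bases / total_bases, log2_ratio = NA)
  }
  # Binomial(100, 0.01) upper tail at 4
  res <- enrichment_depletion_test(mk_loads(4, 100, 1, 100))
  expect_equal(res$direction, "enrichment")
  expect_equal(res$p_value, enum_binom_upper(4, 100, 0.01), tolerance = 1e-12)
  expect_equal(res$p_value, 0.0184, tolerance = 1e-2)

  # observed exactly at expectation: enrichment branch, p >= 0.5, not significant
  res2 <- enrichment_depletion_test(mk_loads(25, 100, 25, 100))
  expect_equal(res2$direction, "enrichment")
  expect_gte(res2$p_value, 0.5)
  expect_false(res2$significant)

  # observed 0 with expected > 0: depletion with p = (1 - pi)^n
  res3 <- enrichment_depletion_test(mk_loads(0, 50, 10, 100))
  expect_equal(res3$direction, "depletion")
  expect_equal(res3$p_value, 0.9^50)
})

test_that("group pooling sums counts and bases before testing", {
  loads <- rbind(
    data.frame(sample = "a", region = "r", observed = 3, n_total = 50,
               surveyed_region_bases = 10, surveyed_total_bases = 100,
               expected = 5, log2_ratio = NA),
    data.frame(sample = "b", region = "r", observed = 4, n_total = 30,
               surveyed_region_bases = 20, surveyed_total_bases = 100,
               expected = 6, log2_ratio = NA))
  res <- enrichment_depletion_test(loads, by = c(a = "g", b = "g"))
  expect_equal(nrow(res), 1)
  expect_equal(res$observed, 7)
  expect_equal(res$n_total, 80)
  expect_equal(res$expected, 80 * 30 / 200)
})

test_that("a planted 3x regional rate is detected with the expected effect size", {
  g <- make_genome(seed = 70)
  sigs <- make_signature_set(3, seed = 70)
  lens <- genome_lengths(g)
  region <- gr("chr1", 1, round(0.05 * sum(lens)))  # 5% of the genome
  cat1 <- simulate_catalogue(g, sigs, c(0.4, 0.4, 0.2), 3000, seed = 71,
                             regions = list(hot = region),
                             region_multipliers = c(hot = 3))
  surveyed <- whole_genome_gr(g)
  loads <- genomic_distribution(cat1, surveyed, list(hot = region))
  res <- enrichment_depletion_test(loads)
  expect_equal(res$direction, "enrichment")
  expect_lt(res$p_value, 0.05)
  expect_lt(abs(res$log2_ratio - log2(3)), 0.3)
})

test_that("intermutation distances difference positions per chromosome", {
  cat1 <- somaticsigs:::new_catalogue("s", data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    pos = c(100L, 150L, 400L, 77L),
    ref = c("C", "C", "G", "T"), alt = c("T", "A", "A", "C"),
    stringsAsFactors = FALSE))
  rf <- intermutation_distances(cat1)
  expect_equal(rf$distance, c(NA, 50, 250, NA))
  expect_equal(rf$distance[rf$chrom == "chr1"], c(NA, 50, 250))
  expect_true(is.na(rf$distance[rf$chrom == "chr2"]))
  expect_equal(rf$type, c("C>T", "C>A", "C>T", "T>C"))
  # number of distances = n_snvs - n_chromosomes_with_snvs
  expect_equal(sum(!is.na(rf$distance)), 4 - 2)

  # one SNV per chromosome: no distances; empty catalogue: empty series
  cat2 <- somaticsigs:::new_catalogue("s", data.frame(
    chrom = c("chr1", "chr2"), pos = c(5L, 9L), ref = "C", alt = "T",
    stringsAsFactors = FALSE))
  expect_equal(sum(!is.na(intermutation_distances(cat2)$distance)), 0)
  empty <- somaticsigs:::new_catalogue("e", somaticsigs:::empty_snv_frame())
  expect_equal(nrow(intermutation_distances(empty)), 0)

  # duplicate positions with different alt: distance 0 retained
  cat3 <- somaticsigs:::new_catalogue("s", data.frame(
    chrom = "chr1", pos = c(10L, 10L), ref = "C", alt = c("A", "T"),
    stringsAsFactors = FALSE))
  expect_equal(intermutation_distances(cat3)$distance, c(NA, 0))
})
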