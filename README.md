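# somaticsigs

Mutational-pattern analysis of somatic single-nucleotide variants (SNVs) in
R. Somatic mutational processes — deamination, UV exposure, defective
repair, mutagens — each leave a characteristic imprint across the 96
trinucleotide mutation channels. `somaticsigs` is for cancer and somatic
genomics researchers who have SNV calls (VCF) and a reference genome
(FASTA) and want to quantify those imprints:

* **96-channel mutation matrices** from VCFs + FASTA (pyrimidine reference
  frame, COSMIC channel order), 6/7-type spectra with an optional CpG
  split, and profile comparison (RSS, cosine similarity).
* **De novo signature extraction** by non-negative matrix factorization
  (multiplicative updates, generalised Kullback–Leibler or Frobenius
  objective, multi-restart, rank survey).
* **Refitting against known signatures** by Lawson–Hanson non-negative
  least squares: for each sample, `min ||S·x − d||²` with `x ≥ 0`, where
  `S` is the signature matrix and `d` the sample's 96-channel count
  vector; per-sample reconstruction diagnostics flag profiles with cosine
  similarity α < 0.95.
* **Strand asymmetries**: transcriptional (or replicative) strand
  assignment, 192-channel stranded matrices, and exact conditional tests
  of equal rates (two-sided, conditional binomial at p = 1/2).
* **Regional enrichment/depletion** of mutations with surveyed-base
  (callable-loci) correction and one-sided binomial tests, plus
  intermutation-distance (rainfall) series for kataegis inspection.
* **A deterministic synthetic-data module** (toy genomes, stranded gene
  annotations, signature mixtures, planted strand/region effects) so the
  entire pipeline is testable end to end without downloads, and a CLI
  (`exec/somaticsigs`) exposing every step for shell pipelines.

## Worked example

Simulate a small cohort from three known signatures, build the mutation
matrix, and refit:

```r
library(somaticsigs)

study <- simulate_study(list(seed = 11, n_samples = 4, n_mutations = 2500,
                             strand_bias = 0.75))
m <- build_mut_matrix(study$catalogues, study$genome)
fit <- fit_to_signatures(m, study$signatures)
round(fit$contribution, 1)
#>          sample01 sample02 sample03 sample04
#> TrueSig1    104.8   1351.6    928.6    393.1
#> TrueSig2   1124.6    556.6   1571.5   1819.2
#> TrueSig3   1243.5    572.3     94.1    285.6
round(fit$diagnostics$cosine, 4)
#> [1] 0.9984 0.9988 0.9972 0.9986
```

The fitted weights are estimated mutation counts per signature and sample;
compare with the generating truth `study$weights * 2500` (e.g. sample01:
114.7 / 1116.3 / 1269.0) — recovery to within a few tens of mutations. The
diagnostics row is the cosine similarity between each observed and
reconstructed profile; values below 0.95 would flag samples whose catalogue
the signatures cannot explain.

The simulation planted a 3:1 transcriptional strand bias; the stranded
matrix and exact test recover it:

```r
m192 <- build_mut_matrix_stranded(study$catalogues, study$genome,
                                  study$annotations$genes)
strand_bias_test(m192, by = setNames(rep("all", 4), colnames(m192)))
#>   type transcribed untranscribed log2_ratio      p_value
#> 1  C>A          87           223  -1.357956 6.408663e-15
#> 2  C>G          71           224  -1.657608 1.251138e-19
#> 3  C>T         460          1230  -1.418953 6.000113e-81
#> 4  T>A         174           481  -1.466950 3.451212e-34
#> 5  T>C         327           846  -1.371367 1.961595e-53
#> 6  T>G         204           644  -1.658492 7.769829e-54
```

Every type shows the planted excess on the untranscribed strand
(log2 ratios near −log2 3 ≈ −1.58, transcribed counted in the numerator).

The same pipeline runs from the shell:

```sh
somaticsigs simulate --out sim/ --n-samples 4 --n-mutations 2500 --seed 11
somaticsigs matrix --vcf sim/sample01.vcf,sim/sample02.vcf --fasta sim/genome.fasta --out m.tsv
somaticsigs fit --matrix m.tsv --signatures sim/true_signatures.tsv --out contrib.tsv
```

A synthetic example of the replication-direction BED6 convention (strand
`+` = rightward-moving fork) ships at
`inst/extdata/replication_direction_synthetic.bed`.

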