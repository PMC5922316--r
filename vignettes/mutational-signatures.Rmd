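---
title: "Mutational signatures and patterns with somaticsigs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutational signatures and patterns with somaticsigs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaticsigs)
```

Somatic mutational processes — spontaneous deamination, UV damage, defective
mismatch repair, mutagen exposure, and many others — each leave a
characteristic imprint on the genome. `somaticsigs` quantifies those imprints
from catalogues of somatic single-nucleotide variants (SNVs): it builds
trinucleotide mutation spectra, extracts and refits mutational signatures,
tests strand asymmetries and regional enrichment, and computes
intermutation-distance series. This vignette explains the models, the
numerical choices and the limits of what the bundled simulations can show.

## The 96-channel mutation model

Every SNV is reduced to a *channel*: its substitution type in the pyrimidine
reference frame (C>A, C>G, C>T, T>A, T>C, T>G — purine-reference calls are
reverse-complemented, so G>A counts as C>T) crossed with the 5' and 3'
flanking reference bases. Channels are ordered by substitution type, then 5'
base, then 3' base (each A < C < G < T), the convention used by published
signature compendia, so channel $i$ (0-based) is
$i = 16\,t + 4\,r_{5'} + r_{3'}$ and renders as, e.g., `A[C>T]G`.

Two classes of SNV cannot be assigned a channel: variants at a chromosome
terminus (no flanking base) and variants whose context contains `N`. These
are excluded and tallied, not errors — they carry no context information. A
disagreement between the VCF REF allele and the genome base, by contrast, is
a hard error: it almost always means the calls were made against a different
reference build, and skipping such records silently would hide a systematic
problem. Profiles built from fewer than 200 classifiable SNVs trigger a
warning, the usual rule of thumb below which a 96-channel profile is too
noisy to be representative.

Internally all coordinates are 1-based inclusive (the VCF and `GRanges`
convention); BED input is converted at the boundary. Multi-allelic VCF
records are split into one substitution per alternate allele, and records
failing FILTER are dropped by default (`keep_filtered = TRUE` retains them)
— somatic call sets are conventionally pre-filtered, and the retained
records are attributed to the file's single sample.

## Signature refitting: non-negative least squares

Given a signature matrix $S$ (96 × K, columns are probability profiles) and
a sample's count vector $d$, the refit solves

$$\min_x \lVert S x - d \rVert_2^2 \quad \text{subject to } x \ge 0.$$

`nnls_fit()` implements the Lawson–Hanson active-set algorithm: variables
enter the passive (positive) set one at a time by most-negative gradient, an
unconstrained least squares is solved on the passive set, and infeasible
steps are truncated at the feasibility boundary. At convergence the
Karush–Kuhn–Tucker conditions hold — zero gradient on positive weights,
non-negative gradient on zero weights — which the tests verify directly and
against an exhaustive simplex-grid search and an independent active-set
implementation. Because each signature column sums to 1, the fitted weights
are on the mutation-count scale; "relative" contributions are computed per
sample as $x_k / \sum_j x_j$, so a stacked bar always fills to 1.

Refitting is per-sample independent — fitting a sample alone or within a
cohort gives identical weights — which is what makes the method usable on
single samples and small cohorts. The quality of a refit is summarised by
the cosine similarity between the original and reconstructed profile,

$$\alpha = \frac{\sum_i A_i B_i}{\sqrt{\sum_i A_i^2}\sqrt{\sum_i B_i^2}},$$

which is scale-invariant and lies in $[0, 1]$ for non-negative profiles.
Samples with $\alpha < 0.95$ are flagged: their catalogue is not fully
explained by the provided signatures, and the per-channel difference profile
points at what is missing.

## De novo extraction: non-negative matrix factorization

`extract_signatures()` factorises the count matrix $M \approx W H$ with
multiplicative updates. The default objective is the generalised
Kullback–Leibler divergence, the natural likelihood for count data (a
Frobenius option exists); the classical multiplicative updates guarantee a
monotone non-increasing objective, which the tests assert on every
iteration. Numerical choices: factors are initialised uniformly on
$[0.1, 1]$; divisions and logarithms are floored at $10^{-12}$; iteration
stops when the relative objective change drops below $10^{-8}$ or after
5,000 iterations. Restart $r$ of `nrun` is seeded `seed + r`, the best run
is chosen by lowest final objective (ties by lowest run index), and the
result is bit-reproducible for a given seed. Signature columns are
normalised to sum 1 with contributions rescaled, so $WH$ is unchanged.

NMF needs the number of signatures up front. `rank_survey()` reports, per
candidate rank, the best objective, the mean reconstruction cosine and a
stability score (mean matched-signature cosine across restarts); the
preferred rank is where reconstruction stops improving sharply while
stability stays high. Signature matching — here and in the recovery tests —
maximises total cosine over one-to-one assignments (exact permutation search
up to 7 signatures, greedy beyond).

## Strand asymmetries

Transcription-coupled repair acts on the transcribed (template) strand, so
its activity shows up as an asymmetry between mutations whose pyrimidine
sits on the coding versus the template strand. Gene annotations report the
coding (untranscribed) strand; an SNV whose pyrimidine base lies on the
annotation strand is labelled *untranscribed*, on the opposite strand
*transcribed*. SNVs outside genes are *outside*; positions covered by genes
on both strands are *ambiguous* and excluded (same-strand overlaps are
merged first). In replication mode the same machinery applies with interval
strand encoding fork direction (`+` = rightward-moving fork, as in the
bundled `inst/extdata/replication_direction_synthetic.bed` example, a
synthetic file illustrating the expected BED6 layout), yielding
*leading*/*lagging* labels. The package consumes replication-direction
annotations as files; deriving them from replication-timing experiments is
out of scope.

Counts on the two strands are compared with the exact conditional test of
equal Poisson rates: conditional on the total $n = n_1 + n_2$, $n_1 \sim
\mathrm{Binomial}(n, 1/2)$ under the null, and the two-sided p-value doubles
the smaller tail, capped at 1. The tests verify this against explicit
enumeration for all totals up to 20. For stranded (192-channel) signatures
the per-strand masses of each substitution type are scaled by the
signature's attributed mutation total and rounded to pseudo-counts before
the same test — a choice made explicit here because signature loadings are
probabilities, not counts, and some mapping to counts is unavoidable.
Significance is flagged at raw $p < 0.05$ to mirror the usual presentation;
a Benjamini–Hochberg column is always emitted alongside.

## Regional enrichment and depletion

Whether mutations concentrate in or avoid a set of regions (promoters, gene
bodies, binding sites…) is tested against a uniform-rate null restricted to
*surveyed* bases — positions callable in that sample. With $n$ surveyed
mutations and $\pi$ the surveyed-region fraction of surveyed bases, the
expected regional count is $n\pi$ and the observed count is compared to
$\mathrm{Binomial}(n, \pi)$, one-sided: enrichment ($P[X \ge \mathrm{obs}]$,
the branch also taken at equality, for determinism) or depletion
($P[X \le \mathrm{obs}]$). Ignoring the surveyed correction would, for
example, report spurious depletion wherever coverage is poor. Regions and
surveyed sets are merged before intersection so double-covered bases count
once; group-level tests pool counts and bases across samples rather than
combining p-values, which keeps the test a single binomial on pooled data.

`intermutation_distances()` supplies the rainfall series — per chromosome,
each SNV's distance to its predecessor, coloured by the 6 substitution
types. Runs of very small distances indicate kataegis; detection is left
visual, as is conventional.

## The synthetic-data module

Every analysis above is exercised end to end on synthetic data with known
ground truth, generated deterministically from a seed:

* **Genome** — i.i.d. bases at a set GC fraction (default 0.42,
  human-like); default size three chromosomes of 120, 100 and 80 kb. At
  this size every trinucleotide context occurs thousands of times, which the
  placement model requires.
* **Signatures** — symmetric-Dirichlet draws over the 96 channels
  (concentration 0.05), redrawn deterministically until pairwise cosines
  fall below 0.5, giving peaked, well-separated processes.
* **Catalogues** — *context-conditional placement*: each mutation draws a
  channel from the sample's mixture, then a position uniformly among
  matching contexts. The generating 96-distribution is therefore exact by
  construction, regardless of genome composition. Strand bias is planted by
  accepting in-gene placements with probability `strand_bias` when the
  pyrimidine falls on the gene strand (so the untranscribed:transcribed
  ratio converges to `strand_bias/(1 - strand_bias)`); regional rate
  multipliers are planted by rejection with probability proportional to the
  multiplier. Each round of rejections is redrawn, up to 100 rounds, after
  which the simulation errors rather than silently under-delivering.
* **Annotations** — genes are slotted without overlap, one per equal-width
  slot, with fixed-width promoters immediately 5' of each gene; the default
  40 genes × 5 kb cover two thirds of the toy genome, deliberately
  gene-dense so that a 2,000-mutation catalogue yields on the order of a
  thousand strand-labelled mutations and the planted log-ratio is estimated
  with a standard error well inside the tolerance checked by the tests.
  Surveyed loci cover the genome minus ~2% of random gaps.

The default problem sizes used throughout the tests and the acceptance
script — 30 samples × 3,000 mutations for extraction recovery, 2,000
mutations for the planted 3:1 strand bias, 3,000 for the planted 3× regional
rate on 5% of the genome, 10,000 for generative fidelity — were chosen as
the smallest sizes at which the statistical effects are comfortably
detectable, and they run in seconds to minutes.

What the simulations do *not* emulate — and hence what passing tests cannot
show about real data: repeat structure and local composition bias of real
genomes, clonal structure and variant allele fractions, sequencing artefacts
and caller-specific error modes, correlated mutation processes (true
kataegis), replication-timing realism, and realistic (COSMIC-like)
signature shapes beyond separation. Results on real cohorts depend on those
factors; the simulations validate the algebra and the statistics, not the
biology.

## Known limitations

* Only single-nucleotide substitutions are modelled: no indel, doublet or
  extended (1536-channel) contexts.
* NMF extraction is the classical multiplicative-update variant; Bayesian
  or probabilistic extraction methods are out of scope, though their output
  can be refit with `fit_to_signatures()`.
* Published signature compendia are consumed as user-supplied files
  (`read_signature_matrix()`); none is redistributed with the package.
* VCF genotype columns are ignored — one VCF is one sample's catalogue.
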