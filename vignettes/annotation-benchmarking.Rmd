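---
title: "Benchmarking gene family abundance estimation from shotgun metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking gene family abundance estimation from shotgun metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metafam)
```

## The estimation problem

A shotgun metagenome is a random sample of DNA fragments from a community of
genomes. Functional annotation asks: what fraction of the community's coding
capacity belongs to each protein family? metafam implements both the
estimator and the machinery to benchmark it against ground truth.

The ground truth comes from *mock communities*. Given reference genomes with
annotated protein-coding genes, the abundance of family $i$ is

$$A_i = \sum_j C_{i,j}\, A_j,$$

where $C_{i,j}$ is the copy number of family $i$ in genome $j$ (always
*counted* from the gene table, never supplied directly) and $A_j$ is the
genome's coverage in the community. Relative abundances
$R_i = A_i / \sum_i A_i$ sum to one. `expected_family_abundance()` computes
this profile.

The estimator mirrors what annotation pipelines do with real data:

1. **Simulate reads** (`simulate_reads()`): reads are allocated to genomes by
   a multinomial draw proportional to $A_j$, positioned uniformly, stranded
   uniformly, and corrupted by an error model.
2. **Predict ORFs** (`predict_orfs()`): six-frame translation, splitting
   each frame on stop codons, discarding peptides shorter than `min_len`
   amino acids (default 15; strictly shorter, so a 15-residue peptide
   survives). ORFs are *not* required to start with methionine — reads are
   genome fragments, and requiring a start codon would discard most true
   gene fragments.
3. **Classify** (`naive_translated_align()` + `classify_hits()`):
   Smith–Waterman local alignment against the reference proteins, hits kept
   iff their bit score is at least the threshold (inclusive, matching
   "at least *b* bits" semantics), then one winner per read (`per_read`) or
   per ORF (`per_orf`).
4. **Estimate abundance** (`count_abundance()` / `coverage_abundance()`):
   each winning hit contributes $1/L_k$ (count) or $X_k/L_k$ (coverage),
   where $L_k$ is the *winning hit's own* target gene length in amino acids
   and $X_k = \mathrm{send} - \mathrm{sstart} + 1$ the aligned target
   residues. $X_k$ counts target residues rather than alignment columns so
   that gaps in the target do not inflate coverage. Profiles are then scaled
   to sum to one.
5. **Score** (`l1_error()`): $D = \tfrac12 \sum_i |R_i - \hat R_i|$, which
   is 0 for perfect recovery, 1 for disjoint supports, and coincides
   algebraically with Bray–Curtis dissimilarity on normalized profiles.

## Error models

`error_model()` supports five shapes. Two decisions deserve emphasis:

* **poly4 percent convention.** The position-dependent Illumina-style rate
  is $p(i) = (a + b\,i^4)/100$ with defaults $a = 3\times10^{-3}$,
  $b = 3.3\times10^{-8}$, i.e. the parameters are percentages. Without the
  division by 100 the "probability" would exceed 1 near position 100, so the
  percent reading is the only self-consistent one. At position 100 the
  default rate is 0.03303.
* **Substitution/indel mix.** Given an error, substitution probability is
  $r/(r+1)$ with $r$ the `sub_indel_ratio` (default 4:1, the approximate
  composition of raw Illumina error), insertions and deletions splitting
  the remainder evenly (1/10 each).

The homopolymer (454-style) model resamples each homopolymer run length
from $\mathrm{round}(N(n, 0.03 + 0.15n))$ clamped at zero. It is a
deliberately simple approximation of pyrosequencing length noise and is
documented as such; none of the package's quantitative benchmarks depend
on it.

Read allocation follows coverage literally: reads $\propto A_j$, not
$A_j \times$ genome length. The alternative (which realizes per-base
coverage $A_j$) is available via `weight_by_length = TRUE`; with the
equal-length genomes of the synthetic generator the two coincide up to
noise, which is why the generator keeps genome lengths homogeneous.

## The built-in aligner

Real pipelines delegate homology search to external tools; the package
instead ships a self-contained translated search so that every benchmark
can run without external binaries. It is exact Smith–Waterman (BLOSUM62,
gap open 11, extend 1, via Biostrings) with the Karlin–Altschul
conversion $S' = (\lambda S - \ln K)/\ln 2$, $\lambda = 0.267$,
$K = 0.041$ (published gapped-BLOSUM62 constants), and
$E = \mathrm{db\_residues}\cdot\mathrm{query\_len}\cdot 2^{-S'}$. These
constants only need to be *internally* consistent: all thresholds used
here are swept or validated against this aligner's own score scale, never
transferred from another tool.

All-vs-all Smith–Waterman over a library is quadratic, so
`aligner_params(seed_k = k)` enables a k-mer seed prefilter: only
(peptide, gene) pairs sharing an exact amino-acid k-mer are aligned. With
`seed_k = 6`, a true homolog of 30+ residues at a 1% nucleotide error rate
retains a clean 6-mer with near certainty, while unrelated 20-residue
peptides rarely do; the tests verify the prefilter only prunes pairs and
never changes a surviving alignment. The default (`seed_k = NULL`) remains
exhaustive, which is what small fixtures and oracle tests use.

Ties in winner selection are broken by bit score, then E-value, then
lexicographic target gene id — an arbitrary but fully deterministic order,
chosen because reproducibility matters more than any particular
convention.

## Read-length dependent thresholds

Short-read annotation accuracy is sharply sensitive to the bit-score
threshold, and the optimum grows with read length.
`default_bitscore_threshold()` interpolates linearly over two anchors —
31 bits at 100 bp and 35 bits at 250 bp — and clamps outside them with a
warning, since values beyond the anchors are extrapolations. Users
sweeping their own data should prefer `threshold_sweep()`, which reports
the optimum and the band of thresholds within 1% of it.

## Sequencing depth, variance, and diversity

In the absence of biological variation a family's classified-read count is
Poisson, so its coefficient of variation is $1/\sqrt{\text{mean}}$:
about 100 classified reads gives CV $\le 0.10$. `bootstrap_family_cv()`
verifies this empirically; `reads_for_target_cv()` inverts it into a
library-size calculator,
$N = \lceil (1/\mathrm{cv}^2)\,\mathrm{AGS}/L \rceil$ — e.g. 300,000 reads
for a 1-kb single-copy gene at a 3-Mb average genome size.

Rarefaction (`rarefy_classifications()`) samples *source reads* without
replacement — depth is a read count, and subsampling ORFs would break the
read-level dependence structure. Bootstrap resampling uses replacement,
and a read drawn twice counts twice. Alpha diversity uses Shannon entropy
in natural-log units (the unit is a pure convention and is documented
wherever reported) and the classical Good's coverage $1 - F_1/N$.

## The comparison layer

Family-by-sample matrices are tested family-wise with rank-based tests:
Kruskal–Wallis for categorical covariates, Kendall's tau for continuous
ones; constant families get $p = 1$ by convention. For total $n \le 10$
the Kruskal–Wallis p-value is computed *exactly* by enumerating every
distinct assignment of the observations to groups — clinical cohorts in
this field can have as few as 4 subjects per group, where the chi-square
asymptotic is unreliable.

Multiple testing uses Storey q-values with $\pi_0$ estimated by the
smoother variant (naive estimates over
$\lambda \in \{0.05, \dots, 0.95\}$, cubic spline with 3 df, evaluated at
the largest $\lambda$, clamped to $(0,1]$). The smoother-vs-bootstrap
choice is open in the literature; the smoother is the common default and
`pi0 = 1` reproduces Benjamini–Hochberg exactly, which both the tests and
sceptical users can exploit. Default significance levels are $q \le 0.10$
for families and $q \le 0.25$ for pathway enrichment. Enrichment tests are
one-sided Fisher (enrichment direction only), with $\pi_0 = 1$ by default
because the number of pathways is usually too small for a stable
$\pi_0$ estimate.

PERMANOVA delegates to `vegan::adonis2` (Anderson's pseudo-F,
$p = (1 + \#\{F_\mathrm{perm} \ge F_\mathrm{obs}\})/(1 + n_\mathrm{perm})$,
default $10^4$ permutations) wrapped for seed determinism. PCA treats
*samples* as observations and families as variables, dropping
zero-variance families and scaling the rest to zero mean and unit
variance by default.

## What the synthetic generator does and does not emulate

`synth_reference_set()` plants genes with known family labels on random
strands, separated by 10-nt random spacers, drawing each genome's
genes from a shared family pool with replacement (so copy numbers vary).
Proteins are uniform-random over the 20 amino acids; nucleotide sequences
are random synonymous reverse-translations. Defaults — 10 genomes,
~50 genes each, 100 families, 150–250 aa genes — are the scale used by the
package's own end-to-end benchmarks, with log-normal community coverages
(`sdlog = 1`) as a skewed species-abundance shape.

Deliberate idealizations, and hence what passing benchmarks do *not*
demonstrate about real data:

* families are unrelated random sequences — there is no remote homology,
  no shared domains, no compositional bias, so cross-family
  misclassification is rarer than in real databases;
* genomes are ~95% coding with equal lengths, so classification rates are
  higher and length-weighting subtleties smaller than in real genomes;
* every community member is in the reference (unless `clade_exclude()` is
  used), unlike real communities with novel taxa;
* no paralog divergence: copies of a family are synonymous variants of one
  protein.

The benchmarks therefore validate the *estimator machinery* — formulas,
thresholds, normalizations, samplers, test statistics — not the biological
difficulty of any particular environment.

## Numerical choices and degenerate inputs

* Profiles are "normalized" iff their sum is within $10^{-9}$ of 1;
  `l1_error()` and `bray_curtis()` refuse unnormalized input rather than
  silently renormalizing.
* All-zero profiles, empty classification sets, zero-coverage communities
  and all-zero count vectors are hard errors; a threshold at which nothing
  classifies is *not* an error and scores L1 = 1.
* Zero-mean families have undefined CV and are reported as `NA`.
* Coordinates are 1-based inclusive throughout (GFF convention), and
  `length_aa` is `floor(span/3)` when no protein is supplied, otherwise
  the protein length.
* Seeded routines snapshot and restore the caller's RNG state, so library
  calls never perturb user random streams.

## Benchmark problem sizes

The shipped test suite exercises, among smaller fixtures: a 10-genome ×
~50-gene mock community; a 50,000-read 101-bp library at 1% uniform error
(profile recovery to L1 < 0.05; rarefaction at depths $10^3$, $10^4$,
$5\times10^4$); a 1,200-read 3-kb library (where per-ORF + coverage
annotation clearly beats per-read + count, and the ordering reverses for
short reads); and 4,000-read error-free and shuffled negative-control
libraries (classification rate > 90% vs false-positive rate < 1% at the
default threshold). These sizes were chosen as the smallest at which the
Monte-Carlo comparisons above are decisive.

## Known limitations

* Only the standard genetic code (table 1) is implemented; organisms with
  alternative codes would need a different translation table.
* The built-in aligner is a benchmarking oracle, not a speed-competitive
  search engine; real studies should import external search results via
  `parse_tabular_alignments()` (BLAST or RAPsearch2 m8 dialects).
* Average genome size is an input to `ags_normalize()`, never estimated.
* Paired-end reads and quality-aware error profiles are out of scope.
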