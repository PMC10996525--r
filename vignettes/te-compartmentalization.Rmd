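---
title: "TE compartmentalization: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TE compartmentalization: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The statistic

Transposable elements (TEs) are not spread evenly through eukaryotic
genomes: in many lineages, genes belonging to rapidly evolving,
environment-facing multigene families sit inside TE-rich neighbourhoods.
`tecompart` operationalises that observation as a per-gene statistic.
For a gene $g$ on a chromosome of length $C$, take the flanking windows
of length $L$ (default $L = 50$ kb) immediately up- and downstream of the
gene span, truncated at the chromosome ends; subtract every annotated
CDS interval genome-wide (the focal gene's neighbours included; introns
and UTRs remain); and over the resulting noncoding flank $F_g$ define
the TE density

$$ d_g = \frac{\big|\,F_g \cap \bigcup \text{TE intervals}\,\big|}{|F_g|}, $$

the proportion of noncoding flank positions covered by resolved TE
annotations. A gene is **TE-compartmentalized** when $d_g$ lies at or
above the $\tau$-th percentile (default $\tau = 90$; 95 as fallback and
for sharper call sets) of the per-species density distribution. The
statistic is computed for all TEs together and separately per class
(LINE, SINE, LTR, DNA); simple repeats and low-complexity annotations
are carried through I/O but never counted as TE sequence.

Repeat annotations arrive fragmented and overlapping (RepeatMasker-style
output). Before any coverage computation they are resolved greedily by
score: records are ranked by descending score (ties: leftmost start,
then longer record) and a record survives only if it overlaps no
already-kept record. Survivors are kept intact; losers are dropped
whole. After resolution the per-class covers are disjoint, so the class
covers partition the total cover exactly — an invariant the test suite
asserts.

## Downstream characterisation

* **GO enrichment / purification** — one two-sided Fisher's exact test
  per term (called, annotated genes vs all annotated eligible genes),
  Benjamini–Hochberg correction over terms, both directions reported.
  Species with under 20% of genes GO-annotated are refused; a study set
  below 4 annotated genes is not tested. If no term reaches $q < 0.05$
  at $\tau = 90$ the call set is recomputed at $\tau = 95$ and retested.
* **Multigene-family fold** — ratio of the fraction of called genes in
  families of at least 10 members to the same fraction among background
  genes.
* **Chromosomal context** — a gene is subtelomeric when its midpoint
  falls in the first or last 10% of its chromosome; the observed
  subtelomeric proportion of called genes is compared against 1,000
  resamplings of equally many genes drawn without replacement. GC or
  recombination tracks are compared between called and background genes
  by a two-sided rank-sum test on bp-weighted track means over the gene
  span plus its noncoding flanks, and per-species direction signs feed an
  exact two-sided binomial test across species.
* **Folded allele-frequency spectra** — population variants are
  filtered (biallelic; SVs strictly longer than 50 bp with TE coverage
  of at least 0.5; 500 bp single-linkage breakpoint merging), assigned
  to called or other genes (TE SVs by noncoding flank, SNVs by CDS,
  called-group priority on overlap), folded into minor-allele-count bins
  $1..\lfloor n/2\rfloor$, and compared by a $2 \times K$ chi-square.
* **Selection posteriors** — FUBAR-style per-site posteriors are pooled
  within called and other gene families (families of at least 10 genes;
  a family is called when any member is called), counting sites with
  $P(\text{positive}) > 0.95$ or $P(\text{constraint}) > 0.95$, and
  per-species signs are tested across species with the same exact
  binomial.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `flank_len` | 50,000 | bp | flank window per side; 10 kb behaves similarly and is exposed |
| `percentile` | 90 (95 fallback) | — | call threshold on the density distribution |
| `min_study` | 4 | genes | smallest GO test set |
| `min_annotation_fraction` | 0.20 | — | species-quality floor for GO testing |
| `family_size_threshold` / `min_family` | 10 | genes | multigene family floor |
| `terminal_frac`, `n_perm` | 0.10, 1000 | — | subtelomere geometry and permutations |
| `sv_min_len`, `sv_min_te_cov`, `sv_merge_dist` | 50 bp (strict), 0.5 (inclusive), 500 bp | — | TE-SV filter and merge |
| `posterior_cutoff` | 0.95 | — | per-site selection call |

"At least 10 genes" was preferred over the alternative reading "more
than 9 homologs excluding self" (which would be 11); the threshold is a
plain argument wherever it appears.

## Numerical choices

* **Coordinates** are 0-based half-open everywhere internally;
  converters to GFF3/VCF 1-based conventions live only in the readers
  and writers, which removes off-by-one ambiguity from every interval
  subtraction.
* **Percentile** is the linear-interpolation quantile (R type 7). Genes
  exactly at the cutoff are called, so a degenerate all-equal density
  distribution calls every gene (with a warning) rather than none.
  Genes whose flanks are entirely coding have undefined density (0/0)
  and are excluded from the distribution instead of being scored 0.
* **Permutation p-values** double the smaller tail with a +1 pseudocount
  in numerator and denominator, capped at 1, so the attainable floor is
  $2/(N+1)$. With few called genes the doubled discrete tail is
  conservative; calibration is therefore checked at chromosome scale
  (1,000 genes, 100 called), where the null rejection rate at
  $\alpha = 0.05$ sits within [0.03, 0.07].
* **Chi-square pooling**: adjacent high-frequency bins are pooled from
  the top of the folded spectrum until every expected cell reaches 5 (or
  two bins remain); columns empty in both spectra contribute nothing.
  The binning of the original analysis is not recorded anywhere, so this
  rule is stated explicitly and tested for calibration instead.
* **Strand** is carried through I/O but never used: flanks are taken on
  both sides of every gene, making the statistic strand-symmetric.
* **Fisher/BH/rank-sum/binomial** computations are delegated to the
  standard stats routines; the test suite pins them against exhaustive
  hypergeometric enumeration, the direct step-up formula, and direct
  binomial summation.

## The synthetic-data generator

No nucleotide sequence is simulated — only annotation geometry, which is
all the statistic consumes. One synthetic species consists of:

* 5 chromosomes of 40 Mb carrying 1,000 non-overlapping genes of 2 kb
  with a fixed three-exon CDS structure. Genes are placed uniformly with
  a guard band of one flank length on each side, so one gene's planted
  flank signal cannot bleed into a neighbour's flank. (The analysis code
  itself handles arbitrarily overlapping flanks; the random-instance
  oracle tests exercise exactly that.)
* Gene families with truncated power-law sizes (exponent 2, sizes
  1–30). A configurable fraction of *genes* (default 5%) belongs to
  "labile" families, chosen in size-weighted order with a best-fit last
  pick so the quota is hit within about one gene. Size weighting plants
  the multigene-family enrichment; quota exactness keeps a
  95th-percentile call set commensurate with the planted set.
* TE intervals in the four classes, planted per flank as a Poisson
  number of exponential-length fragments (class means 300–800 bp,
  RepeatMasker-fragment scale) placed without overlap, so realized flank
  coverage has expectation `te_rate_background` (default 0.05) or
  `te_rate_labile` (default 0.5) exactly.
* A GO layer (50 terms, 60% of genes annotated) with one planted term
  carried by 90% of annotated labile-family genes and 2% of others; an
  optional subtelomeric placement bias for labile genes; a 50-genome
  haploid population with TE SVs in flanks (labile flanks receive an
  `afs_skew`-weighted admixture of counts just above $n/2$ — high minor
  allele frequency after folding) and syn/nonsyn SNVs in CDS; and
  per-site posteriors with a planted excess (+0.04) of positively
  selected sites in labile families.

Every generator stream derives from one seed via fixed offsets, so each
stage is independently reproducible and a rerun is byte-identical.

What the generator does **not** emulate: sequence content (GC tracks,
when needed, are emitted directly), TE age structure and nested
insertions, linkage and demography (allele counts are drawn from the
neutral $1/i$ shape, not a coalescent), gene-family clustering error,
and GO term correlation structure (terms are flat labels; no DAG
propagation — a known divergence from ancestor-propagating enrichment
tools). Passing the planted-recovery tests therefore demonstrates that
the machinery measures what it claims under controlled geometry, not
that any particular biological genome will show these signals.

## Problem sizes used by the checks

The validation suite runs, as the package's own choice of scale: 1,000
random small-interval instances against per-base brute force; all 2×2
tables with total ≤ 12 against hypergeometric enumeration; planted
recovery and GO recovery on the default 1,000-gene species; 500 null
replicates of the subtelomere test at chromosome scale; 100 power and
200 null replicates of the spectrum comparison at n = 50 with 500
variants per group; and 20 default-size species for the cross-species
selection test. The acceptance script (`scripts/acceptance.R`)
recomputes the same quantities from scratch at a caller-supplied seed.

## Known limitations

* Flat GO semantics understate enrichment of specific terms whose
  ancestors carry the annotations.
* The `TECOV` INFO key and the BED6+1 repeat dialect are this package's
  conventions for information that standard formats do not standardise;
  both are documented in the readers.
* With heavily tied density distributions (for instance, very sparse
  repeat annotations) percentile calls saturate; the caller is warned.
* The chi-square spectrum comparison tests distribution equality, not
  specifically a high-frequency excess; the planted-skew power study
  shows it detects the excess of interest at realistic sizes.
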