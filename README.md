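# tecompart

Across eukaryotes, genes from rapidly evolving multigene families —
chemoreception, immunity, venom, pathogenicity effectors — are often
found embedded in transposable-element-rich genomic neighbourhoods.
`tecompart` implements the analysis behind that observation as a tested,
reusable R pipeline: it scores every gene by the TE density of its
noncoding flanking regions, calls the upper percentile of that
distribution as *TE-compartmentalized*, and characterises the called
set functionally and population-genetically.

For a gene $g$ with noncoding flank $F_g$ (the 50 kb windows on each
side of the gene span, minus all annotated CDS genome-wide), the core
statistic is

$$d_g = \frac{|F_g \cap \bigcup \mathrm{TE}|}{|F_g|},$$

and a gene is called when $d_g$ reaches the $\tau$-th percentile
(τ = 90, or 95) of the per-species distribution, computed for all TEs
and per class (LINE, SINE, LTR, DNA). Around that core the package
provides:

* scored-overlap resolution of repeat annotations (higher score wins,
  survivors intact);
* GO enrichment and purification of the called set (Fisher exact +
  BH-FDR, minimum 4-gene test sets, 20% annotation-quality filter,
  95th-percentile fallback) and cross-species term aggregation;
* multigene-family fold enrichment (families ≥ 10 genes);
* subtelomere permutation tests (terminal 10% of each chromosome,
  1,000 resamplings) and GC/recombination comparisons with
  cross-species binomial trend tests;
* TE-associated structural-variant filtering (length > 50 bp, TE
  coverage ≥ 0.5, 500 bp single-linkage breakpoint merging), folded
  allele-frequency spectra and a χ² spectrum comparison between called
  and other genes;
* aggregation of FUBAR-style per-site selection posteriors
  (P > 0.95 cutoffs) into per-group proportions with cross-species
  sign tests;
* a synthetic-genome generator that plants every one of these signals
  with recorded ground truth, and a one-call pipeline
  (`run_species()`) with a JSON manifest and byte-identical reruns.

Formats: GFF3 (genes/CDS), BED6+1 (repeats, RM2Bed-style with a class
column), VCF 4.x (SVs with `SVLEN`/`TECOV`, SNVs with `EFF`), bedGraph
tracks, and plain TSV for GO/family/posterior tables. All coordinates
are 0-based half-open internally.

## Worked example

Simulate one species with planted compartmentalization and recover the
plant:

```r
library(tecompart)

cfg <- simulation_config(seed = 42)          # 1,000 genes, 5% labile
sim <- simulate_species(cfg)
repeats <- resolve_repeat_overlaps(sim$repeats)
profiles <- flank_profiles(sim$ann, repeats)  # per-gene flank TE density
calls <- call_compartmentalized(profiles, te_class = "ALL",
                                percentile = 95, species_id = "demo")
calls
#> compartment_calls [demo, class ALL, tau=95]: 50 called / 1000 eligible (cutoff 0.1592)
```

The 50 called genes are exactly the planted labile set (sensitivity
1.00, precision 1.00 at this seed), and GO enrichment pins the planted
term far ahead of the background:

```r
head(go_enrichment(calls, sim$go_map), 3)
#>     term_id study_hits study_n pop_hits pop_n      fold           q direction
#>  GO:0000001         26      28       37   586 14.706564 1.19272e-32  enriched
#>  GO:0000031          4      28       30   586  2.790476 8.89027e-01  enriched
#>  GO:0000013          3      28       20   586  3.139286 8.89027e-01  enriched

multigene_fold(calls, sim$family_map)$fold
#> [1] 1.99
```

`GO:0000001` is the planted term: 26 of the 28 annotated called genes
carry it against 37 carriers genome-wide (14.7-fold enrichment,
q ≈ 10⁻³²), and called genes are twice as likely to belong to a
multigene family. The full pipeline — compartmentalization, enrichment,
chromosomal context, folded spectra, selection summary, manifest — runs
with one call:

```r
run_species(run_config(seed = 42), "out/")
```

A thin CLI wrapper (`exec/tecompart`) exposes `simulate` and `run-all`
subcommands over the same functions.

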