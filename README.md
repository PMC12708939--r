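# ribopause

Codon-resolved analysis of ribosome-profiling (Ribo-seq) data, built for
the question raised by tRNA wobble-U34 modification mutants: do ribosomes
pause when a cognate codon (AAA, GAA or CAA, decoded by
tRNA-Lys/Glu/Gln) sits in the A site, and how does translational
efficiency (TE) shift genome-wide?

The package provides, as tidyverse-style functions over tibbles:

* **Footprint placement** — 28/29-nt reads placed by unique exact match on
  spliced transcripts; P site at a fixed 12-nt (28-mers) or 13-nt
  (29-mers) offset from the 5' end; per-transcript P-site profiles and
  3-nt periodicity QC over the CDS interior.
* **Codon × site occupancy** — footprint counts per codon at the E/P/A and
  ±6-nt ribosome positions, per million library reads, grouped into
  cognate (NAA = AAA/GAA/CAA), synonymous (NAG) and control (NGA, NGG)
  codon sets, and differenced mutant − wild type — including restricted to
  a single transcript.
* **TE statistics** — median-of-ratios normalization per assay;
  `mRNA_FClog2`, `ribo_FClog2`, per-condition TE and `TE_FClog2`
  (`= ribo_FClog2 − mRNA_FClog2` exactly at zero pseudocount); a
  permutation-based significance test standardized by a trend-shrunk
  variance, with Benjamini–Hochberg correction.
* **Codon usage** — per-transcript codon frequencies (stop excluded) and
  their rank correlation with TE fold change.
* **A synthetic generator** — seeded Ribo-seq/RNA-seq simulator (two
  conditions × two replicates, A-site dwell multipliers, NB counts) that
  emits ground truth so every stage is checked by recovery, plus
  `run_simulate()` / `run_analysis()` for manifest-checked end-to-end runs.

The core quantity behind the pause analysis: ribosome density at P-site
position *p* of transcript *t* is modeled as proportional to
abundance(*t*) × dwell(codon at *p* + 3), so slowed decoding of a codon in
the A site shows up as excess normalized footprint counts attributed to
that codon group at the A site, relative to a wild-type library.

## Worked example

Simulate a wobble-U34-style experiment (mutant A-site dwell 3× on
AAA/GAA/CAA), place footprints, and difference the grouped occupancy:

```r
library(ribopause)
library(dplyr)

cfg <- sim_config(n_transcripts = 50, depth = 50000, seed = 7)
tr  <- generate_transcriptome(cfg)

occ <- lapply(c("wt", "mut"), function(cond) {
  fp <- simulate_footprints(tr, cfg, cond)
  a  <- match_footprints(fp$reads, tr)
  count_by_codon_site(a, tr, library_total = nrow(fp$reads),
                      condition = cond) |> group_counts()
})
differential_occupancy(occ[[2]], occ[[1]]) |>
  filter(site == "A") |> select(group, site, diff)
#> # A tibble: 4 × 3
#>   group site   diff
#>   <chr> <chr> <dbl>
#> 1 NAA   A     79700
#> 2 NAG   A     -2960
#> 3 NGA   A     -4280
#> 4 NGG   A     -3880
```

The cognate NAA group gains ~80,000 footprints per million at the A site
in the mutant; the synonymous and control groups sit near zero (their
slight negative values are the compositional echo of normalizing by a
library total that pausing has inflated — see the methods vignette).

TE comparison on the simulated count matrices:

```r
cm  <- simulate_counts(tr, cfg)
fit <- te_analysis(cm$rna, cm$ribo, seed = 7)
fit
#> TE comparison: mut vs wt
#>   50 genes (50 tested), 4 significant at padj < 0.05

tidy(fit) |> arrange(padj) |>
  select(gene_id, mRNA_FClog2, ribo_FClog2, TE_FClog2, padj) |> head(4)
#> # A tibble: 4 × 5
#>   gene_id mRNA_FClog2 ribo_FClog2 TE_FClog2        padj
#>   <chr>         <dbl>       <dbl>     <dbl>       <dbl>
#> 1 t0039       -0.612         2.83      3.44 0.000000133
#> 2 t0025        0.0629        2.14      2.08 0.00508
#> 3 t0003        0.144         1.88      1.73 0.0153
#> 4 t0018        0.549         2.42      1.87 0.0189
```

The significant genes are the simulated TE-ratio-4 genes: mRNA changes
near zero, ribosome occupancy up ~2 log2 units. `autoplot(fit)` draws the
MA-style plot of `TE_FClog2` against mRNA abundance;
`plot_differential_occupancy()` and `plot_psite_profile()` draw the pause
panel and the P-site plot. Codon usage does not predict the TE shift in
this design:

```r
usage_te_correlation(usage_by_group(codon_frequencies(tr)), tidy(fit),
                     group = "NAA")
#> # A tibble: 1 × 5
#>   group method coefficient pvalue     n
#>   <chr> <chr>        <dbl>  <dbl> <int>
#> 1 NAA   rank        0.0420  0.772    50
```

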