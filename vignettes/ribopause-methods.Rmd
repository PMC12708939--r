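---
title: "Codon-resolved ribosome pausing and TE analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-resolved ribosome pausing and TE analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribopause)
```

## The biological question

Loss of the wobble-U34 modifications (mcm^5 and s^2 on the first anticodon
uridine of tRNA-Lys(UUU), tRNA-Glu(UUC) and tRNA-Gln(UUG)) slows decoding of
their cognate codons AAA, GAA and CAA. In ribosome-profiling data this shows
up two ways: locally, as elevated footprint density when a cognate codon
occupies the ribosomal A site; and globally, as shifted translational
efficiency (TE) of many transcripts. `ribopause` implements the codon-level
occupancy analysis and the TE statistics needed to detect both signals, plus
a synthetic Ribo-seq/RNA-seq generator so that every stage can be validated
by recovering known ground truth.

## Coordinate frame and footprint model

All codon logic runs in spliced-transcript coordinates, 0-based and
half-open; a transcript model is a sequence plus `[cds_start, cds_end)`
with an ATG start and a stop codon at the end (relaxable). Genomic
coordinates, strand, and isoform collapsing are out of scope.

Ribosome footprints of 28 or 29 nt are placed by exact substring matching
against the whole transcript set, keeping a read only if it occurs at
exactly one (transcript, position). Multi-mapping reads are discarded —
single-base codon attribution needs unique placement — and the dropped
classes (`wrong_length`, `no_match`, `multi_match`) are reported.
Reverse-complement matching is not attempted since footprints derive from
the mRNA sense strand. The P site sits at a fixed offset from the 5' end:
12 nt for 28-mers, 13 nt for 29-mers. These offsets are treated as known
constants of the protocol; offset learning from metagene profiles is
deliberately not implemented.

Periodicity QC uses only CDS-internal P sites, from the start codon up to
the last codon before the stop. A transcript passes when the frame-0
fraction reaches a threshold, default 0.6. The threshold is a pragmatic
default: noiseless data gives exactly 1.0, and a 5' assignment jitter of
rate `r` moves roughly `r` of the mass off frame, so 0.6 tolerates severe
but not pathological jitter.

## Codon-by-site occupancy and differentials

For each accepted footprint and each configured ribosome site (default:
E, P, A and the −6/+6 nt codon positions; all codon-aligned offsets from
the P site), the codon at `p_site + offset` is looked up; positions outside
the CDS or out of frame contribute nothing at that site, while the same
footprint still counts at its addressable sites, so footprints near the
start codon are not lost entirely. Counts are kept per codon and site, both
raw and per million library reads, and summed over codon groups (default:
cognate NAA = AAA/GAA/CAA, synonymous NAG, and unrelated NGA/NGG controls).
The mutant-versus-wild-type comparison is the entry-wise difference of
normalized tables, which is antisymmetric under condition swap, and can be
restricted to a single transcript while keeping whole-library
normalization. Replicates are normalized per library and then summed within
a condition by default (pooling before normalization is available as an
option); the per-replicate tables remain inspectable.

One caveat matters when pausing is widespread. Normalizing by the total
library read count makes the per-million scale *compositional*: if A-site
dwell triples at ~5% of positions genome-wide, the mutant library total
inflates by ~10%, and every *other* A-site group is depressed by that
factor after normalization. In the default simulation this produces a
systematic negative differential of a few percent for the control groups at
the A site (several binomial standard errors at depth 2×10^5), while
control entries at non-A sites stay within noise because codon identity at
one site is nearly independent of the A-site codon. This is a property of
total-count normalization itself, not an artifact of the implementation;
when interpreting real data, a strong cognate A-site gain should be read
jointly with the mild compensatory depression of everything else.

## The synthetic generator

The generator emulates the data structure the analysis assumes: two
conditions × two biological replicates, 28/29-nt footprints in equal
proportion, NB-distributed counts. Defaults were chosen once as a compact,
realistic desk-scale experiment and are not tuned per analysis:

* 200 transcripts, CDS lengths uniform on 300–900 nt (multiples of 3),
  18-nt random UTR padding so boundary P sites still fit a full read;
* uniform sense-codon weights; log-normal transcript abundances
  (sdlog 1) shared between conditions so density differences are purely
  dwell-driven;
* ribosome density at P-site `p` proportional to
  `abundance × dwell(codon at p+3)`; mutant dwell 3× on AAA/GAA/CAA, a
  free parameter of the recovery experiment rather than an estimate of the
  biology, which the source literature does not quantify;
* 2×10^5 footprints per condition, split evenly across replicates;
  5' jitter of ±1 nt at rate 0.05, the minimal perturbation that degrades
  without destroying periodicity;
* counts: RNA ~ NB(mean 200 × abundance, dispersion 0.05) with a tighter
  abundance spread (sdlog 0.5) so per-gene counts stay informative at desk
  scale; ribo means multiplied by the gene's true TE ratio (10% of genes
  at ratio 4 by default).

Footprints whose read window would leave the transcript are excluded from
the sampling support rather than clipped, because the analysis accepts only
full-length exact matches. Reads are exact substrings of their transcript
whenever jitter is off, and every read has exactly one ground-truth row.
What the generator does *not* emulate: rRNA/tRNA contamination, adapters,
sequencing errors, alignment ambiguity, UTR ribosome occupancy, and
codon-usage biases of real genomes — so green tests show the machinery is
correct and calibrated under the stated statistical structure, not that
real libraries are this clean.

## TE statistics

Counts are normalized per assay by median-of-ratios size factors (RNA and
Ribo library compositions differ, so the factors are computed separately).
Fold changes use a pseudocount (default 1) so zero-count genes remain
defined; with pseudocount 0 and positive counts the identity
`TE_FClog2 = ribo_FClog2 − mRNA_FClog2` is exact. Genes with mean
normalized count below 1 in both assays are reported untested.

Significance testing with two replicates per condition cannot rest on
per-gene variances alone. The statistic is the difference of replicate-mean
log2 TE between conditions, standardized by a pooled within-condition
variance shrunk (prior weight 20 vs the 2 per-gene degrees of freedom)
toward a variance trend over mRNA-abundance bins. Its null distribution is
built by recomputing the statistic under every balanced reassignment of
condition labels to sample columns and pooling across genes —
standardization is what makes the null statistics exchangeable across
genes — with a two-sided normal tail taking over where the permutation
resolution runs out (fewer than 10 pooled exceedances). Two robustness
choices, applied identically to observed and permuted statistics, keep the
calibration honest when a minority of genes genuinely changes:

1. the per-gene difference is centered at a MAD-trimmed iterated median,
   because size-factor normalization absorbs part of a one-directional TE
   shift into the factors, displacing every null gene by a constant that a
   plain median under-corrects;
2. the variance trend uses the median bin variance rescaled by the
   chi-square consistency factor rather than the bin mean, because under
   label permutation a changed gene's within-group variance absorbs its
   whole condition effect and a mean trend would roughly double the
   permuted null scale.

On synthetic truth (2,000 genes, 10% at TE ratio 4, NB dispersion 0.05)
this test has empirical type-I error near 0.05, realized false-discovery
proportion near the nominal 5–10% at BH `padj < 0.05`, and recovers the
true log2 effect of 2 to within ~0.1 (the residual is pseudocount and
normalization shrinkage). Multiple testing uses Benjamini–Hochberg step-up
adjustment over the tested genes. FDR control is approximate: in strong,
one-sided signal regimes the pooled permutation null is slightly light and
the realized FDP can modestly exceed the nominal level.

Codon-usage analysis counts CDS codons excluding the stop (decoded by
release factors, not tRNAs) and correlates group usage — by default the
summed frequency of a codon group, the natural reading of "combined
usage" — with `TE_FClog2`, rank-based by default since no functional form
is assumed.

## Numerical and design notes

* Matching uses an Aho–Corasick dictionary (`Biostrings::PDict`) against
  the transcripts concatenated with 30-N separators, which no 28/29-nt
  ACGT read can span; an exhaustive k-mer enumeration serves as the test
  oracle.
* The site list is configuration-driven; the default holds the five
  positions named in the field's pause analyses (E, P, A, ±6 nt), and
  further codon-aligned positions can be added without code changes.
* Stop codons are counted where addressable (A/+6 near the CDS end) but
  excluded from the default groups.
* Sequences with ambiguity letters are rejected in strict mode and masked
  from codon addressing otherwise; they can never match an exact read.
* All generators and the pipeline are deterministic given a seed; sub-seeds
  for independent stages are derived by fixed offsets, and manifests with
  MD5 checksums make byte-level reproducibility checkable.
* Problem sizes in the test suite (10–200 transcripts, 10^3–2×10^5 reads,
  2,000 genes × up to 10 simulation seeds) were chosen so the full suite
  runs in minutes on one CPU while keeping Monte-Carlo error well inside
  the asserted tolerances.

## Known limitations

* Only 28/29-nt footprints with fixed offsets are modeled; other lengths
  are dropped rather than offset-corrected.
* The TE test is a calibrated permutation hybrid, not a negative-binomial
  GLM; it answers "is this gene's TE shift exceptional given genes of
  similar abundance", not "what is the NB-likelihood of these counts".
* Compositional normalization effects (above) are reported, not corrected;
  no attempt is made to re-anchor differentials on an invariant codon set.
* Correlation of usage with TE is descriptive; no tRNA-abundance weighting
  or codon-adaptation modeling is attempted.
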