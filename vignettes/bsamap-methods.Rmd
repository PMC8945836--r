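---
title: "Methods and modeling choices in bsamap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modeling choices in bsamap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsamap)
```

# The problem

A recessive-to-incompletely-dominant EMS mutation is segregating in an F2
population of a selfing crop. The phenotype (here, leaf chlorophyll measured
as a SPAD value) separates the three genotype classes: homozygous mutants read
below 10, heterozygotes between 10 and 20, wild types above 20. The goal is
to go from two pooled-sequencing libraries of phenotype-extreme bulks to a
single candidate gene and a diagnostic marker. `bsamap` implements each stage
of that chain and a forward simulator that makes the chain testable end to
end.

# The F2 simulator

`simulate_f2()` builds each individual as the union of two recombinant
gametes. Crossovers are drawn as a Poisson process on the genetic (cM) axis —
the Haldane model, no interference — with the parental phase at the left map
end Bernoulli(1/2). This choice is deliberately the simplest standard model:
the recombinant fraction between loci d cM apart has the closed form
r = (1 − e^(−2d/100))/2, which the test suite verifies directly on simulated
gametes, and map distances enter only through this one function. Gamete
breakpoints are stored on each individual, so the same simulated plants can
be genotyped later at markers that did not exist when the population was
simulated (`genotype_at()`) — exactly what iterative fine mapping needs.

The SPAD phenotype is the class mean of the causal-locus dosage (defaults
30/15/5 for dosage 0/1/2) plus Gaussian noise (sigma = 2), truncated at zero.
The class means straddle the 10/20 diagnostic thresholds by 2.5 sigma, so a
single reading misclassifies a heterozygote as a mutant with probability
about 0.6%. That is negligible for bulking 25 plants but not for screening
~1,000 heterozygotes during fine mapping; real phenotyping practice reads the
SPAD meter several times per leaf and shows essentially no misclassification
(perfect marker cosegregation in hundreds of plants). `simulate_f2()` models
this with `n_readings`: the recorded SPAD is the mean of n independent
readings (the pipeline default is 3, giving an effective SD of
sigma/sqrt(3) and misclassification around 10^-5). The per-reading sigma
stays at 2 and remains tunable for robustness experiments.

Bulks follow the published design: the G bulk samples only wild-type-class
plants (SPAD > 20) and the Y bulk only mutant-class plants (SPAD < 10), 25
each; heterozygotes enter neither bulk. Because the trait is incompletely
dominant and both bulk classes are homozygous, the expected SNP-index at
the causal site is 1 in Y and 0 in G (a dominant-trait design that pools all
non-mutant plants would instead give 1/3 in G; the simulator can represent
that only by explicit construction, and the tests cover the arithmetic).

Pooled sequencing is modeled per site as total depth ~ Poisson(coverage)
(defaults 39.82x for G, 33.75x for Y) and mutant-allele depth ~
Binomial(depth, p) with p the true bulk allele frequency. Read errors,
mapping bias and depth overdispersion are *not* modeled, so a green
calibration test establishes that the statistics are correct under binomial
sampling, not that real libraries are this clean. The default SNP panel is
one site per 10 kb — the window step — so every window holds sites.

# The scan statistic and its null band

Per-site SNP-index is the alt (mutant-parent) read fraction; sites where
either pool is below `min_depth` (default 7, a conventional QTL-seq floor —
the original pipelines filter at the variant-caller level with unpublished
settings) are excluded. Windows are 1-based half-open, anchored at 1, width
1 Mb, step 10 kb; window values are unweighted means over member sites
(matching the "average index per window" convention), and trailing partial
windows are kept but flagged.

The confidence band is a Monte-Carlo null conditional on depth: resample two
bulks of 25 F2 plants (each plant's dosage 0/1/2 with probability 1/4, 1/2,
1/4 — equivalently Binomial(50, 1/2) mutant alleles per bulk), thin to the
pool depths binomially, and take empirical alpha/2 and 1−alpha/2 quantiles of
delta over 10,000 replicates. Bands are computed once per unique depth pair
and broadcast. The window band is the mean of the member sites' bands,
mirroring the averaging applied to the observed statistic; this is
conservative for a window mean of correlated sites but is the convention that
matches windowed QTL-seq practice. Windows with delta above the upper band
form maximal runs, merged when their genomic spans overlap; no-data windows
break runs.

Two things a green scan test does not establish: the published band software
is not described in detail, so this band is "standard QTL-seq practice"
rather than a reimplementation of a specific tool; and on a single simulated
chromosome *everything* is linked to the causal locus, so called regions are
legitimately broad (delta = 1 − 2r stays positive across the chromosome) and
the precision of localization comes from the fine-mapping stage, not the
scan.

# Fine mapping

Recombinant screening uses only mutant-class plants: a recombinant at a
marker is a selected plant calling A or H there; NN calls contribute nothing
but are tallied. `narrow_interval()` reports the cosegregating (zero-
recombinant) markers and the nearest flanking markers with recombinants on
each side. Boundary choices: SPAD values of exactly 10 or 20 classify as HET
(the published thresholds leave the endpoints open, and the conservative
reading keeps borderline plants out of both selected classes); with no
cosegregating marker the function returns the adjacent pair with minimal
counts plus a warning; with every marker cosegregating it errors ("add
markers").

The pipeline's fine-mapping stage is iterative, as in practice: up to eight
rounds of fresh nine-marker ladders inside the shrinking interval, genotyping
the same selected plants each round. Two robustness rules matter here and are
pipeline-level policy (the `narrow_interval()` contract is unchanged):

* a selected plant with no B call anywhere in the round's panel is treated as
  a phenotyping error, not a recombinant (a heterozygote cannot be
  distinguished from a plant whose breakpoints lie outside the panel, and
  with confirmed phenotyping the former dominates), and
* when no marker cosegregates, the next interval brackets *all* markers tied
  at the minimal recombinant count with one neighbour on each side. Late
  rounds leave a handful of recombinants, counts tie across several markers,
  and committing to a single tied marker demonstrably biases the interval off
  the causal locus.

# Candidate-gene triage

`annotate_variant()` works in CDS coordinates (1-based; minus-strand genes
are reverse-complemented into CDS space, `genomic_to_cds()` handles the
mapping). SNVs translate ref and alt codons under the standard genetic code;
length-changing variants are frameshift when the length difference is not a
multiple of 3. EMS consistency is purely "is a single-base substitution":
EMS produces predominantly G/C→A/T transitions, but the published filter
excludes indels rather than transversions, and the implementation follows
that. The cascade applies four per-gene predicates in a fixed order (exonic
variant; some EMS-consistent variant; some non-synonymous variant; expressed
in at least one line) and logs every removal; because each step is a pure
per-gene predicate the final set is order-independent, which the tests assert
against an independent set-algebra recomputation. Homolog deduplication
(58 → 56 genes in the motivating interval) is input metadata, not computed.

The gene-table fixture realizes the motivating interval's census — 56 genes,
15 with exonic variants: 2 frameshift deletions, 3 nonsynonymous (2 expressed
in neither line), 10 synonymous — with synthetic identifiers and sequences,
so triage retains exactly one gene. In the pipeline the fixture is laid over
the narrowed interval and the designated candidate is the gene covering the
simulated causal position; the recovery test therefore checks that scan +
narrowing put the causal position inside the interval and that the cascade
logic isolates the right gene, not that gene annotation itself was inferred
from sequence.

# Expression stages

The differential-expression stage is an explicit stand-in for a negative-
binomial tool: median-of-ratios size factors, Welch t on log2(normalized + 1),
Benjamini–Hochberg adjustment, and the published DEG rule (FDR < 0.05 and
|log2FC| >= 1). The contribution being exercised is the thresholding and
up/down accounting, not dispersion modeling, so published DEG counts from
real libraries are out of scope; the tests calibrate the null rate and the
power on spiked counts at realistic library depth (~10^6). Percentages are
reported to 2 decimals and are null (not 0/0) when there are no DEGs.
Relative expression is textbook 2^−ΔΔCt on replicate-mean Cts.

# Marker validation

Fluorescence genotyping uses rectangular gating on FAM/HEX intensities with
ties counting as detected — cluster plots in practice are read visually, and
threshold gating keeps the operation deterministic and testable; the
simulator generates well-separated clusters. Cosegregation maps AA↔WT,
AB↔HET, BB↔MUT, excludes NN calls from concordance but counts them, and the
1:2:1 ratio is tested by Pearson chi-square with df = 2.

# Numerical and reproducibility choices

All randomness flows through per-operation integer seeds (`withr`-scoped, so
callers' RNG streams are untouched); the pipeline derives stage seeds from
one master seed by fixed offsets and records them in its report, making
reruns byte-identical. Band quantiles use R's default empirical quantile;
with 10,000 replicates and depths around 40 the delta distribution is fine-
grained enough that the exclusion rate sits within a percent of nominal.
Window prefix-sums make the scan O(sites + windows) and are tested for exact
equality against a brute-force recomputation. BED output converts to 0-based
half-open coordinates in the writer only; everything internal is 1-based.

# Known limitations

* One chromosome, one causal locus; no unlinked genome against which the scan
  would show its full contrast.
* Binomial/Poisson sequencing only — no error reads, no overdispersion, no
  mapping artifacts; `min_depth` and the band cannot be tuned against real
  noise here.
* The null band is a standard Monte-Carlo construction, not a reimplementation
  of any specific published tool; regional mean deltas from real data are not
  comparable targets.
* The DE stage deliberately replaces negative-binomial inference; its results
  on real counts will differ from DESeq-family tools.
* Adapter scanning is ungapped (read-through adapters are ungapped in
  practice) and duplicate removal is exact sequence-pair identity, i.e.
  library-level pre-alignment deduplication.
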