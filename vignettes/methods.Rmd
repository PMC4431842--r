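---
title: "Diagnostic SNP mining, introgression masking and admixture profiling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnostic SNP mining, introgression masking and admixture profiling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxadiag)
```

## The problem

Cultivated citrus — and several other vegetatively propagated crops —
descends from a small number of strongly differentiated ancestral taxa
(here labelled mandarin, pummelo, citron and micrantha after the four
citrus gene pools *C. reticulata*, *C. maxima*, *C. medica* and
*C. micrantha*). Hybridisation followed by clonal propagation froze admixed,
highly heterozygous genomes, so the ancestry of any accession can be read
from markers whose alleles are private to one ancestral taxon. This package
mines such species-diagnostic SNPs from reference panels of the ancestral
taxa, protects the mining step against interspecific introgression hiding
inside those panels, and profiles arbitrary accessions against the
resulting marker set.

## The differentiation statistic

For a biallelic marker with alternate-allele frequency `p`, the expected
heterozygosity is `He(p) = 1 − p² − (1 − p)² = 2p(1 − p)`. For focal taxon
*i* we form two subpopulations: the focal taxon itself (frequency `p_Ti`)
and the pooled rest, whose frequency `p_T−i` is the **unweighted mean** of
the non-focal taxon frequencies. The total population weights the two
subpopulations equally, `p_tot = (p_Ti + p_T−i)/2`, and

```
G_ST(i) = [He(p_tot) − (He(p_Ti) + He(p_T−i))/2] / He(p_tot).
```

Because `He` is strictly concave, Jensen's inequality guarantees
`G_ST ∈ [0, 1]` for any frequency configuration — a property the test suite
verifies over 10⁵ random four-taxon draws and an exhaustive 11⁴ grid
against a literal term-by-term evaluation of the formula.

Two analytic anchors pin the weighting down. A marker fixed in the focal
taxon and absent elsewhere gives exactly 1. A taxon represented by a single
heterozygous accession (`p = 0.5`) against three taxa fixed for the shared
allele gives exactly 1/3 — the signature value for private heterozygous
variation. Weighting all four taxa equally in the total (instead of the two
subpopulations) would drive the second case negative, which contradicts the
interpretation of `G_ST` as a proportion of diversity among subpopulations;
hence the equal two-subpopulation weighting used here.

No small-sample correction enters the `G_ST` decomposition; the unbiased
`2n/(2n−1)` correction is applied only to reported `He` in the diversity
summaries, where it is the conventional estimator.

## Marker classification and panel QC

Each marker receives exactly one class from its per-taxon `G_ST` profile:

* `DIAGNOSTIC` — highest `G_ST` strictly above `diagThreshold`
  (default 0.9).
* `TAXON_SPECIFIC_POLYMORPHISM` — highest `G_ST` at most `specificMaxGst`
  (default 0.5, inclusive) with the variant segregating in exactly one
  taxon while all others are fixed for the same shared allele.
* `PARTIAL` — between the two thresholds.
* `ND` — the remainder: similar diversity in two or more taxa, or
  monomorphic. Monomorphic markers get `G_ST = 0` with a flag rather than
  an undefined value, keeping tables rectangular; the flag bars them from
  panels.

The boundary conventions (strict `>` for diagnostic, inclusive `≤` for the
specific rule) are configurable; the defaults follow the usual phrasing of
the selection rule. Panel construction groups diagnostic and taxon-specific
markers per taxon and discards any marker whose diagnostic allele is
observed at frequency ≥ `qcThreshold` (default 0.1) in a second taxon — a
marker sharing its polymorphism between two taxa cannot trace a single
ancestry. The 0.1 default tolerates genotyping error and rare gene flow
while rejecting genuinely shared polymorphism; it is a design choice, not a
measured constant.

Assay development imposes one more filter: competitive allele-specific PCR
needs ~50 nt of clean flanking sequence, so `proximityFilter()` rejects
candidates with any other SNP or indel within `window` bp (default 50) on
either side, applied symmetrically.

## Introgression masking

A reference accession carrying a donor haplotype over a gene fragment
(interspecific heterozygosity) contaminates its taxon's frequency
estimates and depresses `G_ST` for every diagnostic marker in that
fragment. The original screen for this pattern was visual — ordination of
accessions per fragment plus per-accession heterozygosity. The package
automates it: accession × fragment pairs are flagged when

* fragment `Ho ≥ hetThreshold` (default 0.3), and
* the accession is heterozygous at ≥ `minDifferentialHets` (default 2)
  markers in the fragment whose provisional between-taxon frequency
  difference is ≥ `differentialDelta` (default 0.8).

Pure reference accessions in strongly differentiated taxa show fragment
`Ho` well below 0.1 while donor-heterozygous fragments sit near 0.5, so 0.3
separates the two modes with margin. Requiring two differential
heterozygous sites guards against single genotyping errors. The
differential threshold is 0.8 rather than a stricter 0.9 because the
provisional frequencies are computed **before** masking: the very
introgressions being detected dilute the focal-taxon frequency (three
donor-heterozygous accessions among eleven references pull an observed
fixed-difference contrast down to ≈ 0.86), and a 0.9 cutoff would blind the
screen precisely in the fragments that need flagging. 0.8 tolerates about
20% contaminated gene copies while remaining far above within-taxon
frequency differentials. PCoA output remains available for visual audit but
carries no decision weight.

Masking sets flagged calls to missing — it only ever removes data — and a
single re-estimation pass is the default (a `passes` argument allows
iteration to a fixed point). Markers left without callable copies in some
taxon are dropped from the post panel with a logged reason. For markers
whose diagnostic allele is a true fixed difference, masking the
introgressed accessions can only concentrate the focal frequency, so
per-marker `G_ST` never decreases; the suite asserts this on simulated
truth.

## Admixture profiling

For each taxon's panel markers with a non-missing call, an accession's
profile is the fraction carrying two (`FHom`), one (`FHet`) or zero
(`FAbs`) copies of the diagnostic allele; the three always sum to one.
The contribution estimate is the per-taxon mean diagnostic-allele dosage
share, `s_t = FHom_t + FHet_t/2`, normalised across taxa. Normalising per
taxon **before** the cross-taxon division prevents unequal panel sizes from
biasing contributions. The estimator is deterministic, linkage-free and
unbiased for pedigree admixture when panel markers are true fixed
differences: an F1 yields `FHet = 1` on both parental panels and exactly
0.5/0.5 contributions; a first backcross yields 0.75/0.25 in expectation,
with Mendelian sampling noise of order `0.5/√F` for `F` independently
transmitted fragments. Missing calls are excluded from denominators rather
than imputed, preserving frequency semantics. This direct estimator stands
in deliberately for model-based clustering (e.g. Structure's MCMC linkage
model), which is out of scope; the bundled `citrusWgsComparison()` table
(six varieties, WGS-derived *C. maxima* proportions from Wu et al. 2014
against marker-based estimates) illustrates the level of agreement such
dosage-share estimates achieve (Pearson r ≈ 0.987).

## The simulator and what it does (not) emulate

`scenarioConfig()` defaults emulate the reference study design: four taxa
with 11/9/5/1 reference accessions, nine chromosomes carrying 54 gene
fragments of 500 bp with ~18 SNPs each (≈ 37 SNP/kb), and a marker-class
mix — 6.5% fixed differences per taxon, 12% taxon-private polymorphism per
taxon, 14% shared — that reproduces the observed proportions of diagnostic
(~26%) and taxon-private (~48%) markers. Within-taxon minor allele
frequencies follow `Beta(0.5, 3)`, a skewed site-frequency spectrum.
References are drawn under Hardy–Weinberg within taxon, independent across
markers. Gametes transmit one parental haplotype per fragment (free
recombination between fragments, none within — at amplicon scale
intra-fragment recombination is negligible), and introgression is injected
as one resident plus one donor haplotype over selected fragments, the
signature the masking screen targets. A single seed drives the run, with
per-stage sub-seeds derived deterministically so stages can be regenerated
independently; identical configs give identical outputs.

The simulator specifies frequencies rather than evolving them: there is no
coalescent history, no linkage within fragments beyond co-transmission, no
genotyping-error model, and reference taxa are ideal random-mating pools.
Passing tests therefore demonstrate correctness of the estimators under
the model's assumptions, not robustness to assay artefacts or population
structure within taxa.

## Validation scenarios: sizes and choices

Problem sizes were chosen so the full suite runs in well under a minute per
scenario while retaining statistical power:

* **Mining recovery** — 4 taxa × 10 accessions, 1,026 markers, 10% fixed
  differences per taxon over an *undifferentiated* shared-polymorphism
  background. Background classes able to reach sample fixation in ten
  accessions (taxon-private or strongly structured polymorphism) are
  excluded on purpose: a marker fixed in the observed sample is
  operationally diagnostic there, so demanding exact recovery of the
  planted truth would be ill-posed under such backgrounds.
* **Masking** — the study-scale reference set (11/9/5/1) on a denser,
  strongly differentiated fragment panel (54 fragments × 50 markers,
  60% fixed differences, 34% structured shared polymorphism) so that
  donor-heterozygous fragments show `Ho ≈ 0.5`, as observed in real
  introgressed amplicons. Under this design a power calculation puts the
  per-fragment miss probability of the `Ho ≥ 0.3` screen below 1% and the
  expected false-flag count near zero, giving flag precision/recall ≥ 0.95
  with comfortable margin. Four of the eleven mandarin references receive
  pummelo introgression on 20% of fragments.
* **Profiling** — fixed-difference-only panels (≥ 100 markers/taxon) with
  50 replicate pedigrees per genome fraction in
  {0, 0.125, 0.25, 0.5, 0.75, 1}; mean absolute contribution error is
  ~0.02, dominated by Mendelian transmission noise across 54 fragments.

## Numerical and interface conventions

Coordinates: VCF and marker tables are 1-based; BED fragments are 0-based
half-open and converted once at load. Genotypes are unphased unordered
pairs (`0/1` ≡ `1|0`), stored as alternate-allele dosage; the pair view is
derivable and round-trips exactly. Accepted missing encodings: `./.`,
`NN`, `NA`, `-`; heterozygotes may be two-letter strings or IUPAC codes.
Result TSVs write reals to 15 significant digits (round-trip ≥ 12), write
atomically (temp file, then rename), and encode missing as `NA`.
Ordination axes fix their sign so the first nonzero loading is positive,
making outputs deterministic. Multilocus genotype identity treats missing
calls as wildcards (a strict mode is available), matching how clonal groups
with patchy data are collapsed. Wright's fixation index is reported as
`Fw = 1 − Ho/He_unbiased`, zero at Hardy–Weinberg; Weir–Cockerham's θ uses
the standard diploid variance-components estimator with per-marker sample
sizes, and the multilocus value pools components before the ratio.

## Known limitations

The flagging screen needs several markers per fragment; with fewer than ~5
informative SNPs the binomial noise in fragment `Ho` overwhelms the
threshold. Contributions from the dosage-share estimator ignore linkage
between fragments and underestimate uncertainty for small panels. The
biallelic model rejects multi-allelic records outright rather than
splitting them. Taxa represented by a single reference accession (as one
taxon here is) contribute maximally noisy frequencies; their taxon-specific
polymorphism class is then undetectable by construction, and diagnostic
calls lean entirely on the other taxa being fixed.
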