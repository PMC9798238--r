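---
title: "Bin-map construction and QTL mapping in selfed RIL populations: models and methods"
author: "binQTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bin-map construction and QTL mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binQTL)
```

binQTL implements a complete genotyping-by-sequencing (GBS) QTL-mapping
workflow for recombinant inbred line (RIL) populations from a biparental
cross, together with a meiosis-level simulator that generates the inputs
the workflow expects. This vignette describes the models behind each
stage, the tunable parameters and their defaults, the numerical choices,
and what the simulation-based validation does and does not demonstrate.

## The synthetic RIL population

GBS genotypes are sparse and error-prone, and raw sequencing data for a
real mapping population are far too large for routine testing. The
simulator therefore generates populations with the statistical structure
the downstream methods assume, at the dimensions of a maize RIL study
(275 lines, 10 chromosomes, ~2.06 Gb and ~2,181 cM; the preset
`maizeGenomeTemplate()` carries these numbers).

* **Meiosis.** Each meiosis draws a Poisson number of crossovers with
  mean equal to the chromosome's genetic length in Morgans, placed
  uniformly on the cM scale — a no-interference (Haldane) crossover
  process. Interference matters little after the six-plus meioses that
  separate two RILs, and the map function used downstream (Kosambi) is a
  marginal transform, not a crossover model.
* **Descent.** Lines descend from the F1 by single-seed descent for
  `selfingGenerations` generations (default 6), so residual
  heterozygosity (~`2^-6` of the genome) is retained and exercises the
  heterozygote handling of every downstream stage. `forceHomozygous`
  resolves leftover heterozygous segments for fully inbred scenarios.
* **Genotype observation.** SNP calls are read off the final diploid
  mosaic (`A`/`B`/`H`), then corrupted: each call flips to one of the
  other two codes with probability `errorRate` (default 0.01) and is
  masked to `N` with probability `missingRate` (default 0.05). This
  emulates the GBS genotype-call error process; read depths and
  restriction-site biology are deliberately not modelled — the pipeline
  starts from genotype calls.
* **Phenotypes.** A line's genetic value is the sum of additive QTL
  effects (score +1/0/-1 for A/H/B) plus an optional polygenic normal
  deviate; year, location, genotype-by-year, genotype-by-location,
  genotype-by-year-by-location, replicate and residual effects are
  independent normals. The default design is 2 years x 2 locations x 3
  replicates; `paperEnvironments()` provides the unbalanced layout of a
  two-year/one-extra-location trial. `paperTraitArchitecture()` holds
  five moderate protein-content QTLs and solves the residual variance
  analytically so the entry-mean heritability equals 0.81.

What passing tests on these simulations shows: the pipeline's inference
is correct when its assumptions hold. What they do not show: robustness
to depth-dependent allele dropout, segregation distortion hotspots,
reference bias, or mis-anchored markers, none of which the generator
produces.

## Genotype quality control

`selectParentalInformative()` keeps SNPs where both parents are
homozygous for different alleles (aa x bb); `encodeByParent()` recodes
progeny calls by parental origin and masks alleles carried by neither
parent (abnormal bases) to `N`. `filterSegregation()` tests A:B counts
against the 1:1 RIL expectation by a 1-df chi-square (heterozygous and
missing calls excluded, consistent with a near-homozygous population;
Yates correction available but off by default since counts are large)
and removes SNPs with p below `alpha = 0.001`. `filterCallRate()` drops
SNPs below a non-missing fraction of 0.2, then lines below 0.2, and
iterates this fixed order to a fixpoint so the filter is idempotent.
`filterScaffolds()` removes markers on unanchored sequence names, which
cannot be ordered on the physical map.

## Sliding-window bin calling

The window rule is the core smoothing device: a 15-SNP window slides one
SNP at a time over a line's non-missing calls; a window is called `A`
(or `B`) when at least 11 of its 15 sites come from that parent, and `H`
otherwise. Missing calls are skipped so every window holds 15 informative
sites. Runs of equal window calls merge into blocks; the junction between
two blocks is a recombination breakpoint localized to the interval
between the last SNP supporting the left genotype and the first SNP
supporting the right genotype.

Two details deserve emphasis:

* **Phantom heterozygous runs.** A window sliding across a clean A-to-B
  crossover must pass through compositions (10/5 ... 5/10) in which
  neither parent reaches 11/15, emitting a short `H` run at every
  crossover. Counting its two flanks as breakpoints would double the
  breakpoint count and double the apparent map expansion. These runs are
  identified by their empty physical cover (their flanking breakpoint
  intervals overlap) and collapsed — into a single breakpoint when the
  outer blocks differ, or into a merged block when an error cluster
  produced an `H` island inside one parental segment. Genuine
  heterozygous segments have positive cover and are kept, so A-H and H-B
  transitions still count as breakpoints.
* **Corroborated evidence.** With a 1% error rate an isolated miscall
  that mimics the other parent would otherwise truncate the breakpoint
  interval and exclude the true crossover; a boundary SNP must therefore
  agree with its neighbour in the evidence subsequence.

Bins follow the population-breakpoint convention: the chromosome is cut
into 100-kb grid cells; every cell containing at least one breakpoint
midpoint (any line) starts a new bin, and a bin is the maximal run of
cells to the next boundary (0-based half-open internally, 1-based
inclusive in reports). Each line's bin genotype is the covering block
call; bins overlapping the line's own breakpoint interval fall back to
the majority of the raw SNP calls inside the bin, then to the flanking
blocks' shared call, then to `N`. Lines with fewer than 15 informative
calls on a chromosome are genotyped by raw majority throughout.

Under the study conditions (1% error, 5% missingness, GBS density of
~33 SNPs/Mb) this recovers over 99.8% of bin genotypes and ~96-98% of
true crossovers with the breakpoint interval containing the true
position; at several-fold sparser SNP density, parental segments shorter
than the 11-SNP majority span become intrinsically invisible to the
window rule and recovery drops — a property of the method, not of the
implementation.

## The genetic map

Marker order is taken from physical position; no de novo ordering is
attempted. For adjacent bins the observed recombination frequency is the
mean pairwise discordance of the genotype scores with heterozygote pairs
counted one half (`|x1 - x2| / 2` on the +1/0/-1 scale). This weighting
is not ad hoc: it is the natural expectation of the two-locus selfing
chain, and excluding heterozygotes instead silently swallows the
junctions flanking residual heterozygous segments.

The observed frequency is converted to a meiotic fraction by numerically
inverting the exact expectation of the 10-state two-locus diploid
selfing Markov chain at the population's generation
(`rilFiniteInverse(R, generations)`, default 6). At fixation this
reduces to the classical Haldane-Waddington correction
`R = 2r / (1 + 2r)` (`generations = Inf`), but applying the fixation
formula to an F7 population underestimates map length by roughly 15-20%
— the chain has not yet accumulated its asymptotic recombination — which
is why the generation-aware inverse is the default. Distances are
Kosambi, `d = 25 ln((1+2r)/(1-2r))`. Adjacent bins with no homozygous
informative pair are merged rather than assigned an arbitrary distance.
With these choices an error-free simulation at GBS density recovers
~94-99% of the simulated map length; genotyping error inflates the map,
which is monotone and covered by tests.

## Composite interval mapping

Genotype probabilities at evaluation positions (all bin markers plus a
1-cM pseudomarker grid) condition on the nearest informative flanking
calls, treating the RIL genome as a two-state A/B Markov chain whose
step probabilities come from the same generation-aware transform used by
the map builder. Observed heterozygotes are degenerate `H` at their own
marker and treated as missing when conditioning elsewhere; their
transmission model over multiple generations is not identified from
two-state data, and at F7 they are ~1.5% of calls.

The scan is Haley-Knott regression of the phenotype on the expected
genotype score `P(A) - P(B)`, with forward-selected marker cofactors
(partial-F entry at p < 0.05, at most 5) excluded within 10 cM of the
test position; `LOD = (n/2) log10(RSS0/RSS1)` with the null model
holding the intercept and retained cofactors. The dominance column
`P(H)` is available (`dominance = TRUE`) but off by default: with ~1.5%
residual heterozygotes it is a sparse per-marker indicator whose extra
degree of freedom inflates the genome-wide null maximum from ~3.3 to
~4.4, and a selfed-RIL cross is conventionally scanned with the 1-df
additive model. EM-based mixture likelihood was not used; the
no-cofactor scan is verified against an independent per-position
least-squares oracle at 1e-10.

Thresholds are empirical 95th percentiles (type-7) of the genome-wide
maximum LOD over 1,000 phenotype permutations, with cofactors held fixed
by default (`policy = "reselect"` re-runs selection per permutation).
Each permutation draws its index vector from a substream derived from
the single seed, so results do not depend on execution order. At the
study dimensions the threshold lands at ~3.3-3.5, consistent with a
reported genome-wide threshold of 3.0 at alpha 0.05.

Support intervals take the contiguous run of evaluation points within
`drop = 1.5` LOD of the peak and extend one evaluation point beyond on
each side (the usual grid convention); physical bounds span the full
flanking bin markers, since a bin marker is an interval rather than a
point. Additive effects are half the difference between the
probability-weighted class means (positive = the female-parent allele
increases the trait); per-QTL PVE is the drop-one R-squared difference
in the joint additive model over all retained peaks (peaks closer than
1 cM are merged first), and `100 (1 - 10^(-2 LOD / n))` for a lone peak.
Peak search masks each found peak's support interval plus the cofactor
exclusion window, because cofactors entering and leaving the model
create steps in the profile that would otherwise split one locus.

Calibration, measured over ten independent population simulations so the
result is not conditional on one map's local marker layout: genome-wide
type-I error 4.0-4.5% at nominal 5%, power 97-99% for a 10%-PVE QTL at
n = 275, and 1.5-LOD interval coverage 93-95% among detections. The
problem sizes used throughout the validation suite — 275 lines at 300
SNPs per chromosome for threshold work, 2 x 2,000 SNPs x 200 lines for
bin fidelity, chromosomes 9-10 at their published SNP counts for map
recovery, 10 x (40 + 20) replicates for calibration, 50 replicates for
heritability recovery — are the package's own choices, dense enough for
each property to be measured and small enough to run routinely.

## Phenotype analysis

`fitMixedModel()` performs two REML fits with lme4. The BLUE fit treats
line as fixed (cell-means coding, so the estimates are on the trait
scale without re-centering) with random environment,
replicate-within-environment and line-by-environment terms; replicate
identifiers are nested within environment, since a "rep 1" in one trial
has nothing to do with "rep 1" in another. The variance-component fit
treats line as random and, when year and location factors are coded,
splits the genotype-by-environment variance into genotype-by-year,
genotype-by-location and genotype-by-year-by-location components (cells
absent from an unbalanced layout simply contribute nothing); otherwise a
single genotype-by-environment component is reported in the
genotype-by-year slot with one "location". Random terms with fewer than
two levels are dropped, and with no replication the component fit is
skipped with a message. lme4's default optimizer stops about 1e-5 short
of the REML optimum in relative terms, so a stringent Nelder-Mead polish
(`polish = TRUE`) refines it until the balanced-design identity between
REML and the closed-form ANOVA estimators holds to ~1e-8; simulation
studies can disable both the polish and the (expensive) fixed-line BLUE
fit. Significance of random terms, where needed, is by likelihood-ratio
comparison of the fitted lme4 models rather than a classical
mean-square ANOVA table.

Broad-sense heritability on an entry-mean basis is

H² = σ²G / (σ²G + σ²GY/Y + σ²GL/L + σ²GLY/(LY) + σ²E/(LYR)),

monotone in σ²G and in each design count (property-tested).
`envCorrelations()` reports pairwise-complete Pearson correlations of
per-line environment means.

## QTL integration and downstream statistics

QTLs from different environments merge into one consensus locus when
their confidence intervals overlap or their peaks lie within 20 Mb, with
single-linkage closure over chains (A~B and B~C merges all three — the
pairwise wording of the rule does not address chains, and transitive
closure is the only order-independent choice). Consensus loci are named
`q<prefix><chromosome>` with position-ordered ordinals when a chromosome
hosts more than one, and flagged stable when detected in at least two
environments. The same 20-Mb rule applies to all lists supplied,
including peaks from a single environment.

Marker-group phenotype contrasts use Welch's unequal-variance t-test
(the robust default when only "a significance test" is specified).
Expression-trait association is pairwise-complete Pearson correlation
with the t-transform p-value; across a gene panel, Benjamini-Hochberg
adjusted p-values are reported alongside the raw ones. Relative
expression follows `2^-ddCq` with replicate means and delta-method
propagation of the replicate standard errors.

## Orchestration and reproducibility

`runPipeline()` executes simulate, qc, binmap, geneticmap, blue, scan
and merge in order, writing plain-text artifacts (TSV/CSV/BED/VCF) that
each carry a header naming the producing stage and parameters, plus a
JSON manifest with the configuration, per-stage counts and MD5 checksums
of every artifact. Configurations are nested lists that round-trip
through YAML; unknown keys are rejected. A single seed drives everything
through derived substreams, and re-running a configuration reproduces
every artifact byte for byte (covered by tests). The package's functions
are the intended interface; there is no shell executable.

## Known limitations

* Crossover interference is not simulated, and the conditional
  probability chain treats the RIL genome as Markov, which is an
  approximation for finite-generation selfing.
* Marker order is anchored to the physical map; misassembled reference
  regions would propagate into the genetic map unflagged.
* Segments shorter than the 11-of-15 majority span are invisible to the
  window rule; at GBS density this affects well under 5% of junctions,
  but the limit is intrinsic to the published smoothing rule.
* The 1.5-LOD support interval undercovers slightly on dense maps
  (~93-95% rather than nominal); this is a known property of the
  LOD-drop construction, not corrected here because the drop value is
  part of the method.
* QTL-by-environment interaction is handled by scanning environments
  separately and merging, not by a joint multi-environment model.
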