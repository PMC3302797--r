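---
title: "Methods: haplotype-block diversity dynamics in breeding programs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype-block diversity dynamics in breeding programs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapdyn)
```

## Scope and assumptions

`hapdyn` analyses inbred, biallelic SNP panels partitioned into
breeding-phase groups: a founder phase (landraces and pre-breeding
cultivars) and one or more improved phases. Three assumptions run through
everything:

1. **Accessions are effectively homozygous.** Each accession contributes a
   single haplotype; heterozygous calls are residual heterozygosity or
   assay artefacts and are coerced to missing at load time (the coercion is
   counted and reported). No phasing or imputation is attempted.
2. **Allele labels are arbitrary.** Calls are stored as A/B per SNP; every
   statistic in the package is invariant to swapping the labels, which is
   property-tested.
3. **The SNP map is trustworthy.** Positions are 1-based base pairs;
   within-chromosome position ties are rejected outright rather than broken
   arbitrarily, because window identity — and therefore every downstream
   count — must be deterministic.

## SNP quality control

`filter_informative()` removes, in order: (1) SNPs with no map position;
(2) SNPs whose missing-or-heterozygous fraction over *all* accessions is
strictly greater than 0.5; (3) SNPs whose minor-allele frequency is at or
below 0.02. The boundary conventions (strict in rule 2, inclusive in
rule 3) follow the rules' wording exactly and are pinned by unit tests at
50/100 missing vs 51/100 and 2/100 vs 3/100 alleles. Two deliberate
choices:

* The allele frequency is computed **over non-missing calls only**. The 2%
  rule exists to guard against genotyping error; a missing call carries no
  allele and should not dilute the denominator.
* The criterion order affects only the disposition labels in the report.
  The retained set is order-independent, which is tested by permutation.

Both thresholds are arguments, so the same QC applies to other panels.

## Haplotype blocks and the diversity index

A block is a window of `window = 5` consecutive SNPs on one chromosome,
slid **one SNP at a time**. The step size is not negotiable arithmetic: a
step of 1 is the only convention under which a 3259-SNP map on 12
chromosomes yields 3259 − 4 × 12 = 3211 blocks, the identity
`sum(max(0, n_c − window + 1))` that the enumerator is property-tested
against. Chromosomes with fewer than 5 SNPs contribute no block. Window
size is a parameter; 5 is the default everywhere.

For a group of size `n`, the block's **diversity index** is the number of
distinct 5-symbol strings among group members with all five calls present,
divided by `n`. Two readings of the denominator are possible; the default
keeps the full group size, staying literal to the index definition, and a
`complete_case_denominator` switch provides the alternative. Missingness
therefore biases the default index downward — acceptable at the ~1.5%
missing rates the package targets, and visible in tests that pin an
accession with one missing call to a 1/41 index in an otherwise
monomorphic block.

"Number of polymorphisms" could also be read as the count of segregating
sites inside the window; `census_all(counter = "segregating")` implements
that alternative, but distinct haplotype strings remain the default
because the index is defined from *consecutive allele combinations*, not
sites.

Group comparisons count blocks with a higher index in either group and
test the two index vectors with a two-sided Mann–Whitney test
(`wilcox.test`). With heavy ties and identical constant samples the test
is undefined; the package maps that case to p = 1 (no evidence of
difference).

## Reduced-diversity scan

A block is flagged when **both** later groups hold **strictly** fewer than
`ratio = 0.5` times the founder group's distinct-haplotype **count**. The
rule operates on raw counts, not indices, because the group sizes differ
(41/50/63 by default) and the collapse criterion is about the number of
surviving haplotypes; `use_index = TRUE` gives the normalised variant.
Blocks where the reference count is zero, or where any group has no
complete-case member, cannot be evaluated and are never flagged.

Flagged blocks merge when their window indices are consecutive — i.e.
adjacent windows sharing four SNPs — and a run must contain at least
`min_blocks = 2` windows to become a region (every region worth reporting
spans more than one window; `min_blocks = 1` disables the filter). A
base-pair gap tolerance is deliberately *not* used: adjacency is defined
by the SNP map, not by physical distance, so marker-sparse stretches do
not silently bridge unrelated signals. Region spans run from the first SNP
of the first block to the last SNP of the last block, and annotation
overlap (QTLs, genes, centromeres) is closed-interval with a shared base
pair sufficing.

## Linkage disequilibrium

`delta_squared()` is the squared haploid correlation
`D²/(p(1−p)q(1−q))` over complete-case accessions — for inbred lines the
natural estimator, equal to the squared Pearson correlation of the
0/1-coded vectors (the oracle the implementation is tested against on
1000 random pairs). It is undefined when a SNP is monomorphic among the
complete cases or fewer than two complete cases exist.

"Neighbouring SNPs" means **consecutive in map order** only, capped at
2000 kb; that is the only reading under which "distance between adjacent
SNP pairs" is a meaningful axis. Distances bin into left-open right-closed
50-kb intervals anchored at zero, so 50 000 bp falls in bin 1 and
50 001 bp in bin 2. Bin means are restricted by default to pairs in
"complete LD", `0 < Δ² < 1` — an unusual but explicit filter; exact 0s and
1s are counted separately and an inclusive mode (`complete_only = FALSE`)
is provided.

## Novel polymorphisms and accrual

A **novel SNP** is monomorphic among the reference group's non-missing
calls, with the alternate allele appearing in a later group. The union
reading ("either later group") is adopted because per-group frequencies
are reported alongside, so the stricter conjunction can be recovered by
filtering; the weaker assumption loses no information.

A cultivar's **novel block count** is the number of windows where its
complete 5-call string is absent from the reference group's complete
strings. Windows where the cultivar has a missing call contribute zero
rather than being imputed; windows where the reference has no complete
string are skipped and counted. One new SNP allele perturbs every window
containing it — five, for interior SNPs — a consequence pinned by a
brute-force test. The reference defaults to the founder-phase group; any
accession-id vector can be passed instead (e.g. all earlier-registered
cultivars).

`fit_accrual()` is ordinary least squares of count on registration year,
exactly the linear model the per-year accrual rate is defined by, with the
classical slope t-test; no robust or count-model variants are fitted by
default. It returns a classed object with `print`, `summary`, `coef`,
`predict`, `residuals` and `plot` methods.

## Ancestry

Founder frequencies walk every pedigree path from a cultivar to nodes
without recorded parents, **counting one occurrence per path** — a founder
reached through two crosses counts twice, which is the literal reading of
"ancestors were counted"; a unique-ancestor mode is available. Edges to a
flagged recurrent parent are skipped, so in backcross breeding only the
donor lineage contributes. The input format makes the recurrent flag
explicit rather than inferring backcrosses from repeated parent names,
because source pedigree notations vary. Cycles abort with the offending
node named.

Group-by-component statistics report mean ± SE (SE = sd/√n) per ancestral
component, all pairwise two-sided Mann–Whitney tests with a Bonferroni
correction **per component** (p × number of group pairs, capped at 1), and
a compact letter display built greedily over groups in descending mean
order, with a repair pass guaranteeing that two groups share a letter
exactly when their adjusted p is at or above α. Admixture classification
is `max(Q row) < 0.8`, strict, so a 0.8 top component is not admixed.

The simple-matching distance `1 − matches/comparable` over pairwise
non-missing calls is exported in PHYLIP square format so external
neighbour-joining tools can build trees; tree construction itself is out
of scope.

## The simulator

`simulate_panel()` exists because panels of this kind are generally not
redistributable: it generates data with the statistical structure the
analyses assume, plus full truth metadata, so that every stage — and the
package as a whole — is testable without any external download.

**What it emulates.** Defaults reproduce the reference study design: 12
chromosomes of 31.7 Mb (≈380 Mb genome) carrying 3259 SNPs; three
breeding-phase groups of 41/50/63 irrigated accessions plus 22/1/0
non-irrigated ones (177 total); registration years 1931–2005 split at
1974/75. Phase-1 accessions are drawn from `n_ancestral_pools = 4`
allele-frequency pools diverged from a common ancestor by a
Balding–Nichols model at `pool_divergence = 0.25` (substantial
subpopulation structure, as expected between geographically separated
landrace pools of a selfing crop), with per-accession admixture
proportions from a concentrated Dirichlet — these proportions are the
true Q-matrix. Improved cultivars descend from a bottlenecked founder
subset (`founder_counts_per_phase = c(10, 10)`) through pedigree-recorded
crosses, 20% of them recurrent-parent backcrosses, with Poisson(1)
crossovers per chromosome and a central 20% centromeric interval retaining
only 10% of crossovers — allowing the long merged low-diversity regions
that real centromeres produce.

**Novel-polymorphism injection.** `novel_accrual_rate` (default 3/year) is
defined as the *observed* accrual of novel block polymorphisms per year of
breeding. Mutations are injected per cross as a Poisson count with mean
proportional to the child's registration-year gap to its parents, at SNPs
kept monomorphic in phase 1, and propagate thereafter by inheritance; by a
telescoping argument the expected per-cultivar mutation count at year *t*
is rate-linear in *t − 1931* regardless of pedigree shape. Because a
mutation is observed in `sum(n_c − w + 1) · w / n_snp ≈ 4.93` windows
(chromosome ends) and only when all `w` window calls survive the
missing/het corruption (`(1 − m)⁵ ≈ 0.93`), the internal per-SNP intensity
divides by these two closed-form factors. Both are functions of the
configuration alone. Recombination also creates window strings unseen in
phase 1; this adds a mostly year-independent baseline absorbed by the
regression intercept and a small positive slope component. At the
defaults the recovered slope across replicate programs is unbiased to
within a few percent of the configured rate.

**What it does not emulate.** SNP density heterogeneity along chromosomes
(positions are uniform draws); phenotypic selection (selection enters only
as founder bottlenecks); coalescent-realistic genealogies within pools
(phase-1 genotypes are independent draws given ancestry, so phase-1
within-group LD is near zero — which exaggerates the phase-1 vs phase-2 LD
contrast relative to real data); and the composition of novelty: in real
programs most new window strings arise from recombination among existing
haplotypes with only a few dozen genuinely new SNPs, whereas the simulator
makes mutation the controlled, dominant channel so that the accrual rate
is a known truth parameter. Passing direction and recovery tests on this
generator therefore validates the *method's* arithmetic and sensitivity,
not any claim about a particular real panel.

**Noise defaults.** `missing_rate = 0.01` and `het_rate = 0.005` reflect
call rates typical of array genotyping on inbred rice; heterozygous noise
is applied only as a corruption process and lands in the missing mask,
consistent with the het-as-missing rule.

## Numerical and engineering choices

* Internal coordinates are 1-based inclusive everywhere; BED conversion
  (0-based half-open) happens only at the writer/reader boundary.
* Q-matrix rows must sum to 1 within 1e-6; simulator truth rows are exact
  to floating point.
* Identical configuration and seed give byte-identical outputs, including
  the pipeline's summary JSON; all randomness flows through R's RNG.
* `run_pipeline()` validates its configuration exhaustively (all schema
  errors reported at once), fills method defaults, and records thresholds
  and seed in the output bundle.

## Problem sizes used in tests

The validation suite runs full-design simulations (177 × 3259) where the
design itself is under test — accrual recovery uses five replicate
programs — and 60-accession, 216-SNP panels (204 blocks) for
direction-of-effect and property checks over multiple seeds, with
brute-force oracles (string censuses, run finders, correlation
equivalence) on 20 × 50 random matrices. These sizes give stable
directional statistics while keeping the whole suite near twenty seconds.

## Known limitations

* The diversity index is depressed by missingness under the default
  denominator; compare groups with similar call rates or switch to the
  complete-case denominator.
* Δ² between adjacent pairs only; no long-range LD matrices, D′, or decay
  curve fitting.
* The scan flags diversity collapse relative to one reference group; it is
  not a formal selection test and assigns no significance to individual
  regions.
* Mann–Whitney p-values use the tie-corrected normal approximation
  inherited from `wilcox.test`; with tiny groups and heavy ties this can
  dip below the exact enumeration bound.
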