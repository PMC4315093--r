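---
title: "Methods: LD decay and LD-based effective population size from SNP-array cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LD decay and LD-based effective population size from SNP-array cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`popld` implements the analysis chain used in SNP-array surveys of
smallholder ("village") and conservation poultry flocks: staged quality
control, per-population diversity statistics, within-chromosome pairwise
linkage disequilibrium (LD), distance-binned decay curves, and effective
population size (Ne) trajectories inferred from the relationship between LD
and recombination distance.  This vignette is the package's own account of
the statistical machinery, the tunable parameters, and the design decisions
taken where the methodology leaves genuine choices open.

## The data model

A cohort is a diploid call matrix (samples x markers, entries 0/1/2 counting
copies of the `allele_b` of each marker, `NA` missing) with a marker map
(chromosome, 1-based bp position, allele labels) and a sample table
(sample id, population label).  Chromosome labels follow the chicken
convention: autosomes 1-28, sex chromosomes Z/W, `"0"`/`"unmapped"` for
unplaced markers, anything else treated as a linkage group.  Distances
between markers are `|pos_b - pos_a|` in bp, positions inclusive and
1-based.  Allele orientation is stable but arbitrary: every statistic the
package computes (r², heterozygosity, F, PI_HAT) is invariant to swapping
the counted allele, so the PED/MAP reader simply counts the second allele
listed in a six-column map, or the lexicographically larger observed allele
for a plain four-column map.

## Staged quality control

Two regimes are shipped as named presets because structure and LD analyses
use different thresholds:

| stage              | `structure`    | `ld`           |
|--------------------|----------------|----------------|
| sample missingness | > 0.05 dropped | > 0.05 dropped |
| sex / unmapped     | dropped        | dropped        |
| marker missingness | > 0.05 dropped | > 0.05 dropped |
| monomorphic        | dropped        | dropped        |
| MAF                | <= 0.02 dropped| <= 0.05 dropped|
| HWE exact test     | (not applied)  | p <= 0.001 dropped |
| kinship (PI_HAT)   | >= 0.45        | >= 0.45        |
| LD pruning (r²)    | >= 0.2         | (not applied)  |

MAF cuts are exclusive-of-equal removal rules (a marker exactly at the bound
is removed).  The stage order is fixed as listed; the order matters because
MAF and HWE are recomputed on the surviving sample set, so the
high-missingness samples are settled first.  Applying the pipeline twice
with the same configuration changes nothing on the second pass, and the
per-stage attrition report conserves counts (removed + retained = input)
within each domain.

**HWE exact test.**  Conditioning on the observed allele counts, the exact
distribution of the heterozygote count follows the classic two-term
recurrence `P(h+2)/P(h) = 4 n_AA(h) n_aa(h) / ((h+1)(h+2))`; the two-sided
p-value sums every configuration whose probability does not exceed the
observed one.  The "does not exceed" comparison uses a relative tolerance of
1e-10 so that tie handling does not depend on the floating-point route used
to compute the masses; the test suite verifies agreement with a closed-form
enumeration oracle to 1e-12 for every configuration with up to 200
genotypes.

**Kinship.**  Relatedness uses the allele-frequency-conditioned
method-of-moments IBD estimator (the estimator behind the conventional 0.45
PI_HAT cut-off, rather than a GRM-based one): per marker, P(IBS|IBD) follows
from the cohort allele frequencies; the IBD-state probabilities are solved
from the IBS counts over each pair's shared markers, truncated to [0, 1] and
renormalised, and `PI_HAT = P(IBD=1)/2 + P(IBD=2)`.  Removal is greedy: the
highest-kinship offending pair loses the member with the larger mean
kinship to everyone else (ties: higher missingness, then the later
lexicographic id).  The estimator's sampling noise scales with the number of
effectively independent markers; with only a few hundred markers in strong
LD the spread of PI_HAT across genuinely unrelated pairs can reach a few
tenths, which is why the validation fixtures use several chromosomes and
dense panels.

**LD pruning.**  A sliding window of 50 markers advancing by 5 repeatedly
removes the lower-MAF member of the strongest pair at or above the r²
threshold until no within-window pair remains above it; the surviving set is
re-verified pair-by-pair in the tests.

## Diversity statistics

Per marker within a population: MAF, observed heterozygosity (fraction of
heterozygotes among non-missing calls), and expected heterozygosity
`2 p (1-p) n/(n-1)` with `n` the non-missing chromosomal count.  The
small-sample correction is applied by default and can be disabled
(`correct_he = FALSE`).  The per-individual inbreeding coefficient uses the
homozygosity method: `F = (O_hom - E_hom) / (L - E_hom)` with
`E_hom = sum_i (1 - 2 p_i q_i n_i/(n_i - 1))` over the individual's
non-missing markers.  The population-level F is the mean of individual F
values, reported with its SD and a one-sample t-test against zero (testing a
single sample of per-individual deviations against zero is the paired
construction collapsed to one margin; no natural second member of a pair
exists here).  The ratio summary `1 - mean(H_O)/mean(H_E)` is logged
alongside for comparison.  Under partial selfing at rate *s* the mean F is
validated against Wright's equilibrium `s/(2-s)`.

PCA standardises each polymorphic marker by `2p` and `sqrt(2p(1-p))`,
imputes missing calls to the marker mean, and eigendecomposes the resulting
genomic relationship matrix `XX'/L`.  Components are ordered by eigenvalue
with the sign fixed so the largest-magnitude marker loading is positive —
coordinates are therefore reproducible under sample permutation.  Mean
imputation is a deliberate, simple choice; it shrinks high-missingness
samples toward the origin, which is conservative for cluster separation.

## Pairwise LD

For two biallelic loci with haplotypes A1B1, A1B2, A2B1, A2B2 at frequencies
f11, f12, f21, f22:

r² = (f11 f22 − f12 f21)² / (f_A1 f_A2 f_B1 f_B2).

Genotype data are unphased, so haplotype frequencies are estimated by EM
over the double-heterozygote phase ambiguity (every other genotype pair
resolves its two gametes deterministically).  The EM initialises at linkage
equilibrium and stops when the largest frequency change is below 1e-8 or
after 1000 iterations; its marginals equal the observed allele frequencies
at every iteration.  On phase-resolved data it reduces exactly to direct
haplotype counting, and with a single ambiguous individual it matches a
1e-6-resolution grid search of the explicit one-parameter likelihood — both
are asserted in the tests.  If either locus is monomorphic among the
pair-complete individuals, r² is defined as 0.

`ld_scan()` emits every within-chromosome pair inside *both* windows — at
most `window_snps` markers apart (default 5000) and at most `window_kb`
apart (default 10,000 kb) — with no reporting floor, ordered by chromosome
and positions.  Decay curves use consecutive half-open intervals
`(lower, upper]` over the edges 10, 20, 40, 60, 100, 200, 500, 1000, 2000,
5000 kb (with a 10,000 kb extension for macro-chromosomes 1-5); "sliding
window bins" is interpreted as these non-overlapping intervals, since the
curve is a sequence of bin means and a genuinely overlapping window is not
reconstructible from a printed decay curve.  Empty bins are reported with a
zero count.

The fixed-effects model for LD,

r² = μ + Pop + Chr + (Pop × Chr) + b·dist + e,

is fitted by OLS with Type-I sequential F-tests in exactly that term order
(`keep.order` preserves the interaction ahead of the covariate).  On a
balanced design with the covariate orthogonal to the cells the sequential
sums of squares coincide with the textbook closed forms, which is how the
fit is cross-checked.  Missing population-by-chromosome cells drop the
affected interaction contrasts with a warning.

## Effective population size

The drift-recombination expectation `E[r²_adj] = 1/(α + 4 Ne c)` links
adjusted LD to Ne at recombination distance `c` (Morgans); `α = 1` assumes
no mutation (the default) and `α = 2` accounts for it.  The sample-size
adjustment is `r²_adj = r² − 1/(2n)` with `n` the *chromosomal* sample size
(twice the diploid count); negative values are floored at zero and flagged.
Physical distances convert linearly, `c = ō_chr × d_bp`, with `ō` the
chromosome's Morgans-per-bp ratio from a per-chromosome genetic-length
table.  Each distance bin then yields one estimate

Ne = (1/r̄²_adj − α) / (4 c̄),   referring to  t = 1/(2 c̄)  generations ago,

so long distances speak about the recent past and short distances about the
distant past.  Per-bin `c̄` is the mean of per-pair conversions (less biased
than the bin midpoint when marker spacing is uneven; a midpoint mode exists
behind `c_mode = "midpoint"`).  The adjust-then-average order is used; for a
fixed sample size it is algebraically identical to average-then-adjust.
Bins whose mean adjusted r² falls outside `(0, 1/α)` are skipped with a log
message.  Ne values are kept at full precision; rounding is left to the
reporting layer.

The packaged chicken genetic-length table
(`chicken_recomb_map_synthetic.tsv`) is a constructed, literature-style
approximation (macro-chromosomes near 2 cM/Mb rising above 10 cM/Mb for the
smallest micro-chromosomes) supplied as a convenience default for real-data
runs; it is explicitly synthetic, and every validation run uses
simulator-defined maps instead, so nothing in the test suite depends on its
provenance.

## The synthetic-data generator

Validation rests on a forward-in-time Wright-Fisher simulator
(`simulate_cohort()`), written so that the LD-to-Ne mapping can be tested
against known demographic truth:

* discrete generations; each offspring draws two parents uniformly
  (selfing allowed) and receives one recombinant gamete from each;
* crossovers per gamete are Poisson with mean equal to the chromosome's
  genetic length, placed uniformly in genetic distance (no interference);
* founder haplotypes carry site frequencies drawn from a symmetric
  Beta(0.5, 0.5) spectrum — a U-shaped stand-in for a neutral,
  post-ascertainment frequency spectrum; the validated properties condition
  on realised frequencies, so the exact founder spectrum is immaterial;
* a burn-in of four times the first epoch's Ne precedes the epoch schedule,
  long enough for LD at the distances analysed to equilibrate under drift
  and recombination;
* optional population splits evolve copies independently at the final
  epoch's size;
* emitted markers are those reaching an ascertainment MAF floor (default
  0.05) in the pooled sample; the phased truth, demography, and any planted
  violations are returned in a machine-readable ledger.

The gamete-dropping inner loop is compiled (Rcpp) and draws from R's RNG,
so a config seed reproduces a cohort byte-for-byte.  `n_markers` is the
*founder* panel size: drift over the burn-in fixes a large fraction of
sites (heterozygosity decays by `exp(-T/2Ne)`, and the U-shaped founder
spectrum fixes faster than that), so validation runs oversize the founder
panel (typically 8,000-15,000 sites per chromosome) to leave a
post-ascertainment panel of the order of several hundred to a thousand
markers; realised counts are what the reports state.

`plant_violations()` appends markers and samples that the QC stages must
catch — monomorphic markers, markers seeded just below a MAF target,
all-heterozygote (HWE-violating) markers, 20%-missing markers and samples,
duplicated samples and parent-offspring duos — all recorded in the ledger.
Planting happens after ascertainment, so the MAF floor can never remove a
planted marker, and low-MAF carriers are placed only on samples that survive
the sample filters (otherwise the marker would degrade to monomorphic before
its own stage is reached).

What the generator does *not* emulate: genotyping error, batch effects, the
real panel's ascertainment scheme (designed in commercial lines), selection,
mutation after founding, migration beyond clean splits, and sex-chromosome
inheritance.  Passing tests therefore demonstrate the statistical machinery
under idealised neutral demography, not robustness to array artefacts.

## Validation design and chosen tolerances

All expected values in the test suite are produced by independent oracles
(enumeration, closed forms, grid search, textbook sums of squares,
simulations with known truth); none are copied from the implementation.
The stochastic checks run under fixed seeds at desk-scale problem sizes
chosen so the whole suite completes in a few minutes on one CPU; the
realised sizes (replicates, marker counts, sample sizes) are stated in the
test code and in the acceptance report's `n` fields.

Three tolerance choices deserve justification, all fixed before the
corresponding checks were first run:

* **Sved-curve agreement.**  `E[r²] ≈ 1/(1 + 4Nec) + 1/(2n)` is a
  first-order approximation: more refined treatments (e.g. Hill-Weir-style
  expectations) differ from it by tens of percent once `4Nec` is large, and
  EM-based r² from finite unphased samples carries additional upward bias
  beyond the `1/(2n)` correction.  The per-bin acceptance band is therefore
  `0.25 × expected + 3 × SE` over replicate seeds — an approximation
  allowance plus Monte-Carlo noise, not a pure z-test.  Observed deviations
  in the shipped conditions run from ~1% (short range) to ~50% relative in
  the longest-distance bin, always inside the band and always in the
  positive direction the approximation analysis predicts.

* **Constant-Ne recovery.**  Mid-distance bins are defined as
  (100, 200], (200, 500], (500, 1000] and (1000, 2000] kb under the
  simulated 1 cM/Mb map — the range where `4 Ne c` is of order one and the
  inversion is best conditioned.  The median over ten replicates must land
  within ±30% of truth; the method's known biases (the same upward LD bias
  as above, which maps to underestimated Ne) leave it 15-20% low, inside
  the band.

* **Two-epoch decline.**  After a drop from Ne 500 to 50 fifty generations
  ago, recent-t (long-distance) bins must estimate below old-t
  (short-distance) bins; the assertion is this ordering.  The *magnitude*
  at short distances is strongly attenuated (medians of 130-180 rather than
  500) because the recent bottleneck adds LD at all scales faster than
  recombination can erase it at small c — a well-known contamination of
  ancient Ne estimates by recent demography, and the reason the ordering,
  not the ancient level, is the validated property.

## Known limitations

* LD-based Ne inherits every bias of the Sved/Corbin relation: estimates at
  short genetic distances are contaminated by recent demography, and the
  `1/(2n)` adjustment under-corrects EM-based r² from small unphased
  samples, biasing Ne slightly downward.
* The per-chromosome Morgans-per-bp conversion assumes a uniform
  recombination rate within each chromosome; fine-scale rate variation
  (hotspots, the macro/micro contrast within arms) is not modelled.
* The exact HWE test and the MoM kinship estimator assume biallelic markers;
  multi-allelic sites must be split or dropped upstream.
* `filter_markers()` recomputes frequencies on the current sample set only;
  there is no cross-population joint QC beyond pooling.
* PCA mean-imputation is inappropriate above ~20% missingness; the QC
  presets remove such markers and samples first.
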