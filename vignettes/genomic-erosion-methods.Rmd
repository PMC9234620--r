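---
title: "Measuring genomic erosion in declining subpopulations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring genomic erosion in declining subpopulations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragdiv)
```

# The problem

When a local subpopulation collapses — habitat loss, fragmentation — its
effective size shrinks long before field counts show it. Drift then erodes
heterozygosity, consanguineous matings become more likely, and individuals
grow more related to one another, even while limited gene flow from
neighbouring demes persists. `fragdiv` quantifies this erosion from sparse
SNP-array genotypes of two connected subpopulations sampled at two time
points: per-individual heterozygosity and inbreeding, runs of homozygosity
(ROH), pairwise relatedness, allele-frequency drift, and forward
simulations that ask whether the observed divergence is demographically
plausible. A pedigree gene-dropping simulator with exact identity-by-descent
truth validates every estimator.

# Estimators

## Site-based heterozygosity

For individual $i$, `site_heterozygosity()` reports the fraction of called
array loci that are heterozygous. This is heterozygosity at a fixed set of
ascertained SNPs — comparable across individuals typed on the same array —
not per-nucleotide genome heterozygosity.

## Moment-based inbreeding, $\hat F^{III}$

`fhat3()` implements the third moment estimator of the
GCTA/PLINK `--ibc` family. With dosage $x_{ij} \in \{0,1,2\}$ counting
copies of the allele whose frequency is $p_j$,

$$\hat F^{III}_i = \frac{1}{L_i} \sum_j
  \frac{x_{ij}^2 - (1 + 2p_j)x_{ij} + 2p_j^2}{2p_j(1-p_j)},$$

over loci with $p_j \in (0,1)$ and a called genotype. The per-locus term is
$-1$ for any heterozygote and symmetric under joint allele relabelling
($x \to 2-x$, $p \to 1-p$), which makes the estimator allele-order
invariant. Negative values mean heterozygosity above Hardy–Weinberg
expectation. Reference frequencies default to the full pooled sample (all
populations and years), matching what one gets by running the estimator on
a combined dataset; per-cohort frequencies can be supplied instead.
Loci fixed in the reference are skipped, not clamped, because the term is
undefined there.

## Runs of homozygosity

Two independent callers, deliberately different in kind:

**Window counting** (`call_roh_windows()`): every window of `window_snps`
consecutive SNPs passes if it contains at most `window_het_max`
heterozygous and `window_miss_max` missing calls; a SNP is eligible when at
least `snp_hit_threshold` of the windows containing it pass; maximal runs
of eligible SNPs are split at inter-marker gaps above `max_gap_kb` and
filtered on SNP count, length and density.

**Hidden Markov model** (`call_roh_hmm()`): two states per marker.
Hardy–Weinberg emits $(p^2, 2pq, q^2)$; autozygous emits
$(p(1-\varepsilon), \varepsilon, q(1-\varepsilon))$ with heterozygote error
rate $\varepsilon$ (default $10^{-3}$). Transition probability across an
inter-marker distance $d$ is $1 - e^{-\rho d}$, with per-bp rates
$\rho_{HW \to AZ} = 6.7\times10^{-8}$ and
$\rho_{AZ \to HW} = 5\times10^{-9}$ (the defaults of the model-based
caller this mirrors). Viterbi decoding; autozygous runs at least
`min_report_kb` long are reported. Missing genotypes emit probability 1 in
both states; loci with $p \in \{0,1\}$ are clamped to a pseudo-frequency
$1/(2n+1)$.

$F_{ROH}$ (`f_roh()`) is the summed segment length over the marker-covered
genome — per chromosome, last minus first marker position. On a sparse
array the assembly length would deflate $F_{ROH}$ non-comparably, so the
covered length is the denominator and is reported alongside.

### Window geometry on a sparse array

The defaults assume ~85.5 kb mean marker spacing: minimum run length 1 Mb,
at least `min_snps = 25` SNPs per run, density at most 200 kb/SNP, gaps
above 500 kb split runs. One default departs from dense-data practice
deliberately: the scanning window is `window_snps = 25`, equal to
`min_snps`, not the conventional 50. A window can only pass inside a tract
that (nearly) contains it, so a 50-SNP window at 85.5 kb spacing would
raise the effective detection floor to roughly $50 \times 85.5\,
\mathrm{kb} \approx 4.3$ Mb — far above the 1 Mb floor the other
parameters target, and above the 5 Mb boundary that separates the length
classes of interest. Sizing the window to the minimum reportable run keeps
the two thresholds consistent; with 25-SNP windows the practical floor is
about 2.1 Mb, and planted-tract recall for tracts $\ge$ 2 Mb exceeds 0.9
(see `tests/testthat/test-acceptance.R`). All values are config-exposed.

The 5 Mb length-class boundary is assigned to the LONG class inclusively
(`length_bp >= 5e6`); runs shorter than 5 Mb reflect background
relatedness or older inbreeding, longer runs recent consanguinity.
Segment length is `end - start` in bp over the run's terminal markers,
1-based inclusive positions. Chromosomes with fewer SNPs than the window
are scored with a single truncated window rather than dropped — sparse
microchromosomes would otherwise vanish from the analysis.

## Pairwise identity by descent

`estimate_ibd()` is the method-of-moments estimator behind PLINK's
`--genome`: observed genome-wide IBS0/1/2 counts are equated to their
HWE expectations given allele frequencies and solved sequentially for
$(Z_0, Z_1, Z_2)$, the probabilities that a random locus shares 0/1/2
alleles identical by descent; negatives are truncated to zero and the
triple renormalized; $\hat\pi = Z_2 + Z_1/2$. The finite-sample
bias-correction factors some implementations add are omitted: with the
~10k-marker panels this package targets, recovery tests bound the residual
bias directly (mean $\hat\pi$ within $\pm 0.03$ of $2\varphi$ for
parent–offspring through first-cousin pairs). Zero-truncation leaves a
small positive floor for truly unrelated pairs (about $+0.014$ at 10k
markers); it is visible in the validation output and should be kept in
mind when interpreting near-zero means.

Relationship classes follow pedigree-calibrated bins, lower-bound
inclusive: HIGH ($\hat\pi \ge 0.40$; parent–offspring, full siblings),
MODERATE ($[0.18, 0.40)$; half-siblings, avuncular,
grandparent–grandchild), COUSIN ($[0.09, 0.18)$; 0.09 is the lower end of
values observed for known first cousins), UNRELATED below.

## Quality control

Fixed stage order: SNP call rate, individual call rate, Hardy–Weinberg
screen, chromosome exclusion, LD pruning. Two panels leave QC: the
unpruned panel for ROH calling (pruning thins exactly the marker runs ROH
detection needs) and the pruned panel for heterozygosity, $\hat F^{III}$
and IBD (those assume quasi-independent loci).

Call-rate filtering iterates locus-then-sample rounds to a fixpoint:
a single pass is not idempotent because dropping a low-call-rate sample
can push a borderline locus back below threshold, and downstream logic
relies on QC being a no-op on its own output.

The HWE screen is the conditional exact test on genotype counts
(two-sided by probability mass, computed by the standard recurrence on the
heterozygote-count distribution), defaulting to $\alpha = 10^{-6}$ over
all samples pooled; both the threshold and per-population stratification
are configurable since reasonable practice varies.

LD pruning is greedy within 50-SNP windows stepping by 5: while any kept
pair has $r^2 > 0.2$, the member of the worst pair with the lower minor
allele frequency is removed (ties: the later locus). Sweeps repeat until a
full pass removes nothing. $r^2$ and MAF are computed from integer
genotype cross-products with pairwise deletion — not floating-point
correlation — so the decisions are bit-identical under ref/alt
relabelling; monomorphic loci have undefined $r$ and are never tested.

## Comparison machinery

`wilcoxon_rank_sum()` and `chi_square_2x2()` are thin wrappers over the
standard R routines with conventions pinned: W is the Mann–Whitney U of
the first sample (midranks for ties, exact p for small tie-free samples,
normal approximation with continuity correction otherwise), and the Yates
correction defaults to on with both variants reported in replication
output. `subsample_statistic()` implements sample-size matching: seeded
subsampling without replacement of the larger group at the smaller group's
size, returning the full distribution of any statistic. Variances of
allele-frequency changes are compared both by the classical F-test and by
a locus-permutation test; $\Delta p$ vectors are far from normal, so the
permutation route is the one to trust.

## Two-deme Wright–Fisher simulator

`wf_simulate()` iterates, per unlinked locus and generation: migration
mixes frequencies, $p' = (1-m)\,p_{\text{self}} + m\,p_{\text{other}}$,
then the next generation is a binomial draw of $2N(t)$ gene copies.
Sizes and migration follow per-generation schedules; "increasing
isolation" is a non-increasing $m(t)$. Migration acts on frequencies
(conservative backward migration) by default; a variant drawing integer
migrant counts is available (`migration_model = "individuals"`). No
mutation — over the few-generation horizons of interest drift dominates
utterly. `fit_plausibility()` places an observed between-deme divergence
as an empirical quantile in the simulated distribution of
$\mathrm{var}(p_A - p_B)$ per candidate scenario; it reports, it does not
test.

# The synthetic-data generator

`gene_drop()` gives every founder two haplotypes drawn under HWE from a
founder frequency spectrum (default: minor-allele frequency uniform on
$[0.05, 0.5]$, random orientation), then transmits recombinant haplotypes
down the pedigree with crossovers as a Poisson process at 1 cM/Mb
(Haldane, no interference; the true recombination map of a wild bird is
rarely known, so the rate is a parameter). Founder-haplotype identity is
tracked as exact segment structure, so autozygous tracts, realized
inbreeding and pairwise IBD states are exact by construction rather than
marker-approximated. The default genome is 30 autosomes totalling ~1 Gb
with ~11.7k markers at ~85.5 kb mean spacing — the sparse-array regime
this package is built for. `plant_roh()` writes homozygous tracts with a
controllable heterozygote error rate into any background, and
`make_two_deme_cohorts()` samples HWE genotypes from simulated deme
frequencies, so the drift simulator feeds the full estimator pipeline.

What the generator does *not* emulate: background linkage disequilibrium
outside pedigree structure (cohort draws are locus-independent),
ascertainment bias of a real array, genotyping-intensity artefacts, and
sex chromosomes. Consequently the short-ROH background that LD creates in
real data is absent here, false-positive rates on synthetic outbred
individuals are optimistic lower bounds, and passing tests demonstrate
estimator correctness under the stated model, not robustness to every
artefact of real arrays.

# Numerical choices

* Genotypes are integer dosages $\{0, 1, 2, \mathrm{NA}\}$ with 0 =
  homozygous reference; all statistics are allele-order covariant, and the
  property tests enforce this exactly (hence the integer-arithmetic
  $r^2$ above).
* Positions are 1-based inclusive; interval length is `end - start` bp.
* Loci are re-sorted on load (chromosome blocks contiguous, positions
  strictly increasing); duplicated positions are an error.
* Undefined quantities (frequency of an untyped locus, heterozygosity of
  an uncalled individual, LONG proportion of an empty group) are `NaN`,
  never silently 0.
* HWE recurrence probabilities are normalized at the end; the two-sided
  mass comparison uses a $1 + 10^{-12}$ slack so ties of equal
  probability are included as in the reference enumeration.
* The Viterbi recursion is in log space; a brute-force path enumerator
  (`enumerate_az_path()`) is exported and the suite asserts exact
  agreement on chains up to 12 markers.
* Every stochastic routine takes an explicit seed; replicate streams in
  `fit_plausibility()` are spawned from the root seed so results do not
  depend on evaluation order.

# Problem sizes

The test suite validates at the study's own scale where it matters —
estimator recovery and ROH calling run on the full ~1 Gb / 11.7k-marker
genome with 50 individuals or pairs per condition — and at reduced scale
for workflow plumbing (two-deme panels of a few thousand markers). The
acceptance script (`scripts/acceptance.R`) recomputes the headline
validation quantities from scratch at full scale in well under a minute.

# Known limitations

* The moment IBD estimator's zero-truncation floor (above) biases
  near-zero means upward by ~0.01–0.03 depending on marker count.
* $F_{ROH}$ depends on the caller's detection floor (~2 Mb here); it is a
  lower bound on autozygosity, comparable across groups typed on the same
  panel, not an absolute inbreeding coefficient.
* The HMM uses hard genotype calls with a flat error rate, not genotype
  likelihoods; array data provide no per-call likelihoods.
* Weir–Cockerham $F_{ST}$ between two demes can be slightly negative for
  identical populations; the two-deme island-model expectation
  $1/(1+4Nm)$ is only a loose guide at $d = 2$.
* `fit_plausibility()` compares variances of true frequencies; observed
  cohort frequencies carry binomial sampling variance that the caller
  must remove (see `analysis/06_wf_plausibility.R` for the correction).
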