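---
title: "Detecting Dobzhansky-Muller incompatibilities with the variance in two-locus heterozygosity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting Dobzhansky-Muller incompatibilities with the variance in two-locus heterozygosity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmiscan)
```

## The problem and the statistic

When two diverged lineages hybridize, alleles that never met before are
combined in the same genomes. A Dobzhansky-Muller incompatibility (DMI) is
a negative epistatic interaction between such alleles at two loci: each
parental background carries one of the incompatible alleles (haplotypes
`Ab` and `aB`), and one of the two recombinant haplotypes produced after
admixture (`AB`) is selected against. Because only one recombinant suffers,
selection leaves a characteristic *imbalance between the two recombinant
haplotypes* -- something ordinary linkage disequilibrium (LD) does not
distinguish from population structure or residual parental linkage.

`dmiscan` detects this footprint through the variance in two-locus
heterozygosity. Let `g_ik` be the frequency of haplotype `ik`, `p_i`, `p_k`
the allele frequencies, and `K` the number of heterozygous loci (0, 1 or 2)
seen when two haplotypes are drawn at random. The per-locus
heterozygosities are `h_A = 1 - p_a^2 - p_A^2` and likewise `h_B`; under
independence `K` has variance `sigma2_exp = h_A + h_B - h_A^2 - h_B^2`. The
observed variance deviates from this by

```
delta2 = 2 * sum_ik (g_ik^2 - p_i^2 p_k^2),      X2 = delta2 / sigma2_exp.
```

`X2` (the normalized deviation) is the focal statistic. A DMI drives `X2`
negative while classical LD `D = g_AB g_ab - g_aB g_Ab` is negative; the
companion statistic `deltaD2 = D2_ab - D2_AB`, with
`D2_ik = g_ik^2 - p_i^2 p_k^2`, quantifies the recombinant imbalance
directly. Two algebraic identities tie these together and are enforced in
the test suite: `delta2 = 4 D (2 g_ab + 2 g_AB - 2 D - 1)`, and, when
`D < 0`, `(D2_ab - D2_AB) / sum |D2_ik| = -(1 - p_A - p_B)`. The package
computes all of these in `two_locus_stats()`, with
`var_K_enumeration()` as a brute-force oracle that enumerates the ten
unordered haplotype pairs.

Two conventions are worth stating because the literature is loose about
them. First, `deltaD2` is oriented as `D2_ab - D2_AB` (positive when the
`AB` recombinant is deficient); which mixed-ancestry class is called `ab`
is fixed by marker order in the scan and flips sign under parent
relabelling, so candidate calls never depend on it. Second, `D' = 0` when
`D = 0` exactly; the normalization `D' = D / |Dmax|` is otherwise the
classical range normalization.

## The deterministic model

`run_trajectory()` iterates the two-locus recursion for a hybrid
population founded as `g_aB = f`, `g_Ab = 1 - f`. Haplotype fitnesses are
`w_ab = 1`, `w_Ab = 1 + alpha`, `w_aB = 1 + beta`,
`w_AB = (1+alpha)(1+beta)(1+gamma)` with `gamma <= 0` for a DMI. Each
generation applies selection, then recombination at probability `c`, then
migration (`m1` injecting pure `aB`, `m2` pure `Ab`) -- migrants enter
after selection, at the juvenile stage. Founders are generation 1, so
recombinants first appear in generation 2. The recursion stops at a
generation cap (10000) or when a minor allele frequency falls below
`maf_stop = 0.005`; the near-fixation state itself is not recorded, since
beyond it the pair is effectively monomorphic for detection purposes.

With the reference parameterization (`alpha = 0.001`, `beta = 0.002`,
`gamma = -0.5`, `c = 0.1`, `f = 0.5`, no migration) the detection window --
the generations with `X2 < 0` -- is:

```{r window}
tr <- run_trajectory(selection_params(0.001, 0.002, -0.5, "haploid"),
                     demography(f = 0.5, c = 0.1))
detection_window(tr)
```

Diploid populations are handled by `diploid_step()` on the gamete pool,
with genotype fitness `(1+alpha)^nA (1+beta)^nB (1+gamma)^e(nA, nB)`. The
dominance of the epistasis sets the exponent `e`: `codominant`
(`e = nA * nB`), `recessive` (the same except the double heterozygote is
unaffected, `e(1,1) = 0`), and `homo_homo` (only the double homozygote
suffers, `e = 4`). Stronger dominance exposes the incompatibility earlier
and purges it faster, so the codominant window is earliest and shortest
and the homo-homo window latest and longest; the recessive mode -- the one
used throughout the simulations -- sits between them.

`parameter_grid()` tabulates windows over `c`, `f`, `gamma`, `m1`, `m2`.
Two robust orderings, both asserted as tests: the magnitude of the most
negative `X2` is unimodal in `c` with its peak at low-to-intermediate
recombination (at very small `c` the DMI is purged before any detectable
imbalance arises, and the window is empty), and it shrinks monotonically
as `f` moves away from 1/2, with no negative `X2` at all for strongly
skewed admixture. Strong same-direction selection without epistasis
(Hill-Robertson interference) can also push `X2` negative, but only
briefly and weakly in the first few generations -- the deterministic
comparison in the test suite confines it to before generation 10 --
whereas a DMI keeps `X2` negative for hundreds of generations.

## The forward simulator

`sim_hybrid()` is an individual-based, ancestry-labelled simulator: each
of `N` diploids carries two 0/1 haplotypes per marker (1 = parent-1
ancestry). It is the package's fixture generator -- every simulated data
set in the tests and the acceptance analysis is produced by it at run
time.

Design choices, fixed once:

* **Genetic map.** Interval recombination probability is
  `min(interval cM / 100, 0.5)` with independent intervals and no
  interference; chromosomes assort freely. The standard study layout
  (`uniform_genome()`) is 100 markers per chromosome at 1 cM spacing with
  3e5 bp per cM, giving 30-Mb, 100-cM chromosomes -- a teleost-like scale
  that makes 1-Mb binning meaningful.
* **Mating and selection.** Both parents of each offspring are drawn with
  probability proportional to fitness, with replacement (hermaphroditic,
  selfing allowed). This fecundity weighting is the standard equivalent of
  juvenile-stage viability selection for these statistics.
* **Migration** replaces a binomially drawn number of juveniles
  (expectation `m * N`) with pure parental individuals, after selection.
* **Moran model.** Per-age death probabilities
  `c(0.2, 0.2, 0, 0, 0, 0, 0.25, 0.5, 0.75, 1)` from age 0; founders start
  at age 0; the dead are replaced by juveniles bred from survivors; one
  step is one generation. The comparison with Wright-Fisher is
  qualitative: with overlapping generations the recombinant imbalance
  builds more slowly, so the negative-`X2` onset is later (tested as a
  median ordering over 20 paired seeds).
* **Growth.** An optional early expansion multiplies the population by
  `1 + growth_rate` per generation for `growth_duration` generations
  (e.g. 5% for 35 generations); the schedule is followed exactly.
* **Sampling.** `sample_ancestry()` excludes individuals whose
  minor-parent genome fraction is below 10% before drawing the sample.
  For deliberately minimal genomes (one or two markers) this fraction is
  a meaningless proxy for genome-wide ancestry, so analyses on such
  genomes set the threshold to 0; with realistic marker counts the rule
  almost never binds after the first few generations.
* **Randomness.** A single seed set at simulation start; identical
  configuration and seed give bit-identical populations.

What the generator does *not* emulate: mutation, ancestry-call errors
(hard calls are taken as true), more than two source populations,
continuous space, and crossover interference. Passing tests therefore
speak to the statistical behaviour of the method under clean ancestry
data, not to robustness against upstream inference error.

## The genome scan

The scan consumes an ancestry hard-call matrix (markers x individuals,
dosage 0/1/2 of parent-1 ancestry, `NA` missing) and mirrors the analysis
pipeline used for natural hybrid populations:

1. `filter_loci()`: keep markers with both homozygote frequencies > 0.05
   and heterozygous-or-missing fraction < 60% ("or" read as the combined
   fraction, over all retained individuals).
2. `ld_thin()`: one deterministic forward pass dropping the later marker
   of any pair within 10 kb with dosage `r^2 > 0.9`
   (pairwise-complete individuals; the earlier marker always wins).
3. `pairwise_scan()`: sample up to 700 markers (seeded) and compute
   `X2`, `D'`, `deltaD2` for every pair. Phased mode uses the haplotypes
   directly. Pseudo-phased mode uses only individuals homozygous at both
   loci -- the only individuals whose two-locus phase is known without
   computational phasing -- counting two identical haplotypes each, and
   requires at least 50 such haplotypes per pair (with 200+ sampled
   individuals this is typically met). Frequencies are plug-in estimates.
4. Candidate rule: `X2 < -0.005` and `D' < 0`. The `D'` condition ensures
   the depleted haplotype is a recombinant, not a parental type.
5. `bin_pairs()`: markers map to half-open 1-Mb windows
   (`floor(pos / 1e6)`, 0-based); a bin pair containing any candidate
   marker pair is a putative DMI; same-bin pairs are excluded.
6. `bootstrap_support()`: 20 bootstrap scans of 700 markers each, all
   drawn from the fixed thinned set. With `p_bin` the median fraction of
   tested bin pairs that are candidates, the chance of seeing the same
   bin pair `x` times is binomial, and the support threshold `k` is the
   smallest count whose upper-tail p-value beats the
   Benjamini-Hochberg-style criterion
   `p < (#bin pairs with count >= k) / (total candidate occurrences
   across bootstraps) * 0.001`. "Total significant pairs" is counted over
   candidate *bin* pairs; marker-pair counting is a defensible
   alternative reading, and the choice is deliberately isolated in this
   one function. If nothing is ever flagged (`p_bin = 0`), `k` falls back
   to 1 with a warning.

The G test of allelic independence (`g_test_scan()`) is provided as the
classical baseline; it is applied to interchromosomal pairs on the same
haplotype estimates. It is sharp in the first generations after
admixture, while parental LD is still strong, and loses sensitivity once
that linkage decays -- the regime where `X2` keeps working.

## Evaluation harness

`classify_pairs()` labels each scanned pair against the simulated truth
(`dmi_pair`, `dmi_chrom`, `neutral`); `sensitivity_specificity()` gives
Wald 95% intervals over replicates; `fp_tp_rates()` computes flagged
fractions per class and threshold with confidence intervals from
resampling 2000 pairs 1000 times; `distance_profile()` tracks how the
flagged fraction decays with genetic distance from the true loci (with
its whole-genome limit equal to the global rate). Detection in a
replicate means the flag at the exact true marker pair; flagged linked
neighbours count as false positives, which overstates the false positive
rate in exactly the way the per-distance profile makes visible.

## Problem sizes and numerical choices

The packaged analyses use the study conditions of the simulation design:
`N = 5000` diploids, admixture `f = 0.5`, recessive DMIs, 30 generations
and 200 sampled individuals for the multi-chromosome two-DMI design
(`alpha, beta ~ Exp(0.001)`, `gamma ~ U[-1, -0.001]`, four DMI plus two
neutral 100-marker chromosomes, 30 replicates); 50 replicates of the
neutral unlinked-pair null (`gamma = 0`, `c = 0.5`, 300 sampled,
checkpoints every 10 generations through 150); 20 paired seeds for the
Moran/Wright-Fisher and migration-swamping orderings. Replicate counts
are the package's choice of a desk-scale design; the generating
conditions themselves are not scaled down.

Tolerances: haplotype frequency vectors are validated to 1e-12 and
renormalized on construction; the algebraic identities are asserted to
1e-10 over 1000 random simplices; `X2` is reported as `NA` (and the pair
as unusable) whenever a locus is monomorphic rather than dividing by
zero. One observed limit is worth recording: at late generations drift
takes the allele frequencies of a neutral pair away from 1/2, where the
finite-sample null of plug-in `X2` develops a heavy negative tail, so
the minimum across many late checkpoints can undershoot the -0.001
envelope that holds near even frequencies. The neutral *candidate* rule
at -0.005 with `D' < 0` remains conservative; the corresponding
acceptance check reports the measured minimum honestly.

## Limitations

Known limitations, beyond the generator simplifications above: the
method is blind to incompatibilities in which both recombinants suffer
(no imbalance, hence no negative `X2`); tightly linked pairs produce no
recombinants to select against within the observation window; the
detection window is transient and demography-dependent, so absence of
signal is not absence of a DMI; and epistasis strength is not estimated,
only detected.
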