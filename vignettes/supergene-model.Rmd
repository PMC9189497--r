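---
title: "Supergene introgression, associative overdominance and balanced lethals: the model behind aodsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supergene introgression, associative overdominance and balanced lethals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aodsim)
```

## The question

Supergenes are sets of tightly linked loci inherited as a unit, typically
because structural variants — here a chromosomal inversion — suppress
recombination between two arrangements. Suppressed recombination protects
co-adapted haplotypes but also lets recessive deleterious mutations
accumulate independently on each arrangement. When each arrangement carries
its own private recessive load, heterokaryotypes (one copy of each
arrangement) mask it and appear fitter than either homokaryotype: the
inversion behaves as if overdominant even though no single site is. This is
associative overdominance (AOD).

`aodsim` simulates a scenario in which a supergene polymorphism is *created
by introgression*: two populations diverge in isolation, each fixed for one
arrangement; a single migrant then carries the inverted arrangement into
the focal population. AOD generated by the masked private loads may let the
new arrangement invade and may balance the polymorphism; continued mutation
accumulation may then destabilize it or push it toward one of the
pathological end states — a half-lethal system (one homokaryotype inviable)
or a balanced lethal system (both inviable, half of all zygotes lost every
generation).

## The model

The simulator is an individual-based, discrete-generation Wright-Fisher
model of diploid hermaphrodites with multiplicative viability selection.

**Genome.** A linear 20 Mb genome in two 10 Mb chromosomes. The inversion
occupies the central 50% of chromosome 1 (25% of the genome); chromosome 2
serves as an unlinked control. Selected mutations can arise only inside 40
uniformly spaced 5 kb segments (200 kb of "allelic content"), a standard
device that concentrates bookkeeping on a tractable number of sites while
recombination still acts over the full physical map. Positions are
continuous, so the infinite-sites assumption holds exactly.

**Mutation.** Deleterious mutations arise at `mu = 4.5e-9` per bp per
generation within the segments, with effect magnitudes `|s| ~ Gamma(shape
0.5, rate 10)` (mean 0.05, highly leptokurtic — mostly small effects with a
long tail) and a fixed dominance coefficient `h` (0 or 0.1). Fitness is
`prod(1+s)` over homozygous and `prod(1+h s)` over heterozygous mutations,
relative to a genotype free of all currently segregating mutations; each
factor is floored at zero, so `s <= -1` is an unconditional recessive
lethal. Mutations that fix are pruned from genotypes into a per-population
registry — relative fitness is unchanged, and the registries are what later
reconstructs fixed differences. After admixture, beneficial mutations also
arise, 1000-fold more rarely (`4.5e-12` per bp), co-dominant (`h = 0.5`),
with exponential effects of mean `kappa = 0.001`.

The gamma and exponential parameters are read as *rate* 10 (so `E|s| =
alpha/beta = 0.05`) and *mean* 0.001 respectively; the alternative readings
(mean 5, rate 0.001) would make typical effects super-lethal or absurdly
large and are not biologically interpretable.

**Recombination.** Crossovers initiate at `rho = 3.0e-8` per bp per
meiosis and gene conversion (GC) at `gamma = 1.8e-8` per bp, with Poisson
tract lengths of mean `lambda = 500` bp, for a total `r = 4.8e-8`. In
inversion heterokaryotypes, crossovers are completely suppressed inside the
inversion (modelled as zero crossover rate there, with the genome-wide
crossover count reduced accordingly), while GC continues to operate
everywhere — GC is therefore the only gene flux between arrangements inside
the supergene. A gamete's arrangement label is that of the chromatid
carrying the inversion interval after crossover resolution; GC copies
content but never flips the label. Chromosomes assort independently.
Removing GC (`gc_off_transform()`) folds `gamma` into `rho`, holding total
`r` constant, so comparisons isolate gene flux rather than total
recombination.

**Pipeline.** Stage 1 (`run_burnin()`): both populations of size `N_BI =
2500` evolve independently for `T_BI` = 200 000 or 500 000 generations
(divergence time) from mutation-free founders, without beneficial
mutations. Stage 2 (`run_replicate()`): the focal population is reduced to
its post-admixture size `N` (100-2500) by uniform sampling, one random
migrant replaces one random resident (the inversion enters at frequency
`1/N`), privately fixed mutations re-materialize as segregating sites in
the merged context, and evolution continues until the inversion fixes, is
lost, the population goes extinct, or 200 000 generations elapse.
Because burn-in stochasticity rivals parameter effects, replicates are run
from banks of independent burn-ins (`make_burnin_bank()`).

## Statistics

* **AOD** (`compute_aod()`), following Ohta's apparent selection
  coefficients: `s1' = 1 - W_AA/W_AB`, `s2' = 1 - W_BB/W_AB`,
  `s' = min(s1', s2')`, with asymmetry `|s1' - s2'|`. Positive `s'` means
  the heterokaryotype beats both homokaryotypes.
* **Load decomposition** (`compute_loads()`): for a genomic region, the
  *drift load* is `1 - prod(1+s)` over deleterious mutations privately
  fixed relative to the sister population (these re-segregate after
  admixture), the *mutational load* is one minus the population mean of
  region-restricted fitness over segregating mutations, and the
  *segregation load* composes them multiplicatively,
  `1 - L_seg = (1 - L_drift)(1 - L_mut)`, consistent with multiplicative
  fitness.
* **Outcome classification** (`classify_outcome()`): while both
  arrangements segregate, karyotype classes with mean fitness below 0.01
  are inviable, giving `POLY_BOTH_VIABLE`, `HALF_LETHAL` or
  `BALANCED_LETHAL`. Outcomes are evaluated at checkpoint generations
  100 000 / 150 000 / 200 000 (scaled accordingly).
* **Invasion**: the inverted arrangement still present `N` generations
  after migration.

**Absent homokaryotype classes.** Late in a half-lethal or balanced-lethal
trajectory no AA (or BB) adults exist after selection, exactly because the
class is lethal, so its realized mean fitness is undefined exactly when it
matters most. The classifier therefore falls back to the *expected*
homokaryotype fitness over random within-arrangement haplotype pairs
(`expected_karyotype_fitness()`; exhaustive enumeration up to 2000 pairs,
Monte Carlo beyond). Realized class means are used whenever the class is
present; the expected-pairing values are also recorded alongside the
realized ones in the time series (`sp_exp` etc.), since at one-migrant
frequencies the AA class is almost never realized at early generations.

## Numerical realization

Two exact accelerations keep the engine honest and fast; both are
implemented in the compiled core (and mirrored by a pure-R reference
engine, `engine = "R"`, used for cross-validation):

* **Interval-parity crossovers.** The gamete assembly only ever needs the
  source chromatid at the parental mutation positions and at the inversion
  start (the label's anchor). For each interval between consecutive such
  points, the parity of the Poisson crossover count is drawn directly:
  a flip with probability `(1 - exp(-2 rho d))/2` (Haldane), with `d` the
  interval length excluding the inversion for heterokaryotypes. This is an
  exact realization of the crossover process restricted to its observable
  consequences, and it preserves the joint linkage of label and content.
* **Thinned gene conversion.** Only GC tracts that can overlap a mutable
  segment can move a mutation. Initiations are drawn Poisson on windows
  extending `4*lambda + 100` bp left of each segment; the probability that
  a tract from outside reaches a segment underflows double precision, so
  the thinning is exact in floating point.

Other choices: parents are drawn with replacement proportionally to
fitness (selfing permitted, switchable); fixation pruning runs every
generation on the offspring; fitness caches are recomputed after pruning so
cached and recomputed values always agree; extinction (all fitness zero) is
a terminal replicate status, not a crash. Per-replicate seeds derive from a
root seed by a counter-based split, making banks and whole block designs
bit-reproducible.

## Rescaling and desk-scale problem sizes

`rescale_config(cfg, Q)` applies the standard diffusion rescaling:
`N` and time divided by `Q`, per-bp rates and selection coefficients
multiplied by `Q`, preserving `N mu L`, `N r L` and `N s`. The full-scale
study design (burn-ins of 2500 individuals for up to 500 000 generations,
10 burn-ins x 10 000 replicates per parameter set) is cluster-scale; the
package's examples, tests and acceptance script run at `Q` = 25-100:

* burn-in calibration (fixed-count ratios, load decomposition): `Q = 25`
  (N_BI = 100, T_BI = 8000 vs 20 000), 10-20 independent pairs — minutes;
* engine oracles (segregation, suppression, clocks): `Q = 100` micro
  populations — seconds;
* outcome-map and invasion experiments: `Q = 25` with 10^2-10^3 replicates
  per cell, early termination making lost replicates cheap.

Rescaling is exact for diffusion-limit quantities (frequency dynamics,
fixation probabilities, ratios and fractions) but distorts absolute
selection coefficients: at `Q = 25` the mean scaled `|s|` is 1.25, so a
substantial fraction of mutations become effectively lethal when
homozygous, which accelerates stepwise degeneration relative to the
gradual many-small-effects erosion of a literal unscaled run. `Q = 25` was
chosen for the calibration quantities as the strongest acceleration whose
fixation-lag bias leaves the fixed-count ratio near its long-run value
(stronger scaling shortens the runs relative to the ~4N-generation lag
before the first fixations, inflating the ratio). Quantities reported by
the acceptance script are deliberately scale-free (a ratio and a
fraction).

A note on the mutational target: `compensate_segment_mu = TRUE` inflates
`mu` inside the segments by `L / 200kb`, emulating a genome-wide target
folded into the segments. This option exists for completeness but is off by
default: concentrating a full genome's deleterious input into 5 kb blocks
whose internal recombination rate is ~`r * 5kb ~ 2e-4` turns each segment
into a quasi-asexual block; recessive lethals ratchet up within blocks and
the population collapses (all-zero fitness) within a few thousand
generations even at modest scaling — a regime with no biological
counterpart here. With the default, the per-gamete deleterious rate is
`mu * 200kb ~ 9e-4`, and the rare-outcome structure (degeneration states as
tail events among many replicates) is the object of study.

## What the generator does and does not emulate

The burn-in generator produces the statistical structure the analysis
assumes: private fixed differences (drift load), standing deleterious
variation (mutational load), linkage disequilibrium along the chromosome,
and between-burn-in stochasticity. It does not emulate neutral sequence
variation (no neutral mutations are simulated), variation in mutation or
recombination rate along the genome, new structural variants, demography
beyond the single bottleneck, or any form of balancing selection other than
AOD itself (no frequency dependence, no disassortative mating). Passing
tests therefore demonstrate internal consistency of the model and
faithfulness to its stated dynamics — not that real supergene systems,
which experience all of the above, will quantitatively match.

The fixture module (`make_population()`, `make_balanced_lethal_fixture()`,
`make_divergent_pair()`) builds deterministic populations with known
karyotypes and loads so that every statistic has a closed-form check: for
example, a divergent pair with `k` symmetric private recessives of effect
`s` yields expected-pairing AOD `s' = 1 - (1+s)^k` exactly after admixture.
The same construction supplies controlled AOD *gradients* for dynamical
claims: per-replicate AOD estimates from a desk-scale population of a few
dozen haplotypes are noise-dominated (and `s' = min(s1', s2')` couples the
migrant's own quality into the estimate with the opposite sign), so the
AOD-helps-invasion property is tested against the constructed true `s'`
levels run through the full bottleneck/admixture dynamics, rather than by
stratifying on a noisy self-estimate.

## Known limitations

* Small-`N` desk runs resolve the polymorphism quickly (drift time scales
  with `N`), so long-persistence phenomena are tail events that require
  large replicate counts rather than long runs. At full scale the
  degeneration end states (half-lethal, balanced lethal) occur at
  frequencies of roughly 10^-4 to 10^-2 and were characterized from 10^5
  replicates per parameter set; no desk-scale replicate budget reaches
  that regime from evolved burn-ins, so those specific occurrence claims
  are outside what the test suite can confirm.
* The size-dependence of the end states does not survive aggressive
  rescaling. At full scale, balanced lethals need small populations
  (purifying selection too weak to break symmetric degeneration) while
  half-lethals need large ones (efficient purging snowballs an asymmetry).
  At `Q = 100` with an enriched symmetric high-load profile, the package's
  own experiments show the direction *inverting*: the smallest scaled cells
  (N of a few) lose the polymorphism before any degeneration can happen,
  while mid-sized cells (N = 25) persist and degrade symmetrically to
  balanced lethality almost deterministically — because scaled mutations
  are individually lethal and purging at 2N = 50 cannot oppose them. The
  mechanisms (sheltered accumulation, purging differential, persistence
  thresholds) are all present, but their balance point moves with `Q`;
  conclusions about which sizes produce which end state must come from
  near-unscaled runs.
* The expected-pairing fallback is itself an estimator; for very small
  arrangement counts it enumerates all pairs (deterministic), but with a
  single haplotype of an arrangement it must pair the haplotype with
  itself, which overstates homozygosity of rare recent variants.
* Only two chromatids per meiosis are modelled (no four-strand
  bookkeeping), one gamete returned per meiosis; crossover interference is
  absent beyond Poisson counts.
* Generations are discrete and non-overlapping; there are no sexes and no
  spatial structure.
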