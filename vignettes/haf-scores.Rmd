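---
title: "HAF scores: model, expectations, and carrier prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HAF scores: model, expectations, and carrier prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hafscore)
```

## The statistic

A sample of `n` phased haplotypes typed at `S` biallelic sites, polarized
against an outgroup so that 0 is ancestral and 1 is derived, is the
universal input (`hap_matrix`). Sites monomorphic in the sample carry no
information for the statistic and are removed first. The HAF vector of a
haplotype replaces each derived allele it carries with that allele's
derived count `w` in the sample (an integer in `1..n-1`, never a
proportion — all score arithmetic stays exact), and the ℓ-HAF score is the
sum of the ℓ-th powers of those entries. ℓ = 1 everywhere by default; the
ℓ-th-root transform `haf_root()` is provided for comparing different ℓ.

Two identities anchor the implementation and its tests. First, the sample
mean of the ℓ-HAF scores equals `(1/n) Σ_w ξ_w w^{ℓ+1}` where `ξ_w` is the
site frequency spectrum — checked exactly on random matrices. Second, on a
non-recombining genealogy the score of every haplotype decomposes by epoch:
while exactly `k` ancestral lineages exist, those lineages cut the sample
into `k` clades, and a haplotype's score is `Σ_k m_k w_k^ℓ` over the
mutation counts `m_k` and clade sizes `w_k` along its root path
(`genealogy_epoch_decomposition()` reconstructs every score exactly from
the recorded genealogy).

## Expected scores

**Constant population size.** With `E[ξ_w] = θ/w` under the neutral
coalescent, `E[ℓ-HAF] = (θ/n) Σ_{w<n} w^ℓ`, i.e. `θ(n−1)/2` for ℓ = 1 and
`θ(n−1)(2n−1)/6` for ℓ = 2 (`expected_haf_constant()`). Here
`θ = 2NμL` is the scaled mutation rate of the whole window for a haploid
population of size `N`; the expected pairwise coalescence time is `N`
generations.

**Clade-size moments.** Because the topology of a neutral genealogy is
independent of its branch lengths, mutation counts and clade sizes
separate, and the clade-size moments are purely combinatorial:
`E[W^{(ℓ)}] = ℓ! n^{(ℓ)}/k^{(ℓ)}` in rising factorials
(`expected_clade_rising()`), converted to ordinary moments with Stirling
numbers of the second kind (`expected_clade_moment()`, recurrence
`S(ℓ,q) = q S(ℓ−1,q) + S(ℓ−1,q−1)` computed exactly). These are verified
against exhaustive enumeration of all labeled coalescent topologies for
`n ≤ 5` and against topology simulation for a third moment.

**Exponential growth.** For current size `N0` growing at rate `r`
(`α = 2N0 r` scaled), only the epoch durations change. Working backward
from `k = n` to `k = 2` and conditioning each epoch on the (expected)
later ones gives

`t_k = (1/r) e^{x_k} E1(x_k)`, with `x_k = k(k−1) e^{r τ_k} / α` and
`τ_k = t_{k+1} + … + t_n`,

where `E1` is the exponential integral (`epoch_times_exponential()`).
Combining `E[M_k] = μ t_k` with the Stirling-number expansion of the
clade moments yields `expected_haf_exponential()`; the result depends only
on (θ, n, α). At θ = 48, n = 200, α = 80 it evaluates to
`r round(expected_haf_exponential(demography(48, 200, alpha = 80)), 4)`,
and as α → 0 it recovers the constant-size closed form.

Two numerical points deserve note. `E1` appears multiplied by `e^x` at
arguments spanning many orders of magnitude, so the package evaluates
`e^x E1(x)` directly: a power series below `x = 1`, a modified-Lentz
continued fraction above — finite and accurate even at `x = 1e8`, where
forming `exp(x)` and `E1(x)` separately would overflow and underflow. And
the recursion is a plug-in approximation (later epochs enter at their
expectations, not their distributions): direct simulation of
growth-coalescent epoch times shows a systematic bias of about one percent,
which is why tests compare epoch times at 3% relative tolerance rather
than at Monte-Carlo standard-error resolution.

**Sweep phase.** When a fraction ν of the sample carries the favored
allele of a strong hard sweep (`Ns ≫ 1`, no recombination), the expected
carrier and non-carrier 1-HAF scores are approximately
`θn(ν + 1/2 − 1/((1−ν)n+1))` and `θn(1/2 + 1/(2n) − 1/((1−ν)n+1))`
(`expected_haf_carrier()`, `expected_haf_noncarrier()`); their difference
`θn(ν − 1/(2n))` grows through the sweep. The peak of the expected carrier
score over the sweep is `θn(1 − 1/(2n))² ≈ θn` (`haf_peak()`),
independent of the selection coefficient. The peak formula comes from an
exact treatment and is deliberately *not* forced to agree with a numeric
maximization of the carrier approximation: the approximation overshoots
near its maximum (its analytic max is ≈ 1.31·θn at ν ≈ 1 − (√n−1)/n,
which would contradict both the peak formula and simulation). Our forward
simulations, and an independent structured-sweep coalescent
cross-check, track the carrier curve closely for ν up to ≈ 0.3–0.5 and
fall below it at higher ν, where drift fixes hitchhikers and removes them
from the polymorphic pool; the package therefore treats the carrier
formula as a low-to-mid-ν approximation.

## Simulators

**Neutral coalescent** (`sim_neutral()`): epoch durations exponential with
rate `k(k−1)/(2N)` per generation at constant size; under growth the same
process through the deterministic time rescaling, so a waiting time is
`(1/r)·log(1 + E·α e^{−rτ}/(k(k−1)))` with `E ~ Exp(1)`. Mutations are an
infinite-sites Poisson process at rate `θ/(2N)` per lineage per
generation, placed uniformly on branches and uniformly on the 50 kb
window (collisions redrawn); genealogies can be recorded for the epoch
decomposition. Everything is reproducible from a seed.

**Recombination backend.** The internal engine is non-recombining;
re-implementing the ancestral recombination graph would be out of
proportion to its role here, since recombination leaves expected HAF
scores unchanged and only shrinks their variance (marginal genealogies
along the window partially average out). Samples with ρ > 0 are generated
by the bundled msprime driver through the system `python`, exchanged as
ms-format text, and scored entirely in R. Rates follow the same
conventions (`ρ = 2N r_bp L`).

**Forward Wright–Fisher sweeps** (`sim_sweep_forward()`): a haploid
population of `N` genomes with multiplicative viability selection —
carriers of the favored allele have fitness `1 + s/2`, half the diploid
homozygote advantage, matching the heterozygosity-0.5 convention for
phased data. Each generation brings Poisson(θ/2) new mutations and,
when ρ > 0, single-crossover recombination at per-meiosis rate ρ/(2N).
The initial population is one neutral coalescent sample of `N` genomes,
so the sweep acts on equilibrium standing variation without a long
burn-in; `ν0 N` copies of the favored allele (1 for a hard sweep) are
planted at onset. Trajectories that lose the allele are conditioned away:
at ρ = 0 the favored-allele count is a one-locus Markov chain independent
of the linked neutral variation, so the chain is drawn first with
restart-on-loss (cheap) and the population is then evolved once along the
successful trajectory; at ρ > 0 the full simulation restarts directly.
Restart counts are reported. Samples of `n` haplotypes are drawn without
replacement the first time each requested population frequency is
crossed, with carrier truth read off the favored site.

What the generator emulates: equilibrium standing variation, hitchhiking,
drift, new mutation during the sweep, and (optionally) crossover within
the window. What it does not: gene conversion, multi-origin soft sweeps
(only standing-variation soft sweeps via `ν0 > 1/N`), background
selection, population structure, and sequencing/phasing error — so
passing tests speak to the model, not to the full messiness of real data.

## PreCIOSS

`predict_carriers()` computes ℓ-HAF scores, fits a two-component 1-D
Gaussian mixture by EM, assigns each haplotype to its maximum-posterior
component, and labels the higher-mean component "carrier". EM details the
procedure leaves open were fixed as follows and surfaced as arguments:
5 restarts, the first initialized deterministically by splitting scores at
the median and the rest from random responsibilities; convergence at
relative log-likelihood change `1e-6` or 500 iterations; a variance floor
of `1e-6` times the sample variance so duplicated scores cannot collapse a
component; posterior ties assigned to the carrier side. When the component
means sit closer than twice the larger component SD, the two-cluster
assumption is unsupported and the prediction carries a `low_confidence`
flag — labels are still emitted, as on neutral data. Evaluation uses
balanced accuracy, `(TP/(TP+FN) + TN/(FP+TN))/2`, which stays informative
under the severe class imbalance of early and late sweeps, and a
two-sided Wilcoxon rank-sum test of carrier vs non-carrier scores
(exact for small tie-free groups through `stats::wilcox.test`).

## Data ingestion

ms-style text is the interchange format with the wider simulator
ecosystem (`read_ms()`/`write_ms()`, fractional positions scaled by a
window length, carrier truth in a JSON sidecar). Phased VCF windows are
read with vcfR and polarized against an explicit outgroup table (which
takes precedence) or the `AA` INFO tag; multi-allelic, unphased,
partially missing, or unpolarizable sites are dropped and counted in a
log line, and with no ancestral source at all the reader refuses rather
than guessing polarity. Windows default to 50 kb centered on a focal
coordinate. Coordinates are 1-based inclusive at the VCF boundary.

## Problem sizes and reproducibility

The test suite runs the stochastic checks at desk scale with
standard-error-based bands, so they remain statistically valid at these
sizes: 2000 replicates for the constant-size and growth simulation means,
600 for the recombination comparison, 50 sweep trials for the carrier
curve, 60 per selection coefficient for the peak, 30 sweeps for
classifier recovery, 2000 trees for the exact decomposition check, and
2000 permutations for the rank-sum calibration. `scripts/acceptance.R`
rebuilds the headline quantities at 20000/20000/10000 replicates from a
single `--seed`. All simulators consume the R RNG stream (the msprime
backend is seeded from it), so identical seeds give identical output.

## Known limitations

The growth expectation inherits the ~1% plug-in bias of the epoch
recursion; the sweep-phase carrier/non-carrier formulas are
strong-selection, no-recombination approximations that degrade above
ν ≈ 0.5 and near fixation; the variance of ℓ-HAF is not provided (only
means); and arbitrary piecewise demographies beyond constant size and
exponential growth are out of scope, though externally simulated data for
such models can be scored through `read_ms()`.
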