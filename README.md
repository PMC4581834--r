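# hafscore

Haplotype allele frequency (HAF) scores and carrier prediction for ongoing
selective sweeps.

When a favored allele rises through a population, the haplotypes that carry
it drag linked ("hitchhiking") variants to high frequency. The HAF framework
turns that signature into a per-haplotype statistic: write each of the `n`
sampled haplotypes as a binary vector over the `S` sites that are
polymorphic in the sample (0 = ancestral, 1 = derived), replace every
derived allele by its derived count `w` in the sample, and sum the ℓ-th
powers of the entries:

    ℓ-HAF(h) = Σ_j c_j^ℓ,   c_j = w_j if haplotype h carries site j, else 0

with ℓ = 1 the default. Carriers of an ongoing sweep accumulate
high-frequency hitchhikers and hence high 1-HAF scores; the sample mean
depends on the data only through the site frequency spectrum ξ_w:
`mean = (1/n) Σ_w ξ_w w^{ℓ+1}`.

The package provides:

* **Scoring** — `hap_matrix()`, `filter_polymorphic()`, `haf_vectors()`,
  `haf_score()`, `site_spectrum()`, `mean_haf_from_spectrum()`.
* **Theory** — expected ℓ-HAF under neutrality at constant size
  (`expected_haf_constant()`: `θ(n−1)/2` for ℓ = 1), under exponential
  growth (`expected_haf_exponential()`, via the conditional-expectation
  epoch-time recursion `t_k = (1/r) e^{x_k} E1(x_k)` with
  `x_k = k(k−1)e^{rτ_k}/α` and a Stirling-number expansion of the clade-size
  moments), and during a sweep (`expected_haf_carrier()`,
  `expected_haf_noncarrier()`, `haf_peak()` ≈ θn).
* **Simulators** — a neutral coalescent engine with genealogy recording
  (`sim_neutral()`, constant size or exponential growth; ρ > 0 through an
  msprime backend), epoch decomposition (`genealogy_epoch_decomposition()`),
  and a forward Wright–Fisher sweep simulator with carrier ground truth
  (`sim_sweep_forward()`).
* **PreCIOSS** — `predict_carriers()` fits a two-component Gaussian mixture
  to the ℓ-HAF scores by EM and labels the higher-mean component "carrier";
  `balanced_accuracy()`, `carrier_separation_test()` and
  `evaluate_prediction()` score predictions against known truth.
* **I/O** — ms-style simulator text (`read_ms()`/`write_ms()`), phased VCF
  windows with ancestral-allele polarization (`read_vcf_window()`), TSV/JSON
  score tables (`write_scores()`), and a thin `haf` command-line wrapper
  (`exec/haf`) with `score`, `expect`, `simulate` and `precioss`
  subcommands.

## Worked example

```r
library(hafscore)

dem <- demography(theta = 48, n = 200)      # scaled mutation rate, sample size
expected_haf_constant(dem)
#> [1] 4776
expected_haf_exponential(demography(theta = 48, n = 200, alpha = 80))
#> [1] 126.8616

set.seed(1)
s <- sim_neutral(dem, reps = 1)[[1]]
s
#> <hap_matrix> 200 haplotypes x 385 sites
#>   positions: 32.8174 .. 49,771.28 bp
summary(haf_score(s)$score)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>    3242    5342    9226    7600    9307    9364
```

The neutral expectation 4776 = θ(n−1)/2 is the reference level a single
sample's mean fluctuates around (here 7600 — per-sample variation is large
because all haplotypes share one genealogy). Under fast growth (α = 80) the
genealogy is star-like and the expectation collapses to ≈ 127.

Carrier prediction on a simulated hard sweep, sampled when the favored
allele reaches 60% of a population of 2000:

```r
dem2 <- demography(theta = 48, n = 100, N = 2000)
res  <- sim_sweep_forward(dem2, sweep_params(s = 0.05),
                          sample_nu = 0.6, reps = 1, seed = 7)
pred <- predict_carriers(res[[1]]$samples[[1]], seed = 7)
tidy(attr(pred, "fit"))
#> # A tibble: 2 × 4
#>   component    mean     sd weight
#> 1 non-carrier  541. 394.    0.402
#> 2 carrier     1315.   6.60  0.598
evaluate_prediction(pred)
#> # A tibble: 1 × 7
#>      tp    fp    tn    fn balanced_accuracy single_class wilcoxon_p
#> 1    60     0    40     0                 1 FALSE          1.98e-17
```

The tight high-mean component is the swept clade; here every one of the 60
true carriers is recovered (balanced accuracy 1.0) and the Wilcoxon
rank-sum test rejects identical carrier/non-carrier score distributions at
p ≈ 2e-17.

The same pipeline runs from a shell:

```sh
haf expect --theta 48 --n 200
haf simulate sweep --theta 48 --n 200 --N 2000 --s 0.05 \
    --sample-nu 0.6 --seed 9 --out sweep.ms
haf precioss --in sweep.ms --truth sweep.ms.truth.json --out scores.tsv
```

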