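# aflpsgs

Population genetics and fine-scale spatial genetic structure (SGS) for
**dominant markers** (AFLP-style band presence/absence data), in R.

Dominant markers show a band whenever at least one amplifiable allele is
present, so only the band-absent fraction of a sample — an estimate of the
null-homozygote proportion `z = q²` — is observable per locus. `aflpsgs`
carries that one-sided information through the complete analysis chain used
in studies of natural plant populations:

* **Allele frequencies** — empirical-Bayes estimation with a non-uniform
  Beta prior on `z` fitted across loci by noise-corrected moments; the
  null-allele frequency estimate is the posterior mean
  `q̂ = B(a+m+½, b+n−m)/B(a+m, b+n−m)`.
* **Diversity** — Nei gene diversity `H_E`, percentage of polymorphic loci,
  and the partition `Ht = Hw + Hb`; Nei (1972/1978) distances between
  populations.
* **Structure** — one-level AMOVA (Excoffier sums of squares from phenotype
  distances, Φ_ST with a permutation test), Wright's `F_ST` from
  across-population frequency variance with a multilocus permutation
  G-test, and a Mantel test of isolation by distance.
* **SGS within populations** — pairwise kinship for dominant phenotypes
  under an assumed inbreeding coefficient,
  `F̂_ij = Σ_l (x_il−B_l)(x_jl−B_l) / Σ_l 4 p_l q_l h_l²` with
  `h = F_IS + (1−F_IS) q` and `B = 1 − q h`; distance-class correlograms
  with permutation envelopes; the regression slope `b_F` of kinship on
  ln(distance); `Sp = −b_F/(1−F_1)`; Wright's neighbourhood size
  `N_b = (F_1−1)/b_F`; and gene-dispersal distances
  `σ_g = √(N_b/(4π D_E))` under census density and reduced effective
  densities (1/2, 1/4, 1/10).
* **Simulators with known truth** — a Balding–Nichols island model
  (`simulate_clustered`) and a forward-time isolation-by-distance model on
  a torus (`simulate_spatial`), so every estimator is testable without
  external data.

See the vignette (`vignettes/dominant-marker-sgs.Rmd`) for the models,
assumptions, numerical choices and limitations.

## Worked example

Simulate six diverged populations typed at 400 dominant loci, then run the
whole pipeline from one configuration:

```r
library(aflpsgs)

sim <- simulate_clustered(n_populations = 6, n_individuals = 30,
                          n_loci = 400, theta_div = 0.2, seed = 42)
cfg <- run_config(markers = sim$markers, samples = sim$samples,
                  densities_per_ha = c(P01 = 8.19, P02 = 8.19, P03 = 8.19,
                                       P04 = 8.19, P05 = 8.19, P06 = 8.19),
                  n_perm = list(sgs = 999, fst = 999, amova = 499, mantel = 999),
                  seed = 42)
report <- run_all(cfg)
report$amova
#> AMOVA (one level)
#>          df     SSD    MSD variance  pct
#> between   5 2819.37 563.87   17.125 25.5
#> within  174 8723.03  50.13   50.132 74.5
#> Phi_ST = 0.255  p = 0.002 (499 permutations)
report$fst
#> Fst = 0.173  G = 16367.34  p = 0.001 (999 permutations)
summarize_across_populations(report)$mean_HE
#> [1] 0.3523398
```

The AMOVA splits phenotype variance between (25.5%) and within (74.5%)
populations; Φ_ST = 0.255 is its fixation index and the permutation p-value
(add-one rule) is the smallest achievable at 499 permutations, i.e. the
planted divergence is detected. The allele-frequency `F_ST` (0.173) sits
below Φ_ST, the expected pattern for dominant data (see the vignette). Mean
`H_E` is the unweighted average gene diversity across the six populations.

For a single population with spatial structure:

```r
sp <- simulate_spatial(extent = 300, density = 0.01, sigma_s = 10.3,
                       sigma_p = 10.3, generations = 100, n_loci = 300,
                       n_sample = 200, seed = 5)   # true N_b ≈ 20
fr  <- population_freqs(sp$markers, sp$samples$pop)[["SIM"]]
K   <- kinship_dominant(sp$markers, fr, f_is = 0)
D   <- pairwise_geo_distances(sp$samples)
fit <- fit_sgs(K, D, n_perm = 999, seed = 5)
c(F1 = fit$F1, b_F = fit$b_F, Sp = fit$Sp, significant = fit$b_F_significant)
#>          F1         b_F          Sp significant
#>  0.05872198 -0.03035253  0.03224608  1.00000000
dispersal_estimates(fit$F1, fit$b_F, census_density_per_ha = 100)$N_b
#> [1] 31.01152
```

The first-class kinship (`F1`), the negative log-distance slope (`b_F`,
outside its 95% permutation envelope) and `Sp` quantify the spatial
structure. The implied neighbourhood size (31.0) sits well above the
simulation's truth of 20 — a systematic overshoot of this estimator when
the sampled stand spans only a handful of genetic neighbourhoods, which the
vignette quantifies and explains. SGS *detection* is reliable in this
regime; absolute dispersal estimates lean high.

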