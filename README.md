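# microca

Monte Carlo modeling of cell-nucleus microdosimetry and chromosome
aberrations for high-energy ion beams, with the energy deposition split
into **direct** (ion tracks crossing the nucleus) and **indirect** (delta
electrons of tracks that miss it) contributions.

The package is aimed at radiation biophysicists studying radiation
quality: how the linear energy transfer (LET) and the tissue-transported
spectrum of an ion beam shape stochastic energy deposition in a cell-sized
target, and how that maps onto simple and complex chromosome exchanges.

## What it computes

For a spherical nucleus (radius 4 µm) in a periodic box irradiated by a
mono-energetic beam or a poly-energetic fluence spectrum:

1. **Track surrogate** — primary chords (Poisson in fluence
   `Φ = D / (0.1602·LET)`), discrete core energy depositions plus delta
   electrons with a `1/T²` knock-on spectrum, transported as a condensed
   random walk with periodic boundary conditions;
2. **Microdosimetry** — per-track imparted energies ε, single-ion spectra
   `f(ε)` and the direct/indirect dose fractions;
3. **Damage** — nanometric dose scored in 20 nm voxels, intersected with a
   46-fiber random-walk interphase chromatin model; DSBs Poisson-sampled
   per voxel (`λ = k·E`, calibrated to ~35 DSB/cell/Gy), complex above
   500 eV;
4. **Repair** — 24 h of first-order rejoining (τ = 1.7 h simple, 23.7 h
   complex) with distance-dependent misrepair of complex breaks (Gaussian
   proximity kernel);
5. **Aberrations** — simple exchanges (2 breaks, 2 chromosomes) and
   complex exchanges (>2 breaks, ≥2 chromosomes) per cell;
6. **Statistics** — linear-quadratic dose-response fits
   `y(D) = αD + βD²` by parametric bootstrap with 95% prediction bands,
   and the containment/Kolmogorov–Smirnov comparison measures
   `m_i→j`, `m_j→i`, `m_KS` integrated over 0–1 Gy.

Six reference beams ship with the package (H 1000 MeV … Fe 1000 MeV/n,
LET 0.22–149.2 keV/µm), as does a synthetic generator for
tissue-transported poly-energetic spectra.

## Worked example

```r
library(microca)
set.seed(42)

b <- reference_beam("O")            # O-16, 325 MeV/n, LET 21.5 keV/um
pool <- chromatin_pool(2)           # interphase chromatin configurations
cal <- calibrate_k(histories = 100, pool = pool)

cfg <- run_config(b, doses = c(0.1, 0.25, 0.5, 0.75, 1), histories = 150,
                  contributions = c("tot", "dir", "ind"), seed = 7,
                  break_params = break_model_params(k = cal$k),
                  n_draws = 1000)
bundle <- run_experiment(cfg, pool = pool)
bundle
#> <result_bundle>
#>   beam: O 325 MeV/n (LET 21.5 keV/um)
#>   doses: 0.1, 0.25, 0.5, 0.75, 1 Gy, 150 histories each
#>   tot/simple: mu_alpha=0.07943 mu_beta=0.1405 R2=0.983
#>   tot/complex: mu_alpha=0.02893 mu_beta=0.3268 R2=0.972
#>   dir/simple: mu_alpha=0.1173 mu_beta=0.00638 R2=0.989
#>   ...
bundle$comparisons
#>   endpoint m_t_to_di m_di_to_t     m_ks
#> 1   simple   0.80013   0.84393 0.311615
#> 2  complex   0.80877   0.82252 0.336025
```

The fits say the O beam produces ~0.22 simple and ~0.36 complex exchanges
per cell at 1 Gy (αD + βD² at D = 1) at these scaled-down history counts,
and the comparison rows say the total response is statistically close to
the sum of the separately simulated direct and indirect responses
(containment around 0.8, `m_KS` around 0.3 at these history counts).

Microdosimetry from the same machinery:

```r
run <- simulate_aberrations(b, 1, 100, "tot",
                            break_params = break_model_params(k = cal$k),
                            pool = pool)
100 * run$energy[["ind"]] / sum(run$energy)
#> 18.8      # percent of nucleus energy from indirect (delta-only) tracks
mean(run$n_dsb)
#> 34.1      # DSB per cell at 1 Gy (calibration target 35)
```

Lower-level module surfaces (`sample_irradiation()`, `score_events()`,
`generate_chromatin()`, `induce_breaks()`, `simulate_repair()`,
`classify_exchanges()`, `fit_lq()`) are exported and documented
individually; the vignette in `vignettes/` explains the model and every
calibrated constant.

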