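# aapflux

Quantifying how photoheterotrophy by aerobic anoxygenic phototrophic (AAP)
bacteria modulates the carbon fluxes of a freshwater lake.

AAP bacteria harvest light with bacteriochlorophyll-a reaction centers
(absorption maximum near 870 nm) and use the photochemically generated ATP
to spare respiration and boost anabolism. Because infrared light (>740 nm)
is usable by those reaction centers but not by oxygenic phototrophs,
paired **dark vs infrared (IR)** bottle incubations isolate the
photoheterotrophic contribution of AAP bacteria to whole-community
metabolism. `aapflux` implements the complete desk side of such a study
for limnologists and aquatic microbial ecologists:

- **Winkler chemistry** — thiosulfate standardization against KIO3
  (1 IO3⁻ ≡ 6 S2O3²⁻), dissolved O2 from titrant volumes
  (1 O2 ≡ 4 S2O3²⁻) with reagent-displacement volume correction, and
  respiration / net primary production (NPP) rates from T0 vs end-point
  bottles with Welch t intervals.
- **Carbonate system** — total alkalinity by Gran linearization
  F(Va) = (V0+Va)·10^(−pH), freshwater equilibrium constants K1(T), K2(T),
  Kw(T), and DIC = CA·(1 + h/K1 + K2/h)/(1 + 2K2/h) with full speciation.
- **Radiotracer rates** — ³H/¹⁴C monomer assimilation from scintillation
  DPM with killed-control subtraction, and fractionated H¹⁴CO3⁻
  incorporation scaled by ambient DIC.
- **Light-effect inference** — random-intercept linear mixed models
  y_ij = x_ijᵀβ + b_j + ε_ij (date as the random intercept), fitted by
  maximum likelihood through a profiled one-dimensional optimization,
  tested by likelihood-ratio ANOVA, summarized as percent differences
  with 95% CIs, plus light × covariate interaction fits.
- **Community analysis** — rare-ASV prevalence filtering, a
  negative-binomial variance-stabilizing transform (common dispersion),
  Bray-Curtis dissimilarities, distance-based linear models (DistLM) with
  pseudo-F permutation tests and adjusted-R² forward selection, and dbRDA
  ordination.
- **Lake CO2 budget** — photoperiod from solar declination, daily IR
  respiration weighted by light time
  (R_IR·L + R_dark·(24−L)), trapezoidal integration over the 180-day warm
  season, and upscaling to grams of CO2 for the 0.5 m surface layer of a
  1.16 km² lake at a respiratory quotient of 1.
- **Synthetic-data generator** — bottle-level tables with known ground
  truth (multiplicative IR effects, date-level random intercepts,
  titration and Poisson counting noise, Dirichlet-multinomial count
  matrices covarying with temperature and AAP abundance) so every stage is
  testable without any external download.

## Worked example

```r
library(aapflux)
study <- simulate_study(sim_config(seed = 1))   # two seasons, 16 dates, triplicates
res   <- run_pipeline(study, seed = 1, n_perms = 999)
print(res)
```

```
Light-effect summaries (percent difference vs dark reference):
       analyte percent ci_lo ci_hi      direction  p_value  n n_dates
1 CO2_fixation    1.96 -1.36  5.29   higher in IR 2.49e-01 96      16
2      glucose   17.08 14.35 19.81   higher in IR 3.56e-20 96      16
3      leucine    7.43  5.19  9.67   higher in IR 5.59e-09 96      16
4     pyruvate    9.91  7.61 12.21   higher in IR 8.97e-13 96      16
5  respiration   14.17 11.51 16.84 higher in dark 1.22e-16 96      16
6    thymidine   10.65  8.09 13.21 higher in dark 3.54e-12 96      16
Seasonal dark - IR CO2 difference: 5.749e+06 g over 2 season(s)
Community DistLM marginal tests:
    predictor pseudo_f explained_pct     p
1 temperature    3.140         18.32 0.001
2         aap    3.217         18.69 0.001
3        null    0.981         6.55  0.439
```

The generator's true IR effects are −15.2% on respiration and +18.1%,
+9.5%, +5.9% on glucose, pyruvate and leucine; this single realization
estimates 14.2%, 17.1%, 9.9% and 7.4% — each interval covering its truth —
while CO2 fixation (true effect 0) stays non-significant and the null
community covariate is rejected at chance level. The seasonal figure is
the CO2 overestimate that dark-only respiration measurements would have
produced for the simulated lake's surface layer over the two seasons.

The `analysis/` directory holds the same workflow as numbered stages
(`01_simulate.R` … `05_community.R`), each writing its tables under
`results/` with provenance headers.

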