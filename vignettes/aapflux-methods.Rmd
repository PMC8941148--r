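---
title: "Methods: from bottle incubations to a lake CO2 budget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from bottle incubations to a lake CO2 budget}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aapflux)
```

# The scientific problem

Community respiration in lakes is conventionally measured in the dark, on
the assumption that heterotrophic metabolism is light-independent. Aerobic
anoxygenic phototrophic (AAP) bacteria violate that assumption: their
bacteriochlorophyll-a reaction centers (absorbing near 870 nm) produce ATP
photochemically, which spares respiratory catabolism and redirects organic
carbon to anabolism. Incubating bottles behind a filter that passes only
infrared light (>740 nm) creates conditions that the whole community
except AAP bacteria perceives as darkness, so paired dark/IR incubations
quantify the photoheterotrophic term directly. `aapflux` covers every
computational step of such a study: titration chemistry, tracer
bookkeeping, mixed-model inference on the light effect, community
modelling, and the upscaling of the dark-vs-IR respiration difference to a
whole-lake seasonal CO2 budget.

# Rate derivation

## Winkler oxygen

Dissolved O2 follows from the iodometric stoichiometry (1 mol O2 fixes
iodine equivalent to 4 mol thiosulfate):

$$[\mathrm{O_2}] = \frac{V_t \, c_{thio} / 4}{V_{bottle} - V_{displaced}} \times 10^6 \;\mu\mathrm{mol\,L^{-1}},$$

with the titrant standardized against a KIO3 standard
(1 IO3⁻ ≡ 6 S2O3²⁻). The effective volume subtracts the 2.4 mL of sample
displaced by the two fixing reagents — standard Winkler practice, applied
by default and toggleable, since only the fixing reagents (not the acid
added after fixation) displace live sample. Respiration is
(mean T0 − mean end)/h over the 24-h incubation; NPP is the reverse
difference for the light bottles. Negative respiration values are retained
with a warning rather than truncated, to avoid biasing the downstream
mixed models. Welch t-intervals describe per-date uncertainty — the conventional
unequal-variance default for difference-of-means estimates.

## Carbonate system and DIC

Total alkalinity comes from Gran linearization of the acid titration,
$F(V_a) = (V_0 + V_a)\,10^{-\mathrm{pH}}$, an OLS line through the points
past the carbonic-acid equivalence (pH < 4.5 by default; the cutoff is a
configuration choice, and recovery is accurate to <0.5% provided the
titration proceeds well past the equivalence volume, which the simulator
and any sensible protocol do). DIC then follows from temperature, pH and
TA with zero-ionic-strength freshwater constants — Plummer & Busenberg
fits for K1 and K2, the Harned & Owen/Millero refit for Kw — appropriate
for an oligotrophic seepage lake where ionic-strength corrections are
negligible. The measured pH is treated as a free-proton activity; the pH
scale of the field instrument is not recoverable, and at freshwater ionic
strengths the distinction is far below the other uncertainties.

## Radiotracers

Monomer assimilation converts killed-control-corrected DPM through the
specific activity (1 GBq mmol⁻¹ = 6×10⁴ DPM nmol⁻¹), the sample volume and
the incubation time. Killed-control subtraction floors at zero with a
warning, since Poisson counting noise can invert small signals. Carbon
units multiply the molar rate by the substrate's carbons per molecule
(glucose 6, pyruvate 3, leucine 6, thymidine 10); whether published
"nmol C" rates include that factor is not recoverable from most papers'
text, so both conventions are supported (`carbon_units = FALSE` reports
molar units). Bicarbonate incorporation converts each filtration
fraction's per-litre activity into a fraction of the added label, scales
by ambient DIC and the incubation time, and sums the fractions; differing
filtration volumes (30 mL coarse filter, 5 mL refiltrate, 1 mL
total-activity aliquot) enter as per-fraction volume factors.

# The light-effect model

Bottle-level rates enter untransformed, replicates as individual rows:

$$y_{ij} = \beta_0 + \beta_1\,\mathrm{IR}_{ij} + b_j + \varepsilon_{ij},
\qquad b_j \sim N(0, \sigma_d^2),\; \varepsilon_{ij} \sim N(0, \sigma^2),$$

with the sampling date $j$ as a random intercept. Estimation is maximum
likelihood (REML available) via the profiled likelihood over
$\lambda = \sigma_d^2/\sigma^2$: at each $\lambda$ the GLS coefficients
and the residual variance are closed-form, leaving a one-dimensional
optimization that is fast and free of convergence tuning. The treatment
term is tested by likelihood-ratio ANOVA against the nested model on a
$\chi^2_1$ reference (an F variant would require a denominator-df
convention; the χ² choice matches ML likelihood-ratio practice and its
type-I error is verified by simulation in the tests). The effect is
reported as a percent difference relative to the model-implied dark mean,
$100\,|\beta_1|/\beta_0$, with the interval obtained by scaling the Wald
interval of $\beta_1$ by the same factor — the simplest construction
consistent with percent-difference reporting; a delta-method variant would
additionally propagate the uncertainty of $\beta_0$, which is negligible
here because the reference mean is estimated from all dates.

Noise-free data (zero residual variance) make the ML likelihood
unbounded; the fitter detects this and returns the exact least-squares
solution with zero variances instead of failing, which keeps fully
deterministic simulations usable end to end. Designs with one observation
per date leave $\sigma_d^2$ and $\sigma^2$ confounded and are rejected
with an explicit identifiability error.

Interaction models `rate ~ light * log10(x)` with the same random
intercept report per-level intercepts and slopes; an interaction is
flagged when the likelihood-ratio test against the additive model gives
p < 0.05.

# Community composition

Rare ASVs are removed unless their count strictly exceeds 3 in at least
20% of samples. Counts are then variance-stabilized: median-of-ratios
size factors, a single common dispersion estimated by the method of
moments on normalized counts, and the closed-form transform of the
constant-dispersion negative-binomial family,
$f(x) = \log_2\!\big(1 + 2\alpha x + 2\sqrt{\alpha x(1+\alpha x)}\big) -
\log_2(4\alpha)$, which approaches $\log_2 x$ for large counts. This is a
deliberate re-derivation of the common-dispersion case rather than a port
of any reference implementation; its stabilizing behaviour is verified as
a property (variance flat within 25% across a 10-fold mean gradient),
not bit-for-bit. Under-dispersed inputs fall back to $\log_2(x/s + 1)$
with a warning. Negative transformed values are clipped to zero before
Bray-Curtis, which requires non-negative abundances.

DistLM partitions the Gower-centered inner-product matrix
$G = -\tfrac12 J (D \circ D) J$ against predictor hat matrices:
pseudo-F = [tr(HGH)/m] / [tr((I−H)G(I−H))/(n−m−1)]. Marginal tests
permute sample labels without restriction; sequential tests during
forward selection use Freedman–Lane residual permutation under the
reduced model — the commercial implementation used in many studies does
not document its scheme, so these two standard choices are stated
explicitly and validated distributionally (exact enumeration at n = 5,
type-I rate within [2%, 9%] at n = 200 null replicates). Forward
selection maximizes adjusted R² (AIC available). dbRDA is the
eigen-decomposition of HGH with scores scaled by the square roots of the
eigenvalues and biplot vectors as predictor–axis correlations.

# The seasonal CO2 budget

Daylength comes from the Spencer declination series with the −0.833°
sun-altitude convention; measured sunrise/sunset times can override it as
data. Daily rates are NPP·L, dark respiration·24, and the
light-time-weighted IR respiration $R_{IR} L + R_{dark}(24-L)$ — the IR
effect only operates while there is light. Daily values are interpolated
linearly between sampling dates, constant-extended to the window edges,
and integrated by trapezoid over 180 days from the first sampling date
with water temperature above 10 °C (linear interpolation is the stated
choice where only "integration" is specified; a step-function alternative
gives the same order of magnitude). The integrated µmol O2 L⁻¹ convert to
grams of CO2 with a respiratory quotient of 1 (exposed as a parameter —
freshwater RQs are notoriously variable), the molar mass 44.01 g mol⁻¹
and the 5.8×10⁸ L volume of the 0.5 m surface layer of a 1.16 km² lake.
NPP is identical in the dark and IR scenarios and cancels exactly in
the dark-minus-IR difference.

With these stated parameters, a constant rate gap of 0.03 µmol O2 L⁻¹ h⁻¹
over 12 light hours and 180 days yields 1.65×10⁶ g CO2. Published
ecosystem figures of order 10⁹ g for comparable rate gaps are not
reconcilable with a 5.8×10⁸ L layer volume by these equations; the
implementation therefore reports every intermediate quantity (integrated
µmol L⁻¹, per-scenario grams, difference) so any scaling discrepancy
surfaces transparently rather than being absorbed.

# The synthetic-data generator

The generator is first-class, tested code that defines the study
conditions. Defaults: 16 sampling dates in two 28-day-spaced seasons
(mid-April onward), triplicate bottles per treatment per date, T0 oxygen
300 µmol L⁻¹, mean dark respiration 0.30 µmol O2 L⁻¹ h⁻¹ with a −15.2%
multiplicative IR effect, dark-mean monomer rates 0.55/12.67/0.36/0.12
nmol C L⁻¹ h⁻¹ (glucose/pyruvate/leucine/thymidine) with IR effects
+18.1/+9.5/+5.9/−8%, and CO2 fixation 0.06 µmol C L⁻¹ h⁻¹ with no IR
effect — the seasonal means and effect sizes typical of a temperate
meso-oligotrophic lake with an active AAP community. Rates
follow $y = (\mu_0 + b_j)(1 + e_t) + \varepsilon$: the treatment effect is
multiplicative on the date baseline (matching percent-difference
reporting and scale-free across substrates) and constant across dates by
default, with an optional per-date effect SD for heterogeneity
experiments. Between-date and within-date SDs (0.08 and 0.02 rate units
for respiration; 25% and 6% relative for tracers) are calibration
choices: field campaigns of this design rarely report variance
components, so they were set once to give a realistic seasonal spread
around the per-date means and mixed-model intervals a few points wide.

Titrant volumes are back-computed from target O2 concentrations through
the exact Winkler stoichiometry and perturbed by 0.001 mL reading noise;
Gran curves are generated by root-finding the proton condition along the
dilution-corrected titration and perturbed by 0.002 pH units; DPM are
Poisson draws around the target incorporation (a Normal approximation is
statistically indistinguishable above ~10⁴ DPM and Poisson sampling
remains cheap, so Poisson is simply always used when counting noise is
on). Configurations in which negative rates or titrant volumes would
occur with probability above 1% are rejected as unusable scenarios. All
randomness flows from one explicitly passed seed through a
state-preserving wrapper; the caller's RNG stream is untouched.

Count matrices are Dirichlet-multinomial: per-ASV baseline log abundances
(SD 1.2), per-ASV loadings on standardized temperature and AAP covariates
with global effect sizes, a null covariate always included, total
Dirichlet concentration θ = 300 and 20,000 reads per sample. The default
effect size 0.3 was calibrated once so that a single covariate explains
roughly a fifth of the Bray-Curtis variation, a realistic regime for
lake bacterioplankton, before any downstream assertion was written.

What the generator does *not* emulate: raw sequencing reads and their
processing, pigment signals, diel light curves, temporal autocorrelation
beyond the date random intercept, taxon-specific tracer uptake, or
phylogenetic structure among ASVs. Passing tests therefore demonstrate
that the computational chain is correct and well-calibrated under the
stated generative model, not that field data meet that model.

# Problem sizes and tolerances

The test suite uses the design sizes of the emulated study (16 dates × 3
replicates) for recovery checks: 200 seeds for the effect-recovery and
coverage bands (bias < 1.5 percentage points, coverage within 92–98%),
300–400 replicates for type-I checks of the LRT, 100–200 for DistLM
type-I/power, and exhaustive enumeration (120 permutations, 2500-point
likelihood grids) for the inference primitives. Chemistry round-trips are
held to 10⁻⁹ relative error, Gran recovery to 0.5%, speciation closure to
10⁻¹². These sizes keep the full suite under a few minutes on a single
core while leaving the Monte-Carlo bands comfortably away from their
thresholds.

# Known limitations

- The fixed-effect intervals are Wald intervals under ML; with few dates
  they can be slightly anticonservative (the simulated coverage stays
  within 92–98% at 16 dates).
- The VST's common dispersion ignores the mean-dispersion trend of real
  amplicon data; for resemblance-based analyses this is the intended
  fit-type, but gene-wise shrinkage methods are out of scope.
- The budget treats the surface layer as homogeneous and ignores gas
  exchange, sediment terms and within-day rate variation beyond the
  light-time weighting.
- The carbonate module is freshwater-only: no ionic-strength corrections,
  borate or nutrient alkalinity.
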