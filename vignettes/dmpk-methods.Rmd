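---
title: "Models and conventions behind dmpkr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions behind dmpkr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmpkr)
```

`dmpkr` packages the computations of a preclinical DMPK characterization
program — permeability and efflux, metabolic stability with
in-vitro-to-in-vivo extrapolation (IVIVE), CYP phenotyping and inhibition,
plasma-protein binding, non-compartmental pharmacokinetics, tissue
distribution and excretion mass balance. This vignette explains the models
each module implements, the conventions and numerical choices it commits
to, and what the synthetic-data generator does and does not emulate.

## Units and data model

Concentrations are canonicalized to µg/L (numerically identical to ng/mL;
tissue homogenate data in ng/g are treated as commensurate) and in-vivo
time to hours at the I/O boundary (`read_profiles()`); in-vitro incubation
time is in minutes. Doses are mg/kg. This single internal system exists
because in-vivo exposure tables routinely mix µg/L·h with L/h/kg, and a
silent factor-of-1000 error in a clearance is the classic failure mode; the
unit is a mandatory column in every input file and is never inferred.
`analysis_report()` refuses any numeric parameter without units.

Below-limit-of-quantification (BLOQ) values are retained and flagged, never
dropped. The policy consumers apply is the common NCA convention: values
before the first quantifiable point count as 0, BLOQ values after the peak
are kept as 0 for trapezoidal integration but are excluded from terminal
regressions.

## Transport and cytotoxicity

Receiver wells are repeatedly sampled and refilled with blank buffer, so
raw receiver concentrations understate transport. The corrected cumulative
amount is

$$Q(t_n) = C_n V_\mathrm{receiver} + \sum_{i<n} C_i V_\mathrm{sample},$$

which reduces to the naive $C_n V_\mathrm{receiver}$ when the sample volume
is zero. The correction is on by default and can be toggled off for
comparison — assay write-ups often leave unstated whether it was applied,
and the toggle makes the difference inspectable.

The apparent permeability is the least-squares slope of $Q$ versus time in
seconds over *all* sampled points (not a two-point difference), divided by
monolayer area (default 0.33 cm²) times donor concentration. A regression
is the noise-robust reading of the defining relation
$P_\mathrm{app} = (dQ/dt)/(A C_0)$ when six time points are sampled. Flags:
a non-positive slope floors $P_\mathrm{app}$ at 0; receiver concentrations
exceeding 10% of the donor violate the sink-condition linearity assumption;
an apical-to-basolateral $P_\mathrm{app}$ above 3×10⁻⁶ cm/s marks ready
blood–brain-barrier passage. The efflux ratio
$ER = P_\mathrm{app}^{B\to A} / P_\mathrm{app}^{A\to B}$ uses the
conventional 1.5 cutoff for calling a P-glycoprotein substrate, and is
censored (not 0, not infinite) when the denominator is zero.

TC50 estimation fits a four-parameter logistic of relative growth rate
against ln(concentration), with both asymptotes bounded to [0, 120]% —
viability assays produce occasional >100% wells, and unbounded asymptotes
make shallow curves unidentifiable. The reported TC50 is the concentration
at which the *fitted curve* crosses 50% RGR; if that crossing lies beyond
the tested range, or the fit does not converge, the result is censored at
the highest tested concentration rather than extrapolated.

## Microsomal stability and IVIVE

Depletion is modeled as first order: $k_e$ is minus the slope of
ln(remaining) versus incubation time, $t_{1/2} = 0.693/k_e$. Estimation is
per replicate with the arithmetic mean ± SD reported — replicate summary
tables in this field behave as means of per-replicate computations, not
pooled fits. Two numerical choices matter:

* **The 0.693 constant.** The half-life and scaling relations use the
  rounded constant 0.693 by default (the convention in microsomal-stability
  reporting); `half_life_constant = log(2)` switches to full precision.
  The difference is ~0.02% and only matters when round-tripping published
  tables.
* **The log-linear window.** Fast-turnover species deplete log-linearly
  only over an initial window before the system saturates. The automatic
  rule takes the *longest* prefix of time points whose ln-linear fit has
  r² ≥ 0.95, falling back to the maximal-r² prefix when noise keeps every
  prefix below threshold (a short-circuiting "stop at first failure" rule
  was tried and discarded: on noisy slow-depletion series it truncated the
  window to three points and produced spurious infinite half-lives). An
  explicit window always overrides detection.

Scaling to whole-body intrinsic clearance uses

$$CL_\mathrm{int} = \frac{0.693}{t_{1/2}} \cdot
  \frac{1}{C_\mathrm{protein}} \cdot \mathrm{MPPGL} \cdot
  \frac{\text{liver g}}{\text{kg BW}},$$

with incubation protein 0.2 mg/mL by default, MPPGL 45 mg/g for all
species, and liver weights of 40, 32, 30 and 25.7 g/kg body weight for rat,
dog, monkey and human. Hepatic clearance uses the well-stirred model
$CL_h = Q_h CL_\mathrm{int} / (Q_h + CL_\mathrm{int})$ with hepatic blood
flows 55.2, 30.9, 43.6 and 20.7 mL/min/kg respectively. No binding
correction (fu,p/fu,mic) is applied and no parallel-tube or dispersion
model is offered: the package implements the plain well-stirred form, whose
structural guarantees ($CL_h < Q_h$, monotone in $CL_\mathrm{int}$) the
test suite asserts on a parameter grid. A species lookup outside the four
supported species fails loudly rather than defaulting.

## CYP phenotyping and inhibition

Phenotyping reports the transformation ratio
$100(1 - C_\mathrm{remaining}/C_\mathrm{control})$ against the zero-time
control, with a validity check that the NADPH-free negative control shows
essentially no turnover.

IC50 fitting uses a logistic of % activity on log₁₀ inhibitor
concentration. Three constraints stabilize it:

* The top asymptote is bounded to [90, 110]% — the zero-inhibitor blank
  *defines* 100% and is the normalizer, not a fitted point (it has no
  log-concentration).
* The bottom asymptote is **fixed at 0% by default** (a three-parameter
  fit). For reversible enzyme inhibition complete inhibition is attainable
  at sufficient inhibitor, and freeing the bottom makes curves whose
  descent is only partly spanned by the tested range (e.g. an IC50 at half
  the top tested concentration) non-identifiable: the bottom and the
  midpoint trade off almost freely. `bottom = NULL` frees the parameter,
  bounded to be non-negative, for mechanisms with a genuine activity floor.
* **Censoring before fitting:** when the mean observed activity never
  falls below 50% of control, no numeric IC50 is reported at all — the
  result is "> top tested concentration". A fitted midpoint beyond the
  tested range must never be read as a measured potency.

Potency classes follow the common 10/50 µmol/L convention (potent /
moderate / weak); a censored result is negligible unless inhibition at the
top concentration still reached 25%, in which case it is classed weak.

## Non-compartmental analysis

The default integrator is the plain linear trapezoid (the convention of the
widely used desktop NCA tools); linear-up/log-down is available by flag and
is exact on mono-exponential declines. AUMC integrates $t\,C(t)$ with the
matching rule. The terminal slope $\lambda_z$ is selected automatically:
candidate sets are the last 3, 4, … quantifiable points after (and, for
extravascular profiles, excluding) the peak; the set with the highest
adjusted r² wins and ties go to the larger set. Manual point selection is
supported and overrides the search. Extrapolated quantities use the
observed last quantifiable concentration:
$AUC_{0\text{–}\infty} = AUC_{0\text{–}t} + C_\mathrm{last}/\lambda_z$,
with the matching AUMC tail terms
$t_\mathrm{last}C_\mathrm{last}/\lambda_z + C_\mathrm{last}/\lambda_z^2$;
truncated (`*_0t`) variants carry no tail. Extrapolation above 20% of
$AUC_{0\text{–}\infty}$ raises a flag. Unit bookkeeping is explicit:
dose (mg/kg) over AUC (µg/L·h) carries a factor 1000 into CL/F (L/h/kg),
and $V_z/F = (CL/F)/\lambda_z$.

Absolute bioavailability defaults to the per-subject (crossover) mean of
dose-normalized AUC ratios, with ratio-of-group-means as the alternative —
the two differ by under a percent in typical designs but the per-animal
mean is what crossover studies report. Steady-state metrics over a dosing
interval $\tau$ are $AUC_{ss}$, $C_{av} = AUC_{ss}/\tau$, the degree of
fluctuation $(C_{max}-C_{min})/C_{av}$, and the accumulation index against
first-dose $AUC_{0\text{–}\tau}$; successive pre-dose troughs are screened
for a time trend (linear regression at the 5% level) before steady state is
accepted. Dose proportionality is reported as group-mean ratios normalized
to the lowest dose next to the dose ratios themselves: exposure ratios
rising faster than dose flag saturable elimination.

## Tissue distribution and binding

Destructive sampling (one group of animals per time point) yields one mean
concentration per tissue per time, so per-animal AUCs do not exist; the
composite method integrates the means. Tissue (ng/g) and blood (µg/L)
exposures are treated as numerically commensurate when forming
tissue-to-blood ratios, as is conventional for homogenate data.
Fraction-of-total exposure divides each matrix's AUC by the sum over all
matrices and is guaranteed to sum to 100%. Note that ratios of group means
(what the composite design supports) differ from means of per-animal
ratios by several percent in real tables; the package computes the former
and makes no claim to reproduce the latter beyond that accuracy. The
accumulation screen flags any tissue whose terminal concentration exceeds
20% of its peak. Protein binding is the ultrafiltration identity
$100(C_t - C_f)/C_t$, with a free concentration above total treated as an
error (device pre-saturation artifact), not clipped.

## Excretion mass balance

Per-interval recoveries convert measured matrix amounts to drug amounts
(`conc × volume × dilution factor`, with the homogenate dilution factor —
10 for a 10% homogenate — an explicit required input for feces rather than
a hard-coded constant) and express them as percent of the administered
dose, requiring body weight as an input since excretion-study weights are
rarely published. Cumulative curves are running sums, monotone by
construction; total recovery below 5% of dose flags extensive metabolic
transformation as the dominant elimination route.

## The synthetic-data generator

Every assay module has a paired generator with known ground truth:
one-compartment oral/IV/multiple-dose kinetics (multiple doses by
superposition), mono-exponential microsomal depletion with an optional
post-window plateau, linear receiver-flux transport with the
sampling-and-replacement bookkeeping applied to the emitted concentrations,
logistic inhibition curves, partition-coefficient-scaled tissue profiles
with a solvable tissue peak time, and programmed route fractions split
across the standard excretion intervals. Noise is multiplicative
log-normal, mean-preserving, parameterized by CV — the standard
bioanalytical error model — with optional log-normal between-subject
variability on clearance and volume (defaults when used in examples:
20% between subjects, 5% residual; these are fixture conventions, not
claims about any real study).

The central property the test suite enforces is *generator inversion*: at
zero noise every analysis module recovers its generator's parameters to
numerical tolerance (Papp and ER, $k_e$ and $t_{1/2}$, IC50, excretion
fractions), and at realistic noise the recovery error is quantified (200
seeded oral profiles at 5% CV: $\lambda_z$ within 10% of truth in ≥95% of
profiles, median AUC and Cmax error under 5%).

What the generator does **not** emulate — and hence what passing tests do
not show about real data: multi-compartment distribution, saturable
(Michaelis–Menten) elimination, enterohepatic recirculation, absorption
lag times, correlated assay errors, and LC-MS/MS calibration structure. A
one-compartment model was chosen as the minimal model consistent with
mono-exponential terminal phases, with no claim that any real compound is
one-compartment; supra-proportional exposure is emulated phenomenologically
(dose-dependent $k_e$) where a test needs it.

## Problem sizes and runtime choices

Simulation-based tests use 200 replicate profiles for recovery studies,
3–6 replicates for in-vitro fixtures, and dense grids (step 0.01 h over
up to 100 h) where trapezoid-versus-closed-form convergence is asserted at
0.5%. These sizes keep the full suite in seconds while leaving the
recovery statistics stable to well within the asserted tolerances.

## Known limitations

* IVIVE is binding-uncorrected well-stirred only; no fu-corrected, no
  parallel-tube/dispersion models.
* No compartmental or population PK fitting; NCA only.
* No mechanism-based (time-dependent) CYP inactivation or $K_i$
  estimation; inhibition is summarized at the IC50 level.
* The tissue module is descriptive (composite AUCs and ratios); no PBPK
  or mechanistic Kp prediction.
* Group-comparison hypothesis testing (fed/fasted, sex) is out of scope:
  it requires per-animal data the summary workflows here do not assume.
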