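---
title: "Multiscale modeling of gastrointestinal levodopa absorption"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale modeling of gastrointestinal levodopa absorption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(levogut)
```

## The problem

Levodopa, the standard treatment of Parkinson's disease, is chemically
an aromatic amino acid and is absorbed by the same intestinal
transporters that carry dietary amino acids. A protein-containing meal
therefore competes with the drug for its own absorption route, while
amino acids on the blood side of the enterocyte *trans-stimulate*
carrier-mediated secretion of the drug into the circulation. The net
effect of a diet on levodopa exposure is the result of gastric
emptying, dissolution, luminal degradation, carrier competition,
trans-stimulation and whole-body disposition acting together, on
different time scales and in different intestinal segments.

`levogut` models this system at two coupled scales:

1. a **whole-body pharmacokinetic model** whose oral-absorption part is
   a compartmental-transit chain (stomach, seven small-intestinal
   segments, colon, each with a solid and a dissolved pool), and
2. **constraint-based (flux balance) enterocyte models**, one per
   small-intestinal segment, that decide at every time step how much
   levodopa crosses the epithelium, given the current luminal and
   plasma amino-acid state.

## The whole-body model

The drug model has exactly 42 states: 9 luminal compartments x
{solid, dissolved} = 18; 7 enterocyte amounts (stomach and colon carry
none, as no absorption takes place there); and 17 systemic states
(venous, arterial and portal blood, lung, eleven perfused organs, a
cumulative urine sink and a cumulative degraded + fecal sink).

Transit is first order: stomach to duodenum at the gastric-emptying
rate (GER), segment *i* to *i+1* at the per-segment transit rate, and
terminal ileum to colon, with fecal elimination from the colon. The
per-segment reading of the single published transit rate reproduces
the classical compartmental-transit cascade. Dissolution follows a
surface-scaled saturation law, `kd * m^(2/3) * (Csat(pH) - C)`,
floored at zero (no re-precipitation); saturation solubility is a
piecewise-linear function of the compartment pH, higher in the acidic
stomach than in the intestine. Dissolved drug degrades at first-order
rates (a gastric rate and a lumped intestinal rate covering enzymatic,
microbial and chemical loss).

Organs are perfusion-limited (`dA/dt = Q (C_art - A/(V Kp))`), the
lung sits in series between venous and arterial blood, the liver is
fed by hepatic artery plus portal vein, renal clearance drains the
kidney into cumulative urine and hepatic clearance drains the liver
into the degraded sink. Blood-flow conservation (venous return equals
cardiac output) is validated at construction. Because every transfer
moves mass between states and all losses end in explicit sinks, the
derivative of the total drug inventory is identically zero between
dose events — the test suite asserts this to 1e-10 on random states
and to 0.1% of the dose over full simulated regimens.

Two prandial states are built in (fasted / fed); switching sets the
five food-sensitive parameters (GER 3.96 vs 0.33 per h, stomach volume
50 vs 1000 ml, colon volume 1000 vs 7000 ml, transit rate 2.1 vs
0.57 per h, gastric pH 2 vs 5) and leaves everything else untouched.

The default kinetic parameterization (flows, volumes, partition
coefficients, clearances) is a physiologically plausible levodopa-like
set for a 70 kg adult: polar-drug partition coefficients well below
one for most tissues, a combined clearance of about 20 l/h reflecting
co-administration of a peripheral decarboxylase inhibitor, and a
distribution volume of roughly 40 l. These defaults produce a peak
plasma concentration of about 2.4 mg/l one hour after a fasted 200 mg
dose. They are configuration, not constants: fitted values flow in
through the configuration layer or `fit_model()`.

The derivative is implemented twice: a readable R closure (the
reference) and a C translation used by the integrator; the suite
cross-checks them on random states. Integration uses an adaptive
stiff-capable solver (relative tolerance 1e-8, absolute 1e-10), with
dose events applied as discontinuous additions to the stomach solid
state by stop-and-restart. Nonnegativity is asserted, not enforced:
state clipping is disabled, and externally imposed uptake rates are
smoothly gated (`A/(A + 1e-6 mg)`) so a zero-order drain cannot push a
state negative.

## The enterocyte model

The packaged reduced network is a deterministic desk-scale stand-in
for a genome-scale enterocyte reconstruction: the 20 proteinogenic
amino acids plus cystine and ornithine, each present in lumen, cytosol
and blood with exchanges and facilitated transports (92 reactions, 66
metabolites), a lumped biomass demand and three amino-acid
interconversions sufficient to make it feasible. The count is larger
than a minimal sketch because every species must be available as an
antiport co-substrate on both membranes. The published genome-scale
enterocyte reconstruction can be dropped in through the SBML loader;
all module operations apply unchanged.

The levodopa transport module adds exactly 36 reactions reflecting
the three-carrier scheme:

* **luminal antiporter** (system b0,+-like): 20 reactions, one per
  dibasic or neutral substrate, importing luminal levodopa in strict
  1:1 exchange for a cytosolic amino acid; cystine has the highest and
  ornithine the lowest affinity;
* **basolateral antiporter** (LAT2-like): 13 reactions importing a
  neutral amino acid from blood in exchange for cytosolic levodopa —
  the trans-stimulation route;
* **basolateral uniporter** (TAT1-like): one reaction; plus one
  luminal and one basolateral levodopa exchange.

A linear coupling constraint fixes the uniporter share of basolateral
levodopa efflux at 4/5 in *every* flux solution, rather than as a
post-hoc scaling. The acidic amino acids (aspartate, glutamate) sit on
none of the carriers.

Only the rank order of substrate affinities is available, so ranks map
to geometric carrier-share weights `w = 2^-rank`, and levodopa's share
of a shared carrier with capacity `V_T` is `w_L q_L / (w_L q_L + sum
w_i q_i)` over the amounts present. This preserves the printed order
exactly, gives the full capacity to levodopa when no competitor is
present, and drives the share to zero under a saturating high-affinity
competitor. Levodopa itself ranks near tyrosine (rank 11) on the
luminal carrier, consistent with its aromatic side chain. The
substrate lists and ranks live in `transporter_catalog()` and are
plain data, auditable and replaceable without touching code.

### Flux balance analysis

`fba()` solves `max c'v` subject to `S v = 0`, bounds, and the
coupling rows. No linear-programming backend is available in this
R environment, so the package carries its own dense bounded-variable
two-phase simplex (`lp_solve()`), with Bland's rule as an anti-cycling
fallback. It is validated two independent ways: against exhaustive
vertex enumeration on networks of up to six reactions, and against a
second LP implementation on random bounded problems. Alternate optima
are resolved lexicographically — the objective is fixed and the total
absolute flux minimized — so flux vectors are deterministic.
Inequality couplings (carrier-capacity allocations) become equality
rows with bounded slacks.

### The extended (kidney/brain) model

For the amino-acid ranking, the enterocyte model is extended with a
systemic levodopa pool and three competing fates: transport across the
blood-brain barrier, renal elimination, and a residual systemic sink;
a cytosolic loss reaction (enterocyte decarboxylation) provides the
pre-systemic loss route. In the fasting reference, flux-ratio
constraints fix systemic delivery at 66% of the luminal uptake and
renal elimination at 30% of the absorbed flux — imposed as
constraints because they are calibrated experimental outcomes, not
predictions of the reduced network. With the luminal influx fixed at
15 mmol/gDW/h and the brain reaction as objective, the reference
solution delivers 9.9 mmol/gDW/h systemically (66%), eliminates
2.97 renally (30% of absorbed) and delivers 6.93 to the brain.

Under co-administration of one amino acid (matched amounts on every
shared carrier), three mechanisms move the brain flux: luminal
competition scales the uptake, renal-carrier competition scales the
renal loss (sparing levodopa for the brain), and blood-brain-barrier
competition caps the brain reaction (capacity 0.7 x influx, scaled
with the reference influx so that class membership is invariant to
the arbitrary influx value — an LP-scaling property the tests check
at 5, 15 and 30 mmol/gDW/h). The resulting partition: serine,
threonine and asparagine (renal competitors, weak luminal
competitors) improve brain delivery, with serine first; aspartate and
glutamate are exactly neutral; high-affinity luminal or
blood-brain-barrier substrates compete, with cystine last.

## The coupling loop

The multiscale simulation uses the static optimization approach: the
horizon (default 18 h) is divided into fixed steps (default 0.1 h, so
180 steps and 1260 segment-level flux solves per scenario). Each step:

1. integrate the whole-body model one step with the current
   per-segment uptake and secretion rates;
2. read the segment states and select the interaction **mode**:
   competition when luminal amino acids exceed 1e-6 mmol;
   trans-stimulation when the lumen is amino-acid-free but the plasma
   pool exceeds its fasting baseline; otherwise plain uptake
   (competition with an empty competitor set);
3. derive bounds: the levodopa luminal exchange is limited by the
   amount available over one step (`amount/(MW x gDW x step)`), the
   summed luminal antiport flux by levodopa's affinity share of
   `V_T = 15 mmol/gDW/h`, luminal amino-acid exchanges by their own
   amounts, and the summed basolateral antiport flux by the
   exchangeable plasma amino-acid supply (capping the total antiport
   directly — bounding only the blood-side exchanges would be
   bypassed by cytosol-to-blood recycling of the co-substrate);
4. solve one flux-balance problem per segment (objective: luminal
   uptake in competition mode, basolateral secretion in
   trans-stimulation mode);
5. convert fluxes to mass rates (`flux x gDW x 197.19 mg/mmol`) that
   debit the segment lumen and credit the portal vein in the next
   step.

Segments whose lumen and enterocyte hold no levodopa are resolved to
zero flux without a solver call; this is an exact shortcut, since the
zero vector is feasible and optimal when the objective's bounds force
zero.

Dietary amino acids follow a parallel luminal transit chain (dissolved
only, same transit rates), are absorbed only in the proximal jejunum,
and feed a single well-mixed plasma pool that relaxes to the fasting
baseline first order (0.3 per h). These states are additional to —
and excluded from — the 42-state drug census. The enterocyte's own
amino-acid turnover (about one mmol per dose cycle) is negligible
against dietary loads (hundreds of mmol) and is not fed back into the
amino-acid mass balance.

### Scale calibration

Two constants set where the carrier constraints sit relative to the
luminal drug fluxes, and both are deliberate modeling choices made
once:

* `segment_dry_weight = 0.05 g` per segment is an *effective*
  carrier-normalization mass, chosen so that the carrier capacity
  (`V_T x gDW x MW` which is about 150 mg/h per segment) is
  commensurate with the luminal drug flux after a clinical dose — not
  an anatomical mucosal mass. With an anatomical value the carrier
  would never saturate and no dietary interaction could register.
* `bl_per_mmol = 0.2 mmol/gDW/h` per mmol of plasma amino acid makes
  the fasting basolateral exchange capacity (13 mmol/gDW/h summed
  over the antiporter substrates) sit just below the luminal carrier
  capacity (15), so that trans-stimulation has headroom to act: an
  elevated plasma pool lifts the basolateral cap and measurably
  raises absorption, while fasting plasma levels leave the system
  mildly secretion-limited. This is the mechanism by which protein
  redistribution and serine supplementation improve exposure.

## Parameter estimation and sensitivity

Fitting is global multistart constrained least squares: a seeded
Latin-hypercube sample of the box constraints, each start polished by
bounded Levenberg-Marquardt, best converged start returned. The
objective is the weighted sum of squared concentration residuals with
weights `1/max(observed, 0.1 mg/l)`. The synthetic-observation
generator samples the plasma curve on a quarter-hour grid to 6 h and
applies mean-one multiplicative lognormal noise of a given
coefficient of variation; the suite verifies parameter recovery to
1% without noise and 15% under 5% noise, and that the best-so-far
objective is monotone over starts.

The food-induced emptying delay is isolated by the sequential
two-occasion procedure: stage 1 pins GER at the fasted literature
value (3.96 per h) and fits the kinetic parameters on fasted data;
stage 2 freezes those kinetics, switches the remaining prandial
parameters to their fed literature values, and fits GER alone on fed
data. On synthetic data generated at the fed value the procedure
recovers 0.330 per h to within 1%. Setting `fed_physiology = FALSE`
keeps stage 2 under stage-1 physiology, so that occasions differ only
in the emptying rate.

Sensitivity ranking uses the non-normalized time derivative of the
plasma concentration with respect to each parameter, approximated by
central differences (relative step 1e-4) and scored by the
trapezoidal integral of its absolute value; flow perturbations
re-balance cardiac output and liver inflow so flow conservation is
preserved at the perturbed point. The scoring is verified against the
closed-form integral for one-compartment exponential decay within 1%.
Under impaired (fed) gastric emptying the emptying rate dominates the
ranking; note that non-normalized derivatives favor small-valued
parameters, so a ranking computed on a differently scaled parameter
set is not comparable across parameterizations.

## Goodness of fit

Predicted-observed agreement is summarized by the two-sample
Kolmogorov-Smirnov p-value between the two concentration samples and
the Pearson correlation of the paired values. Applying a two-sample
KS test to paired series is unconventional; it is provided because it
is a reported summary in this literature, and it is documented as
such. Constant series leave the correlation undefined (`NA`).

## Diet scenarios

`build_scenario()` encodes the standard designs against an 18 h day
(three 6-hourly doses):

* `ac` — 100 mg every 6 h, fasted, no amino acids (the reference);
* `fed_aproteic` / `fed_proteic` — the same dosing under fed
  physiology, without/with an amino-acid load at each dose;
* `lpd` — low-protein diet: 200 mg three times daily with 0.8 g of
  amino acids per kg body weight per meal; the dose precedes the
  meal, so fasted physiology applies. Meals default to an equimolar
  mix over the 22 catalog species; single-species variants
  (cystine-only, ornithine-only) expose the affinity extremes;
* `prd` — protein redistribution: the daily protein moved to the
  last (evening) meal, represented as a plasma amino-acid pool at
  three times the fasting baseline when the first dose of the
  simulated day is taken, decaying first order, with no daytime
  luminal amino acids;
* `serine_rich` — reference dosing with 5 g serine added to the
  plasma pool one hour after each dose (a serine-rich post-dose
  meal).

Scenarios are scored by the area under the plasma curve above the
per-stage efficacy thresholds. The threshold concentrations are not
published; the defaults (0.5 / 0.9 / 1.4 / 2.0 mg/l, increasing with
stage) are documented placeholders, and every threshold-relative
result is reported per threshold so conclusions can be audited under
user-supplied values. Relative changes are
`100 (AUC_s - AUC_ref) / AUC_ref` against the first (reference)
scenario.

With the package's default parameterization the qualitative orderings
are stable and asserted in the acceptance suite: cystine-accompanied
dosing falls far below ornithine-accompanied dosing, which falls
below the fasted reference; protein redistribution and serine
supplementation sit above the reference; the fed state blunts and
delays the plasma peak. The *magnitudes* of the percentage changes,
by contrast, depend on the kinetic parameter set: they should be
interpreted under a parameterization fitted to the population of
interest, supplied through the configuration layer, not under the
generic defaults.

## Numerical choices and limitations

* ODE tolerances 1e-8/1e-10; LP feasibility/optimality tolerance
  1e-9; steady state asserted to 1e-9 on every returned flux vector.
* The static-optimization coupling has a transport lag that is first
  order in the step: drug arriving within a step is absorbed from the
  next step on. At the default 0.1 h step the total exposure of the
  fasted reference shifts by about 2% upon step halving, and
  successive refinements shrink the change; results at a fixed step
  are exactly reproducible.
* Degenerate flux optima are resolved by total-flux minimization;
  carrier shares use rank information only (no Km values are
  published); the 36-reaction module inventory is reconstructed from
  the carrier scheme (20 + 13 + 1 + 2) and is configuration-visible
  so it can be corrected against a published inventory without code
  change.
* The amino-acid side model is deliberately coarse (free amino acids
  released at meal time, proximal-jejunal absorption, one plasma
  pool). Di/tripeptide absorption can be represented by scaling the
  free fraction of a meal, but is off by default.
* Synthetic observations emulate averaged healthy-volunteer plasma
  curves (smooth, single-peak, multiplicative error). They do not
  reproduce erratic multi-peak absorption, inter-individual
  variability, or time-varying gastric emptying — passing recovery
  tests shows the estimation machinery is correct, not that real
  data behave this simply.
* Test and example problem sizes: coupled scenario checks run one
  dose + meal cycle (6 h, 60 steps); the full three-dose day (180
  steps, about 1260 flux solves) is exercised by the dose-free
  step-count check and available through the scenario runner.

## Reproducing the reference numbers

`scripts/acceptance.R` rebuilds the extended network from scratch,
fixes the luminal influx at 15 mmol/gDW/h, applies the fasting
flux-ratio constraints, maximizes brain delivery and writes the
systemic-delivery percentage (66) and the renal share of the absorbed
flux (30) as JSON. The `--seed` argument fixes all randomness (the
reference solve itself is deterministic).
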