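---
title: "Methods: release kinetics, synchronization indices and the virtual trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: release kinetics, synchronization indices and the virtual trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnsync)
```

## The problem

Dietary starch sources differ widely in how fast and how completely they
release glucose during digestion, and that pace interacts with protein
digestion: if glucose and amino nitrogen arrive at the terminal small
intestine out of step, amino acids are deaminated or fermented instead of
absorbed for growth. `cnsync` quantifies this *carbon–nitrogen release
synchronization* from in vitro digestion time-courses and links it to
marker-based digestibility and balance measurements from cannulated-pig
trials.

## Release curves and interval rates

A curve is one substrate × nutrient × replicate cumulative release
series over a two-phase simulated digestion: 120 min gastric, then
480 min intestinal, **each phase on its own clock**. Intestinal minute 0
is the moment intestinal juice (with the glucose-liberating
amyloglucosidase) is added, which is why cross-phase rates are refused by
default and why the baseline of an interval is always the *measured*
value at its start — intestinal $D_0$ need not be zero.

Rates are direct differences, $K = (D_{t_2}-D_{t_1})/(t_2-t_1)$, between
sampled points only. No kinetic model is fitted to measured data, and no
smoothing is applied: wet-assay replicates occasionally dip at adjacent
time points, and those negative rates are *retained and flagged*
(`flag_negative`, a `cnsync_negative_rate` warning) rather than clipped,
because downstream analysis compares relative differences between diets
rather than absolute rates. An opt-in linear interpolation
(`interpolate = TRUE`) exists for dense simulator grids only.

Units: diet-level glucose is carried in g/kg DM; ingredient-level
reporting uses g/100 g (factor 10, applied at I/O by `convert_units()`);
soluble nitrogen g/kg; total amino acids mmol/kg. Conversions needing
outside information (mmol/kg to g/kg would need a molar mass) are
refused.

## The synchronization indices

Over a common rapid-release window — default minutes 0–20 of the
intestinal phase, where all diets release glucose, soluble nitrogen and
amino acids fastest — each diet $d$ gets
$$\mathrm{Relative\ G/N}_d = \frac{K_{Glucose,d}/K_{GlucoseR}}{K_{Nitrogen,d}/K_{NitrogenR}},\qquad
\mathrm{Relative\ G/AA}_d = \frac{K_{Glucose,d}/K_{GlucoseR}}{K_{AA,d}/K_{AAR}},$$
$$\mathrm{G/N}_d = K_{Glucose,d}/K_{Nitrogen,d}\ (\mathrm{g/g}),\qquad
\mathrm{G/AA}_d = K_{Glucose,d}/K_{AA,d}\ (\mathrm{g/mmol}),$$
with reference rates $K_{\cdot R}$ the arithmetic means of the per-diet
mean rates across the panel. Two exact identities follow and are tested
to 1e-12/1e-9 relative: the mean over diets of each relative rate is 1,
and $\mathrm{G/N}_d / \mathrm{Relative\ G/N}_d = K_{GlucoseR}/K_{NitrogenR}$
is one constant for the whole panel (likewise for G/AA). The relative
indices are invariant to rescaling any one nutrient's curves by a common
factor; the absolute ratios scale with it.

**Replicate semantics.** `sync_table()` computes indices per replicate
against a *fixed* context whose reference rates come from the per-diet
mean rates, then reports per-diet mean ± SEM (n = 3 in the emulated
design). Averaging the reference over diet means rather than over all
replicate values is a free choice when group sizes are equal (the two
coincide); diet means are the default because they keep the context
well-defined for unbalanced panels.

**Classification.** The synchrony label is decided by Relative G/AA
alone. A diet can sit near 1 on Relative G/N yet release amino acids far
faster than glucose — soluble nitrogen tracks early protein
solubilization, while total amino acids track proteolysis to absorbable
products, which is the nutritionally binding stream. The default closed
band $[0.75, 1.50]$ is the widest band consistent with the reference
partition of the five gradient diets (mean Relative G/AA 1.40 must stay
`Syn`, 1.63 must become `Asyn_C`, 0.71 `Asyn_N`); both bounds are
configurable, and boundary values classify as `Syn`. `Asyn_C` marks
relative glucose excess (nitrogen insufficiency), `Asyn_N` relative
nitrogen excess. Zero glucose release is legal (Relative G/N of 0);
zero nitrogen or amino-acid rates make the ratios undefined and raise
an error suggesting a wider window instead of returning infinities.

Letter displays are produced for all four index columns; reports that
want significance marks only on Relative G/AA and G/AA (the customary
presentation) can drop the others.

## Digestibility and balance

All equations are the standard marker-based forms:
$ATTD = (FI - Feces)/FI \times 100$;
$AID = [1-(AA_{digesta}/AA_{diet})(Cr_{diet}/Cr_{digesta})]\times 100$;
$IAA = AA_{digesta}(Cr_{diet}/Cr_{digesta})$ from nitrogen-free-fed
animals; $SID = AID + (IAA/AA_{diet})\times 100$. Choices worth noting:

* The basal endogenous loss entering SID is the across-animal
  **arithmetic mean** of per-animal IAA (the nitrogen-free group yields a
  single pooled basal value); `basal_endogenous_loss(..., fun = median)`
  switches to the median.
* Crude protein runs through the same AID formula as individual amino
  acids.
* Negative AID values (possible for trace analytes) are reported with a
  warning, never truncated; `SID \ge AID` always, with equality iff
  IAA = 0.
* `attd` + 100·fecal/intake = 100 exactly; the same complement links
  ATTD of gross energy with the fecal-energy fraction FE/FIGE.
* Per-diet summaries use mean ± SEM over animals (n = 6 in the emulated
  design); comparison letters are delegated to `group_compare()`
  (Kruskal–Wallis/Wilcoxon is the customary method for amino-acid
  digestibility, ANOVA/Tukey and the t-test for balance and growth).
  Letters are always computed from the data at hand; printed
  significance marks in legacy tables that conflict with their own SEMs
  are not reproduced.

## Diet design

`substitution_gradient()` works in integer hundredths of a percent, so
level sums and step equality are exact rather than float-approximate:
with a 69.20% starch allowance and 5 levels the substitute takes 0,
17.30, 34.60, 51.90, 69.20%. `complete_formula()` fills a formula to
100.00% with a named filler (88.35% normal maize starch for the
nitrogen-free diet), and `validate_diet()` checks non-negativity,
sum-to-100 within 0.01 percentage points, and the 0.3% chromic-oxide
marker. Analyzed starch contents are treated as measured outputs of a
formulation, never as design inputs.

## The simulator: what it emulates and what it does not

Measured curves exist only as figures, so the simulator is the package's
source of test data, built from first-order saturating kinetics
$D(t) = A(1-e^{-k\,\max(0,t-\mathrm{lag})})$ — a deliberate stand-in (no
mechanistic model is claimed), chosen because it reproduces the
qualitative shape of the observed curves: most release within the first
120 intestinal minutes, fastest in the first 20–60, then a plateau.

* **Sampling schedules** follow the assay: intestinal 0, 20, 60, 90,
  120, 240, 360, 480 min for all nutrients; gastric 0, 60, 120 min for
  soluble nitrogen and amino acids. Gastric glucose is not generated
  (no amyloglucosidase in the gastric phase).
* **Panel defaults** (the emulated study conditions): five diets with
  waxy fractions 1, 0.75, 0.5, 0.25, 0; glucose $(A, k)$ interpolated
  linearly between a fast/high endpoint (520 g/kg, 0.030/min) and a
  slow/low endpoint (240 g/kg, 0.008/min), magnitudes set so 0–20 min
  G/N lands near the reported 6–19 g/g and G/AA near 0.2–0.7 g/mmol;
  shared protein-mix kinetics for nitrogen (14 g/kg, 0.15/min
  intestinal) and amino acids (900 mmol/kg, 0.030/min intestinal);
  3 replicates; additive Gaussian noise with SD 5% of each curve's $A$,
  clipped at zero — large enough to produce the occasional adjacent-time
  decreases that exercise the fluctuation-flagging path.
* **Designed panels.** With a shared $k$, the 0–20 min rate scales with
  $A$, so `design_panel_params()` solves per-diet glucose/amino-acid
  amplitudes whose noiseless Relative G/AA equals any prescribed target
  vector exactly (an affine correction $a = 1 + \alpha(r-\bar r)$ with
  $\alpha = (1-\bar r)/\mathrm{var}_{pop}(r)$ aligns the two amplitude
  means). This is how the `Syn, Syn, Asyn_C, Asyn_N, Asyn_N` recovery
  experiment is constructed.
* **Ingredient archetypes** map release rate (rapid/slow) to $k$
  (0.040 vs 0.008/min), level (high/low) to $A$ (80 vs 20 g/100 g), and
  duration to a $k$ multiplier (transient ×3: the plateau arrives early;
  persistent ×1: release continues across the run).
* **Virtual trial.** Six pigs per diet (plus a nitrogen-free group),
  9-day periods, 2.05 g/kg dietary chromium (0.3% Cr₂O₃), ~29 kg pigs.
  Digesta concentrations are generated by *inverting* the AID/IAA
  equations from configured truths, so with zero assay noise the
  pipeline reproduces every truth to numerical precision — the
  noiseless-inversion identity is the trial's correctness oracle.
  Default truths for ATTD, excretion fractions, ADG and ADFI follow the
  reported per-diet balance patterns; per-analyte AID truths are
  synthetic plausible values (Syn diets a few points higher). Assay
  noise is multiplicative Gaussian (CV 5%) per measured concentration
  or amount.
* **Determinism.** One global seed; every stream (diet × nutrient,
  trial) derives a fixed sub-seed from it, so identical seed + config
  gives byte-identical output with no time-based entropy.

What the simulator does **not** emulate: between-replicate correlation
(wet replicates share suspensions; independence is assumed),
gastric-emptying or absorption physiology, substrate-by-enzyme
interactions, and any link from synchrony class to growth or microbiota.
Passing tests therefore demonstrate that the *computational* pipeline is
correct and recoverable under realistic noise — not that the biological
effect sizes are as simulated.

## Statistics plumbing

`group_compare()` wraps `aov` + `TukeyHSD`, Welch's `t.test`, and
`kruskal.test` + pairwise `wilcox.test` (unadjusted, normal
approximation), and builds compact letter displays by insert-and-absorb
over the pairwise p-value matrix, lettering from the highest group mean
("a" = highest). An optional second tier (x/y at 0.05 < P < 0.10) marks
trends and is off by default. No multiple-testing correction is applied
across metrics. A 400-repetition null simulation guards the type-I error
in the unit suite; the full 2,000-repetition check (5 groups, n = 6)
runs with the acceptance suite and must land in [0.03, 0.07] at
α = 0.05.

## Numerical choices and problem sizes

Exactness claims are tiered: algebraic identities (telescoping rate
sums, relative-rate normalization, ATTD complement, noiseless trial
inversion) are tested at 1e-12 relative (1e-9 where division chains
accumulate error); formulation arithmetic is exact by integer-hundredths
representation. Stochastic checks fix their seeds: AID recovery uses
n = 200 animals/diet (max |error| within 3 SE), class recovery uses 20
seeds at 5% noise with majority voting, and the type-I simulation uses
2,000 repetitions — sizes chosen to keep the whole suite comfortably
under a few minutes on a single core while leaving Monte-Carlo margins
wide.

## Known limitations

* The classification band is calibrated to a five-diet panel measured in
  one assay system; other systems may need different bounds (both are
  parameters).
* Relative indices depend on panel composition: adding or removing a
  diet changes every diet's reference rate, hence its relative indices
  (the absolute G/N and G/AA do not move).
* The rate window must avoid intervals where replicate fluctuation makes
  nitrogen or amino-acid rates non-positive; the errors say so rather
  than guessing a fix.
* Energy-system modelling (DE/ME/NE), nitrogen-retention modelling
  beyond the printed fractions, protein molecular-size profiling and all
  microbiome analysis are out of scope.
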