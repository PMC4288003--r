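---
title: "Methods: PBPK modeling of OATP1B1 substrates in genetic variant populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PBPK modeling of OATP1B1 substrates in genetic variant populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oatpbpk)
```

## The problem

Hepatic uptake through OATP1B1 is often the rate-determining step in the
clearance of statins and other anionic drugs. Because the *SLCO1B1*
haplotypes \*1b (doubled transporter expression) and \*5/\*15 (reduced
intrinsic activity) are common, the same dose produces systematically
different exposure across genotype groups. `oatpbpk` predicts those
differences from three ingredients: (i) a whole-body PBPK model fitted to
*nongenotyped* mean plasma data, (ii) in vitro activity ratios and
expression multipliers of the variants, and (iii) population haplotype
frequencies. Only the hepatic active uptake clearance changes between
genotypes; every other parameter is held fixed.

## Model structure and assumptions

The body is represented by perfusion-limited lung, gut, spleen, kidney and
rest-of-body compartments (tissue:plasma partition coefficients `Kp`),
permeability-limited muscle and adipose (extracellular/intracellular pairs
linked by a passive clearance), arterial and venous blood, and a liver
discretised into `n_liver_subunits` serial pairs of blood and intracellular
tissue (default 5). Serial discretisation makes hepatic extraction behave
like a tube rather than a single well-stirred pot; with one sub-unit the
model is the well-stirred limit and plasma AUC is higher (about 10% for the
IV and 20% for the oral pravastatin-like fixture — a documented
discretisation effect, not an error).

Clearance conventions, all in L/h:

* `CL_act_tot` and `CL_pass_liver` act on unbound plasma concentration in
  liver blood (`fu_p`/`RB_P` conversion from blood concentration); both are
  divided equally across sub-units.
* `CL_bile` acts on unbound intracellular concentration (`fu_liver`) and
  fills a bile-duct compartment of volume 0.318% of liver volume, which
  empties into the gut lumen at a continuous 350 mL/day (0.01458 L/h).
  Gallbladder storage and meal-triggered emptying are deliberately absent.
* `CL_renal` is plasma-referenced and acts on venous plasma.
* Muscle/adipose passive clearances are fixed ratios of `CL_pass_liver`
  (`pass_ratio_muscle`, `pass_ratio_adipose`); their intracellular unbound
  fraction is derived as `fu_p/Kp` so a passive-only tissue equilibrates
  exactly at its `Kp`.

Oral absorption moves lumen drug into the *portal inflow of liver sub-unit
1* at `ka·FaFg`, with the complement `ka·(1 − FaFg)` going to an unabsorbed
sink. Routing absorbed drug through the liver (rather than into gut tissue
or venous blood) is required for uptake-dependent first-pass exposure; the
gut compartment itself is a plain perfusion-limited tissue.
Biliary-recirculated drug faces the *same* `FaFg` split as the initial
dose: one consistent mechanism, chosen because nothing in the data
distinguishes the two pools (the alternative — complete reabsorption of
biliary drug — was examined during design and changes none of the
qualitative conclusions; see the noncompartmental analysis below).

The model is linear throughout: no saturable transport, no
inter-individual variability, mean profiles only.

### Default physiology

`default_physiology()` is a documented 70-kg reference table (volumes:
lung 0.5, adipose 18, muscle 29, gut 1.2, spleen 0.15, kidney 0.31,
liver 1.8, rest 10, arterial 1.7, venous 3.9 L; flows: cardiac 390,
liver 97 = hepatic artery 22 + portal 75, muscle 45, kidney 70, adipose 20,
rest 158 L/h). The values are standard-compilation magnitudes shipped as an
implementation fixture; the validator enforces cardiac-output closure,
portal consistency (liver flow ≥ gut + spleen) and the bile-volume ratio.

## Genotype clearance algebra

With `f_OATP1B1` the fraction of total active uptake mediated by OATP1B1:

$$CL_{act,OATP1B1} = f \cdot CL_{act,tot}, \qquad
  CL_{act,other} = (1-f)\,CL_{act,tot}$$

The nongenotyped OATP1B1 clearance is treated as the frequency-weighted
mean over \*1a, \*1b, \*15 carriers. Effective ratios multiply intrinsic
activity and expression ($r_{*1b} = 0.81 \times 2$ for the pravastatin
preset, $r_{*15} = 0.35 \times 1$), so

$$CL_{act,*1a} = \frac{CL_{act,OATP1B1}}{P_{*1a} + P_{*1b} r_{*1b} + P_{*15} r_{*15}},
\qquad CL_{act,v} = r_v\, CL_{act,*1a}$$

and the weighted mean of the per-variant clearances reproduces the input
exactly (a property tested to 1e-12 over 1,000 random specifications).
Genotype totals add back the unchanged `CL_act_other`; an ethnic activity
scalar (0.584 for Japanese vs Caucasian populations) multiplies *all*
active-uptake entries, including `CL_act_other`. Keeping expression
multipliers separate from intrinsic ratios makes the "no expression
difference" re-analysis of \*1b a one-field change. \*5 is merged into
\*15 and only homozygote groups are represented; heterozygote
interpolation is out of scope. For studies typed only at c.521T>C,
`relabel_c521()` maps TT→\*1a and CC→\*15 as an explicit utility rather
than baked-in assumption.

A useful corollary: a compound whose \*15 effective ratio is 1 (the
fluvastatin-like fixture) has *identical* \*15 and \*1a clearances, hence
pointwise identical predicted profiles — the in vitro data predict that the
c.521T>C polymorphism leaves that compound's in vivo PK unchanged even
though it is an OATP1B1 substrate.

## Parameter estimation

`fit()` estimates any subset of `{CL_act_tot, CL_bile, CL_pass_liver, ka,
FaFg}` by minimising the unweighted sum of squared residuals of
log-transformed concentrations, pooled over all datasets (log residuals
because the profiles span orders of magnitude; the original objective is
not stated in the source methods). The optimizer is differential evolution
(rand/1/bin, crossover 0.7, mutation factor dithered in [0.5, 1]),
working in log10 parameter space so that the initial population is
log-uniform within the bounds — our reading of "nonlinear sampling" for
clearances spanning orders of magnitude, documented as an interpretation.
A bounded L-BFGS-B polish from the DE optimum is on by default (the
objective is smooth near the optimum; the polish only replaces the DE
point if it improves the loss, and determinism for a fixed seed is
preserved). Candidate simulations that fail are penalised, not fatal.
Estimates landing on a bound are flagged with a warning.

`residual_bootstrap()` resamples the pooled log-scale residuals with
replacement, rebuilds pseudo-datasets around the fitted profile, and refits
each replicate with a reduced-budget DE initialised in a ±0.15 log10 cloud
around the point estimate (first member exactly at it). Percentile 2.5/97.5
intervals are reported; replicates that fail to refit are dropped and more
than 20% drops is an error.

## Noncompartmental Fa·Fg and enterohepatic recirculation

`nca_fafg()` implements the classical availability decomposition
$F_{oral} = (AUC_{po}/D_{po})/(AUC_{iv}/D_{iv})$,
$CL_{h,b} = (CL_{plasma} - CL_{renal})/R_{B/P}$,
$F_h = 1 - CL_{h,b}/Q_h$, $\widehat{F_aF_g} = F_{oral}/F_h$.

Working through the AUC balance of this linear model yields a result worth
stating: if $CL_{plasma}$ is taken self-consistently as
$D_{iv}/AUC_{iv}$ at infinite time, the estimate is *exact* even with
recirculation — the recirculation gain in $F_{oral}$ and the inflation of
the apparent hepatic availability cancel identically (the package verifies
this numerically: 0.4596 estimated vs 0.46 generating, independent of
`CL_bile`). The familiar overestimation under enterohepatic recirculation
appears when the clearance entering the availability term represents
*single-pass* hepatic elimination capacity — the quantity $F_h$
conceptually assumes — rather than the recirculation-net clearance. The
package provides the closed form (`hepatic_extraction()`): per sub-unit
net removal $k = (CL_{act}+CL_{pass})\frac{f_{u,p}}{R_{B/P}}
\frac{CL_{bile}}{CL_{pass}+CL_{bile}}/n$ and
$E = 1 - (Q_h/(Q_h+k))^n$, validated against a steady-state infusion
simulation. With that input the estimate becomes
$F_aF_g/(1 - E\,F_aF_g) > F_aF_g$ whenever `CL_bile > 0`, and collapses to
the exact value when `CL_bile = 0` — the configuration used in the
acceptance analysis of the noncompartmental bias.

## Sensitivity analyses

`local_sensitivity()` raises one compound parameter by 1% and reports
$S(t) = \frac{(y'(t) - y(t))/y(t)}{0.01}$, normalized to both parameter and
output; outputs are the plasma or liver concentration trace (0.1 h grid by
default inside the analysis window — up to 8 h for the pravastatin-like,
24 h for the rosuvastatin-like compound) or a scalar plasma AUC. Times
where the output is zero yield marked `NA`s; a zero-valued parameter
requires an explicit absolute step. Coefficients with $|S| \ge 0.3$ are
flagged. A central-difference mode at smaller steps serves as the
verification oracle; the forward estimate converges to it as the step
shrinks (Richardson-style check in the test suite). Note the 1%-raise
convention itself carries an irreducible truncation of order
$(S-1)/2 \times 1\%$ plus curvature terms; for coefficients just above the
0.3 flag threshold of the absorption-rate parameter this deviation reaches
about 1.2% relative — a property of the convention, not of the
implementation.

`invitro_ratio_sensitivity()` differentiates the genotype algebra instead
of the ODE model: the intrinsic activity ratio of one variant is raised by
1% (expression multiplier held fixed — for a multiplicative step the
effective-ratio convention coincides), the per-variant totals are
re-derived from the *fixed* nongenotyped `CL_act_tot` (both OATP1B1 and
other components re-derived at each fractional contribution `f`), and
normalized coefficients are tabulated over `f` in [0.2, 1]. At the
pravastatin preset (`f = 0.83`) only the \*15 total is sensitive to the
\*1a:\*15 ratio (|S| = 0.58 vs 0.05 for \*1a and \*1b), and every |S| grows
monotonically with `f`; the frequency-weighted perturbations of the
per-variant OATP1B1 clearances sum to zero because the population mean is
held fixed. `ratio_scenario_profiles()` turns the two literature \*15
ratios (0.20, 0.50) into full per-genotype profile sets; \*1a/\*1b profiles
shift only through the small population-mean reweighting, which is
reported as an attribute.

## Synthetic data

`make_fixture()` returns three statin-like compounds with the published
genotype constants and documented fixture clearances: the magnitudes were
chosen once to give a pravastatin-like profile (tmax ≈ 1 h, ~50% renal
contribution), a rosuvastatin-like profile (slow absorption, tmax ≈ 3 h,
biliary-dominated elimination, larger distribution volume) and a
fluvastatin-like compound (high-extraction, c.521T>C-neutral). They are
*not* reproductions of any fitted parameter table. `generate_dataset()`
simulates the true profile and applies multiplicative lognormal noise
(`sdlog = cv`, default CV 0.2 — within the reported in vitro interstudy
variability ceiling of 60%) per time point and replicate, returning
mean ± SD profiles like digitized study means; `generate_genotyped_cohort()`
does the same per genotype group with independent seeds. What the generator
emulates: mean profiles, sampling schedules, lognormal observation scatter,
genotype stratification. What it does not: inter-individual parameter
variability, study-to-study physiology differences, below-limit censoring,
digitization error. Passing the round-trip tests therefore demonstrates
estimator correctness under the model's own assumptions, not robustness to
real-data model misfit.

## Numerical choices

* Units: amounts ng, volumes L, time h; doses mg ×10^6; concentrations
  reported in ng/mL.
* Solver: `lsoda`, `rel_tol = 1e-8`, `abs_tol = 1e-10` ng by default;
  1e-10/1e-12 inside sensitivity analyses; 1e-7/1e-9 inside the fit loop.
  Integration is segmented at input discontinuities (infusion start/end,
  oral dose times) so every segment has a smooth right-hand side; the state
  reported at an oral dose time is the post-dose state.
* The compiled C right-hand side is the production path; a line-for-line R
  implementation backs it as a cross-check (trace agreement ~1e-8) and as
  readable documentation of the equations.
* `pk_metrics()` uses trapezoidal AUC on the reported grid (no
  interpolation at window edges; at least two grid points required) and
  first-occurrence tie-breaking for tmax.
* Negative states beyond a tolerance-scaled floor abort with a message
  suggesting tighter tolerances; within-tolerance negatives are clamped to
  zero only in the reported concentration traces, never in the state
  matrix.
* DE defaults: population 15 × n_parameters, ≤300 generations, convergence
  when the relative population spread drops below 1e-6. The test suite and
  acceptance script run the five-parameter recovery at a reduced budget of
  120 generations with 12 observations per arm, which recovers noise-free
  parameters to ≲0.1%; bootstrap refits use population 6–10 and 5–30
  generations plus the polish.

## Known limitations

* The compartment topology follows the conventions of published whole-body
  models for hepatic uptake substrates; the shipped physiology is a
  reference fixture, not a fitted table, and genotype predictions should be
  read as relative contrasts rather than absolute exposures.
* Linear kinetics only; high-dose saturation of uptake or efflux is out of
  scope.
* Heterozygote groups, the \*14 haplotype, and gene–gene interactions are
  not modeled.
* The bootstrap quantifies residual-resampling uncertainty around a mean
  profile, not between-subject variability.
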