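---
title: "Modeling ethanolamine catabolism through the Eut microcompartment"
author: "eutflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling ethanolamine catabolism through the Eut microcompartment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eutflux)
```

## The biological problem

*Escherichia coli* K-12 can use ethanolamine (EA) as a nitrogen — and, as it
turns out, partially as a carbon — source when vitamin B12 is available. EA
catabolism runs inside a protein-shelled organelle, the Eut bacterial
microcompartment (BMC): ethanolamine ammonia-lyase (EutBC) deaminates EA to
acetaldehyde plus ammonium, and the acetaldehyde is disproportionated by the
encapsulated EutE/EutD and EutG enzymes into acetyl-phosphate (exported for
cytosolic use) and ethanol (excreted). Because NAD(H) and CoA cannot cross
the shell, the internal redox and CoA cycles force the EutE, EutD and EutG
fluxes to run at equal rates.

`eutflux` implements the quantitative half of such a study as a reusable
pipeline: estimating extracellular fluxes from batch-culture time courses,
predicting intracellular flux partitioning by compartmentalized flux balance
analysis (FBA), quantifying fluxes *in vivo* with a dynamic ¹³C
isotope-labeling model fitted by particle swarm optimization (PSO),
correcting measured isotopologue distributions for natural isotope
abundance, and converting population fluxes to per-BMC rates. A
synthetic-data module generates culture tables with the statistical
structure the fits assume, so the whole pipeline is testable end to end
without experimental data.

## Extracellular flux estimation

During balanced exponential growth all biomass-specific rates are constant,
giving closed forms

$$X(t) = X_0 e^{\mu t}, \qquad
  S(t) = S_0 - \frac{q_S X_0}{\mu}\left(e^{\mu t}-1\right),$$

and, for a volatile product subject to first-order evaporation at rate $k$,

$$P(t) = P_0 e^{-k t} + \frac{q_P X_0}{\mu + k}
         \left(e^{\mu t} - e^{-k t}\right).$$

`predict_concentrations()` evaluates these (with analytic limits at
$\mu = 0$ and $\mu = -k$), and `fit_physiology()` minimizes the weighted sum
of squared residuals $\sum_i ((x_i - y_i)/\sigma_i)^2$ jointly over all
series by multi-start Levenberg–Marquardt (10 seeded starts by default;
initial guesses come from a log-linear biomass regression and two-point
secants). The ethanol evaporation constant defaults to 0.0379 h⁻¹, the
experimentally determined value for shaken flask cultures, and is fixed
rather than estimated because a single product series contains little
information to separate production from loss; `fit_k_evap = TRUE` frees it.

Standard errors come from Monte-Carlo resampling of residuals (`mc_n`),
seeded for reproducibility. Fitted fluxes are invariant under a common
rescaling of all $\sigma_i$.

**Exponential-phase windowing.** The closed forms are only valid while all
substrates last. Under the default study conditions (30 mM glycerol, 20 mM
EA, $X_0 = 0.026$ gDW/L, $\mu = 0.45$ h⁻¹) glycerol runs out around 8 h, so
a 0–11 h sampling window necessarily includes post-exponential points. The
generator clips negative noiseless values at zero (and says so), and
`truncate_exponential_phase()` drops all points from the first exhaustion
onwards; the pipeline applies it before fitting, which mirrors fitting the
exponential phase only.

## Compartmentalized flux balance analysis

`build_core_model()` returns a deliberately small (27-reaction) elementally
balanced model of glycerol metabolism — exchanges, lumped glycolysis to
acetyl-phosphate, acetate kinase, lumped TCA oxidation and oxidative
phosphorylation, ATP maintenance, and a biomass reaction with the 4:1 C:N
ratio of *E. coli* biomass — a desk-scale stand-in for a genome-scale model.
Any SBML Level 3 + fbc model (e.g. a published genome-scale reconstruction)
can be substituted through `read_sbml()`.

`add_eut_bmc()` installs the BMC compartment: EutBC, EutE, EutD and EutG
with BMC-internal NAD(H) and CoA pools and **no** cofactor transport across
the shell. Cofactor sequestration then makes $v_{EutE} = v_{EutG}$ (NADH)
and $v_{EutE} = v_{EutD}$ (CoA) hold at every feasible flux distribution —
a structural property of the nullspace, which the tests verify both by flux
variability analysis (FVA) and at multiple solved vertices.

`fba()` solves the LP $\max c^\top v$ s.t. $S v = 0$, $lb \le v \le ub$ with
a dense two-phase primal simplex using Bland's anti-cycling rule. FBA
problems of this size are routinely degenerate, and robustness matters more
than speed, so the solver favors the anti-cycling rule over faster pivoting
heuristics; it is checked against brute-force vertex enumeration. Alternate
optima are *not* tie-broken: partition reports describe the returned vertex,
and `fva()` (flux ranges at ≥ a fraction of the optimum, default 99%) is the
tool for uniqueness claims.

With growth fixed to the observed 0.45 h⁻¹, the measured exchange fluxes
imposed (EA −7.8, ethanol 2.6, acetate 1.7, glycerol −14.7 mmol/gDW/h;
uptake negative by exchange-reaction convention) and ATP maintenance as the
objective, the constraints force the equimolar egress split: ethanol,
acetyl-phosphate and acetaldehyde each carry 33% of EA carbon, and the
acetyl-phosphate remaining after acetate excretion (12% of EA carbon) feeds
anabolism. `ea_partition()` reports these shares; excreted acetate is
attributed to BMC-derived acetyl-phosphate, an accounting convention that
follows from assuming acetate and ethanol originate in the BMCs.
Nitrogen-overflow *percentages* are only meaningful on a genome-scale model
with a realistic biomass nitrogen demand; on the bundled core model the
overflow is reproduced qualitatively, not quantitatively.

## The dynamic isotopic model

The tracer experiment grows the culture on unlabeled glycerol plus fully
¹³C₂-labeled EA. The model has three compartments (environment, cytoplasm,
BMC) and tracks every carbon pool as an unlabeled/labeled pair; each
consuming flux splits between the twins in proportion to the instantaneous
label fraction of its substrate pool (well-mixed pools; an empty pool counts
as unlabeled). Reaction structure: growth; glycerol uptake with a lumped
glycolytic flux producing unlabeled cytosolic acetyl-P; EA uptake into the
BMC and deamination; BMC acetaldehyde partitioning between EutG (ethanol),
EutE/EutD (acetyl-P export) and leak to the medium; cytosolic acetyl-P
partitioning between acetate excretion and an anabolic acetyl-CoA sink;
ammonium excretion and growth-coupled assimilation; first-order ethanol
evaporation (0.0379 h⁻¹); and an optional cytosolic unlabeled-ethanol route
for the small residual unlabeled ethanol seen experimentally.

**Free parameters (13).** $X_0$, $\mu$, initial glycerol, EA and ammonium,
$v_{gly}$ (glycerol uptake), $v_{glycolysis}$, $v_{EutG}$, $v_{AAL}$
(acetaldehyde leak), $v_{AceX}$ (acetate excretion), $v_{NH4X}$ (ammonium
excretion), $v_{cytEtOH}$, and the intracellular pool scale. All dependent
fluxes are eliminated through the steady-state balances
($v_{EA} = 2 v_{EutG} + v_{AAL}$, $v_{EutE} = v_{EutD} = v_{EutG}$,
$v_{Pta} = v_{glycolysis} + v_{EutD} - v_{AceX}$), so every candidate
parameter vector is balance-consistent by construction — fitting the raw
flux list directly would almost surely violate the steady-state relations
that the simulator requires as a precondition. Glycerol uptake is a separate
parameter from the glycolytic acetyl-P flux because measured uptake (≈14.7)
far exceeds the acetyl-P production (≈2.5); the difference feeds biomass
directly and is what makes the glycerol time course informative.
`steady_state_flux_relations()` audits externally supplied sets; the
published rounded values leave a 0.1 mmol/gDW/h acetyl-P residual (within
their reported uncertainty), and `reference_flux_set()` resolves it by
deriving $v_{Pta} = 3.6$ from the balance instead of using the rounded 3.5.

**Numerics.** The ODEs are integrated by `deSolve::lsoda` with a C
right-hand side (rtol 1e-8, atol 1e-9 for simulation; one notch looser
inside the objective). Intracellular pools are initialized at their
quasi-steady composition and kept small (default 1e-3 mM in culture-volume
units) so trajectories are quasi-stationary, mirroring the
metabolic-steady-state assumption while keeping the system well posed. Every
uptake or growth flux is multiplied by a saturating availability factor
$S/(S+\varepsilon)$ with $\varepsilon = 10^{-3}$ mM (10⁻⁶ mM for
intracellular pools) so concentrations remain non-negative across substrate
exhaustion. This is a numerical guard, not Monod kinetics: $\varepsilon$
sits three orders of magnitude below quantifiable concentrations, and the
generator and the fitted model share it. Sub-tolerance integrator overshoot
(more negative than 0 but within 1e-7 mM) is clamped; anything larger is an
error. Cumulative sink and evaporation states are co-integrated so carbon
and nitrogen closure is auditable on every run (`carbon_balance()`; the
tests require relative drift < 1e-6).

**Objective and optimizer.** `mfa_objective()` is the weighted SSE over
biomass, glycerol, EA and ammonium totals plus label-resolved ethanol and
acetate, and refuses data without per-point sigmas. `pso_fit()` minimizes it
with constriction-factor PSO ($\chi = 0.729$, $c_1 = c_2 = 1.49445$),
global-best topology and reflecting bounds — the constriction variant is a
standard, provably stable configuration, chosen because only the iteration
count (2000) and swarm size (50) of the original optimization are known.
Runs are deterministic under a fixed seed. An optional local polish
(L-BFGS-B from the swarm optimum) is off by default and used by the
acceptance script for extra robustness across seeds. On synthetic tracer
data at the study fluxes (12 hourly points, 3 replicates, 2% CV), the full
2000×50 fit recovers the BMC ethanol-release flux and the ammonium excretion
flux to about 1%.

Structurally weak parameters remain weak by design: the pool scale barely
influences the observables once pools are quasi-stationary, and
$v_{cytEtOH}$ is identifiable only through the small unlabeled-ethanol
signal. They are reported as fitted values with their bounds, not as sharp
point claims.

## Natural-abundance correction of isotopologue distributions

Measured carbon-isotopologue distributions (CIDs) of amino-acid fragments
include contributions from naturally occurring heavy isotopes.
`build_correction_matrix()` constructs, for each true state $M_j$, the
expected measured mass-shift distribution: the convolution of the natural
mass-shift distributions of all non-carbon atoms, natural ¹³C on the $n-j$
unlabeled carbons, and a tracer-purity binomial over the $j$ labeled
carbons, truncated at $M_n$ (low-resolution mode: nominal mass shifts only,
which matches full-scan Orbitrap CID usage). Defaults: ¹³C 0.0107, ²H
0.000115, ¹⁵N 0.00364, ¹⁷O/¹⁸O 0.00038/0.00205, ³³S/³⁴S 0.0075/0.0425;
tracer purity 1. `correct_cid()` inverts the system by non-negative least
squares — robust to noise and truncation where a direct matrix inverse can
produce negative fractions — renormalizes, and reports the mean enrichment
$\sum_j j M_j / n$. The forward operation (`generate_raw_cid()`) is the
exact convolution, so correction is tested as a round trip and against
brute-force enumeration over isotope placements.

## Per-BMC arithmetic

`per_bmc_flux()` converts a biomass-specific flux to per-cell
(fmol cell⁻¹ h⁻¹ = q × m_cell × 10¹²) and per-BMC rates; defaults
(m_cell = 2.88×10⁻¹³ gDW, ~6 BMCs per cell, 100 nm diameter, 1.3 fL cytosol)
reproduce a per-cell glycolytic flux of 0.72 fmol/cell/h at
q = 2.5 mmol/gDW/h and a BMC volume occupancy of 0.2–4% for 5–100 BMCs.
Every report echoes its inputs, because per-BMC numbers are only as good as
the census assumptions behind them.

## What the synthetic data do and do not emulate

The generator reproduces: the sampling scheme (12 points over 0–11 h, 3
biological replicates), multiplicative Gaussian noise with a 2% CV plus a
0.02 mM additive floor (an assumption standing in for unpublished NMR
quantification errors), label-resolved ethanol and acetate with totals for
the other quantities, tracer purity, ethanol evaporation, clipping of
negative noisy concentrations at zero, and substrate exhaustion. It does
not emulate: lag or stationary-phase physiology (growth simply stops with
glycerol), acetate re-consumption after substrate exhaustion, replicate-
level biological variability (replicates share one true trajectory),
instrument drift, or correlated errors. Passing recovery tests therefore
demonstrates correctness and identifiability of the estimation machinery
under the stated error model — not robustness to every failure mode of real
cultures.

Problem sizes used by the test suite and acceptance script (12×3 tables,
27-reaction core model, 2000×50 PSO) are the package's default study
conditions; the PSO fit is the only long-running step (~2–3 min).

## Design choices made where the design was open

- **LP backend.** Written in-package (two-phase simplex, Bland's rule)
  because general-purpose LP routines available to R here proved fragile on
  degenerate flux polytopes; correctness is anchored to vertex enumeration.
- **SBML subset.** The reader/writer covers the fbc subset constraint-based
  tools exchange (species, formulas, bounds, objective). It is not a general
  SBML implementation.
- **Acetate attribution.** All excreted acetate counts as EA-derived carbon
  in partition reports — a label-free convention, stated in the report, and
  consistent with treating acetate/ethanol as BMC products.
- **Noiseless tables carry a nominal sigma** (1e-6 mM) so weighted
  objectives remain defined; real sigmas always dominate it.
- **Ethanol observables** enter the isotopic fit label-resolved (not as a
  total); the objective also accepts totals, since either convention maps
  onto the simulated observables.
- **k_evap fixed by default** in both the physiology fit and the isotopic
  model; the constant was measured independently, and freeing it degrades
  identifiability of the ethanol production flux.

## Known limitations

- The core FBA model reproduces carbon partitioning exactly but nitrogen
  overflow only qualitatively; quantitative N-overflow claims require a
  genome-scale model supplied as SBML.
- The isotopic model tracks unlabeled vs uniformly labeled species only —
  no positional isotopomers or EMU decomposition — which matches a ¹³C₂-EA
  tracer but cannot resolve partially labeled fragments.
- Fluxes are constant over time; slow adaptation, catabolite effects and
  post-exhaustion metabolism (e.g. acetate re-uptake) are out of scope.
- The per-BMC conversion depends linearly on the assumed cell mass and BMC
  count; with the defaults and an EA flux of 7.8 mmol/gDW/h it yields
  ~0.37 fmol/BMC/h, and census uncertainty of ±20% propagates directly.
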