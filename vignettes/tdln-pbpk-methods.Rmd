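---
title: "Methods: a minimal PBPK model of the tumor-to-draining-lymph-node axis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a minimal PBPK model of the tumor-to-draining-lymph-node axis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdlnpk)
```

## The model and its assumptions

`tdlnpk` implements a deliberately minimal PBPK description of antibody
disposition along the primary tumor (PT) → tumor-draining lymph node
(TDLN) axis. The compartments are: plasma, one lumped non-tumor tissue,
and any number of lesion chains, each consisting of a tumor interstitium
(ISF) and one or more TDLN compartments.

The transport assumptions are:

* **Convection only.** Antibody crosses the vascular wall by solvent drag
  at effective clearance $(1-\sigma_V)\,L$; diffusive exchange and
  two-pore size-selectivity are deliberately omitted. The same applies to
  lymphatic washout with $(1-\sigma_L)\,L$.
* **No direct vascular entry into the node.** Lymph node vasculature is
  dominated by high endothelial venules, which are specialized for
  lymphocyte trafficking and effectively impermeable to macromolecular
  convection. The TDLN vascular reflection coefficient is therefore fixed
  at 1 in every base configuration, making afferent lymph the node's only
  supply route. Consequently, setting `L_aff = 0` provably isolates the
  node (a test asserts the TDLN trajectory is exactly zero).
* **Quasi-equilibrium target binding.** Antibody–target association and
  dissociation are fast relative to turnover and transport, so free
  antibody, free target, and complex solve an algebraic mass-action
  relation at each instant. The binding layer is applied inside every
  right-hand-side evaluation; no separate complex state is integrated.
  The test suite quantifies this assumption by comparing against an
  explicit-kinetics model ($k_{on} = 100\,/\mathrm{nM/h}$,
  $k_{off} = k_{on} K_d$): total-antibody trajectories agree within 0.1%
  for the renal parameter set over two weeks, well inside the 2% band we
  consider acceptable.
* **Flows as independent clearances.** Organ lymph flow feeding a lesion
  (`L_organ`, 0.001–0.082 L/h across the registry) and the afferent node
  flow (`L_aff`, 0.004 L/h) are both literature-derived constants; they
  are not forced to balance. Excess interstitial convection implicitly
  returns to plasma without carrying antibody. We track antibody mass,
  not fluid, and the mass balance of what we do track is audited: with
  clearance, internalization and transit loss switched off, total
  antibody is conserved to ~1e-15 relative error across all eleven
  parameter sets.
* **Target turnover.** Free target relaxes toward its baseline $R_0$ via
  $k_{syn} = k_{deg} R_0$ and $k_{deg}$; the internalized complex
  ($k_{int}$) is the only target-mediated antibody sink. $k_{deg}$ acts
  on free target only and $k_{int}$ on complex only. A useful consequence
  of the registry's $k_{deg} = k_{int} = 0.01\,/h$ equality: the total
  target pool obeys $dR_{tot}/dt = k_{deg}(R_0 - R_{tot})$ and stays
  pinned at $R_0$ along every trajectory.
* **No radiochemistry.** The model predicts intact-antibody
  concentrations; residualizing isotopes, decay and partial-volume
  effects are out of scope, so predicted SUV is a mean-type, intact-drug
  signal.

## Lymphatic transit survival

Antibody in afferent lymph passes through lymphatic endothelium where a
fraction is pinocytosed; the FcRn-bound share,
$f_{FcRn} = [FcRn]/([FcRn]+K_{d,FcRn})$ at $[FcRn] = 40\,\mu M$, is
recycled intact and continues downstream (it is not returned to plasma),
the remainder is degraded. We model cumulative survival with a
power-shape law

$$F_{surv} = \bigl(1 - p_{up}\,(1-f_{FcRn})\bigr)^{n_{ref}/d_{ln}},$$

with per-event pinocytosis probability $p_{up} = 0.1$ and reference event
count $n_{ref} = 100$, both configurable. The organ-specific shape factor
$d_{ln}$ (19–63 in the registry) attenuates cumulative loss: larger
$d_{ln}$ means higher survival, which matches the direction we enforce in
the sensitivity suite (TDLN exposure non-decreasing in $d_{ln}$). We note
the opposite reading — a longer lymphatic path causing *more* loss — is
also defensible a priori; because the survival law is registered as a
named strategy (`register_transit_strategy()`), an alternative
monotonicity can be swapped in without touching the ODE core, and we do
not silently reinterpret the default. For the registry values the default
law yields survivals of 0.97–1.00.

## SUV conversion

Standardized uptake value is tissue activity concentration divided by
injected dose per body weight. We model the tissue signal as a
two-component volume-weighted sum — interstitial antibody at fraction
$f_{ISF} = 0.2$ (the same 20% ISF fraction used to derive the registry's
ISF volumes) plus residual vascular antibody at $f_{vasc} = 0.05$ — with
tissue density 1 g/mL:

$$SUV = \frac{(f_{ISF}\,C_{tot} + f_{vasc}\,C_p)\; MW \cdot 10^{-6}}
{dose_{mg}/BW_{kg}}.$$

Plasma SUV uses $f_{ISF}=0$, $f_{vasc}=1$. This reproduces the
definitional identity (uniform distribution of the dose in body water
gives SUV 1) and plasma SUV scales of order 10 for a 10 mg tracer dose.
Because clinical reports mix SUVmean/SUVmax/SUVpeak, a per-study
multiplicative `suv_scale` is exposed (default 1) and can be estimated
during calibration. Tracer protein doses are study-specific and rarely
comparable; the package default is a 10 mg, 70 kg IV bolus.

## Parameters that matter

| Parameter | Units | Default / range | Role |
|---|---|---|---|
| `sigma_v_pt` | – | 0.65–0.97 (registry) | tumor vascular reflection; $(1-\sigma_V)L_{organ}$ is the uptake clearance |
| `sigma_l` | – | 0.2 | lymphatic reflection, shared |
| `L_organ` | L/h | 0.001–0.082 | organ lymph flow (0.2% of organ blood flow) |
| `L_aff`, `L_eff` | L/h | 0.004 | afferent/efferent node flows, shared |
| `V_isf_pt` | L | 0.001–0.265 | 20% of lesion volume |
| `V_isf_tdln` | L | 5.84e-5 | 20% of an average node volume |
| `R01`, `R02` | nM | 1–1000 | baseline target density in PT / TDLN |
| `Kd` | nM | 0.058–5 | antibody–target affinity |
| `k_deg`, `k_int` | 1/h | 0.01 | target turnover / complex internalization |
| `dln` | – | 19–63 | lymphatic path shape factor |
| `Kd_FcRn` | nM | 774–2400 | FcRn affinity |
| `CL_p` | L/h | 0.0083–0.075 | plasma clearance |

The lumped non-tumor tissue compartment has no study-specific data behind
it; we use standard minimal-PBPK values (`L_tissue` = 0.12 L/h, roughly
total lymph flow minus tumor flows; `sigma_v_tissue` = 0.95;
`V_isf_tissue` = 8.4 L), all configurable. Only plasma/PT/TDLN outputs
are ever compared to observations.

## Calibration

`fit_suv()` performs box-constrained Levenberg–Marquardt least squares on
SUV residuals, by default weighted by reported SDs where available, with
an optional Latin-hypercube multistart under a fixed seed
(deterministic). Two numerical points deserve mention. First, the
finite-difference Jacobian must step well above the ODE solver's noise
floor; we set the relative step to ~1e-3 (`epsfcn = 1e-6`), without which
the optimizer stalls on solver noise. Second, practical identifiability
is probed at the optimum with 2-fold parameter perturbations: a free
parameter whose perturbation moves the objective by less than 5%
(relative) is flagged non-identifiable rather than reported as a point
estimate. Under this model, node target density (`R02`) and the transit
shape factor (`dln`) are flat from plasma-only data, and the test suite
asserts exactly that; tumor target density (`R01`) is *weakly*
identifiable even from plasma alone, because the efferent return path
couples tumor binding back to plasma at the ~10% level over ten days —
a structural property worth knowing before trusting plasma-only fits.

## Clinical scenario transforms

* **Surgery** (`apply_surgery`): resection zeroes the tumor target
  (R01 = 0; the tumor-bed compartment is kept, since the tissue and its
  drainage persist) and lymphedema scales `L_organ` and `L_aff` by
  $(1-\mathrm{reduction})$; 0.5 and 0.8 represent moderate and severe
  impairment. TDLN exposure is strictly decreasing in the reduction.
  Note the pre-surgery tumor (R01 > 0) is *not* comparable to the
  0-reduction post-surgery state: removing the target frees antibody for
  lymphatic transit, so the tumor-free, flow-intact node actually sees
  more antibody than it did before resection.
* **Metastasis** (`build_metastasis_model`): lesions share plasma but
  carry their own vascular leakiness, lymph flows, target densities and
  transit path; a lung metastasis defaults to the lung row's physiology.
  A target-rich metastasis (R01 ≫ R02) consumes free antibody locally
  and starves its own TDLN — exposure drops to ~30% of the
  matched-density case in the renal example.
* **Inflammation** (`apply_inflammation`): the tumor's efflux is split
  across several TDLN branches in proportion to per-branch afferent
  flows. Compression of intratumoral lymphatics is represented by a
  multiplier near 0 (default 0.01) and inflammation-enhanced peritumoral
  flow by a multiplier of 2; both are unquantified clinically, so the
  defaults are explicit, configurable placeholders. Branch influx
  splitting is mass-conserving by construction and audited by test.

## Sensitivity analysis

`local_sensitivity()` sweeps one parameter at a time over an 11-point
fold grid (0.1–100×), holding everything else fixed, and reports
per-tissue AUC, peak SUV, a monotone direction, and a score
$\max_f |AUC_f - AUC_{ref}|/AUC_{ref}$ (insensitivity threshold 5%, a
package convention). Reflection coefficients are swept on restricted
ranges ($\sigma_V$ absolute in [0.01, 1.25], $\sigma_L$ 0.1–5×) and
clamped at the physical ceiling of 1 with a recorded warning, rather than
simulated as nonphysical. The `R01/R02` ratio sweep scales R01 with R02
held fixed. When `k_deg` is swept, the synthesis rate is re-derived as
$k_{syn} = k_{deg} R_0$ per the parameter contract, preserving the
drug-free baseline at every fold.

One behavior deserves an honest flag: although `k_deg` is often regarded
as an inert parameter, in this model it is not inert at the tumor when
binding saturates the target (renal set: $C_f \gg K_d$). Scaling `k_deg`
scales target resupply, which is rate-limiting for the bound pool, so PT
AUC rises monotonically across the grid (score ≈ 0.46 on the renal set,
as recomputed by `scripts/acceptance.R`). The TDLN is nearly insensitive
(score ≈ 0.08). Holding $k_{syn}$ fixed instead would shift the baseline
fixed point by 1/fold and be even more sensitive — there is no variant of
these turnover equations in which `k_deg` is numerically silent at a
saturated tumor, and we report the model as it is.

## Synthetic data: what it does and does not emulate

`generate_observations()` emulates sparse immuno-PET sampling — by
default three scans at days 2, 4 and 7 in plasma, PT and TDLN, six
subjects, and mean-preserving multiplicative lognormal noise at 20% CV
(additive Gaussian is available). It reproduces the *sampling structure
and dispersion* of clinical antibody imaging, with known ground truth for
recovery studies. It does not emulate: digitization error, residualizing
isotope accumulation, SUV-variant mixing between studies, inter-patient
physiological variability (a single parameter set generates all
subjects), or model misspecification. Passing recovery tests therefore
demonstrate estimator correctness under the model's own assumptions, not
robustness to real-data violations of them.

## Numerical choices

* Integration: `deSolve::lsoda` (stiff-capable), rtol 1e-8, atol 1e-10 nM
  for simulation; 1e-6/1e-8 inside fitting objectives, where the
  objective is smooth at that level. State is clipped at zero before each
  binding solve; non-finite states abort with a diagnostic snapshot.
* Binding quadratic: evaluated in the rationalized form
  $C_b = 2\,C_{tot}R_{tot}/(b+\sqrt{b^2-4C_{tot}R_{tot}})$,
  $b = C_{tot}+R_{tot}+K_d$, which is stable in the weak-binding limit
  where the textbook root cancels catastrophically; the result is clamped
  to the feasible box against last-ulp excursions.
* Transit survival is evaluated in the log domain for large exponents.
* State ordering is deterministic: plasma, lumped tissue, then per lesion
  (total antibody, total target) followed by its branches in declaration
  order.
* Problem sizes: simulations use 2–4 h output grids over 336 h (AUCs
  change by <0.1% on grid halving); recovery studies use 5 scan times ×
  3 tissues × 6 subjects and 50 replicates, sizes at which the full suite
  runs in a few minutes on one core.

## Known limitations

* The ODE structure is a minimal-PBPK reconstruction; organ-specific
  blood-flow-limited compartments, two-pore extravasation and endosomal
  FcRn kinetics are intentionally absent.
* Relative organ-to-organ uptake is compressed for very slowly cleared
  antibodies: a low-`CL_p` study (e.g. atezolizumab, 0.0083 L/h)
  accumulates toward its convective quasi-equilibrium over two weeks, so
  the renal-vs-brain/lung peak-uptake fold computed by the acceptance
  script is ≈ 2.1 — the renal study dominates every brain/lung study
  individually, but by less than the often-quoted five-fold.
* Efferent lymph is assumed to carry free antibody only (cell-bound
  complex stays in the node); the alternative (total antibody) would
  modestly raise plasma recirculation.
* The model is a population-average, qualitative gradient-prediction
  tool; per-patient calibration would require richer longitudinal data
  than current imaging studies provide.
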