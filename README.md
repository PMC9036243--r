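# tdlnpk

A minimal physiologically based pharmacokinetic (PBPK) framework for
therapeutic IgG antibodies that quantifies concentration gradients from
plasma into organ-specific primary tumors (PT) and their tumor-draining
lymph nodes (TDLN).

Adequate antibody exposure in *both* the tumor and its draining nodes is a
prerequisite for effective checkpoint-blockade immunotherapy, especially
in the neoadjuvant setting where T-cell priming in the TDLN matters most.
Yet the TDLN is reached almost exclusively through afferent lymph: high
endothelial venules make direct vascular entry negligible, and antibody
travelling along lymphatic vessels is pinocytosed by endothelial cells and
only partially salvaged by FcRn. `tdlnpk` is aimed at modelers and
translational scientists who want to simulate, calibrate and stress-test
this PT–TDLN delivery axis.

## The model

Plasma (volume $V_p$, clearance $CL_p$) feeds each lesion interstitium by
convective extravasation and a lumped non-tumor tissue compartment:

$$V_p \frac{dC_p}{dt} = -CL_p C_p - \sum_i L_{organ,i}(1-\sigma_{V,i})C_p
 - L_{tis}(1-\sigma_{V,tis})C_p + \sum_j L_{eff,j} C_{f,j}
 + L_{tis}(1-\sigma_L)C_{tis}$$

$$V_{ISF,PT}\frac{dC_{tot,1}}{dt} = L_{organ}(1-\sigma_V)C_p
 - L_{aff}(1-\sigma_L)C_{f,1} - k_{int}C_{b,1}V_{ISF,PT}$$

$$V_{ISF,TDLN}\frac{dC_{tot,2}}{dt} =
 L_{aff}(1-\sigma_L)\,F_{surv}\,C_{f,1} - L_{eff}C_{f,2}
 - k_{int}C_{b,2}V_{ISF,TDLN}$$

Free and bound antibody ($C_f$, $C_b$) are resolved at every instant by
quasi-equilibrium mass-action binding to a target with baseline density
$R_{01}$ (PT) or $R_{02}$ (TDLN), turnover $k_{syn} = k_{deg}R_0$,
$k_{deg}$, and complex internalization $k_{int}$. Transit survival
$F_{surv} = (1 - p_{up}(1 - f_{FcRn}))^{n_{ref}/d_{ln}}$ captures
pinocytosis/FcRn-salvage loss along the lymphatic path, with
$f_{FcRn} = [FcRn]/([FcRn]+K_{d,FcRn})$ and an organ-specific shape
factor $d_{ln}$. Tissue concentrations convert to immuno-PET standardized
uptake values as
$SUV = (f_{ISF} C_{tot} + f_{vasc} C_p)\,MW \cdot 10^{-6} / (dose/BW)$.

The package ships eleven validated antibody:tumor parameterizations
(bevacizumab, trastuzumab, fresolimumab, MMOT0530A and atezolizumab
across renal, breast, lung, brain, esophagogastric, pancreatic, ovarian
and bladder cancers), least-squares calibration against sparse SUV
observations, clinical scenario transforms (metastasis, surgical
resection with lymphedema, inflammation-remodeled TDLN networks), local
one-at-a-time sensitivity analysis, and a synthetic immuno-PET data
generator for parameter-recovery studies.

## Worked example

```r
library(tdlnpk)

study <- get_study("bevacizumab_renal")
study
#> <study_params> bevacizumab_renal  (bevacizumab in renal cell carcinoma)
#>   sigma_v = 0.97 | L_organ = 0.082 L/h | V_ISF,PT = 0.06 L | V_p = 5 L
#>   R01 = 10 nM | R02 = 2.5 nM | Kd = 0.058 nM | Kd,FcRn = 2400 nM
#>   dln = 21 | CL_p = 0.042 L/h

traj <- simulate_model(study, dose_spec(10), times = seq(0, 336, by = 2))
summarize_gradient(traj)
#> <gradient_summary> AUC(PT) = 3301 nM h | AUC(TDLN) = 1036 nM h
#>   PT:TDLN AUC ratio = 3.18
#>   peak SUV: plasma 14 | PT 3.32 | TDLN 1.58
```

A 10 mg bolus (13.3 nM in 5 L of plasma) gives a plasma SUV of 14 at time
zero that decays with `CL_p`; tumor uptake peaks near SUV 3.3 around day
2–3, and the draining node — supplied only by afferent lymph, after ~3%
transit loss — peaks near SUV 1.6. The PT:TDLN AUC ratio of 3.2 is the
steepest gradient among the eleven studies, driven by the renal tumor's
four-fold target-density excess (R01 = 10 vs R02 = 2.5 nM).

What-if scenarios are one-line transforms of a base study:

```r
post_op <- apply_surgery(study, lymph_reduction = 0.5)   # R01 = 0, flows halved
net <- apply_inflammation(study, list(
  tdln_branch_spec("TDLN_intra", "intratumoral", "positive"),
  tdln_branch_spec("TDLN_peri",  "peritumoral",  "positive")))
sens <- local_sensitivity(study, "Kd")                    # 11-point fold grid
```

A thin command-line wrapper is installed as `exec/tdlnpk`
(`tdlnpk simulate --study bevacizumab_renal --dose-mg 10 --t-end 336
--out traj.csv`, plus `fit`, `scenario`, `sensitivity`, `synth`).

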