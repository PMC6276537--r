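# spineLTP

Biophysical simulation of opioid-induced pathological long-term
potentiation (LTP) in a dendritic spine of a hippocampal CA1 pyramidal
neuron, for computational neuroscientists studying how opioids hijack
synaptic plasticity.

Opioids at a glutamatergic synapse weaken the voltage-dependent Mg²⁺ block
of the NMDA receptor and enhance its conductance. The model couples:

* a passive spine membrane, τ_post·dV/dt = −(V − V_rest) + R_m·I_syn,
  driven by kinetic (two-state) AMPA and NMDA receptors,
  dm/dt = α·T·(1 − m) − β·m, under a periodic glutamate pulse train T(t);
* a Woodhull-type Mg²⁺ block with opioid-dependent affinity and electrical
  distance, Mg = [1 + [Mg]₀·e^(−z(δ+0.1s)FV/RT)/(k₀ + 15.58·s)]⁻¹, where
  s(Op) is a saturating function of opioid concentration;
* NMDAR conductance g_NMDA = g_VI + 0.15·s(Op) + g_VD, with g_VD relaxing
  toward max(k(V − V₀), 0);
* stochastic high-voltage-activated calcium channels, with a binomial
  number of open channels B(N, P_open(V)) drawn each integration step;
* spine calcium with the rapid-buffer approximation,
  dc/dt = [−(η·I_AMPA + γ·I_NMDA + I_R)/(z_Ca F V_spine) − K_s(c − c_rest)]
  /(1 + θ(c));
* the CaMKII/PP1/inhibitor-1 bistable switch (eleven phosphorylation
  states P0..P10), whose readout Ph.CaMKII = ΣᵢPᵢ (i ≥ 1) gates the AMPAR
  conductance sigmoid g_AMPA = g_AMPA0·(1 + 1/(1 + e^(−(Ph−40)/0.4))).

LTP is flagged when Ph.CaMKII exceeds the AMPAR phosphorylation threshold
(40 µM) and the AMPAR conductance rises from 0.4 toward 0.8 nS.
Integration is fixed-step forward Euler at 0.05 ms with seeded,
bit-reproducible randomness (the binomial channel draw is the only RNG
consumer). See `vignette("spineLTP-methods")` for the model description,
unit conventions, the calibrated parameter set and its rationale.

## A worked example

```r
library(spineLTP)

normal <- simulate_spine(condition = opioid_condition(Op = 0),
                         config = sim_config(seed = 1))
opioid <- simulate_spine(condition = opioid_condition(Op = 1),
                         config = sim_config(seed = 1))
normal
#> Spine simulation: Op = 0 uM, 5 Hz / 4 ms / 0.2 mM, 10 s
#>   peak Ph.CaMKII :    1.870 uM
#>   final Ph.CaMKII:    1.870 uM
#>   final g_AMPA   :   0.4000 nS (baseline 0.4)
#>   LTP induced    : FALSE (threshold 40 uM)
opioid
#> Spine simulation: Op = 1 uM, 5 Hz / 4 ms / 0.2 mM, 10 s
#>   peak Ph.CaMKII :  100.000 uM
#>   final Ph.CaMKII:  100.000 uM
#>   final g_AMPA   :   0.8000 nS (baseline 0.4)
#>   LTP induced    : TRUE (threshold 40 uM)
```

Without opioid the 5 Hz / 0.2 mM train leaves CaMKII essentially
unphosphorylated and the AMPAR conductance constant — no LTP. With 1 µM
opioid the same stimulus drives the kinase switch to saturation and
doubles the AMPAR conductance: pathological LTP.

The mechanism dissection and the sweeps:

```r
run_five_conditions(seeds = 1:5)
#>   label raw_phospho_camkii ... normalized_camkii   ltp
#>  normal              2.287                0.0000  FALSE
#>  opioid            100.000                1.0000   TRUE
#>    CK=0              2.578                0.0030  FALSE
#>   CMg=0            100.000                1.0000   TRUE
#>   Icr=0             99.426                0.9941   TRUE

detected_threshold(sweep_nmdar_coefficient(seeds = 1:5))   # 0.3
detected_threshold(sweep_glutamate_amplitude(seeds = 1:5)) # 0.14
```

Removing the opioid effect on NMDAR conductance (CK=0) abolishes LTP;
removing its effect on the Mg²⁺ block (CMg=0) barely matters; removing the
VGCC current (Icr=0) attenuates it. The conductance-coefficient sweep is
all-or-none with the first LTP-positive coefficient at 0.3, and lowering
the glutamate amplitude from 0.2 mM in 0.01 mM steps preserves LTP down to
0.15 mM, with a sharp collapse at 0.14 mM.

A thin command-line front end over the same functions is shipped in
`inst/cli/spineltp.R`:

```sh
Rscript inst/cli/spineltp.R simulate --op 1 --seed 42 --out out/
Rscript inst/cli/spineltp.R compare-conditions --seeds 5 --out out/
Rscript inst/cli/spineltp.R sweep --param glut_amp --out out/
```

Parameters load from YAML (`read_spine_config()`); the pinned calibrated
defaults live in `inst/extdata/default_config.yaml`.

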