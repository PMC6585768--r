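# striatobot

A spiking-network model of striatal action selection coupled to a virtual
robot, for computational neuroscientists studying how the direct ("Go",
D1) and indirect ("No-Go", D2) basal-ganglia pathways cooperate and compete.

The model: two independent hemispheres, each a 6 × 6 edge-wrapped grid of 36
*channels* (candidate actions) holding 40 D1- and 40 D2-type medium spiny
neurons (MSNs). Neurons are conductance-based leaky integrate-and-fire
units,

    C_m dV/dt = −g_L (V − V_rest) − g_ex (V − E_ex) − g_in (V − E_in) + I_ext,

connected by GABAergic synapses whose probability is a base pairwise rate
ρ(pre, post) scaled non-monotonically with channel distance — ×1.2 within a
channel, ×3.4 to the 8 neighbouring channels, ×0.3 beyond — so lateral
inhibition peaks one channel (≈40 µm) away. Two neighbouring channels per
hemisphere are wired (contralaterally) to a planar unicycle robot through an
exponential rate filter (τ = 200 ms) and sigmoid-bounded action commands

    a_l = Sig(S_D1/N_D1 · f_r^D1 − S_D2/N_D2 · f_r^D2),   Sig(x) = 2/(1+e^{−4x+4}),
    v = (a_l + a_r)/2,   θ = a_l − a_r,

so D1 activity drives its motor and D2 activity brakes it, with v < 2 m/s
and θ ∈ (−2, 2) rad/s by construction.

The package implements the full experiment suite around this model:
optogenetics-style DC paradigms (bilateral/unilateral excitation and
inhibition), cortical-like Poisson sequence and competing-action paradigms,
a simulated GABA-antagonist disinhibition experiment discriminating
connectivity kernels, and the analyses — binned rates, calcium-like
(τ = 300 ms) filtered-spike-train Pearson correlations by spatial category,
subsampled correlation matrices, sliding-window D1–D2 population
correlations with shuffle controls, winning-channel/selected-action
detection, and recruitment-distance distributions.

## Worked example

```r
library(striatobot)

run  <- run_paradigm("no_stim",      seed = 3)   # background only
amb  <- run_paradigm("bilateral_D1", seed = 3, net = run$network)
frz  <- run_paradigm("bilateral_D2", seed = 3, net = run$network)

path_length(run$trajectory, c(5000, 15000))  # 3.32 m
path_length(amb$trajectory, c(5000, 15000))  # 19.96 m
path_length(frz$trajectory, c(5000, 15000))  # 0.14 m
max(amb$commands$v)                          # 2.00  (saturated; bounded by 2 m/s)
```

Driving all D1-MSNs with +115 pA during seconds 5–15 multiplies the path
travelled by ~6 (ambulation); driving D2-MSNs with +160 pA abolishes
movement (freezing). Unilateral manipulations turn the robot: e.g.

```r
heading_change(run_paradigm("unilateral_D1_exc", seed = 3,
                            net = run$network)$trajectory,
               c(5000, 15000))               # -16.25 rad: contralateral (right) turns
```

The disinhibition experiment recovers the connectivity profile: neurons
recruited only after a simulated GABA antagonist (inhibitory weights at
20%) sit predominantly one channel away from control-recruited neurons when
connectivity is non-monotonic:

```r
rec <- run_recruitment_experiment("non_monotonic", n_trials = 5, seed = 11)
rec$mode                                     # 1.0  (channel distance, ≈ 40 µm)
```

## Command line

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/striatobot.R list-paradigms
Rscript inst/cli/striatobot.R run sequences_D1 --seed 7 --trials 5 --out out/
Rscript inst/cli/striatobot.R reproduce --seed 1 --out acceptance.json
```

`run` writes `neurons.csv`, `synapses.csv`, `spikes.csv`, `trajectory.csv`
and a JSON config snapshot per trial.

See `vignettes/striatobot-methods.Rmd` for the model's assumptions,
parameter choices, calibration, and known limitations.
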