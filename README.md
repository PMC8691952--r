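# cabletron

Can a single neuron *learn* to exploit its dendrites? `cabletron` is an R
package for studying synaptic credit assignment and plasticity in detailed
compartmental neuron models. It provides:

* a multi-compartment **biophysical simulator** (discretized cable
  equations + Hodgkin-Huxley somatic spiking + AMPA/NMDA/GABA synapses,
  with the NMDA magnesium-block sigmoid that produces supralinear
  dendritic integration), built on a tree-sparse implicit Euler solver
  with compiled inner loops;
* the coupled **variational (forward-sensitivity) equations** that track
  `dv_soma/dw` for every synapse through the full nonlinear dynamics —
  an exact answer to "how much would this synapse's weight change move
  the somatic voltage right now?";
* **plasticity kernels** `K(Δt, v_dend)`: polynomial fits of
  spike-triggered averages of those gradients over two locally available
  variables (presynaptic lead time and local dendritic voltage), the
  local surrogate that makes the learning rule biologically plausible;
* a supervised, tempotron-style **learning rule**
  `Δw_i = -α Ē_p Σ_k K_i(Δt_ik, v_dend_i)` with an adaptive teaching
  current, plus an online variant driven purely by the neuron's spiking;
* parameterized **input ensembles** spanning rate codes, precisely timed
  bursts and dense temporal codes at fixed population rate, association
  (feature-binding) tasks, noise manipulations, and structured synapse
  placement;
* **analysis** tools: subthreshold summation nonlinearity, spatial /
  temporal / spatiotemporal weighted input profiles and their
  correlations, and label prediction from learned profile structure.

Morphologies come from SWC reconstructions (`read_swc()`,
`repair_morphology()`, `discretize_morphology()`) or from the built-in
synthetic branched-tree generator (`synthetic_tree()`), so everything
runs without downloads.

## Worked example

Gradients of the somatic voltage with respect to synaptic weights,
verified against brute-force perturbation:

```r
library(cabletron)

geom  <- synthetic_tree(3, 2, 1, seed = 3)      # 129-compartment fixture
spec  <- biophysics_spec("active")              # NMDA nonlinearity on
lay   <- place_synapses(geom, n_e = 16, n_i = 4, seed = 5)
set.seed(42)
trains <- lapply(1:20, function(j) sort(runif(rpois(1, 3), 20, 280)))

sens <- simulate_with_sensitivities(geom, spec, lay, trains, horizon = 300,
                                    active_set = 1:20, sample_times = 300)
round(range(sens$sens_vsoma), 1)
#> [1]  -86.1 1259.5        # mV/uS: inhibitory negative, excitatory positive

# central finite differences on synapse 1 agree to ~1e-5 relative error
eps <- 1e-5; fd <- 0
for (s in c(-1, 1)) {
  l2 <- lay; l2$w[1] <- l2$w[1] + s * eps
  fd <- fd + s * simulate_neuron(geom, spec, l2, trains, 300)$v_soma[12001] / (2 * eps)
}
```

A synapse's influence is large when it was recently active and its local
branch is depolarized into the NMDA operating range — exactly the two
variables the plasticity kernels condition on. Fitting kernels and
training the 2 x 2 nonlinear feature-binding task end to end:

```r
geom2   <- synthetic_tree(6, 3, 1, seed = 1)
lay2    <- place_synapses(geom2, 200, 50, w_e = 2.4e-3, w_i = 3.2e-3)
camp    <- run_gradient_campaign(geom2, spec, lay2, n_runs = 20,
                                 run_length = 2000, seed = 3,
                                 w_range = c(0.4e-3, 1e-3) * 4)
kernels <- fit_all_kernels(camp)          # held-out R2 per stratum
#> held-out R2: basal_E=0.88, apical_E=..., basal_I=0.89, ...
task    <- make_task(input_preset("rate", n_syn = 250), n = 2, seed = 7)
fit     <- train_offline(geom2, spec, lay2, task, kernels,
                         train_config(lambda_syn = 40,
                                      alpha0 = 2e-6 / 40 * 4), seed = 5)
evaluate_model(geom2, spec, fit$layout, task)$p_test
#> [1] 0.7
```

`P_test` is the fraction of correct spike/silence classifications over 20
test presentations per pattern (chance 0.5; a purely linear solution of
the 2 x 2 task caps at 0.75). The methods vignette discusses what desk
scale does and does not show about the full-scale comparison between the
active, passive and point-neuron variants.

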