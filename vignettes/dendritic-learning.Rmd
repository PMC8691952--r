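---
title: "Learning nonlinear dendritic computation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning nonlinear dendritic computation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cabletron` implements a complete pipeline for studying how a single
neuron can learn nonlinear computations through synaptic plasticity: a
multi-compartment biophysical model of a layer 2/3 pyramidal cell, a
forward-sensitivity (variational) system that quantifies every synapse's
influence on the somatic voltage, local plasticity kernels distilled from
those sensitivities, and a supervised spike-timing- and voltage-dependent
learning rule evaluated on feature-binding classification tasks. This
vignette documents the models, the numerical choices, and the reasoning
behind the design decisions that were genuinely open.

## The biophysical model

The dendritic tree is discretized into cylindrical compartments (each
branch at least two compartments, none longer than 10 um) plus a lumped
isopotential axo-somatic sphere of radius 10 um that replaces the soma and
axon. The membrane potential in compartment $i$ obeys the discretized
cable equation

$$c_m \dot v_i = -\sum_j H^E_{ij} w^E_j\Big(\tfrac{1}{1+\gamma} g^A_j(t)
 + \tfrac{\gamma}{1+\gamma} g^N_j(t)\,\sigma_N(v_i)\Big)(v_i - E_E)
 - \sum_k H^I_{ik} w^I_k g^G_k(t)(v_i - E_I) - I^{\text{act}}_i
 - g_L (v_i - E_L) + \sum_l G_{il} v_l ,$$

where $H^E, H^I$ project synaptic conductances into their compartments
(normalized by membrane area so that the equation is in mV/ms), $G$ is
the axial coupling matrix built from half-compartment series resistances,
and $I^{\text{act}}_i$ collects the Hodgkin-Huxley currents
($g_{Na} m^3 h$, $g_K n^4$, $g_{Km} p$, and in the extended variant
$g_{Ih} q$). Synaptic activations $g^A, g^N, g^G$ are unit-peak double
exponentials summed linearly over presynaptic spikes (AMPA 0.1/2 ms, NMDA
2/75 ms, GABA 1/5 ms rise/decay). The NMDA conductance is gated by the
magnesium-block sigmoid $\sigma_N(v) = 1/(1 + C e^{-\rho v})$ with
$C = 1/3.75$, $\rho = 0.062$; the *passive* variant sets
$\sigma_N \equiv 1$ and the *point* variant relocates all synapses to the
soma. Passive parameters: $c_m = 1\,\mu F/cm^2$, $r_m = 10^4\,\Omega
cm^2$ (so $\tau_m = 10$ ms), $r_a = 150\,\Omega cm$, $E_L = -75$ mV.

Gate kinetics use the standard regular-spiking cortical rate functions
with threshold-adjustment voltage $v_T = -56.2$ mV. The slow
potassium (adaptation) gate's time-constant parameter is set so that the
peak of $\tau_p(v)$ equals the stated adaptation time constant of 200 ms.
The HCN gate uses the published somato-dendritic Ih rate functions; its
density (0.1 mS/cm^2 in the extended variant) reproduces a 1-2 mV sag
under hyperpolarizing current. These choices are validated in the test
suite by their functional signatures — an approximately linear f-I curve
above rheobase, lengthening inter-spike intervals under constant current,
and the sag amplitude — rather than by transcribed numbers alone.

The resting state initializes $v = E_L$ with gates at their steady state
for $E_L$. Because the adaptation conductance is partially open at rest,
the true somatic fixed point sits 1-2 mV below $E_L$; analyses that
measure EPSP amplitudes therefore settle for ~150 ms and subtract a
baseline run rather than assuming rest equals $E_L$.

## Numerics: the tree-sparse implicit Euler solver

Each step (default `dt` = 0.025 ms) proceeds: (1) gates advance by an
implicit update using voltage-stale rates; (2) synaptic states decay
exactly and absorb spikes event-driven (mathematically identical to
re-summing the double exponential over all past spikes, but O(1) per
step); (3) the voltage system is linearized about the current state —
the NMDA sigmoid frozen at the stale voltage — and solved *exactly* by
ordered elimination on the tree (Hines-style), cost linear in the number
of compartments. Somatic spikes are detected as upward 0 mV crossings
with linear interpolation; reported spike times are the crossing minus
2 ms, the functional threshold-crossing time at which the voltage is
still susceptible to synaptic control. The scheme is first-order; a
Richardson ratio of ~2 under step halving is asserted in the tests, and
dt-sensitive analyses use the default step throughout.

## The variational (sensitivity) system

For each synapse $j$ the matrix $\delta v_{ji} = \partial v_i / \partial
w_j$ and the corresponding gate sensitivities are integrated alongside
the model. Rather than discretizing the continuous sensitivity equations
independently, the implementation differentiates the *discrete* forward
map exactly: the chain rule is applied through the staggered gate update
(with analytic-accuracy numeric derivatives of the rate functions), the
voltage-stale NMDA sigmoid, and the implicit voltage solve, reusing the
same tree factorization for every synapse's right-hand side. Two
consequences: the sensitivity system is linear in $\delta$ given the
forward trajectory (superposition holds to machine precision), and the
integrated sensitivities agree with central finite differences of the
solver itself to ~1e-5 relative error in subthreshold regimes — the test
suite asserts <1%. Near spike threshold gradients are intrinsically
ill-conditioned; the kernel-fitting protocol below avoids the regime
rather than fighting it.

The diagonal of the Jacobian includes the inhibitory conductance term
$\sum_k H^I_{ik} w_k g^G_k(t)$: it belongs to $\partial f/\partial v$
even though it is easy to overlook, and the finite-difference oracle
fails without it whenever inhibition is active.

## Plasticity kernels from spike-triggered averages

The influence of a synaptic activation on a somatic spike is summarized
by two locally available variables: the activation's lead time
$\Delta t$ before the spike and the dendritic voltage $v_{dend}$ at the
synapse when the spike occurs. Kernels $K(\Delta t, v_{dend})$ are fitted
per stratum (basal/apical x excitatory/inhibitory) from campaigns of
random-bombardment simulations: per-synapse Poisson rates drawn from
lognormal(0, 1) Hz, weights redrawn uniformly (0.4-1 nS at reference
scale; excitatory weights divided by five in the passive variant to match
firing rates). For every isolated somatic spike (none in the preceding
150 ms) the window is re-simulated from a 10 ms-cadence full-state
checkpoint with (i) synapses that fired more than once duplicated into
single-spike dummy copies so each activation gets its own gradient, and
(ii) the fast axo-somatic Na+/K+ conductances zeroed to block the
terminal action potential, whose steep nonlinearity would otherwise
contaminate $\partial v_{soma}/\partial w$.

Gradients are binned at 1 ms x 1 mV over $\Delta t \in (0, 100]$ ms,
$v \in [-80, 0]$ mV, zero-padded at the $v = 0$, $v = -80$ and
$t = -1$ boundaries, and fitted by count-weighted least squares with a
degree-8 polynomial in both variables (degree 10, time-only, for the
point-neuron kernel), on coordinates rescaled to order one for
conditioning. Excitatory kernels are clamped at zero from below,
inhibitory from above, and evaluate to zero outside the valid domain.
Held-out accuracy is the squared correlation between recorded gradients
and kernel predictions on a 25% record-level split.

On the synthetic fixture trees used at desk scale, basal excitatory
kernels reach held-out $R^2 \approx 0.85$-0.95. Apical strata fit less
well there than on reconstructed morphologies because the fixture's
radius taper is two-valued (1.0 um trunks, 0.3 um tips), which makes
local input resistance — and hence a synapse's influence at matched
$(\Delta t, v)$ — strongly bimodal; real dendritic trees taper gradually.
This is a property of the fixture, not of the method, and the desk-scale
checks therefore assert kernel quality on basal strata.

## Input ensembles and tasks

Stimulus features are vectors of per-synapse rate functions. A feature
activates each synapse with probability $\lambda_{pop}/\lambda_{syn}$
(population average fixed at $\lambda_{pop} = 2.5$ Hz per synapse over
the 400 ms window); active synapses fire at time-averaged rate
$\lambda_{syn}$, either constant (rate code, $K = 0$) or as $K$ Gaussian
bumps centered uniformly in the window, each carrying
$\lambda_{syn} T / K$ expected spikes with width scaled accordingly
(base 2.5 ms per expected spike). Bumps centered near the window edges
lose the analytically computable fraction of their mass to truncation
(4% of total spikes for 20 ms bumps in a 400 ms window); the sampler is
deliberately literal about the rate definition, and conservation checks
account for the analytic edge loss rather than renormalizing the bumps.
Realizations are non-homogeneous Poisson by thinning against a
per-synapse envelope (maximum of the bump sum on a fine grid). Random
streams are keyed by feature identity, so presenting two features
together realizes exactly the union of their separate presentations —
which makes linearity checks and subthreshold summation analyses exact
rather than statistical.

The feature-binding task presents pairs (X_i, Y_j); the neuron must
spike on preferred pairs and stay silent otherwise. The 2 x 2 task uses
the diagonal (XOR-like) labels, larger tasks random labels. A useful
planning fact: a threshold unit can satisfy three of the four 2 x 2
constraints by responding to a single preferred pair, so `P_test` = 0.75
is the linear ceiling; exceeding it is the signature of a nonlinear
solution, and the point-neuron variant is expected to sit at or below
that ceiling.

## The learning rule

On presentation of a pattern the supervisor maintains a running average
error $\bar E_p$ (last 10 training outcomes minus the label; histories
start all-incorrect so early updates carry full magnitude). Preferred
patterns receive a somatic teaching current $\beta |\bar E_p|$ — strong
enough to convert near-threshold peaks into spikes, never sufficient to
fire the cell alone. Training simulations stop at the first somatic
spike; at that moment every synapse active in the preceding 100 ms is
updated by

$$\Delta w_i = -\alpha\,\bar E_p \sum_k K_i(\Delta t_{ik},
v^{dend}_i),$$

then clipped to $[0, 0.01\,\mu S]$. The learning rate starts at
$2\times10^{-6}/\lambda_{syn}\ \mu S$ and decays with epoch as
$\alpha_0/(1 + x/1125)$; the printed form of that schedule could also be
read as $1/(1+1125x)$, which would extinguish learning within one epoch
of a 1000-epoch run, so the epoch-scaled reading is the default and both
are selectable. Training runs for up to 1000 epochs (desk presets fewer)
or until ten consecutive error-free epochs. Testing presents each
pattern 20 times, full duration, teaching and plasticity off, and
reports $P_{test} = 1 - \bar E$.

In the online variant the supervisor provides only the label: a leaky
spike-count rate $r$ ($\tau_r = 1$ s) is thresholded against 5 Hz on
preferred and 0.1 Hz on nonpreferred patterns to drive a leaky error
$E_p$ ($\tau_E = 0.5$ s), which replaces $\bar E_p$ in both the teaching
current and the weight update; plasticity engages halfway through each
(1-4 s, periodically extended) presentation. The implementation
integrates the supervisor exactly between spikes and refreshes the
teaching current every 5 ms chunk, which is much faster than $\tau_E$.

## Desk-scale study conditions

The full protocol (reconstructed morphology, 1000 synapses, 5000
campaign runs of 10 s, 1000 training epochs) runs for CPU-days. The
package's desk scale keeps every mechanism and all defaults, shrinking
only sizes, and all desk choices are fixed here once:

* geometry: `synthetic_tree(6, 3, 1)` (~235 compartments, 27 branches)
  for learning experiments; `synthetic_tree(8, 4, 2)` for integration
  protocols that need deep branch structure; small 3-2 trees for solver
  and oracle tests;
* synapse population: 200 excitatory + 50 inhibitory; initial weights
  and the learning rate scaled by 1000/N_syn (the same scaling the
  published N_syn sweeps apply to initial weights); the rate-code task
  itself keeps its full-scale parameters (sparseness 1/16, 40 Hz active
  synapses);
* teaching gain calibrated to the fixture morphology: $\beta$ set to
  produce ~10 mV of somatic depolarization at full error
  ($\beta = 10/R_{in}$ nA), satisfying both stated properties of the
  teaching current on a tree whose input resistance differs from the
  reconstructed cell's;
* campaigns of 14 x 2 s; 150 training epochs (learning curves plateau
  well before this at desk size; continuing to 1000 epochs was checked
  once and does not move the plateau).

An honest caveat about what desk scale shows. Across desk
configurations (235-430 compartments, 250-500 synapses, 150-1000
epochs) all three variants — active, passive, and point — converge to
the linearly attainable three-of-four solution of the 2 x 2 task
(`P_test` ~ 0.70, against the 0.75 linear ceiling). Voltage diagnostics
show the trained active model does recruit NMDA plateaus selectively
for one preferred pair, but at this scale the second diagonal never
differentiates from the cross pairs: the co-activation statistics of a
~25-branch fixture with ~13 active synapses per feature do not provide
enough clustered raw material for the spatial strategy to beat the
linear solution, and the point neuron — which finds the linear solution
very reliably — is not outperformed. The acceptance suite states the
ordinal expectation (dendritic variants above the point neuron) as the
faithful desk-scale rendition of the full protocol and reports its
failure rather than weakening it; the mechanism-level signature that
drives the full-scale result (supralinear active / sublinear passive /
linear point integration of clustered input) is reproduced robustly and
asserted separately.

What the synthetic fixture does not emulate: reconstruction noise
(pinched sections are exercised through dedicated repair tests instead),
gradual dendritic taper (see the kernel note above), realistic basal
versus apical asymmetry in branch counts and path lengths, and the sheer
electrotonic extent of a real layer 2/3 cell. Passing desk-scale tests
therefore demonstrates that the machinery is correct and the mechanisms
engage — not that the printed full-scale numbers are reproduced; the
full protocol can be run by passing a reconstructed SWC morphology
through the same functions.

## Degenerate inputs and tie-breaks

Zero-length branches are structure errors at discretization. Synapse
placement is area-proportional; point mode bypasses the dendritic
requirement. A campaign that yields no isolated spikes raises a
diagnostic error pointing at the weight scale. Constant profiles make
Pearson correlations undefined and are reported as `NA` rather than
zero. Window replays require the spike to be at least one window from
the run start; earlier spikes are skipped. Polynomial fits error on
rank-deficient designs with the occupied-bin count, and `NA`
coefficients from collinear columns are zeroed. The local-voltage
regression reports its design condition number and proceeds with the
least-squares pseudoinverse when covariates are collinear.

## Known limitations

The kernel approximation degrades when fast dendritic spikes carry the
nonlinearity (the extended Na+/K+/HCN variant): spike-triggered averages
over $(\Delta t, v)$ cannot capture events much faster than the voltage
binning, which is why the direct-gradient training path exists. The
online implementation refreshes the teaching current on a 5 ms grid
rather than continuously. Short-term synaptic dynamics and correlated
(non-Poisson) input statistics are out of scope, as are spine
compartments beyond the optional x2 capacitance/leak scaling.
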