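#' Biophysical parameter set
#'
#' Collects all membrane, channel, and synapse parameters of the model in one
#' object. Defaults are the standard layer 2/3 pyramidal-cell values used
#' throughout: passive membrane `c_m` = 1 uF/cm^2, `r_m` = 1e4 Ohm cm^2
#' (tau_m = 10 ms), `r_a` = 150 Ohm cm, `e_l` = -75 mV; axo-somatic spiking
#' conductances g_Na = 80, g_K = 40, g_Km = 3 mS/cm^2 with adaptation
#' time constant tau_Km = 200 ms; AMPA/NMDA/GABA double-exponential kinetics
#' with NMDA/AMPA ratio gamma = 2 and the NMDA magnesium-block sigmoid
#' sigma(v) = 1/(1 + C exp(-rho v)), C = 1/3.75, rho = 0.062.
#'
#' Modes: `"active"` (NMDA voltage dependence on), `"passive"` (sigma == 1),
#' `"point"` (biophysics of the active model; synapses are relocated to the
#' soma by [place_synapses()]), `"extended"` (low-density dendritic Na+/K+
#' plus somato-dendritic HCN channels).
#'
#' @param mode One of `"active"`, `"passive"`, `"point"`, `"extended"`.
#' @param spine_scaling Double membrane capacitance and leak conductance in
#'   dendrites to emulate spine membrane area.
#' @param ... Named overrides of any default listed above (see
#'   [biophysics_defaults()]).
#' @return An object of class `biophysics_spec` (a named list).
#' @export
biophysics_spec <- function(mode = c("active", "passive", "point", "extended"),
                            spine_scaling = FALSE, ...) {
  mode <- match.arg(mode)
  sp <- biophysics_defaults()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(sp))
  if (length(unknown)) stop("unknown biophysics parameters: ",
                            paste(unknown, collapse = ", "))
  sp[names(dots)] <- dots
  dens <- unlist(sp[c("g_na", "g_k", "g_km", "g_na_dend", "g_k_dend",
                      "g_km_dend", "g_ih")])
  if (any(dens < 0)) stop("conductance densities must be >= 0")
  sp$mode <- mode
  sp$spine_scaling <- isTRUE(spine_scaling)
  class(sp) <- "biophysics_spec"
  sp
}

#' @rdname biophysics_spec
#' @export
biophysics_defaults <- function() {
  list(
    c_m = 1, r_m = 1e4, r_a = 150, e_l = -75,
    g_na = 80, g_k = 40, g_km = 3, tau_km = 200,
    e_na = 50, e_k = -80,
    g_na_dend = 2, g_k_dend = 1, g_km_dend = 0.15,
    g_ih = 0.1, e_hcn = -45,
    v_t = -56.2,
    tau_ar = 0.1, tau_ad = 2, tau_nr = 2, tau_nd = 75,
    tau_gr = 1, tau_gd = 5,
    gamma = 2, e_e = 0, e_i = -75,
    nmda_c = 1 / 3.75, nmda_rho = 0.062
  )
}

#' @export
print.biophysics_spec <- function(x, ...) {
  cat("<biophysics_spec> mode =", x$mode,
      if (x$spine_scaling) "(spine scaling)" else "", "\n")
  invisible(x)
}

# Internal: flatten geometry + spec into the solver's arrays.
# Per-compartment effective capacitance handles spine scaling; all
# conductance densities are pre-divided by c_m so rates are in 1/ms.
build_model <- function(geom, spec, block_soma_spikes = FALSE) {
  cp <- geom$compartments
  n <- nrow(cp)
  cm <- rep(spec$c_m, n)
  dend <- cp$branch > 0L
  g_l <- rep(1e3 / spec$r_m, n)   # mS/cm^2
  if (spec$spine_scaling) {
    cm[dend] <- cm[dend] * 2
    g_l[dend] <- g_l[dend] * 2
  }
  gna <- gk <- gkm <- gih <- numeric(n)
  soma <- geom$soma_index
  gna[soma] <- spec$g_na
  gk[soma] <- spec$g_k
  gkm[soma] <- spec$g_km
  if (spec$mode == "extended") {
    gna[dend] <- spec$g_na_dend
    gk[dend] <- spec$g_k_dend
    gkm[dend] <- spec$g_km_dend
    gih[] <- spec$g_ih
  }
  if (block_soma_spikes) {
    gna[soma] <- 0
    gk[soma] <- 0
  }
  # axial couplings per compartment (parent link), divided by cm_i
  parent <- cp$parent
  gup <- glo <- numeric(n)
  soma_lumped <- !isTRUE(geom$uniform_cable)
  half_res <- function(i) {
    ifelse(soma_lumped & cp$branch[i] == 0L, 0,
           spec$r_a * (cp$length[i] * 1e-4 / 2) / (pi * (cp$radius[i] * 1e-4)^2))
  }
  if (n > 1L) {
    for (i in 2:n) {
      j <- parent[i]
      g <- 1e6 / (half_res(i) + half_res(j))  # uS
      glo[i] <- 1e-3 * g / (cm[i] * cp$area[i])
      gup[i] <- 1e-3 * g / (cm[j] * cp$area[j])
    }
  }
  list(
    geom_list = list(n = n, parent = as.integer(parent - 1L),
                     gup = gup, glo = glo),
    spec_list = list(
      gna = gna / cm, gk = gk / cm, gkm = gkm / cm, gih = gih / cm,
      gl = g_l / cm,
      ena = spec$e_na, ek = spec$e_k, el = spec$e_l, ehcn = spec$e_hcn,
      ee = spec$e_e, ei = spec$e_i,
      vt = spec$v_t, taumax = spec$tau_km * 2 * sqrt(3.3),
      nmda_c = spec$nmda_c, nmda_rho = spec$nmda_rho,
      nmda_on = spec$mode != "passive",
      gamma = spec$gamma,
      tau_ar = spec$tau_ar, tau_ad = spec$tau_ad,
      tau_nr = spec$tau_nr, tau_nd = spec$tau_nd,
      tau_gr = spec$tau_gr, tau_gd = spec$tau_gd,
      inj_scale = 1e-3 / (cm[soma] * cp$area[soma])
    ),
    cm = cm
  )
}

#' Distribute synapses over a geometry
#'
#' Places `n_e` excitatory and `n_i` inhibitory synapses. In the default
#' `"dendritic"` mode compartments are drawn with probability proportional to
#' membrane area over basal + apical dendrites; `"point"` puts every synapse
#' at the soma; `"somatic_inhibition"` places inhibitory synapses at the soma
#' and excitatory synapses over the dendrites.
#'
#' @param geom A `dendrite_geometry`.
#' @param n_e,n_i Numbers of excitatory / inhibitory synapses.
#' @param mode Placement mode.
#' @param w_e,w_i Initial weights (uS).
#' @param seed RNG seed.
#' @return An object of class `synapse_layout`: data.frame with columns
#'   `synapse`, `type` ("E"/"I"), `comp`, `branch`, `domain`, `w`.
#' @export
place_synapses <- function(geom, n_e = 800, n_i = 200,
                           mode = c("dendritic", "point", "somatic_inhibition"),
                           w_e = 0.6e-3, w_i = 0.8e-3, seed = 1) {
  mode <- match.arg(mode)
  if (n_e < 0 || n_i < 0) stop("synapse counts must be >= 0")
  cp <- geom$compartments
  dend <- which(cp$domain %in% c("basal", "apical"))
  if (mode != "point" && length(dend) == 0L)
    stop("geometry has no dendritic compartments")
  rng <- local_rng(seed)
  draw_dend <- function(k) {
    dend[rng$sample(length(dend), k, replace = TRUE, prob = cp$area[dend])]
  }
  comp_e <- switch(mode,
    dendritic = draw_dend(n_e),
    somatic_inhibition = draw_dend(n_e),
    point = rep(geom$soma_index, n_e))
  comp_i <- switch(mode,
    dendritic = draw_dend(n_i),
    somatic_inhibition = rep(geom$soma_index, n_i),
    point = rep(geom$soma_index, n_i))
  comp <- c(comp_e, comp_i)
  layout <- data.frame(
    synapse = seq_len(n_e + n_i),
    type = rep(c("E", "I"), c(n_e, n_i)),
    comp = comp,
    branch = cp$branch[comp],
    domain = cp$domain[comp],
    w = rep(c(w_e, w_i), c(n_e, n_i))
  )
  class(layout) <- c("synapse_layout", "data.frame")
  layout
}

layout_arrays <- function(layout, geom, model) {
  cp <- geom$compartments
  list(comp0 = as.integer(layout$comp - 1L),
       is_e = as.integer(layout$type == "E"),
       w = layout$w,
       hscale = 1e-3 / (model$cm[layout$comp] * cp$area[layout$comp]))
}

trains_arrays <- function(trains, nsyn) {
  if (length(trains) != nsyn)
    stop("trains must have one element per synapse (", nsyn, ")")
  for (tt in trains) {
    if (length(tt) && (is.unsorted(tt) || any(tt < 0)))
      stop("spike trains must be sorted and non-negative")
  }
  list(times = as.numeric(unlist(trains, use.names = FALSE)),
       offsets = as.integer(c(0L, cumsum(vapply(trains, length, 1L)))))
}

#' Double-exponential synaptic activation
#'
#' Unit-peak activation of Eq.-style double-exponential kinetics: each
#' presynaptic spike at t0 contributes
#' `(exp(-(t-t0)/tau_d) - exp(-(t-t0)/tau_r)) / g_max`, with `g_max` chosen
#' so a single spike peaks at exactly 1. Spikes sum linearly.
#'
#' @param t Evaluation times (ms).
#' @param spikes Sorted presynaptic spike times (ms).
#' @param tau_r,tau_d Rise and decay time constants, `tau_d > tau_r > 0` (ms).
#' @return Activation values at `t` (unitless).
#' @export
syn_activation <- function(t, spikes, tau_r, tau_d) {
  if (tau_d <= tau_r || tau_r <= 0) stop("need tau_d > tau_r > 0")
  if (length(spikes) && is.unsorted(spikes)) stop("spikes must be sorted")
  tpk <- tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
  norm <- exp(-tpk / tau_d) - exp(-tpk / tau_r)
  vapply(t, function(ti) {
    past <- spikes[spikes <= ti]
    if (!length(past)) return(0)
    sum(exp(-(ti - past) / tau_d) - exp(-(ti - past) / tau_r)) / norm
  }, numeric(1))
}

#' NMDA magnesium-block sigmoid
#'
#' The local-voltage gate of the NMDA conductance,
#' `sigma(v) = 1 / (1 + C exp(-rho v))`. In the passive model variant the
#' gate is identically 1.
#'
#' @param v Voltage (mV).
#' @param mode Model variant; `"passive"` returns 1.
#' @param C,rho Sigmoid shape parameters.
#' @return Gate values in (0, 1\].
#' @export
nmda_gate <- function(v, mode = "active", C = 1 / 3.75, rho = 0.062) {
  if (identical(mode, "passive")) return(rep(1, length(v)))
  1 / (1 + C * exp(-rho * v))
}

#' Hodgkin-Huxley gating rates
#'
#' Voltage-dependent opening/closing rates for the channel gates: `m`, `h`
#' (fast transient Na+), `n` (delayed-rectifier K+), `p` (slow K+,
#' adaptation), `q` (HCN). Rates are in ms^-1.
#'
#' @param v Voltages (mV).
#' @param channel One of `"m"`, `"h"`, `"n"`, `"p"`, `"q"`.
#' @param spec A `biophysics_spec` supplying `v_t` and `tau_km`.
#' @return A data.frame with columns `alpha` and `beta` (ms^-1).
#' @export
gating_rates <- function(v, channel = c("m", "h", "n", "p", "q"),
                         spec = biophysics_spec()) {
  channel <- match.arg(channel)
  ch <- match(channel, c("m", "h", "n", "p", "q")) - 1L
  out <- cpp_gating_rates(as.numeric(v), ch, spec$v_t,
                          spec$tau_km * 2 * sqrt(3.3))
  data.frame(alpha = out[, 1], beta = out[, 2])
}

#' Simulate the compartmental model
#'
#' Integrates the coupled cable + Hodgkin-Huxley + synapse system with a
#' tree-sparse implicit Euler scheme (exact solve of the per-step linearized
#' system by ordered elimination, cost linear in compartment count; gating
#' advanced with voltage-stale rates). Somatic spikes are detected as upward
#' 0 mV crossings with linear interpolation, and reported spike times are
#' crossing minus 2 ms (the functional threshold-crossing time).
#'
#' @param geom A `dendrite_geometry`.
#' @param spec A `biophysics_spec`.
#' @param layout A `synapse_layout`.
#' @param trains List of sorted presynaptic spike-time vectors (ms), one per
#'   synapse.
#' @param horizon Simulation length (ms).
#' @param dt Time step (ms).
#' @param i_soma Somatic current injection (nA): scalar or one value per step.
#' @param record `"soma"` or `"all"` (all compartment voltages).
#' @param record_every_ms Recording cadence (ms; rounded to a step multiple).
#' @param early_stop Stop at the first somatic spike.
#' @param checkpoint_every Full-state checkpoint cadence (ms; 0 = none).
#' @param init_state Optional state vector from a previous run's checkpoint
#'   or `final_state` (resting initialization otherwise).
#' @param t0 Start time (ms) when resuming from a checkpoint.
#' @param block_soma_spikes Zero the fast axo-somatic Na+/K+ conductances.
#' @return An object of class `sim_trace`: list with `times`, `v_soma`,
#'   `spikes` (somatic spike times), `spike_vdend` (voltages in every
#'   compartment at each spike time), `final_state`, and optionally `v_all`,
#'   `checkpoints`/`checkpoint_times`.
#' @export
simulate_neuron <- function(geom, spec, layout, trains, horizon,
                            dt = 0.025, i_soma = 0, record = c("soma", "all"),
                            record_every_ms = dt, early_stop = FALSE,
                            checkpoint_every = 0, init_state = NULL, t0 = 0,
                            block_soma_spikes = FALSE) {
  record <- match.arg(record)
  if (horizon <= 0) stop("horizon must be positive")
  if (dt <= 0) stop("dt must be positive")
  model <- build_model(geom, spec, block_soma_spikes = block_soma_spikes)
  la <- layout_arrays(layout, geom, model)
  tr <- trains_arrays(trains, nrow(layout))
  nsteps <- round(horizon / dt)
  if (length(i_soma) > 1 && length(i_soma) != nsteps)
    stop("i_soma must be scalar or one value per step (", nsteps, ")")
  out <- cpp_simulate(model$geom_list, model$spec_list, la, tr,
                      horizon, dt, as.numeric(i_soma),
                      max(1L, as.integer(round(record_every_ms / dt))),
                      record == "all", early_stop, checkpoint_every,
                      init_state, t0, integer(0), numeric(0))
  out$dt <- dt
  class(out) <- "sim_trace"
  out
}

#' @export
print.sim_trace <- function(x, ...) {
  cat("<sim_trace> t = [", min(x$times), ",", max(x$times), "] ms, ",
      length(x$spikes), " somatic spike(s)\n", sep = "")
  invisible(x)
}

#' Somatic and dendritic input resistance
#'
#' Steady-state voltage response of the passive linear system to a unit
#' current injection in each compartment (MOhm): solves
#' `(diag(g_L) - G) dv = e_i` per compartment from the same discretized
#' operator the simulator uses.
#'
#' @param geom A `dendrite_geometry`.
#' @param spec A `biophysics_spec`.
#' @return Numeric vector of input resistances (MOhm), one per compartment.
#' @export
input_resistance <- function(geom, spec = biophysics_spec("passive")) {
  model <- build_model(geom, spec)
  n <- model$geom_list$n
  A <- matrix(0, n, n)
  parent <- model$geom_list$parent + 1L
  for (i in seq_len(n)[-1]) {
    j <- parent[i]
    A[i, j] <- A[i, j] - model$geom_list$glo[i]
    A[i, i] <- A[i, i] + model$geom_list$glo[i]
    A[j, i] <- A[j, i] - model$geom_list$gup[i]
    A[j, j] <- A[j, j] + model$geom_list$gup[i]
  }
  diag(A) <- diag(A) + model$spec_list$gl
  cp <- geom$compartments
  inj <- 1e-3 / (model$cm * cp$area)   # 1 nA -> mV/ms per compartment
  dv <- solve(A, diag(inj, n))
  diag(dv)
}
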