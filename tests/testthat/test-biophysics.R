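test_that("synaptic activation peaks at 1 at the double-exponential peak time", {
  expect_equal(syn_activation(5, numeric(0), 0.1, 2), 0)
  expect_equal(syn_activation(9.9, 10, 0.1, 2), 0)   # causality

  # closed-form peak time, unit peak
  cases <- list(c(0.1, 2), c(2, 75), c(1, 5))
  for (tau in cases) {
    tpk <- tau[1] * tau[2] / (tau[2] - tau[1]) * log(tau[2] / tau[1])
    expect_equal(syn_activation(10 + tpk, 10, tau[1], tau[2]), 1,
                 tolerance = 1e-12)
    # peak verified by numeric maximization
    tt <- seq(10, 10 + 10 * tau[2], by = 0.001)
    expect_equal(tt[which.max(syn_activation(tt, 10, tau[1], tau[2]))] - 10,
                 tpk, tolerance = 0.002)
  }
  # AMPA kinetics peak at ~0.315 ms
  tpk_a <- 0.1 * 2 / (2 - 0.1) * log(2 / 0.1)
  expect_equal(tpk_a, 0.3153, tolerance = 1e-3)
  expect_error(syn_activation(1, c(5, 3), 0.1, 2), "sorted")
})

test_that("NMDA gate is the stated sigmoid, passive variant is 1", {
  expect_equal(nmda_gate(c(-80, 0, 40), mode = "passive"), rep(1, 3))
  expect_equal(nmda_gate(0), 1 / (1 + 1 / 3.75), tolerance = 1e-12)
  v <- seq(-100, 60, by = 1)
  s <- nmda_gate(v)
  expect_true(all(diff(s) > 0))
  expect_lt(s[1], 0.05)
  expect_gt(s[length(s)], 0.95)
})

test_that("gating rates are finite, nonnegative, and give first-order kinetics", {
  v <- seq(-100, 60, by = 0.5)
  for (ch in c("m", "h", "n", "p", "q")) {
    r <- gating_rates(v, ch)
    expect_true(all(is.finite(r$alpha)), info = ch)
    expect_true(all(is.finite(r$beta)), info = ch)
    expect_true(all(r$alpha >= 0), info = ch)
    expect_true(all(r$beta >= 0), info = ch)
  }
  # relaxation of m from 0 at clamped v follows the closed-form exponential
  vc <- -40
  r <- gating_rates(vc, "m")
  tau <- 1 / (r$alpha + r$beta)
  xinf <- r$alpha / (r$alpha + r$beta)
  dt <- 0.001
  x <- 0
  for (k in seq_len(round(2 * tau / dt))) {
    rr <- gating_rates(vc, "m")
    x <- (x + dt * rr$alpha) / (1 + dt * (rr$alpha + rr$beta))
  }
  expect_equal(x, xinf * (1 - exp(-2)), tolerance = 0.01)
  # slow-K time constant peaks at tau_km
  vv <- seq(-80, 20, by = 0.1)
  rp <- gating_rates(vv, "p")
  expect_equal(max(1 / (rp$alpha + rp$beta)), 200, tolerance = 1)
})

test_that("isopotential passive compartment matches the RC closed form", {
  soma <- soma_geometry()
  sp <- passive_spec()
  lay <- simple_layout(1L, w = 0)
  run <- simulate_neuron(soma, sp, lay, list(numeric(0)), horizon = 60,
                         i_soma = 0.05)
  rin <- input_resistance(soma, sp)
  expect_equal(rin, 1e4 / (4 * pi * (10e-4)^2) * 1e-6, tolerance = 1e-6)
  vth <- -75 + 0.05 * rin * (1 - exp(-run$times / 10))
  expect_lt(max(abs(run$v_soma - vth)) / (0.05 * rin), 0.005)
})

test_that("implicit Euler is first order (Richardson ratio ~ 2)", {
  soma <- soma_geometry()
  sp <- biophysics_spec("active")
  lay <- simple_layout(1L, w = 0)
  sol <- function(dt) {
    run <- simulate_neuron(soma, sp, lay, list(numeric(0)), horizon = 40,
                           dt = dt, i_soma = 0.025, record_every_ms = 1)
    run$v_soma
  }
  v1 <- sol(0.02); v2 <- sol(0.01); v3 <- sol(0.005)
  num <- sqrt(mean((v1 - v2)^2))
  den <- sqrt(mean((v2 - v3)^2))
  expect_equal(num / den, 2, tolerance = 0.2)
})

test_that("resting state is stable and zero input leaves the neuron silent", {
  g <- small_tree()
  spec <- biophysics_spec("active")
  lay <- place_synapses(g, 10, 5, seed = 1)
  run <- simulate_neuron(g, spec, lay, rep(list(numeric(0)), 15),
                         horizon = 400)
  expect_equal(length(run$spikes), 0)
  # settles to a fixed point within ~2 mV of E_L; drift stops
  expect_lt(max(abs(run$v_soma + 75)), 2)
  tail_v <- run$v_soma[run$times > 300]
  expect_lt(max(tail_v) - min(tail_v), 1e-3)
})

test_that("simulation is bit-deterministic and E current vanishes at E_E", {
  g <- small_tree()
  spec <- biophysics_spec("active")
  lay <- place_synapses(g, 10, 5, seed = 2)
  trains <- fixed_trains(15, seed = 4)
  r1 <- simulate_neuron(g, spec, lay, trains, horizon = 200)
  r2 <- simulate_neuron(g, spec, lay, trains, horizon = 200)
  expect_identical(r1$v_soma, r2$v_soma)
  expect_identical(r1$spikes, r2$spikes)
  # driving force: at v = E_E an excitatory synapse passes no current
  expect_equal(nmda_gate(0) * 1 * (0 - 0), 0)
})

test_that("passive response is linear in weight in the small-weight limit", {
  g <- small_tree()
  sp <- biophysics_spec("passive")
  comp <- which(g$compartments$domain == "basal")[5]
  peak <- function(w) {
    lay <- simple_layout(comp, w = w, geom = g)
    base <- simulate_neuron(g, sp, simple_layout(comp, w = 0, geom = g),
                            list(150), horizon = 300,
                            block_soma_spikes = TRUE)
    run <- simulate_neuron(g, sp, lay, list(150), horizon = 300,
                           block_soma_spikes = TRUE)
    max(run$v_soma - base$v_soma)
  }
  w <- 0.1e-3
  expect_equal(peak(w) / (10 * peak(w / 10)), 1, tolerance = 0.02)
})

test_that("f-I curve is approximately linear above rheobase with adaptation", {
  # the full cell: axo-somatic spike generator with the dendritic load
  g <- small_tree()
  spec <- biophysics_spec("active")
  lay <- simple_layout(1L, w = 0)
  rates <- c()
  currents <- seq(0.6, 1.2, by = 0.2)
  for (i in currents) {
    run <- simulate_neuron(g, spec, lay, list(numeric(0)), horizon = 1000,
                           i_soma = i)
    sp <- run$spikes[run$spikes > 200]   # post-transient steady rate
    rates <- c(rates, length(sp) / 0.8)
    if (i == max(currents)) {
      isis <- diff(run$spikes)
      expect_gt(mean(utils::tail(isis, 3)),
                mean(utils::head(isis, 2)))   # spike-rate adaptation
    }
  }
  expect_true(all(diff(rates) > 0))
  fit <- stats::lm(rates ~ currents)
  expect_gt(summary(fit)$r.squared, 0.95)
})

test_that("extended model shows an HCN sag of roughly 1-2 mV", {
  g <- small_tree()
  spec <- biophysics_spec("extended")
  lay <- simple_layout(1L, w = 0)
  run <- simulate_neuron(g, spec, lay, list(numeric(0)), horizon = 1200,
                         i_soma = c(rep(0, 8000), rep(-0.1, 40000)),
                         record_every_ms = 1)
  seg <- run$v_soma[run$times > 200]
  # sag: hyperpolarization peaks early, then HCN pulls back toward rest
  sag_amp <- seg[length(seg)] - min(seg[seq_len(150)])
  expect_gt(sag_amp, 0.5)
  expect_lt(sag_amp, 4)
})

test_that("synapse placement modes and area-proportional sampling law hold", {
  g <- small_tree()
  lp <- place_synapses(g, 20, 10, mode = "point", seed = 1)
  expect_true(all(lp$comp == 1))
  ls <- place_synapses(g, 20, 10, mode = "somatic_inhibition", seed = 1)
  expect_true(all(ls$comp[ls$type == "I"] == 1))
  expect_true(all(ls$comp[ls$type == "E"] != 1))
  l1 <- place_synapses(g, 50, 10, seed = 9)
  l2 <- place_synapses(g, 50, 10, seed = 9)
  expect_identical(l1$comp, l2$comp)
  expect_error(place_synapses(g, -1, 0), "counts")

  # chi-square against the membrane-area law over 10^4 draws
  big <- place_synapses(g, 10000, 0, seed = 5)
  cp <- g$compartments
  dend <- which(cp$domain %in% c("basal", "apical"))
  obs <- tabulate(match(big$comp, dend), nbins = length(dend))
  p <- cp$area[dend] / sum(cp$area[dend])
  keep <- p * 10000 >= 5
  chi <- sum((obs[keep] - 10000 * p[keep])^2 / (10000 * p[keep]))
  expect_gt(stats::pchisq(chi, sum(keep) - 1, lower.tail = FALSE), 0.01)
})

test_that("clustered input integrates supralinearly (active), sublinearly (passive), linearly (point)", {
  g <- memo("fig1_tree", synthetic_tree(8, 4, 2, seed = 1))
  res <- cabletron:::preset_fig1(
    experiment_preset("fig1_summation", seed = 1), g,
    counts = c(1, 4, 8, 16))
  expect_gt(max(res$active$ratio), 1.05)    # crosses above linear
  expect_lt(min(res$passive$ratio), 0.7)    # sublinear
  expect_true(all(abs(res$point$ratio - 1) < 0.1))
})
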