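#' Simulate with synaptic weight sensitivities
#'
#' Integrates the variational (forward-sensitivity) system alongside the
#' model: for each tracked synapse j, the matrix of partial derivatives
#' `dv_i/dw_j` (mV/uS) over all compartments i. The sensitivity update is
#' the exact derivative of the discrete implicit-Euler forward map — the
#' direct synaptic-drive term, the Jacobian diagonal including the NMDA
#' sigmoid derivative, the gating coupling terms with the voltage
#' derivatives of the rate functions, and the axial coupling — solved per
#' step with the same tree factorization as the forward voltage system.
#'
#' @inheritParams simulate_neuron
#' @param active_set Indices of synapses to track (1-based).
#' @param sample_times Times (ms) at which `dv_soma/dw` is sampled.
#' @return A `sim_trace` with additional elements `sens_vsoma` (matrix
#'   `length(sample_times)` x `length(active_set)` of somatic sensitivities,
#'   mV/uS) and `sens_dv_final` (matrix synapse x compartment at the final
#'   time).
#' @export
simulate_with_sensitivities <- function(geom, spec, layout, trains, horizon,
                                        active_set, sample_times = horizon,
                                        dt = 0.025, i_soma = 0,
                                        record = c("soma", "all"),
                                        record_every_ms = dt,
                                        early_stop = FALSE,
                                        checkpoint_every = 0,
                                        init_state = NULL, t0 = 0,
                                        block_soma_spikes = FALSE) {
  record <- match.arg(record)
  if (length(active_set) == 0L) stop("active_set must be nonempty")
  model <- build_model(geom, spec, block_soma_spikes = block_soma_spikes)
  la <- layout_arrays(layout, geom, model)
  tr <- trains_arrays(trains, nrow(layout))
  out <- cpp_simulate(model$geom_list, model$spec_list, la, tr,
                      horizon, dt, as.numeric(i_soma),
                      max(1L, as.integer(round(record_every_ms / dt))),
                      record == "all", early_stop, checkpoint_every,
                      init_state, t0, as.integer(active_set - 1L),
                      as.numeric(sample_times))
  out$dt <- dt
  out$active_set <- active_set
  out$sample_times <- sample_times
  class(out) <- "sim_trace"
  out
}

#' Per-event voltage gradients in a pre-spike window
#'
#' Re-simulates the 150 ms window preceding an isolated somatic spike from a
#' stored full-state checkpoint, with the variational system tracking one
#' dummy copy per synaptic activation in the window (synapses activated more
#' than once are duplicated into single-spike copies, so each event gets its
#' own gradient while the input to the neuron is functionally identical).
#' The fast axo-somatic Na+/K+ conductances are set to zero in the replay to
#' block the terminal action potential, whose steep nonlinearity would
#' otherwise contaminate the gradient. Each record carries the event's
#' synapse, time before the spike, the local dendritic voltage at the spike
#' time, and `g = dv_soma/dw` evaluated at the spike time.
#'
#' @param run A `sim_trace` produced with `checkpoint_every > 0`.
#' @param spike_time A somatic spike time from `run$spikes` with no other
#'   spike in the preceding `window` ms.
#' @param geom,spec,layout,trains As passed to the original simulation.
#' @param window Window length before the spike (ms).
#' @param max_dt Events more than `max_dt` ms before the spike are excluded
#'   from the returned record.
#' @param dt Solver step (ms).
#' @return A data.frame of class `window_gradient` with columns `synapse`,
#'   `comp`, `domain`, `type`, `w`, `dt` (ms before the spike), `v_dend`
#'   (mV), `g` (mV/uS). Zero rows when no synapse was active in the window.
#' @export
spike_window_gradient <- function(run, spike_time, geom, spec, layout, trains,
                                  window = 150, max_dt = 150, dt = 0.025) {
  if (is.null(run$checkpoints)) stop("run was simulated without checkpoints")
  others <- setdiff(run$spikes, spike_time)
  if (any(others > spike_time - window & others < spike_time))
    stop("window contains an earlier somatic spike; excluded by protocol")
  ts <- spike_time - window
  if (ts < min(run$checkpoint_times)) stop("window precedes first checkpoint")
  ci <- max(which(run$checkpoint_times <= ts))
  t_start <- run$checkpoint_times[ci]
  state <- as.numeric(run$checkpoints[ci, ])

  # events inside (ts, spike_time]: one dummy tracked synapse per event
  ev_syn <- integer(0); ev_t <- numeric(0)
  for (j in seq_along(trains)) {
    tj <- trains[[j]]
    sel <- tj > ts & tj <= spike_time
    if (any(sel)) {
      ev_syn <- c(ev_syn, rep(j, sum(sel)))
      ev_t <- c(ev_t, tj[sel])
    }
  }
  if (length(ev_syn) == 0L) {
    out <- data.frame(synapse = integer(0), comp = integer(0),
                      domain = character(0), type = character(0),
                      w = numeric(0), dt = numeric(0), v_dend = numeric(0),
                      g = numeric(0))
    class(out) <- c("window_gradient", "data.frame")
    return(out)
  }
  nsyn <- nrow(layout)
  ndum <- length(ev_syn)
  aug_layout <- rbind(layout, layout[ev_syn, ])
  aug_layout$synapse <- seq_len(nsyn + ndum)
  class(aug_layout) <- c("synapse_layout", "data.frame")
  # originals keep their checkpoint kinetic state but lose in-window spikes;
  # dummies start at zero state with a single spike each
  aug_trains <- lapply(seq_len(nsyn), function(j) {
    tj <- trains[[j]]
    tj[!(tj > ts & tj <= spike_time)]
  })
  aug_trains <- c(aug_trains, as.list(ev_t))
  # expand synaptic state blocks: state layout is v/m/h/n/p/q then
  # xr1, xd1, xr2, xd2 each of length nsyn -> append zeros for the dummies
  n <- nrow(geom$compartments)
  head_len <- 6 * n
  blocks <- lapply(0:3, function(b) {
    c(state[head_len + b * nsyn + seq_len(nsyn)], rep(0, ndum))
  })
  aug_state <- c(state[seq_len(head_len)], unlist(blocks))

  res <- simulate_with_sensitivities(
    geom, spec, layout = aug_layout, trains = aug_trains,
    horizon = spike_time - t_start, active_set = nsyn + seq_len(ndum),
    sample_times = spike_time, dt = dt, init_state = aug_state, t0 = t_start,
    block_soma_spikes = TRUE, record_every_ms = spike_time - t_start)

  v_end <- res$final_state[seq_len(n)]
  delta <- spike_time - ev_t
  out <- data.frame(
    synapse = ev_syn,
    comp = layout$comp[ev_syn],
    domain = layout$domain[ev_syn],
    type = layout$type[ev_syn],
    w = layout$w[ev_syn],
    dt = delta,
    v_dend = v_end[layout$comp[ev_syn]],
    g = as.numeric(res$sens_vsoma[1, ])
  )
  out <- out[out$dt > 0 & out$dt <= max_dt, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("window_gradient", "data.frame")
  out
}
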