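#' Signed and running classification errors
#'
#' `signed_error` is `z - z*`: 0 on correct trials, -1 on missed preferred
#' patterns, +1 on false alarms. `running_error` is the mean of the last
#' `n_avg` recorded outputs minus the label, in `[-1, 1]`.
#'
#' @param z Binary output (1 = at least one somatic spike).
#' @param z_star Binary label (1 = preferred pattern).
#' @param history Vector of recent binary outputs (most recent last).
#' @param n_avg Number of presentations averaged.
#' @return `signed_error`: -1, 0 or +1. `running_error`: value in `[-1, 1]`.
#' @export
signed_error <- function(z, z_star) {
  stopifnot(z %in% c(0, 1), z_star %in% c(0, 1))
  z - z_star
}

#' @rdname signed_error
#' @export
running_error <- function(history, z_star, n_avg = 10) {
  if (length(history) == 0) stop("empty output history")
  h <- utils::tail(history, n_avg)
  mean(h) - z_star
}

#' Supervisory teaching current
#'
#' Depolarizing somatic current injected during training on preferred
#' patterns, `I = beta * |E_p|` (nA): strongest after consistent errors,
#' zero once the pattern is classified reliably. Nonpreferred patterns
#' receive no teaching current.
#'
#' @param e_bar Running average error for the pattern.
#' @param is_plus Whether the pattern is preferred.
#' @param beta Teaching gain (nA).
#' @return Current (nA).
#' @export
teaching_current <- function(e_bar, is_plus, beta = 0.1) {
  if (!is_plus) return(0)
  beta * abs(e_bar)
}

#' Training configuration
#'
#' @param lambda_syn Active-synapse rate of the task (Hz); sets the initial
#'   learning rate `alpha0 = 2e-6 / lambda_syn` (uS).
#' @param alpha0 Initial learning rate (uS); overrides the default scaling.
#' @param lr_decay `"epoch"`: `alpha0 / (1 + epoch/1125)`;
#'   `"literal"`: `alpha0 / (1 + 1125 * epoch)`.
#' @param beta Teaching gain (nA).
#' @param w_max Weight clip (uS).
#' @param epochs Maximum training epochs.
#' @param n_avg Supervisor history length (training).
#' @param stop_after Stop after this many consecutive error-free epochs.
#' @param window Pre-spike integration window of the rule (ms).
#' @param direct_gradient Use windowed variational gradients instead of
#'   plasticity kernels (the route used when kernels are unreliable, e.g.
#'   with dendritic Na+ spikes).
#' @param dt Solver step (ms).
#' @return A `train_config` list.
#' @export
train_config <- function(lambda_syn = 40, alpha0 = 2e-6 / lambda_syn,
                         lr_decay = c("epoch", "literal"), beta = 0.1,
                         w_max = 0.01, epochs = 1000, n_avg = 10,
                         stop_after = 10, window = 100,
                         direct_gradient = FALSE, dt = 0.025) {
  lr_decay <- match.arg(lr_decay)
  if (alpha0 < 0) stop("alpha0 must be >= 0")
  if (w_max <= 0) stop("w_max must be > 0")
  structure(list(alpha0 = alpha0, lr_decay = lr_decay, beta = beta,
                 w_max = w_max, epochs = epochs, n_avg = n_avg,
                 stop_after = stop_after, window = window,
                 direct_gradient = direct_gradient, dt = dt),
            class = "train_config")
}

learning_rate <- function(cfg, epoch) {
  if (cfg$lr_decay == "epoch") cfg$alpha0 / (1 + epoch / 1125)
  else cfg$alpha0 / (1 + 1125 * epoch)
}

#' Kernel-based weight update at a somatic spike
#'
#' Implements `dw_i = -alpha * E_p * sum_k K_i(dt_ik, v_dend_i)`: every
#' synapse active in the pre-spike window is updated in proportion to its
#' kernel-estimated influence on the somatic voltage, with the sign and
#' magnitude set by the running error. Updates are clamped to
#' `[0, w_max]` after application.
#'
#' @param layout A `synapse_layout`.
#' @param events data.frame with `synapse`, `dt` (ms before spike), and
#'   `v_dend` (mV) — one row per presynaptic spike in the window — or, in
#'   direct-gradient mode, a `g` column of `dv_soma/dw` values.
#' @param kernels A `kernel_set` (ignored when `events$g` is present).
#' @param e_bar Running error for the pattern.
#' @param alpha Learning rate (uS).
#' @param w_max Weight clip (uS).
#' @return The layout with updated weights.
#' @export
weight_update <- function(layout, events, kernels, e_bar, alpha,
                          w_max = 0.01) {
  if (nrow(events) == 0 || e_bar == 0 || alpha == 0) return(layout)
  if (!is.null(events$g)) {
    contrib <- events$g
  } else {
    contrib <- numeric(nrow(events))
    dom <- layout$domain[events$synapse]
    ty <- layout$type[events$synapse]
    for (key in unique(paste(dom, ty))) {
      sel <- paste(dom, ty) == key
      parts <- strsplit(key, " ")[[1]]
      k <- kernel_for(kernels, parts[1], parts[2])
      contrib[sel] <- evaluate_kernel(k, events$dt[sel], events$v_dend[sel])
    }
  }
  dw <- vapply(split(-alpha * e_bar * contrib, events$synapse), sum,
               numeric(1))
  idx <- as.integer(names(dw))
  layout$w[idx] <- pmin(w_max, pmax(0, layout$w[idx] + dw))
  layout
}

# events in the pre-spike window for a detected somatic spike
collect_events <- function(trains, layout, t_spike, v_dend, window) {
  ev_syn <- integer(0); ev_dt <- numeric(0)
  for (j in seq_along(trains)) {
    tj <- trains[[j]]
    sel <- tj > t_spike - window & tj <= t_spike
    if (any(sel)) {
      ev_syn <- c(ev_syn, rep(j, sum(sel)))
      ev_dt <- c(ev_dt, t_spike - tj[sel])
    }
  }
  data.frame(synapse = ev_syn, dt = ev_dt,
             v_dend = v_dend[layout$comp[ev_syn]])
}

# enumerate task patterns: one row per (x, y) association
task_patterns <- function(task) {
  expand.grid(x = seq_len(length(task$features_x)),
              y = seq_len(length(task$features_y)))
}

present_pattern <- function(geom, spec, layout, task, ix, iy, seed,
                            i_teach = 0, early_stop = TRUE, dt = 0.025,
                            checkpoint_every = 0, background = TRUE,
                            block_soma_spikes = FALSE,
                            background_throughout = FALSE) {
  ens <- task$ensemble
  horizon <- ens$t_off
  bw <- if (background_throughout) c(0, horizon)
        else if (background) c(0, ens$t_on) else NULL
  trains <- realize_poisson(
    list(task$features_x[[ix]], task$features_y[[iy]]),
    list(task$syn_x, task$syn_y), n_syn = nrow(layout),
    horizon = horizon, seed = seed, background_window = bw)
  run <- simulate_neuron(geom, spec, layout, trains, horizon = horizon,
                         dt = dt, i_soma = i_teach, early_stop = early_stop,
                         checkpoint_every = checkpoint_every,
                         block_soma_spikes = block_soma_spikes)
  list(run = run, trains = trains)
}

#' Offline supervised training
#'
#' Greedy tempotron-style training: patterns are presented in random order
#' each epoch; on preferred patterns the supervisor injects the teaching
#' current `beta * |E_p|`; the simulation stops at the first somatic spike,
#' at which point every recently active synapse is updated through its
#' plasticity kernel (or windowed variational gradient) scaled by
#' `-alpha * E_p`. Supervisor histories start all-incorrect so early
#' updates carry full magnitude. Training halts at the epoch budget or
#' after `stop_after` consecutive error-free epochs.
#'
#' @param geom,spec,layout,task Model components.
#' @param kernels A `kernel_set` (may be `NULL` in direct-gradient mode).
#' @param cfg A `train_config`.
#' @param seed RNG seed (pattern order and Poisson realizations).
#' @param noise Optional `noise_spec` for label noise during training.
#' @return List with `layout` (trained weights), `error_curve` (per-epoch
#'   total error), `epochs_run`.
#' @export
train_offline <- function(geom, spec, layout, task, kernels,
                          cfg = train_config(), seed = 1, noise = NULL) {
  pats <- task_patterns(task)
  np <- nrow(pats)
  history <- lapply(seq_len(np), function(p) {
    zs <- task$labels[pats$x[p], pats$y[p]]
    rep(1 - zs, cfg$n_avg)   # all-incorrect start
  })
  err_curve <- numeric(0)
  rng <- local_rng(seed * 7 + 3)
  counter <- 0L
  clean <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    alpha <- learning_rate(cfg, epoch - 1)
    order_p <- rng$sample(np, np)
    for (p in order_p) {
      counter <- counter + 1L
      zs <- task$labels[pats$x[p], pats$y[p]]
      if (!is.null(noise) && noise$p_mislabel > 0) {
        zs <- apply_noise(zs, noise, seed = seed * 100003 + counter)
      }
      e_pre <- mean(history[[p]]) - zs
      i_teach <- teaching_current(e_pre, is_plus = zs == 1, beta = cfg$beta)
      pres <- present_pattern(geom, spec, layout, task, pats$x[p], pats$y[p],
                              seed = seed * 1000 + counter,
                              i_teach = i_teach, early_stop = TRUE,
                              dt = cfg$dt,
                              checkpoint_every = if (cfg$direct_gradient) 10 else 0)
      run <- pres$run
      z <- as.numeric(length(run$spikes) > 0)
      history[[p]] <- c(history[[p]][-1], z)
      e_bar <- mean(history[[p]]) - zs
      if (z == 1 && e_bar != 0 && alpha > 0) {
        tsp <- run$spikes[1]
        if (cfg$direct_gradient) {
          if (tsp - 150 >= 0 &&
              !any(run$spikes > tsp - 150 & run$spikes < tsp)) {
            wg <- spike_window_gradient(run, tsp, geom, spec, layout,
                                        pres$trains, dt = cfg$dt)
            ev <- wg[wg$dt <= cfg$window, c("synapse", "dt", "v_dend", "g")]
          } else ev <- data.frame(synapse = integer(0), dt = numeric(0),
                                  v_dend = numeric(0), g = numeric(0))
        } else {
          ev <- collect_events(pres$trains, layout, tsp,
                               run$spike_vdend[1, ], cfg$window)
        }
        layout <- weight_update(layout, ev, kernels, e_bar, alpha,
                                w_max = cfg$w_max)
      }
    }
    e_tot <- mean(vapply(seq_len(np), function(p) {
      abs(mean(history[[p]]) - task$labels[pats$x[p], pats$y[p]])
    }, numeric(1)))
    err_curve <- c(err_curve, e_tot)
    clean <- if (e_tot == 0) clean + 1L else 0L
    if (clean >= cfg$stop_after) break
  }
  list(layout = layout, error_curve = err_curve, epochs_run = length(err_curve))
}

#' Test a trained model
#'
#' Presents every pattern `n_reps` times with plasticity and teaching off,
#' full-duration simulation, and reports `P_test = 1 - mean_p |z_bar_p -
#' z*_p|`.
#'
#' @param geom,spec,layout,task Model components.
#' @param n_reps Presentations per pattern.
#' @param seed RNG seed.
#' @param noise Optional `noise_spec` applied at test (weight jitter, burst
#'   shifts).
#' @param dt Solver step (ms).
#' @return List with `p_test`, and `z_bar` (per-pattern response rates).
#' @export
evaluate_model <- function(geom, spec, layout, task, n_reps = 20, seed = 1,
                           noise = NULL, dt = 0.025) {
  pats <- task_patterns(task)
  np <- nrow(pats)
  zbar <- numeric(np)
  counter <- 0L
  for (p in seq_len(np)) {
    z <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      counter <- counter + 1L
      lay <- layout
      tk <- task
      if (!is.null(noise)) {
        if (noise$s_jitter > 0)
          lay <- apply_noise(lay, noise, seed = seed * 4099 + counter)
        if (noise$t_shift > 0)
          tk <- apply_noise(tk, noise, seed = seed * 8191 + counter)
      }
      pres <- present_pattern(geom, spec, lay, tk, pats$x[p], pats$y[p],
                              seed = seed * 2000 + counter, i_teach = 0,
                              early_stop = FALSE, dt = dt)
      z[r] <- as.numeric(length(pres$run$spikes) > 0)
    }
    zbar[p] <- mean(z)
  }
  labels <- task$labels[cbind(pats$x, pats$y)]
  list(p_test = 1 - mean(abs(zbar - labels)), z_bar = zbar, labels = labels)
}

#' Online supervisor dynamics
#'
#' One step of the online error system: `r` is an exponentially weighted
#' spike rate (`tau_r * dr/dt = spikes - r`, incremented by `1/tau_r` per
#' spike), and `E_p` integrates the thresholded rate against the label
#' (`tau_E * dE/dt = H[r - r_L(1-z*) - r_U z*] - z* - E_p`), converging to
#' 0 once the rate sits above `r_U` on preferred or below `r_L` on
#' nonpreferred patterns.
#'
#' @param state List with `r` (per-ms rate) and `e_p`; use
#'   [online_state()] to initialize.
#' @param spiked 1 if a somatic spike occurred in this step.
#' @param z_star Binary label.
#' @param dt Step (ms).
#' @return Updated state.
#' @export
online_step <- function(state, spiked, z_star, dt) {
  state$r <- state$r * exp(-dt / state$tau_r) + spiked / state$tau_r
  thr <- state$r_l * (1 - z_star) + state$r_u * z_star
  target <- as.numeric(state$r >= thr) - z_star
  state$e_p <- target + (state$e_p - target) * exp(-dt / state$tau_e)
  state
}

#' @rdname online_step
#' @param tau_r,tau_e Averaging time constants (ms).
#' @param r_l,r_u Lower/upper rate thresholds (Hz).
#' @export
online_state <- function(tau_r = 1000, tau_e = 500, r_l = 0.1, r_u = 5) {
  list(r = 0, e_p = 0, tau_r = tau_r, tau_e = tau_e,
       r_l = r_l / 1000, r_u = r_u / 1000)   # Hz -> per-ms units
}

#' Online supervised training
#'
#' Trains with feedback computed from the neuron's own spiking: each
#' pattern is presented for `t_train` ms (periodic extension of the 400 ms
#' stimulus; background active throughout); the rate/error system of
#' [online_step()] runs in parallel, the teaching current on preferred
#' patterns is `beta * |E_p|` (updated every `chunk` ms), and from
#' `t_train/2` onward every somatic spike triggers a kernel weight update
#' scaled by the instantaneous `E_p`.
#'
#' @param geom,spec,layout,task,kernels,cfg As in [train_offline()].
#' @param t_train Presentation duration (ms).
#' @param chunk Teaching-current refresh interval (ms).
#' @param epochs Training epochs.
#' @param seed RNG seed.
#' @return List with `layout` and `epochs_run`.
#' @export
train_online <- function(geom, spec, layout, task, kernels,
                         cfg = train_config(), t_train = 2000, chunk = 5,
                         epochs = 500, seed = 1) {
  pats <- task_patterns(task)
  np <- nrow(pats)
  ens <- task$ensemble
  rng <- local_rng(seed * 11 + 5)
  counter <- 0L
  for (epoch in seq_len(epochs)) {
    alpha <- learning_rate(cfg, epoch - 1)
    for (p in rng$sample(np, np)) {
      counter <- counter + 1L
      zs <- task$labels[pats$x[p], pats$y[p]]
      trains <- periodic_task_trains(task, pats$x[p], pats$y[p], t_train,
                                     seed = seed * 3000 + counter,
                                     n_syn = nrow(layout))
      st <- online_state()
      state_vec <- NULL
      t0 <- 0
      while (t0 < t_train) {
        i_teach <- if (zs == 1) cfg$beta * abs(st$e_p) else 0
        run <- simulate_neuron(geom, spec, layout, trains,
                               horizon = chunk, dt = cfg$dt,
                               i_soma = i_teach, init_state = state_vec,
                               t0 = t0)
        state_vec <- run$final_state
        # advance supervisor over the chunk, spikes at their detected times
        tt <- t0
        sp <- sort(run$spikes + 2)   # threshold-crossing times
        for (s in sp) {
          n_silent <- max(0, floor((s - tt) / cfg$dt))
          if (n_silent > 0) st <- online_step(st, 0, zs, n_silent * cfg$dt)
          st <- online_step(st, 1, zs, cfg$dt)
          tt <- tt + (n_silent + 1) * cfg$dt
        }
        if (t0 + chunk > tt) st <- online_step(st, 0, zs, t0 + chunk - tt)
        if (t0 >= t_train / 2 && length(run$spikes) && st$e_p != 0 &&
            alpha > 0) {
          for (si in seq_along(run$spikes)) {
            ev <- collect_events(trains, layout, run$spikes[si],
                                 run$spike_vdend[si, ], cfg$window)
            layout <- weight_update(layout, ev, kernels, st$e_p, alpha,
                                    w_max = cfg$w_max)
          }
        }
        t0 <- t0 + chunk
      }
    }
  }
  list(layout = layout, epochs_run = epochs)
}

# periodic extension of a 400 ms pattern over t_train, background throughout
periodic_task_trains <- function(task, ix, iy, t_train, seed, n_syn) {
  ens <- task$ensemble
  period <- ens$t_off
  n_rep <- ceiling(t_train / period)
  trains <- vector("list", n_syn)
  for (i in seq_len(n_syn)) trains[[i]] <- numeric(0)
  for (r in seq_len(n_rep)) {
    tr <- realize_poisson(
      list(task$features_x[[ix]], task$features_y[[iy]]),
      list(task$syn_x, task$syn_y), n_syn = n_syn, horizon = period,
      seed = seed * 53 + r, background_window = c(0, period))
    for (i in seq_len(n_syn)) {
      trains[[i]] <- c(trains[[i]], tr[[i]] + (r - 1) * period)
    }
  }
  lapply(trains, function(tt) tt[tt <= t_train])
}
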