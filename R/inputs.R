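#' Parameterized synaptic input ensemble
#'
#' Describes the family of stimulus patterns used for the feature-binding
#' tasks. A population of `n_syn` synapses receives stimulus input whose
#' time- and population-averaged rate is held at `lambda_pop` (Hz per
#' synapse): synapses are active with probability `lambda_pop / lambda_syn`
#' and, when active, fire at time-averaged rate `lambda_syn`. With `k = 0`
#' the active rate is constant (a rate code); with `k > 0` it is a sum of
#' `k` Gaussian bumps of elevated rate at uniform random times, each
#' carrying an expected `lambda_syn * T / k` spikes and width
#' `sigma0 * (lambda_syn * T / k)` (wider bumps for more spikes, keeping
#' instantaneous rates physiological). The expected total stimulus spike
#' count is `n_syn * lambda_pop * T` for every parameter choice.
#'
#' @param n_syn Total synapse count across both feature classes.
#' @param lambda_syn Time-averaged rate of active synapses (Hz).
#' @param k Number of precisely timed events per active synapse (0 = rate
#'   code).
#' @param lambda_pop Population-average stimulus rate per synapse (Hz).
#' @param lambda0 Background rate (Hz).
#' @param sigma0 Base bump width (ms) per expected spike.
#' @param t_on,t_off Stimulus window (ms); background precedes `t_on`.
#' @return An `input_ensemble_spec` list.
#' @export
input_ensemble_spec <- function(n_syn = 1000, lambda_syn = 40, k = 0,
                                lambda_pop = 2.5, lambda0 = 1.25,
                                sigma0 = 2.5, t_on = 100, t_off = 500) {
  if (lambda_syn < lambda_pop) stop("lambda_syn must be >= lambda_pop")
  structure(list(n_syn = n_syn, lambda_syn = lambda_syn, k = k,
                 lambda_pop = lambda_pop, lambda0 = lambda0, sigma0 = sigma0,
                 t_on = t_on, t_off = t_off, t_len = t_off - t_on),
            class = "input_ensemble_spec")
}

#' Preset input conditions
#'
#' `"rate"`: sparse rate code (active synapses at 40 Hz, sparseness 1/16).
#' `"optimal"`: one ~50 ms burst per active synapse with an expected eight
#' presynaptic spikes (lambda_syn = 20 Hz, k = 1, bump sd 20 ms).
#' `"temporal"`: dense temporal code, every synapse active with one narrow
#' bump carrying a single expected spike.
#'
#' @param name Preset name.
#' @param n_syn Total synapse count.
#' @return An `input_ensemble_spec`.
#' @export
input_preset <- function(name = c("rate", "optimal", "temporal"),
                         n_syn = 1000) {
  name <- match.arg(name)
  switch(name,
    rate = input_ensemble_spec(n_syn = n_syn, lambda_syn = 40, k = 0),
    optimal = input_ensemble_spec(n_syn = n_syn, lambda_syn = 20, k = 1),
    temporal = input_ensemble_spec(n_syn = n_syn, lambda_syn = 2.5, k = 1))
}

#' Generate one feature pattern
#'
#' Draws the per-synapse activation flags and (for `k > 0`) bump centers for
#' one stimulus feature over `n` synapses, per the ensemble parameterization.
#'
#' @param spec An `input_ensemble_spec`.
#' @param n Number of synapses in this feature's class population.
#' @param seed RNG seed.
#' @return A `feature_pattern`: list with `active` (logical), `lambda_bar`
#'   (Hz), `centers` (list of bump-center vectors, ms), `sigma` (ms), and
#'   the window parameters.
#' @export
make_feature <- function(spec, n = spec$n_syn, seed = 1) {
  rng <- local_rng(seed)
  active <- rng$runif(n) < spec$lambda_pop / spec$lambda_syn
  lambda_bar <- ifelse(active, spec$lambda_syn, 0)
  s_per_event <- spec$lambda_syn * spec$t_len / 1000 / max(1, spec$k)
  sigma <- spec$sigma0 * s_per_event
  centers <- vector("list", n)
  if (spec$k > 0) {
    for (i in which(active)) {
      centers[[i]] <- sort(rng$runif(spec$k, spec$t_on, spec$t_off))
    }
  }
  structure(list(active = active, lambda_bar = lambda_bar, centers = centers,
                 sigma = sigma, k = spec$k, t_on = spec$t_on,
                 t_off = spec$t_off, lambda0 = spec$lambda0,
                 id = seed %% 9973L),
            class = "feature_pattern")
}

#' Evaluate a feature's rate function
#'
#' Stimulus-dependent rate lambda_i(t) in Hz for each synapse of the
#' feature: constant `lambda_bar` for a rate code, or the scaled sum of
#' Gaussian bumps for `k > 0` (each bump is a unit-area Gaussian density in
#' ms, scaled by the expected per-event spike count).
#'
#' @param feature A `feature_pattern`.
#' @param t Times (ms).
#' @return Matrix `length(t)` x n of rates (Hz).
#' @export
feature_rate <- function(feature, t) {
  n <- length(feature$active)
  out <- matrix(0, length(t), n)
  inside <- t >= feature$t_on & t <= feature$t_off
  if (feature$k == 0) {
    for (i in which(feature$active)) out[inside, i] <- feature$lambda_bar[i]
    return(out)
  }
  for (i in which(feature$active)) {
    s_per_event <- feature$lambda_bar[i] * (feature$t_off - feature$t_on) /
      1000 / feature$k
    r <- numeric(length(t))
    for (ck in feature$centers[[i]]) {
      r <- r + s_per_event * stats::dnorm(t, ck, feature$sigma)
    }
    out[, i] <- 1000 * r * inside   # spikes/ms -> Hz, windowed
  }
  out
}

#' Realize Poisson spike trains by thinning
#'
#' Draws non-homogeneous Poisson spike trains against each synapse's rate
#' envelope by rejection (thinning): candidate spikes from a homogeneous
#' process at the envelope rate are accepted with probability
#' `lambda(t) / envelope`. Background activity at `lambda0` runs over
#' `background_window` (by default the pre-stimulus period).
#'
#' @param feature_list List of `feature_pattern`s presented together (their
#'   rates add; typically one X and one Y feature each covering its half of
#'   the synapses — use [pattern_rates()] to inspect the combined rate).
#' @param syn_index List of synapse-index vectors, one per feature, mapping
#'   feature-local synapses to layout synapses.
#' @param n_syn Total synapse count in the layout.
#' @param horizon Simulation horizon (ms).
#' @param seed RNG seed.
#' @param background_window `c(from, to)` ms over which background at
#'   `lambda0` is active; `NULL` for none.
#' @param lambda0 Background rate (Hz); taken from the first feature when
#'   `NULL`.
#' @return List of sorted spike-time vectors (ms), one per synapse.
#' @export
realize_poisson <- function(feature_list, syn_index, n_syn, horizon,
                            seed = 1, background_window = NULL,
                            lambda0 = NULL) {
  trains <- vector("list", n_syn)
  for (i in seq_len(n_syn)) trains[[i]] <- numeric(0)
  grid <- seq(0, horizon, by = 0.1)
  for (f in seq_along(feature_list)) {
    feat <- feature_list[[f]]
    # stream keyed by the feature's identity so that presenting features
    # together realizes exactly the union of their separate presentations
    fid <- if (is.null(feat$id)) f else feat$id
    rng <- local_rng((seed %% 99991L) * 1009L + fid)
    idx <- syn_index[[f]]
    for (loc in which(feat$active)) {
      gi <- idx[loc]
      if (feat$k == 0) {
        lam <- feat$lambda_bar[loc]
        dur <- (feat$t_off - feat$t_on) / 1000
        ns <- rng$rpois(1, lam * dur)
        if (ns > 0) {
          tt <- sort(rng$runif(ns, feat$t_on, feat$t_off))
          trains[[gi]] <- sort(c(trains[[gi]], tt))
        }
      } else {
        # envelope: max over fine grid and bump centers, small safety margin
        sub <- feature_rate_one(feat, loc, c(grid, feat$centers[[loc]]))
        env <- max(sub) * 1.001
        if (env <= 0) next
        ncand <- rng$rpois(1, env * horizon / 1000)
        if (ncand > 0) {
          tc <- rng$runif(ncand, 0, horizon)
          lam <- feature_rate_one(feat, loc, tc)
          keep <- rng$runif(ncand) < lam / env
          if (any(keep)) {
            trains[[gi]] <- sort(c(trains[[gi]], tc[keep]))
          }
        }
      }
    }
  }
  if (!is.null(background_window)) {
    rng <- local_rng((seed %% 99991L) * 1009L + 7L)
    l0 <- if (is.null(lambda0)) feature_list[[1]]$lambda0 else lambda0
    dur <- (background_window[2] - background_window[1]) / 1000
    for (i in seq_len(n_syn)) {
      nb <- rng$rpois(1, l0 * dur)
      if (nb > 0) {
        tb <- rng$runif(nb, background_window[1], background_window[2])
        trains[[i]] <- sort(c(trains[[i]], tb))
      }
    }
  }
  trains
}

# rate of a single synapse of a feature at times t (Hz)
feature_rate_one <- function(feature, i, t) {
  if (!feature$active[i]) return(numeric(length(t)))
  inside <- t >= feature$t_on & t <= feature$t_off
  if (feature$k == 0) return(feature$lambda_bar[i] * inside)
  s_per_event <- feature$lambda_bar[i] * (feature$t_off - feature$t_on) /
    1000 / feature$k
  r <- numeric(length(t))
  for (ck in feature$centers[[i]]) {
    r <- r + s_per_event * stats::dnorm(t, ck, feature$sigma)
  }
  1000 * r * inside
}

#' Build a feature-binding association task
#'
#' Generates `n` features per class (X and Y), each defined over half of the
#' synapses, plus the label matrix. The nonlinear 2 x 2 task uses the
#' XOR-like assignment (diagonal pairs preferred); larger tasks draw labels
#' at random per replication.
#'
#' @param ensemble An `input_ensemble_spec`.
#' @param n Features per class (task is n x n).
#' @param nonlinear_2x2 Use the fixed nonlinearly separable 2 x 2 labels.
#' @param seed RNG seed.
#' @return An `association_task`: list with `features_x`, `features_y`
#'   (lists of `feature_pattern`), `labels` (n x n 0/1 matrix),
#'   `syn_x`, `syn_y` (synapse index vectors), `ensemble`.
#' @export
make_task <- function(ensemble, n = 2, nonlinear_2x2 = (n == 2), seed = 1) {
  if (n > 10) stop("tasks larger than 10 x 10 are not supported")
  half <- ensemble$n_syn %/% 2
  rng <- local_rng(seed)
  fx <- lapply(seq_len(n), function(i)
    make_feature(ensemble, n = half, seed = seed * 1000 + i))
  fy <- lapply(seq_len(n), function(i)
    make_feature(ensemble, n = half, seed = seed * 1000 + 100 + i))
  if (nonlinear_2x2) {
    if (n != 2) stop("nonlinear_2x2 requires n = 2")
    labels <- diag(2)
  } else {
    labels <- matrix(rng$rbinom(n * n, 1, 0.5), n, n)
  }
  structure(list(features_x = fx, features_y = fy, labels = labels,
                 syn_x = seq_len(half), syn_y = half + seq_len(half),
                 ensemble = ensemble),
            class = "association_task")
}

#' @export
print.association_task <- function(x, ...) {
  n <- length(x$features_x)
  cat("<association_task> ", n, " x ", n, " associations, ",
      x$ensemble$n_syn, " synapses (k = ", x$ensemble$k, ", lambda_syn = ",
      x$ensemble$lambda_syn, " Hz)\n", sep = "")
  invisible(x)
}

#' Compress the stimulus presentation window
#'
#' Rescales every feature's bump centers and the stimulus window to a new
#' duration, preserving per-synapse expected spike counts (time-averaged
#' rates scale up as the window shrinks).
#'
#' @param task An `association_task`.
#' @param t_new New stimulus duration (ms), within 25-400.
#' @return The rescaled `association_task`.
#' @export
compress_duration <- function(task, t_new) {
  if (t_new < 25 || t_new > 400) stop("t_new must be in [25, 400] ms")
  ens <- task$ensemble
  scale <- t_new / ens$t_len
  rescale <- function(f) {
    f$t_off <- f$t_on + t_new
    f$lambda_bar <- f$lambda_bar / scale
    f$centers <- lapply(f$centers, function(ck) {
      if (is.null(ck)) NULL else f$t_on + (ck - task$ensemble$t_on) * scale
    })
    # per-event expected spikes (lambda_bar * T / k) are invariant, so the
    # bump width is unchanged
    f
  }
  task$features_x <- lapply(task$features_x, rescale)
  task$features_y <- lapply(task$features_y, rescale)
  ens$t_off <- ens$t_on + t_new
  ens$t_len <- t_new
  ens$lambda_syn <- ens$lambda_syn / scale
  ens$lambda_pop <- ens$lambda_pop / scale
  task$ensemble <- ens
  task
}

#' Noise specification for robustness experiments
#'
#' @param background_ratio Background-to-stimulus population rate ratio
#'   `lambda0 / lambda_pop` (background stays on during the stimulus).
#' @param p_mislabel Per-presentation probability of flipping the label.
#' @param s_jitter Weight jitter scale: weights are multiplied by
#'   `1 + u`, `u ~ unif(-s_jitter, s_jitter)`, thresholded at 0.
#' @param t_shift Burst-time cyclic shift bound (ms).
#' @param shift_mode `"shared"` (one draw per presentation) or
#'   `"independent"` (per synapse).
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(background_ratio = 0, p_mislabel = 0, s_jitter = 0,
                       t_shift = 0, shift_mode = c("shared", "independent")) {
  shift_mode <- match.arg(shift_mode)
  if (p_mislabel < 0 || p_mislabel > 0.2) stop("p_mislabel must be in [0, 0.2]")
  structure(list(background_ratio = background_ratio,
                 p_mislabel = p_mislabel, s_jitter = s_jitter,
                 t_shift = t_shift, shift_mode = shift_mode),
            class = "noise_spec")
}

#' Apply noise manipulations
#'
#' Applies the trial-by-trial perturbations of the robustness protocol:
#' weight jitter multiplies each weight by `1 + u`, `u ~ unif(-s, s)`,
#' thresholded at zero; burst shifts move every event center cyclically
#' within the stimulus window (one shared draw, or an independent draw per
#' synapse); label flips are applied per presentation with `p_mislabel`.
#'
#' @param x A `synapse_layout` (weight jitter), `association_task` (burst
#'   shift), or a 0/1 label (mislabeling).
#' @param noise A `noise_spec`.
#' @param seed RNG seed.
#' @return The perturbed object.
#' @export
apply_noise <- function(x, noise, seed = 1) {
  rng <- local_rng(seed)
  if (inherits(x, "synapse_layout")) {
    u <- rng$runif(nrow(x), -noise$s_jitter, noise$s_jitter)
    x$w <- pmax(0, x$w * (1 + u))
    return(x)
  }
  if (inherits(x, "association_task")) {
    if (noise$t_shift <= 0) return(x)
    win <- x$ensemble$t_len
    t_on <- x$ensemble$t_on
    # shared mode: one draw per presentation shifts every burst time
    s_shared <- rng$runif(1, -noise$t_shift, noise$t_shift)
    shift_feature <- function(f) {
      f$centers <- lapply(seq_along(f$centers), function(i) {
        ck <- f$centers[[i]]
        if (is.null(ck)) return(NULL)
        s <- if (noise$shift_mode == "independent") {
          rng$runif(1, -noise$t_shift, noise$t_shift)
        } else s_shared
        t_on + (ck - t_on + s) %% win
      })
      f
    }
    x$features_x <- lapply(x$features_x, shift_feature)
    x$features_y <- lapply(x$features_y, shift_feature)
    return(x)
  }
  if (is.numeric(x) && length(x) == 1L) {
    flip <- rng$runif(1) < noise$p_mislabel
    return(if (flip) 1 - x else x)
  }
  stop("apply_noise: unsupported object")
}

#' Structured synapse placement for the 2 x 2 task
#'
#' Places excitatory synapses on branch sets chosen to hard-wire (or
#' prohibit) the learned spatial solution. Two possibly overlapping sets of
#' first-order branches are selected per domain; `overlap` = 1 minus the
#' fraction of shared branches (0: both sets are all branches, i.e.
#' unstructured; 1: disjoint half-size sets). For the active model,
#' features of a preferred pair share a basal set and split apical sets;
#' the passive model disperses preferred pairs and clusters nonpreferred
#' in both domains. Inhibitory synapses remain uniformly placed.
#'
#' @param geom A `dendrite_geometry`.
#' @param task A 2 x 2 `association_task` with diagonal labels.
#' @param overlap Structured-connectivity parameter in `[0, 1]`.
#' @param model `"active"` or `"passive"` targeting strategy.
#' @param n_e,n_i Synapse counts.
#' @param w_e,w_i Initial weights (uS).
#' @param seed RNG seed.
#' @return A `synapse_layout`; attribute `branch_sets` records the chosen
#'   sets per domain.
#' @export
structured_placement <- function(geom, task, overlap = 1,
                                 model = c("active", "passive"),
                                 n_e = 800, n_i = 200,
                                 w_e = 0.6e-3, w_i = 0.8e-3, seed = 1) {
  model <- match.arg(model)
  if (overlap < 0 || overlap > 1) stop("overlap must be in [0, 1]")
  if (!all(dim(task$labels) == c(2, 2)) || !all(task$labels == diag(2)))
    stop("structured placement is defined for the diagonal 2 x 2 task")
  cp <- geom$compartments
  rng <- local_rng(seed)
  first_order <- function(domain) {
    idx <- which(cp$domain == domain)
    b <- unique(cp$branch[idx][cp$parent[idx] == geom$soma_index])
    sort(b)
  }
  pick_sets <- function(branches) {
    B <- length(branches)
    n_set <- round(B * (1 - overlap / 2))
    n_shared <- round(B * (1 - overlap))
    perm <- branches[rng$sample(B, B)]
    shared <- perm[seq_len(n_shared)]
    rest <- setdiff(perm, shared)
    extra <- n_set - n_shared
    list(a = c(shared, rest[seq_len(extra)]),
         b = c(shared, rest[extra + seq_len(min(extra, length(rest) - extra))]))
  }
  basal <- pick_sets(first_order("basal"))
  apical <- pick_sets(first_order("apical"))
  # feature -> (basal set, apical set); preferred pairs are (X1,Y1),(X2,Y2)
  assign_sets <- if (model == "active") {
    list(X1 = list(basal$a, apical$a), Y1 = list(basal$a, apical$b),
         X2 = list(basal$b, apical$a), Y2 = list(basal$b, apical$b))
  } else {
    # passive: preferred dispersed (different sets), nonpreferred clustered
    list(X1 = list(basal$a, apical$a), Y1 = list(basal$b, apical$b),
         X2 = list(basal$b, apical$a), Y2 = list(basal$a, apical$b))
  }
  branch_of_comp <- cp$branch
  # subtree branch closure: all branches whose first-order ancestor is in set
  anc <- branch_ancestor_map(geom)
  comp_pool <- function(sets) {
    bset <- unique(unlist(sets))
    all_b <- which(anc %in% bset)
    which(branch_of_comp %in% all_b & cp$domain %in% c("basal", "apical"))
  }
  half <- length(task$syn_x)
  feat_of_syn <- function(features, k_e) {
    # which feature activates each synapse (first active; 0 if none)
    act <- vapply(features, function(f) f$active, logical(half))
    apply(act, 1, function(a) if (any(a)) which(a)[1] else 0L)
  }
  fx <- feat_of_syn(task$features_x)
  fy <- feat_of_syn(task$features_y)
  e_per_class <- n_e %/% 2
  draw_from <- function(pool, k) {
    pool[rng$sample(length(pool), k, replace = TRUE, prob = cp$area[pool])]
  }
  comp_e <- integer(n_e)
  # map layout E synapses onto feature-local indices: first half X, rest Y
  ex_idx <- seq_len(e_per_class)
  ey_idx <- e_per_class + seq_len(n_e - e_per_class)
  pools <- list(
    X = list(`0` = comp_pool(list(basal$a, basal$b, apical$a, apical$b)),
             `1` = comp_pool(assign_sets$X1), `2` = comp_pool(assign_sets$X2)),
    Y = list(`0` = comp_pool(list(basal$a, basal$b, apical$a, apical$b)),
             `1` = comp_pool(assign_sets$Y1), `2` = comp_pool(assign_sets$Y2)))
  for (i in seq_along(ex_idx)) {
    f <- fx[((i - 1) %% half) + 1]
    comp_e[ex_idx[i]] <- draw_from(pools$X[[as.character(min(f, 2))]], 1)
  }
  for (i in seq_along(ey_idx)) {
    f <- fy[((i - 1) %% half) + 1]
    comp_e[ey_idx[i]] <- draw_from(pools$Y[[as.character(min(f, 2))]], 1)
  }
  dendc <- which(cp$domain %in% c("basal", "apical"))
  comp_i <- dendc[rng$sample(length(dendc), n_i, replace = TRUE,
                             prob = cp$area[dendc])]
  comp <- c(comp_e, comp_i)
  layout <- data.frame(
    synapse = seq_len(n_e + n_i),
    type = rep(c("E", "I"), c(n_e, n_i)),
    comp = comp, branch = cp$branch[comp], domain = cp$domain[comp],
    w = rep(c(w_e, w_i), c(n_e, n_i)))
  class(layout) <- c("synapse_layout", "data.frame")
  attr(layout, "branch_sets") <- list(basal = basal, apical = apical)
  layout
}

# first-order ancestor branch id for every branch (itself if first order)
branch_ancestor_map <- function(geom) {
  cp <- geom$compartments
  nb <- max(cp$branch)
  anc <- integer(nb)
  for (b in seq_len(nb)) {
    idx <- which(cp$branch == b)
    root_comp <- idx[1]
    # climb to the branch attached at the soma
    cur <- root_comp
    repeat {
      par <- cp$parent[cur]
      if (par == 0L || cp$branch[par] == 0L) break
      cur <- which(cp$branch == cp$branch[par])[1]
    }
    anc[b] <- cp$branch[cur]
  }
  anc
}
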