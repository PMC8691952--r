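#' Random-input campaign collecting pre-spike voltage gradients
#'
#' Runs repeated simulations under random Poisson bombardment (per-synapse
#' constant rates drawn from lognormal(0, 1) Hz; weights drawn uniformly
#' from `w_range`), finds isolated somatic spikes (no other spike in the
#' preceding window), and computes per-event `dv_soma/dw` by window replay
#' with the variational system ([spike_window_gradient()]). Records carry
#' the covariates used for kernel fitting and the local-voltage regression:
#' input resistance at the synapse, same-branch synchronous excitatory and
#' inhibitory activity in the past 100 ms, the synapse's weight and its own
#' kinetic state (activation at the spike time).
#'
#' @param geom A `dendrite_geometry`.
#' @param spec A `biophysics_spec`; for the passive variant excitatory
#'   weights are conventionally reduced (see `w_scale_e`).
#' @param layout A `synapse_layout`; weights are redrawn per run.
#' @param n_runs Number of independent runs.
#' @param run_length Run length (ms).
#' @param seed RNG seed.
#' @param w_range Weight range (uS) for the random redraw.
#' @param w_scale_e Multiplier on excitatory weights (1/5 for the passive
#'   model to match postsynaptic rates).
#' @param window Pre-spike window (ms).
#' @param dt Solver step (ms).
#' @return A `gradient_campaign`: list with `records` (one row per synaptic
#'   event; columns of [spike_window_gradient()] plus `run`, `spike`,
#'   `r_in`, `sync_e`, `sync_i`, `kinetic`), `n_spikes` (isolated spikes
#'   used), `n_spikes_total`.
#' @export
run_gradient_campaign <- function(geom, spec, layout, n_runs = 5000,
                                  run_length = 10000, seed = 1,
                                  w_range = c(0.4e-3, 1.0e-3),
                                  w_scale_e = 1, window = 150, dt = 0.025) {
  rin <- input_resistance(geom)
  nsyn <- nrow(layout)
  recs <- list()
  n_iso <- 0L
  n_tot <- 0L
  for (r in seq_len(n_runs)) {
    rng <- local_rng(seed * 1000 + r)
    lay <- layout
    lay$w <- rng$runif(nsyn, w_range[1], w_range[2])
    lay$w[lay$type == "E"] <- lay$w[lay$type == "E"] * w_scale_e
    rates <- rng$rlnorm(nsyn, 0, 1)   # Hz
    trains <- lapply(seq_len(nsyn), function(j) {
      ns <- rng$rpois(1, rates[j] * run_length / 1000)
      if (ns == 0) return(numeric(0))
      sort(rng$runif(ns, 0, run_length))
    })
    run <- simulate_neuron(geom, spec, lay, trains, horizon = run_length,
                           dt = dt, checkpoint_every = 10)
    n_tot <- n_tot + length(run$spikes)
    iso <- isolated_spikes(run$spikes, window)
    iso <- iso[iso - window >= 0]
    for (tsp in iso) {
      wg <- spike_window_gradient(run, tsp, geom, spec, lay, trains,
                                  window = window, dt = dt)
      if (nrow(wg) == 0) next
      n_iso <- n_iso + 1L
      wg$run <- r
      wg$spike <- tsp
      wg$r_in <- rin[wg$comp]
      wg$sync_e <- wg$sync_i <- wg$kinetic <- 0
      for (i in seq_len(nrow(wg))) {
        b <- lay$branch[wg$synapse[i]]
        same <- which(lay$branch == b & seq_len(nsyn) != wg$synapse[i])
        cnt <- function(type) {
          idx <- same[lay$type[same] == type]
          if (!length(idx)) return(0)
          sum(vapply(idx, function(j) {
            sum(trains[[j]] > tsp - 100 & trains[[j]] <= tsp)
          }, numeric(1)))
        }
        wg$sync_e[i] <- cnt("E")
        wg$sync_i[i] <- cnt("I")
        tj <- trains[[wg$synapse[i]]]
        taus <- if (wg$type[i] == "E") c(spec$tau_ar, spec$tau_ad) else
          c(spec$tau_gr, spec$tau_gd)
        wg$kinetic[i] <- syn_activation(tsp, tj[tj <= tsp], taus[1], taus[2])
      }
      recs[[length(recs) + 1L]] <- wg
    }
  }
  if (length(recs) == 0L) {
    stop("campaign produced no isolated somatic spikes; ",
         "check the weight scale (w_range / w_scale_e)")
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  structure(list(records = records, n_spikes = n_iso, n_spikes_total = n_tot),
            class = "gradient_campaign")
}

isolated_spikes <- function(spikes, window) {
  if (length(spikes) == 0) return(numeric(0))
  keep <- vapply(seq_along(spikes), function(i) {
    !any(spikes > spikes[i] - window & spikes < spikes[i])
  }, logical(1))
  spikes[keep]
}

#' @export
print.gradient_campaign <- function(x, ...) {
  cat("<gradient_campaign> ", nrow(x$records), " events from ", x$n_spikes,
      " isolated spikes (", x$n_spikes_total, " total)\n", sep = "")
  invisible(x)
}

#' Spike-triggered average of voltage gradients
#'
#' Bins window-gradient records on a (delta-t, dendritic-voltage) grid —
#' 1 ms over (0, 100] and 1 mV over [-80, 0] — and averages `g` per bin,
#' pooling synapses of one stratum (basal or apical; excitatory or
#' inhibitory). The point-neuron variant averages over a delta-t axis only.
#'
#' @param campaign A `gradient_campaign` (or its `records`).
#' @param domain `"basal"`, `"apical"`, or `NULL` to pool.
#' @param type `"E"` or `"I"`.
#' @param temporal_only Build the delta-t-only grid.
#' @return An `sta_grid`: list with bin centers `dt_mid` (and `v_mid`),
#'   matrices/vectors `mean` and `count` (NA mean marks empty bins), and
#'   the stratum labels.
#' @export
spike_triggered_average <- function(campaign, domain = NULL, type = "E",
                                    temporal_only = FALSE) {
  recs <- if (inherits(campaign, "gradient_campaign")) campaign$records
          else campaign
  sel <- recs$type == type & recs$dt > 0 & recs$dt <= 100
  if (!is.null(domain)) sel <- sel & recs$domain == domain
  recs <- recs[sel, , drop = FALSE]
  if (nrow(recs) == 0) stop("no records for stratum ", domain, "/", type)
  ti <- pmin(100L, as.integer(ceiling(recs$dt)))
  if (temporal_only) {
    cnt <- tabulate(ti, 100L)
    s <- vapply(split(recs$g, factor(ti, levels = 1:100)), function(g)
      if (length(g)) sum(g) else 0, numeric(1))
    mu <- ifelse(cnt > 0, s / pmax(1, cnt), NA_real_)
    grid <- list(dt_mid = (1:100) - 0.5, mean = mu, count = cnt,
                 domain = domain, type = type, temporal_only = TRUE)
  } else {
    keep <- recs$v_dend >= -80 & recs$v_dend <= 0
    recs <- recs[keep, , drop = FALSE]
    vi <- pmin(80L, pmax(1L, as.integer(ceiling(recs$v_dend + 80))))
    ti <- pmin(100L, as.integer(ceiling(recs$dt)))
    cnt <- matrix(0L, 100, 80)
    s <- matrix(0, 100, 80)
    for (i in seq_len(nrow(recs))) {
      cnt[ti[i], vi[i]] <- cnt[ti[i], vi[i]] + 1L
      s[ti[i], vi[i]] <- s[ti[i], vi[i]] + recs$g[i]
    }
    mu <- ifelse(cnt > 0, s / pmax(1, cnt), NA_real_)
    grid <- list(dt_mid = (1:100) - 0.5, v_mid = (-80:-1) + 0.5, mean = mu,
                 count = cnt, domain = domain, type = type,
                 temporal_only = FALSE)
  }
  structure(grid, class = "sta_grid")
}

# scaled coordinates for conditioning of the polynomial design
kernel_scale_dt <- function(dt) (dt - 50) / 50
kernel_scale_v <- function(v) (v + 40) / 40

poly_design <- function(dt, v = NULL, deg_t, deg_v = NULL) {
  u <- kernel_scale_dt(dt)
  Tu <- outer(u, 0:deg_t, `^`)
  if (is.null(v)) return(Tu)
  z <- kernel_scale_v(v)
  Zv <- outer(z, 0:deg_v, `^`)
  X <- matrix(0, length(dt), (deg_t + 1) * (deg_v + 1))
  k <- 0
  for (a in 0:deg_t) for (b in 0:deg_v) {
    k <- k + 1
    X[, k] <- Tu[, a + 1] * Zv[, b + 1]
  }
  X
}

#' Fit a plasticity kernel to a spike-triggered-average grid
#'
#' Pads the grid boundaries (v = 0, v = -80 mV, and t = -1 ms) with zeros,
#' then fits a polynomial surface by count-weighted least squares: degree 8
#' in both delta-t and voltage (degree 10 in delta-t for the temporal-only
#' kernel). After fitting, excitatory kernels are clamped at >= 0 and
#' inhibitory kernels at <= 0; the kernel evaluates to 0 outside
#' delta-t in (0, 100] and v in [-80, 0].
#'
#' @param grid An `sta_grid`.
#' @param deg_t,deg_v Polynomial degrees.
#' @return A `plasticity_kernel`: coefficients, degrees, stratum, sign.
#' @export
fit_plasticity_kernel <- function(grid, deg_t = if (grid$temporal_only) 10 else 8,
                                  deg_v = 8) {
  if (grid$temporal_only) {
    occ <- which(grid$count > 0)
    if (length(occ) == 0) stop("fit error: no occupied bins")
    dt <- c(grid$dt_mid[occ], -1)
    y <- c(grid$mean[occ], 0)
    wt <- c(grid$count[occ], 1)
    X <- poly_design(dt, deg_t = deg_t)
    if (length(occ) < deg_t + 1)
      stop("fit error: rank-deficient design (", length(occ), " occupied bins)")
    fit <- stats::lm.wfit(X, y, wt)
    coefs <- unname(ifelse(is.na(fit$coefficients), 0, fit$coefficients))
    out <- list(coef = coefs, deg_t = deg_t, deg_v = NULL,
                temporal_only = TRUE, type = grid$type,
                sign = if (grid$type == "E") 1 else -1, domain = grid$domain)
  } else {
    occ <- which(grid$count > 0, arr.ind = TRUE)
    if (nrow(occ) == 0) stop("fit error: no occupied bins")
    dt <- grid$dt_mid[occ[, 1]]
    v <- grid$v_mid[occ[, 2]]
    y <- grid$mean[occ]
    wt <- as.numeric(grid$count[occ])
    # zero padding at the stated boundaries
    pad_dt <- c(rep(-1, 80), grid$dt_mid, grid$dt_mid)
    pad_v <- c(grid$v_mid, rep(0, 100), rep(-80, 100))
    dt <- c(dt, pad_dt)
    v <- c(v, pad_v)
    y <- c(y, rep(0, length(pad_dt)))
    wt <- c(wt, rep(1, length(pad_dt)))
    X <- poly_design(dt, v, deg_t, deg_v)
    if (nrow(occ) < (deg_t + 1) * (deg_v + 1) / 4)
      stop("fit error: rank-deficient design (", nrow(occ), " occupied bins)")
    fit <- stats::lm.wfit(X, y, wt)
    coefs <- unname(ifelse(is.na(fit$coefficients), 0, fit$coefficients))
    out <- list(coef = coefs, deg_t = deg_t, deg_v = deg_v,
                temporal_only = FALSE, type = grid$type,
                sign = if (grid$type == "E") 1 else -1, domain = grid$domain)
  }
  class(out) <- "plasticity_kernel"
  out
}

#' Evaluate a plasticity kernel
#'
#' Polynomial value with the stratum's sign clamp inside the valid domain
#' (delta-t in (0, 100], v in [-80, 0]); exactly 0 outside. The
#' temporal-only kernel ignores the voltage argument.
#'
#' @param kernel A `plasticity_kernel`.
#' @param dt Time before the somatic spike (ms).
#' @param v_dend Local dendritic voltage at the spike time (mV).
#' @return Kernel values (mV/uS).
#' @export
evaluate_kernel <- function(kernel, dt, v_dend = NULL) {
  n <- length(dt)
  out <- numeric(n)
  inside <- dt > 0 & dt <= 100
  if (!kernel$temporal_only) {
    if (is.null(v_dend)) stop("v_dend required for a 2-D kernel")
    inside <- inside & v_dend >= -80 & v_dend <= 0
  }
  if (!any(inside)) return(out)
  X <- if (kernel$temporal_only) {
    poly_design(dt[inside], deg_t = kernel$deg_t)
  } else {
    poly_design(dt[inside], v_dend[inside], kernel$deg_t, kernel$deg_v)
  }
  val <- as.numeric(X %*% kernel$coef)
  val <- if (kernel$sign > 0) pmax(0, val) else pmin(0, val)
  out[inside] <- val
  out
}

#' Fit kernels for all strata with held-out accuracy
#'
#' Splits campaign records 75/25 at the record level (seed-controlled),
#' builds the spike-triggered-average grid from the training split, fits
#' the kernel, and reports held-out accuracy as the squared correlation
#' between recorded gradients and kernel predictions on the test split.
#'
#' @param campaign A `gradient_campaign`.
#' @param strata data.frame of `domain`/`type` pairs; defaults to the four
#'   dendritic strata.
#' @param temporal_only Fit delta-t-only kernels (point-neuron variant;
#'   strata then collapse over domain).
#' @param seed Split seed.
#' @return A `kernel_set`: list of `plasticity_kernel`s keyed
#'   `"<domain>_<type>"` (or `"<type>"`), with attribute `r2` (held-out
#'   squared correlation per stratum).
#' @export
fit_all_kernels <- function(campaign,
                            strata = expand.grid(
                              domain = c("basal", "apical"),
                              type = c("E", "I"),
                              stringsAsFactors = FALSE),
                            temporal_only = FALSE, seed = 1) {
  recs <- campaign$records
  rng <- local_rng(seed)
  test <- rng$runif(nrow(recs)) < 0.25
  kernels <- list()
  r2 <- numeric(0)
  if (temporal_only) {
    strata <- unique(strata["type"])
  }
  for (s in seq_len(nrow(strata))) {
    dom <- if (temporal_only) NULL else strata$domain[s]
    ty <- strata$type[s]
    key <- if (temporal_only) ty else paste(dom, ty, sep = "_")
    grid <- spike_triggered_average(recs[!test, , drop = FALSE], dom, ty,
                                    temporal_only = temporal_only)
    k <- fit_plasticity_kernel(grid)
    sel <- !test
    hel <- test & recs$type == ty & recs$dt > 0 & recs$dt <= 100
    if (!temporal_only) hel <- hel & recs$domain == dom &
        recs$v_dend >= -80 & recs$v_dend <= 0
    pred <- evaluate_kernel(k, recs$dt[hel],
                            if (temporal_only) NULL else recs$v_dend[hel])
    r2[key] <- if (sum(hel) > 2) stats::cor(recs$g[hel], pred)^2 else NA_real_
    kernels[[key]] <- k
  }
  structure(kernels, r2 = r2, temporal_only = temporal_only,
            class = "kernel_set")
}

#' @export
print.kernel_set <- function(x, ...) {
  cat("<kernel_set>", paste(names(x), collapse = ", "), "\n")
  r2 <- attr(x, "r2")
  if (length(r2)) cat("held-out R2:",
                      paste(sprintf("%s=%.3f", names(r2), r2), collapse = ", "),
                      "\n")
  invisible(x)
}

kernel_for <- function(kernels, domain, type) {
  key <- if (isTRUE(attr(kernels, "temporal_only"))) type
         else paste(domain, type, sep = "_")
  k <- kernels[[key]]
  if (is.null(k)) stop("no kernel available for stratum ", key)
  k
}

#' Serialize a kernel set to JSON
#' @param kernels A `kernel_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
kernels_to_json <- function(kernels, path) {
  obj <- lapply(kernels, unclass)
  attr(obj, "r2") <- NULL
  jsonlite::write_json(list(kernels = obj,
                            temporal_only = attr(kernels, "temporal_only"),
                            r2 = as.list(attr(kernels, "r2"))),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname kernels_to_json
#' @export
kernels_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ks <- lapply(obj$kernels, function(k) {
    k$coef <- as.numeric(k$coef)
    if (!is.null(k$deg_v) && length(k$deg_v) == 0) k$deg_v <- NULL
    class(k) <- "plasticity_kernel"
    k
  })
  structure(ks, r2 = unlist(obj$r2), temporal_only = isTRUE(obj$temporal_only),
            class = "kernel_set")
}

#' Semipartial correlations of local-voltage predictors
#'
#' Regresses the dendritic voltage at spike time on the stated covariates
#' (input resistance, same-branch synchronous excitation and inhibition
#' within 100 ms, own weight, own kinetic state) and reports each
#' covariate's semipartial correlation: the correlation between the
#' covariate and the out-of-sample residual of the model that excludes it
#' (75/25 split).
#'
#' @param campaign A `gradient_campaign` (excitatory records are used).
#' @param covariates Covariate column names.
#' @param seed Split seed.
#' @return Named vector of semipartial correlations; attribute
#'   `condition_number` carries the design condition number.
#' @export
local_voltage_regression <- function(campaign,
                                     covariates = c("r_in", "sync_e",
                                                    "sync_i", "w", "kinetic"),
                                     seed = 1) {
  recs <- if (inherits(campaign, "gradient_campaign")) campaign$records
          else campaign
  recs <- recs[recs$type == "E", , drop = FALSE]
  X <- as.matrix(recs[, covariates, drop = FALSE])
  y <- recs$v_dend
  rng <- local_rng(seed)
  test <- rng$runif(nrow(X)) < 0.25
  kappa_val <- kappa(cbind(1, scale(X[!test, , drop = FALSE])))
  out <- numeric(length(covariates))
  names(out) <- covariates
  for (ci in seq_along(covariates)) {
    Xr <- X[, -ci, drop = FALSE]
    df_tr <- data.frame(y = y[!test], Xr[!test, , drop = FALSE])
    fit <- stats::lm(y ~ ., data = df_tr)
    pr <- stats::predict(fit, newdata = data.frame(Xr[test, , drop = FALSE]))
    resid <- y[test] - pr
    out[ci] <- suppressWarnings(stats::cor(X[test, ci], resid))
  }
  attr(out, "condition_number") <- kappa_val
  out
}
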