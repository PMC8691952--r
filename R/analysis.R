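#' Subthreshold summation nonlinearity
#'
#' Presents two features separately and together (somatic spiking blocked
#' by zeroing the fast axo-somatic Na+/K+ conductances; synaptic weights in
#' the other dendritic domain zeroed), averages the somatic traces over
#' `n_reps` presentations, and returns the peak of the joint average
#' divided by the peak of the sum of the separate averages. Peaks are taken
#' over the second half of the stimulus window (the steady-state response).
#' A ratio above 1 indicates supralinear, below 1 sublinear integration.
#'
#' @param geom,spec,layout,task Model components (trained layout).
#' @param ix,iy Feature indices of the association pair.
#' @param domain `"basal"`, `"apical"`, or `"all"` (no weight zeroing).
#' @param n_reps Presentations averaged.
#' @param seed RNG seed.
#' @param dt Solver step (ms).
#' @return List with `ratio`, `peak_joint`, `peak_sum`.
#' @export
summation_nonlinearity <- function(geom, spec, layout, task, ix = 1, iy = 1,
                                   domain = "basal", n_reps = 20, seed = 1,
                                   dt = 0.025) {
  lay <- layout
  if (domain %in% c("basal", "apical")) {
    lay$w[lay$domain != domain & lay$domain != "soma"] <- 0
  }
  ens <- task$ensemble
  rest <- spec$e_l
  # the same presentation seed is used for x alone, y alone, and the pair:
  # input streams are keyed by feature identity, so the joint realization
  # is exactly the union of the separate ones and a linear cable's joint
  # response equals the sum of the separate responses
  avg_trace <- function(which_feat) {
    acc <- NULL
    for (r in seq_len(n_reps)) {
      feats <- list(); idx <- list()
      if (which_feat %in% c("x", "both")) {
        feats <- c(feats, list(task$features_x[[ix]]))
        idx <- c(idx, list(task$syn_x))
      }
      if (which_feat %in% c("y", "both")) {
        feats <- c(feats, list(task$features_y[[iy]]))
        idx <- c(idx, list(task$syn_y))
      }
      trains <- realize_poisson(feats, idx, n_syn = nrow(lay),
                                horizon = ens$t_off,
                                seed = seed * 100 + r,
                                background_window = c(0, ens$t_on))
      run <- simulate_neuron(geom, spec, lay, trains, horizon = ens$t_off,
                             dt = dt, block_soma_spikes = TRUE,
                             record_every_ms = 1)
      acc <- if (is.null(acc)) run$v_soma else acc + run$v_soma
    }
    list(v = acc / n_reps, t = run_times(ens$t_off, 1))
  }
  vx <- avg_trace("x")
  vy <- avg_trace("y")
  vb <- avg_trace("both")
  half <- vx$t >= ens$t_on + ens$t_len / 2 & vx$t <= ens$t_off
  peak_joint <- max(vb$v[half] - rest)
  peak_sum <- max((vx$v[half] - rest) + (vy$v[half] - rest))
  if (peak_sum <= 0) stop("undefined nonlinearity ratio: zero summed response")
  list(ratio = peak_joint / peak_sum, peak_joint = peak_joint,
       peak_sum = peak_sum)
}

run_times <- function(horizon, every) seq(0, horizon, by = every)

#' Weighted input profiles
#'
#' Spatial profile: per-branch sum of weighted time-averaged stimulus rates
#' `S_b = sum_i w_ib lambda_bar_ib`. Temporal profile: per-1 ms sum of
#' weighted rates over all synapses of a domain `T(t) = sum_i w_i
#' lambda_i(t)`. Spatiotemporal: per-branch temporal profiles concatenated
#' in branch order.
#'
#' @param task An `association_task`.
#' @param layout A `synapse_layout` (trained weights).
#' @param feature `"x"` or `"y"`; `index` its feature number.
#' @param index Feature index within the class.
#' @param kind `"spatial"`, `"temporal"`, or `"spatiotemporal"`.
#' @param domain Restrict to `"basal"`, `"apical"`, `"soma"`, or `"all"`.
#' @param type `"E"` or `"I"`.
#' @return Numeric profile vector (nonnegative).
#' @export
input_profile <- function(task, layout, feature = "x", index = 1,
                          kind = c("spatial", "temporal", "spatiotemporal"),
                          domain = "all", type = "E") {
  kind <- match.arg(kind)
  feat <- if (feature == "x") task$features_x[[index]] else
    task$features_y[[index]]
  syn_global <- if (feature == "x") task$syn_x else task$syn_y
  sel_layout <- layout$type == type &
    (domain == "all" | layout$domain == domain)
  # feature-local index of each selected synapse (0 if other class)
  loc <- match(layout$synapse, syn_global)
  use <- which(sel_layout & !is.na(loc))
  w <- layout$w[use]
  lidx <- loc[use]
  ens <- task$ensemble
  if (kind == "spatial") {
    branches <- sort(unique(layout$branch[layout$domain %in%
                                            c("basal", "apical")]))
    lam <- feat$lambda_bar[lidx] *
      (feat$t_off - feat$t_on) / (ens$t_off - ens$t_on)
    s <- vapply(branches, function(b) {
      sum(w[layout$branch[use] == b] * lam[layout$branch[use] == b])
    }, numeric(1))
    names(s) <- branches
    return(s)
  }
  tgrid <- seq(ens$t_on + 0.5, feat$t_off - 0.5, by = 1)
  rates <- feature_rate(feat, tgrid)[, lidx, drop = FALSE]
  if (kind == "temporal") {
    return(as.numeric(rates %*% w))
  }
  branches <- sort(unique(layout$branch[layout$domain %in%
                                          c("basal", "apical")]))
  out <- numeric(0)
  for (b in branches) {
    sb <- layout$branch[use] == b
    out <- c(out, if (any(sb)) as.numeric(rates[, sb, drop = FALSE] %*% w[sb])
             else numeric(length(tgrid)))
  }
  out
}

#' Pearson correlation between input profiles
#'
#' For E-E comparisons, pass the two features' excitatory profiles. For
#' E-I comparisons, sum the two features' excitatory profiles and the two
#' inhibitory profiles first (`pair_profile_correlation()` does both).
#'
#' @param p,q Profiles from [input_profile()] (same kind/domain).
#' @return Pearson r, or `NA` when a profile is constant.
#' @export
profile_correlation <- function(p, q) {
  if (stats::sd(p) == 0 || stats::sd(q) == 0) return(NA_real_)
  stats::cor(p, q)
}

#' @rdname profile_correlation
#' @param task,layout,ix,iy,kind,domain As in [input_profile()].
#' @param comparison `"EE"` (the two features' excitation) or `"EI"`
#'   (summed excitation vs summed inhibition of the pair).
#' @export
pair_profile_correlation <- function(task, layout, ix, iy, kind = "spatial",
                                     domain = "all", comparison = c("EE", "EI")) {
  comparison <- match.arg(comparison)
  px <- input_profile(task, layout, "x", ix, kind, domain, "E")
  py <- input_profile(task, layout, "y", iy, kind, domain, "E")
  if (comparison == "EE") return(profile_correlation(px, py))
  qx <- input_profile(task, layout, "x", ix, kind, domain, "I")
  qy <- input_profile(task, layout, "y", iy, kind, domain, "I")
  profile_correlation(px + py, qx + qy)
}

#' Correlation of average somatic traces
#'
#' Simulates each feature of a pair in isolation with spiking blocked,
#' averages the somatic voltage over `n_reps` presentations, and returns
#' the Pearson correlation over the stimulus window. With
#' `split_domains = TRUE` the features are presented together but with
#' input restricted to the basal vs apical domain, measuring how well the
#' two domains' contributions align.
#'
#' @param geom,spec,layout,task Model components.
#' @param ix,iy Feature indices.
#' @param n_reps Presentations averaged.
#' @param split_domains Correlate basal-input vs apical-input responses.
#' @param seed RNG seed.
#' @param dt Solver step (ms).
#' @return Pearson r.
#' @export
trace_correlation <- function(geom, spec, layout, task, ix = 1, iy = 1,
                              n_reps = 20, split_domains = FALSE, seed = 1,
                              dt = 0.025) {
  ens <- task$ensemble
  avg <- function(feats, idx, lay, off) {
    acc <- NULL
    for (r in seq_len(n_reps)) {
      trains <- realize_poisson(feats, idx, n_syn = nrow(lay),
                                horizon = ens$t_off,
                                seed = seed * 300 + off + r,
                                background_window = c(0, ens$t_on))
      run <- simulate_neuron(geom, spec, lay, trains, horizon = ens$t_off,
                             dt = dt, block_soma_spikes = TRUE,
                             record_every_ms = 1)
      acc <- if (is.null(acc)) run$v_soma else acc + run$v_soma
    }
    acc / n_reps
  }
  win <- run_times(ens$t_off, 1) >= ens$t_on
  if (split_domains) {
    lb <- layout; lb$w[lb$domain != "basal"] <- 0
    la <- layout; la$w[la$domain != "apical"] <- 0
    feats <- list(task$features_x[[ix]], task$features_y[[iy]])
    idx <- list(task$syn_x, task$syn_y)
    v1 <- avg(feats, idx, lb, 0)
    v2 <- avg(feats, idx, la, 5000)
    return(profile_correlation(v1[win], v2[win]))
  }
  v1 <- avg(list(task$features_x[[ix]]), list(task$syn_x), layout, 0)
  v2 <- avg(list(task$features_y[[iy]]), list(task$syn_y), layout, 5000)
  profile_correlation(v1[win], v2[win])
}

#' Predict association labels from profile correlations
#'
#' Fits a logistic regression of the binary association labels on
#' profile-correlation features and reports leave-one-out cross-validated
#' accuracy — the measure of how much task structure a given profile family
#' (spatial, temporal, spatiotemporal) carries after learning.
#'
#' @param features Matrix (associations x regressors) of correlations.
#' @param labels Binary labels (one per association).
#' @return LOOCV accuracy in `[0, 1]`.
#' @export
predict_labels <- function(features, labels) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (length(unique(labels)) < 2) stop("labels contain a single class")
  if (n < 10) stop("need at least 10 associations for cross-validation")
  correct <- logical(n)
  for (i in seq_len(n)) {
    df_tr <- data.frame(y = labels[-i], features[-i, , drop = FALSE])
    fit <- suppressWarnings(stats::glm(y ~ ., data = df_tr,
                                       family = stats::binomial()))
    pr <- stats::predict(fit,
                         newdata = data.frame(features[i, , drop = FALSE]),
                         type = "response")
    correct[i] <- (pr >= 0.5) == (labels[i] == 1)
  }
  mean(correct)
}

#' Correlation feature table for a trained model
#'
#' Convenience wrapper building the per-association regressor matrix used
#' by [predict_labels()]: E-E and E-I profile correlations per dendritic
#' domain for the requested profile kind.
#'
#' @param task,layout As in [input_profile()].
#' @param kind Profile kind.
#' @param domains Domains included.
#' @return data.frame with one row per association: feature indices, label,
#'   and correlation columns.
#' @export
correlation_features <- function(task, layout, kind = "spatial",
                                 domains = c("basal", "apical")) {
  pats <- task_patterns(task)
  rows <- lapply(seq_len(nrow(pats)), function(p) {
    vals <- c()
    for (d in domains) {
      vals <- c(vals,
                pair_profile_correlation(task, layout, pats$x[p], pats$y[p],
                                         kind, d, "EE"),
                pair_profile_correlation(task, layout, pats$x[p], pats$y[p],
                                         kind, d, "EI"))
    }
    names(vals) <- as.vector(outer(c("EE", "EI"), domains,
                                   function(a, b) paste(b, a, sep = "_")))
    vals
  })
  out <- as.data.frame(do.call(rbind, rows))
  out$x <- pats$x
  out$y <- pats$y
  out$label <- task$labels[cbind(pats$x, pats$y)]
  out
}
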