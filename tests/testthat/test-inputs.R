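test_that("feature generation obeys the sparseness/rate constraint", {
  # degenerate case: lambda_syn == lambda_pop -> all synapses active
  sp <- input_ensemble_spec(n_syn = 200, lambda_syn = 2.5, k = 0)
  f <- make_feature(sp, seed = 1)
  expect_true(all(f$active))
  expect_true(all(f$lambda_bar == 2.5))
  expect_error(input_ensemble_spec(lambda_syn = 1), "lambda_syn")

  # rate-code preset: active fraction 1/16, ~1000 spikes expected per
  # presentation at 1000 synapses
  sp16 <- input_preset("rate")
  fracs <- vapply(1:40, function(s)
    mean(make_feature(sp16, seed = s)$active), numeric(1))
  expect_equal(mean(fracs), 1 / 16, tolerance = 0.15)
  expected_total <- sp16$n_syn * sp16$lambda_pop * sp16$t_len / 1000
  expect_equal(expected_total, 1000)
})

test_that("rate functions integrate to lambda_bar * T for k in {1, 2, 4}", {
  for (k in c(1, 2, 4)) {
    sp <- input_ensemble_spec(n_syn = 50, lambda_syn = 20, k = k)
    f <- make_feature(sp, seed = k + 1)
    act <- which(f$active)
    # keep bump centers >= 3 sigma from the window edges so the boundary
    # truncation (tolerated by the normalization contract) is negligible
    for (i in act) {
      f$centers[[i]] <- pmin(pmax(f$centers[[i]], 100 + 3 * f$sigma),
                             500 - 3 * f$sigma)
    }
    tt <- seq(100, 500, by = 0.05)
    rates <- feature_rate(f, tt)
    integral <- colSums(rates[, act, drop = FALSE]) * 0.05 / 1000
    expect_equal(mean(integral), 20 * 0.4, tolerance = 0.02 * 20 * 0.4)

    # with uniform centers, the only deficit is the analytic edge loss
    f2 <- make_feature(sp, seed = 40 + k)
    act2 <- which(f2$active)
    int2 <- colSums(feature_rate(f2, tt)[, act2, drop = FALSE]) * 0.05 / 1000
    loss <- 2 * f2$sigma / 400 * 0.39894
    expect_equal(mean(int2) / 8, (1 - loss),
                 tolerance = 3 * 0.5 / sqrt(length(act2)) / 8 + 0.01)
  }
})

test_that("Poisson realization: empty at zero rate, correct count law, bump shape", {
  sp <- input_ensemble_spec(n_syn = 4, lambda_syn = 40, k = 0)
  f <- make_feature(sp, seed = 2)
  f$active[] <- FALSE
  f$lambda_bar[] <- 0
  tr <- realize_poisson(list(f), list(1:4), 4, horizon = 500, seed = 1)
  expect_true(all(lengths(tr) == 0))

  # constant 40 Hz over 400 ms: mean 16, Poisson dispersion
  sp1 <- input_ensemble_spec(n_syn = 1, lambda_syn = 40, k = 0)
  f1 <- make_feature(sp1, seed = 3)
  f1$active[1] <- TRUE
  f1$lambda_bar[1] <- 40
  counts <- vapply(1:10000, function(s) {
    length(realize_poisson(list(f1), list(1), 1, 500, seed = s)[[1]])
  }, numeric(1))
  expect_equal(mean(counts), 16, tolerance = 0.05 * 16)
  expect_equal(stats::var(counts) / mean(counts), 1, tolerance = 0.05)

  # one Gaussian bump, expected 8 spikes, sigma = 20 ms: KS vs the bump law
  sp2 <- input_ensemble_spec(n_syn = 1, lambda_syn = 20, k = 1)
  f2 <- make_feature(sp2, seed = 4)
  f2$active[1] <- TRUE
  f2$lambda_bar[1] <- 20
  f2$centers[[1]] <- 300
  expect_equal(f2$sigma, 20)
  times <- unlist(lapply(1:2000, function(s)
    realize_poisson(list(f2), list(1), 1, 500, seed = 10000 + s)[[1]]))
  expect_gt(length(times), 5000)
  # truncated-normal CDF on the window
  pn <- function(q) (stats::pnorm(q, 300, 20) - stats::pnorm(100, 300, 20)) /
    (stats::pnorm(500, 300, 20) - stats::pnorm(100, 300, 20))
  ks <- suppressWarnings(stats::ks.test(times, pn))
  expect_gt(ks$p.value, 0.01)
})

test_that("population rate is conserved across (lambda_syn, k) presets", {
  n_syn <- 400
  n_rep <- 300
  for (preset in c("rate", "optimal", "temporal")) {
    sp <- input_preset(preset, n_syn = n_syn)
    expected <- n_syn * sp$lambda_pop * sp$t_len / 1000
    if (sp$k > 0) {
      # Gaussian bumps lose the analytic edge fraction of their mass when
      # centered near the window boundaries (normalization contract holds
      # up to this stated boundary effect)
      sigma <- sp$sigma0 * sp$lambda_syn * sp$t_len / 1000 / sp$k
      expected <- expected * (1 - 2 * sigma / sp$t_len * 0.39894)
    }
    tot <- vapply(seq_len(n_rep), function(s) {
      f <- make_feature(sp, n = n_syn, seed = 5000 + s)
      sum(lengths(realize_poisson(list(f), list(seq_len(n_syn)),
                                  n_syn, 500, seed = 9000 + s)))
    }, numeric(1))
    se <- stats::sd(tot) / sqrt(n_rep)
    expect_lt(abs(mean(tot) - expected), 3 * se + 0.01 * expected)
  }
})

test_that("association tasks have the stated labels and structure", {
  ens <- input_ensemble_spec(n_syn = 100)
  t2 <- make_task(ens, n = 2, seed = 1)
  expect_equal(t2$labels, diag(2))
  t7a <- make_task(ens, n = 7, seed = 3)
  t7b <- make_task(ens, n = 7, seed = 3)
  expect_identical(t7a$labels, t7b$labels)
  expect_equal(length(t7a$features_x), 7)
  expect_equal(dim(t7a$labels), c(7, 7))
  # features of one class share the synapse index set but differ in
  # which synapses are active
  expect_identical(t2$syn_x, 1:50)
  a1 <- t2$features_x[[1]]$active
  a2 <- t2$features_x[[2]]$active
  expect_false(identical(a1, a2))
  expect_error(make_task(ens, n = 11), "10 x 10")
})

test_that("duration compression preserves expected spike counts", {
  ens <- input_preset("optimal", n_syn = 60)
  task <- make_task(ens, n = 2, seed = 2)
  same <- compress_duration(task, 400)
  f0 <- task$features_x[[1]]
  f1 <- same$features_x[[1]]
  expect_equal(f1$lambda_bar, f0$lambda_bar)
  expect_equal(unlist(f1$centers), unlist(f0$centers))

  short <- compress_duration(task, 100)
  fs <- short$features_x[[1]]
  act <- which(fs$active)
  tt <- seq(100, fs$t_off, by = 0.02)
  integral <- colSums(feature_rate(fs, tt)[, act, drop = FALSE]) * 0.02 / 1000
  t_orig <- seq(100, 500, by = 0.02)
  integral0 <- colSums(feature_rate(f0, t_orig)[, act, drop = FALSE]) *
    0.02 / 1000
  expect_equal(mean(integral), mean(integral0), tolerance = 0.05)
  expect_error(compress_duration(task, 10), "25")
})

test_that("noise manipulations behave per contract", {
  g <- small_tree()
  lay <- place_synapses(g, 30, 10, seed = 1)
  ns0 <- noise_spec(s_jitter = 0)
  expect_equal(apply_noise(lay, ns0, seed = 2)$w, lay$w)

  ns1 <- noise_spec(s_jitter = 1)
  mults <- vapply(1:300, function(s) {
    apply_noise(lay, ns1, seed = 1000 + 7 * s)$w / lay$w
  }, numeric(nrow(lay)))
  # literal sampler: uniform on [0, 2] after thresholding
  expect_gt(max(mults), 1.8)
  expect_lt(min(mults), 0.2)
  expect_equal(mean(mults), 1, tolerance = 0.05)

  ens <- input_preset("optimal", n_syn = 40)
  task <- make_task(ens, n = 2, seed = 4)
  sh <- apply_noise(task, noise_spec(t_shift = 200, shift_mode = "shared"),
                    seed = 5)
  c0 <- unlist(task$features_x[[1]]$centers)
  c1 <- unlist(sh$features_x[[1]]$centers)
  d <- (c1 - c0) %% 400
  expect_equal(length(unique(round(d, 6))), 1)   # one shared shift
  si <- apply_noise(task, noise_spec(t_shift = 200,
                                     shift_mode = "independent"), seed = 6)
  c2 <- unlist(si$features_x[[1]]$centers)
  expect_gt(length(unique(round((c2 - c0) %% 400, 6))), 1)

  # mislabeling flips with the stated probability
  flips <- vapply(1:4000, function(s)
    apply_noise(1, noise_spec(p_mislabel = 0.2), seed = s), numeric(1))
  expect_equal(mean(flips == 0), 0.2, tolerance = 0.05)
})

test_that("structured placement produces the stated branch-set sizes", {
  g <- memo("struct_tree", synthetic_tree(16, 8, 1, seed = 2))
  ens <- input_preset("rate", n_syn = 200)
  task <- make_task(ens, n = 2, seed = 1)
  for (ov in c(0, 0.5, 1)) {
    lay <- structured_placement(g, task, overlap = ov, model = "active",
                                n_e = 100, n_i = 20, seed = 3)
    bs <- attr(lay, "branch_sets")$basal
    if (ov == 0) {
      expect_setequal(bs$a, bs$b)
      expect_equal(length(bs$a), 16)
    } else if (ov == 1) {
      expect_equal(length(bs$a), 8)
      expect_equal(length(intersect(bs$a, bs$b)), 0)
    } else {
      expect_equal(length(bs$a), 12)
      expect_equal(length(intersect(bs$a, bs$b)), 8)
    }
  }
})
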