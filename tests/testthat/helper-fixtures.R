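# Shared fixtures, memoized across test files within one run.
fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, fixture_env)) assign(key, force(expr), fixture_env)
  get(key, fixture_env)
}

small_tree <- function() memo("small_tree", synthetic_tree(3, 2, 1, seed = 3))

# minimal SWC text fixture: soma root with one basal branch (3 points)
write_swc_fixture <- function(path,
                              lines = c("# test cell",
                                        "1 1 0 0 0 6 -1",
                                        "2 3 20 0 0 1 1",
                                        "3 3 40 0 0 1 2",
                                        "4 3 60 0 0 1 3")) {
  writeLines(lines, path)
  path
}

# deterministic Poisson-ish trains for smoke simulations
fixed_trains <- function(nsyn, seed = 1, horizon = 300, rate = 3) {
  rng <- cabletron:::local_rng(seed)
  lapply(seq_len(nsyn), function(j) {
    n <- rng$rpois(1, rate)
    if (n == 0) numeric(0) else sort(rng$runif(n, 20, horizon - 20))
  })
}

# soma-only geometry for point-neuron and RC tests
soma_geometry <- function() {
  structure(list(compartments = data.frame(
    length = 20, radius = 10, area = 4 * pi * (10e-4)^2, parent = 0L,
    branch = 0L, domain = "soma"), soma_index = 1L),
    class = "dendrite_geometry")
}

passive_spec <- function(...) {
  biophysics_spec("passive", g_na = 0, g_k = 0, g_km = 0, ...)
}

simple_layout <- function(comp, type = "E", w = 0.5e-3, geom = NULL,
                          branch = NULL, domain = NULL) {
  k <- max(length(comp), length(type), length(w))
  comp <- rep_len(comp, k); type <- rep_len(type, k); w <- rep_len(w, k)
  if (!is.null(geom)) {
    branch <- geom$compartments$branch[comp]
    domain <- geom$compartments$domain[comp]
  }
  lay <- data.frame(synapse = seq_len(k), type = type, comp = comp,
                    branch = if (is.null(branch)) 0L else branch,
                    domain = if (is.null(domain)) "soma" else domain,
                    w = w)
  class(lay) <- c("synapse_layout", "data.frame")
  lay
}
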