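# Shared fixtures: small networks and fast simulation protocols. All
# fixtures are built in code; nothing is read from disk.

default_net <- function(L = 2, ...) {
  build_network(network_config(L, ...))
}

# Fast protocol for unit tests: shorter epoch, coarser recording. The
# acceptance tests use the full default protocol.
fast <- list(duration = 250, onset = 25, offset = 225, dt = 0.1)

fast_crp <- function(net, norm_A, competitor_norms, n_trials, seed, ...) {
  measure_crp(net, norm_A, competitor_norms, n_trials, seed,
              duration = fast$duration, onset = fast$onset,
              offset = fast$offset, dt = fast$dt, ...)
}

# Hand-constructed CRP objects for estimator tests (no simulation).
synthetic_crp <- function(competitor_norms, mean_response, sd_response,
                          norm_A, n_trials = 10L) {
  structure(
    list(norm_A = norm_A, competitor_norms = competitor_norms,
         mean_response = mean_response, sd_response = sd_response,
         n_trials = n_trials, channel_probed = 1L,
         trials = NULL, config_hash = "synthetic", seed = 0L),
    class = "wta_crp"
  )
}

# Independent brute-force coverage check (set logic written differently from
# the package's membership-matrix route).
oracle_covered <- function(rfs, L) {
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (i == j) next
      hit <- FALSE
      for (rf in rfs) {
        if (i %in% rf && !(j %in% rf)) { hit <- TRUE; break }
      }
      if (!hit) return(FALSE)
    }
  }
  TRUE
}

# Independent cost evaluation from the stated definitions.
oracle_cost <- function(rfs, L, alpha = 1, beta = 1) {
  metabolic <- sum(vapply(seq_len(L), function(i) {
    sum(vapply(rfs, function(rf) i %in% rf, logical(1)))
  }, numeric(1)))
  wiring <- sum(vapply(rfs, function(rf) (L - length(rf)) + length(rf),
                       numeric(1)))
  alpha * metabolic + beta * wiring
}

# Literal enumeration oracle for minimum-cost covered codes: tries every set
# of distinct candidate RFs up to max_units. (Duplicate RFs never help: they
# add positive cost and cover no new pair, so distinct sets suffice.)
oracle_search <- function(L, max_units, alpha = 1, beta = 1) {
  cand <- unlist(lapply(seq_len(L - 1L), function(k) {
    m <- utils::combn(L, k)
    lapply(seq_len(ncol(m)), function(j) m[, j])
  }), recursive = FALSE)
  best <- Inf
  best_rfs <- NULL
  for (u in seq_len(max_units)) {
    idx <- utils::combn(length(cand), u)
    for (j in seq_len(ncol(idx))) {
      rfs <- cand[idx[, j]]
      if (!oracle_covered(rfs, L)) next
      cost <- oracle_cost(rfs, L, alpha, beta)
      if (cost < best) { best <- cost; best_rfs <- rfs }
    }
  }
  list(cost = best, rfs = best_rfs, feasible = is.finite(best))
}
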