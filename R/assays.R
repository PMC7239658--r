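## Measurement protocols over a built network: competitor-strength response
## profiles (CRPs), the categorization index, transition norms and the
## flexibility assay, multi-option scaling, and the first-to-threshold
## unitary-choice assay. Every assay derives its per-condition RNG streams
## from one master seed so that interleaved conditions are matched
## trial-for-trial, and every result embeds the configuration hash and the
## master seed for provenance.

# Run n_trials noisy simulations of one norm vector and return the per-trial
# mean output rates in the response window (the final `window` ms of the
# stimulus epoch). Returns a channels x trials matrix.
run_trial_batch <- function(net, norms, n_trials, batch_seed,
                            duration = 400, dt = 0.1,
                            onset = 50, offset = 350, window = 50,
                            record_every = 10L, noise = TRUE,
                            keep_trace = FALSE) {
  norms_m <- matrix(norms, nrow = net$n_channels, ncol = n_trials)
  res <- with_seed(batch_seed, sim_core(
    net, norms_m, duration, dt, onset = onset, offset = offset,
    noise = noise, record = "out", record_every = record_every))
  tm <- res$trace_steps * dt
  in_window <- tm > (offset - window) & tm <= offset
  means <- apply(res$trace[in_window, , , drop = FALSE], c(2, 3), mean)
  means <- matrix(means, nrow = net$n_channels)
  if (keep_trace) {
    list(window_means = means, trace = res$trace, time = tm)
  } else {
    list(window_means = means)
  }
}

#' Measure a competitor-strength-dependent response profile (CRP)
#'
#' Presents the preferred option A (fixed norm) on the probed channel
#' together with a competing option B whose norm is swept from below to
#' above A's norm, and records the probed channel's output statistics in a
#' fixed response window (the final 50 ms of the stimulus epoch, a
#' steady-state proxy). Conditions share a deterministic per-point seed
#' schedule derived from `seed`, so matched-seed comparisons across circuit
#' perturbations are exact.
#'
#' @param net a `wta_network` with at least 2 channels.
#' @param norm_A norm of the preferred option (a.u.).
#' @param competitor_norms strictly ascending vector spanning values both
#'   below and above `norm_A`.
#' @param n_trials simulated trials per competitor norm (>= 1).
#' @param seed master seed.
#' @param probe_channel,competitor_channel channel ids for options A and B.
#' @param duration,dt,onset,offset,window simulation protocol (ms).
#' @return an object of class `wta_crp`: list with `norm_A`,
#'   `competitor_norms`, `mean_response`, `sd_response`, `n_trials`,
#'   `channel_probed`, `trials` (points x trials matrix of window means),
#'   `config_hash`, `seed`.
#' @export
measure_crp <- function(net, norm_A, competitor_norms, n_trials, seed,
                        probe_channel = 1L, competitor_channel = 2L,
                        duration = 400, dt = 0.1, onset = 50, offset = 350,
                        window = 50) {
  stopifnot(inherits(net, "wta_network"), n_trials >= 1)
  L <- net$n_channels
  if (L < 2L) stop("a CRP needs at least two channels")
  probe_channel <- as.integer(probe_channel)
  competitor_channel <- as.integer(competitor_channel)
  if (probe_channel < 1L || probe_channel > L) {
    stop("invalid probe channel: ", probe_channel)
  }
  if (competitor_channel < 1L || competitor_channel > L ||
      competitor_channel == probe_channel) {
    stop("invalid competitor channel: ", competitor_channel)
  }
  if (is.unsorted(competitor_norms, strictly = TRUE)) {
    stop("competitor_norms must be strictly ascending")
  }
  if (min(competitor_norms) >= norm_A || max(competitor_norms) <= norm_A) {
    stop("competitor_norms must span values both below and above norm_A")
  }
  n_points <- length(competitor_norms)
  point_seeds <- spawn_seeds(seed, n_points)
  trials <- matrix(NA_real_, n_points, n_trials)
  for (k in seq_len(n_points)) {
    norms <- numeric(L)
    norms[probe_channel] <- norm_A
    norms[competitor_channel] <- competitor_norms[k]
    batch <- run_trial_batch(net, norms, n_trials, point_seeds[k],
                             duration = duration, dt = dt, onset = onset,
                             offset = offset, window = window)
    trials[k, ] <- batch$window_means[probe_channel, ]
  }
  structure(
    list(norm_A = norm_A,
         competitor_norms = competitor_norms,
         mean_response = rowMeans(trials),
         sd_response = apply(trials, 1, stats::sd),
         n_trials = n_trials,
         channel_probed = probe_channel,
         trials = trials,
         config_hash = config_hash(net$config),
         seed = seed),
    class = "wta_crp"
  )
}

#' @export
print.wta_crp <- function(x, ...) {
  cat("CRP: probe channel ", x$channel_probed, " at norm_A = ",
      format(x$norm_A), ", ", length(x$competitor_norms),
      " competitor norms x ", x$n_trials, " trials\n", sep = "")
  print(data.frame(competitor_norm = x$competitor_norms,
                   mean = round(x$mean_response, 2),
                   sd = round(x$sd_response, 2)))
  invisible(x)
}

# Adjacent-pair d' with degenerate-pair guards: responses below a floor of
# 0.01 spikes/s are indistinguishable from silence (a fully suppressed
# channel's window mean is a decaying numerical residue whose mean/sd ratio
# is meaningless), two numerically identical zero-variance distributions are
# indiscriminable (d' = 0), and an unequal-mean pair with zero variance is
# perfectly discriminable (Inf).
pair_dprime <- function(m1, s1, m2, s2, tol = 1e-8, floor = 1e-2) {
  if (max(abs(m1), abs(m2), s1, s2) < floor) return(0)
  if (s1 == 0 && s2 == 0) {
    if (abs(m1 - m2) < tol) return(0)
    return(Inf)
  }
  discriminability(m1, s1, m2, s2)
}

#' Categorization index of a CRP
#'
#' Quantifies how step-like a CRP is across the selection boundary, taking
#' response variability into account. Discriminability d' is computed for
#' every pair of adjacent competitor norms; the index contrasts the mean d'
#' of adjacent pairs that straddle the boundary (placed at competitor norm =
#' `norm_A`) with the mean d' of adjacent pairs within either side:
#' `CatI = (between - within) / (between + within)`, in `[-1, 1]`. A perfect
#' step with equal variances gives 1 (within-side d' = 0); a linear profile
#' with equal spacing and equal variances gives ~0 (all adjacent d' equal).
#'
#' @param crp a `wta_crp` with `n_trials >= 2` (so sds are available) and at
#'   least two competitor norms strictly on each side of the boundary.
#' @return scalar CatI.
#' @export
categorization_index <- function(crp) {
  stopifnot(inherits(crp, "wta_crp"))
  if (crp$n_trials < 2L) {
    stop("categorization_index needs n_trials >= 2 for response variability")
  }
  cn <- crp$competitor_norms
  b <- crp$norm_A
  if (sum(cn < b) < 2L || sum(cn > b) < 2L) {
    stop("need at least 2 competitor norms strictly on each side of the boundary")
  }
  m <- crp$mean_response
  s <- crp$sd_response
  n <- length(cn)
  d <- vapply(seq_len(n - 1L), function(k) {
    pair_dprime(m[k], s[k], m[k + 1L], s[k + 1L])
  }, numeric(1))
  straddle <- cn[-n] <= b & cn[-1] >= b
  between <- mean(d[straddle])
  within <- mean(d[!straddle])
  if (is.infinite(between) && is.finite(within)) return(1)
  if (is.finite(between) && is.infinite(within)) return(-1)
  if (between == 0 && within == 0) return(0)   # fully degenerate (flat) CRP
  (between - within) / (between + within)
}

#' Transition norm of a CRP
#'
#' The competitor norm at which the mean response drops through the midpoint
#' between its upper and lower plateaus, located by linear interpolation
#' between the bracketing samples. This is the behavioural signature of the
#' selection boundary: a flexible circuit shifts it with the strength of the
#' preferred option.
#'
#' @param crp a `wta_crp` whose mean response has a decreasing span.
#' @return the interpolated transition norm. If the response never crosses
#'   the midpoint within the sampled range (e.g. a flat CRP), an error of
#'   class `wta_no_transition` is signalled.
#' @export
transition_norm <- function(crp) {
  stopifnot(inherits(crp, "wta_crp"))
  m <- crp$mean_response
  cn <- crp$competitor_norms
  upper <- max(m)
  lower <- min(m)
  mid <- (upper + lower) / 2
  for (k in seq_len(length(m) - 1L)) {
    if (m[k] >= mid && m[k + 1L] < mid) {
      frac <- (m[k] - mid) / (m[k] - m[k + 1L])
      return(cn[k] + frac * (cn[k + 1L] - cn[k]))
    }
  }
  stop(structure(
    class = c("wta_no_transition", "error", "condition"),
    list(message = paste0(
           "mean response does not cross its plateau midpoint within the ",
           "sampled competitor range (flat or out-of-range CRP)"),
         call = sys.call(-1))))
}

#' Flexibility assay: does the selection boundary track the winner's norm?
#'
#' Measures two CRPs in an interleaved manner -- identical except that the
#' preferred option's norm takes a low and a high value -- under one shared
#' seed schedule, and reports both transition norms together with
#' `shift_ratio = (transition_high - transition_low) / (norm_A_high -
#' norm_A_low)`. A dynamically flexible boundary gives a ratio near 1; a
#' fixed boundary (e.g. after [silence_feedback()]) gives a ratio near 0.
#'
#' @param net a `wta_network`.
#' @param norm_A_low,norm_A_high the two preferred-option norms
#'   (`norm_A_high > norm_A_low`), both spanned by `competitor_norms`.
#' @param competitor_norms strictly ascending sweep.
#' @param n_trials trials per competitor norm.
#' @param seed master seed (shared by both CRPs).
#' @param ... passed to [measure_crp()].
#' @return an object of class `wta_flexibility`: list with `transition_low`,
#'   `transition_high`, `delta_A`, `shift_ratio`, `crp_low`, `crp_high`.
#' @export
flexibility_assay <- function(net, norm_A_low, norm_A_high, competitor_norms,
                              n_trials, seed, ...) {
  if (!(norm_A_high > norm_A_low)) {
    stop("norm_A_high must exceed norm_A_low")
  }
  crp_low <- measure_crp(net, norm_A_low, competitor_norms, n_trials, seed, ...)
  crp_high <- measure_crp(net, norm_A_high, competitor_norms, n_trials, seed, ...)
  t_low <- transition_norm(crp_low)
  t_high <- transition_norm(crp_high)
  delta <- norm_A_high - norm_A_low
  structure(
    list(transition_low = t_low, transition_high = t_high,
         delta_A = delta, shift_ratio = (t_high - t_low) / delta,
         crp_low = crp_low, crp_high = crp_high,
         config_hash = crp_low$config_hash, seed = seed),
    class = "wta_flexibility"
  )
}

#' @export
print.wta_flexibility <- function(x, ...) {
  cat("Flexibility assay: transition norms ", format(x$transition_low),
      " -> ", format(x$transition_high), " for delta_A = ", format(x$delta_A),
      " (shift ratio ", format(round(x$shift_ratio, 3)), ")\n", sep = "")
  invisible(x)
}

#' Multi-option assay: selection among more than two options
#'
#' For each condition (a full-length norm vector; zero entries mean the
#' option is absent) runs `n_trials` simulations, scores the per-trial winner
#' (argmax of response-window output) against the idealized WTA oracle, and
#' reports the winner channel's mean output. Conditions with an oracle tie
#' are rejected.
#'
#' @param net a `wta_network`.
#' @param conditions list of numeric norm vectors, each of length
#'   `n_channels` with at least 2 active (positive) options.
#' @param n_trials trials per condition.
#' @param seed master seed.
#' @param noise logical; `FALSE` gives a deterministic (noise-free) run, the
#'   cleanest reading of the winner-output-vs-option-count curve.
#' @param ... protocol arguments passed to the internal trial runner.
#' @return an object of class `wta_multi_option`: a data frame with one row
#'   per condition (`n_options`, `oracle_winner`, `accuracy`,
#'   `winner_mean_output`) plus attributes `config_hash` and `seed`.
#' @export
multi_option_assay <- function(net, conditions, n_trials, seed,
                               noise = TRUE, ...) {
  stopifnot(inherits(net, "wta_network"), is.list(conditions), n_trials >= 1)
  L <- net$n_channels
  cond_seeds <- spawn_seeds(seed, length(conditions))
  rows <- lapply(seq_along(conditions), function(i) {
    norms <- conditions[[i]]
    if (length(norms) != L) {
      stop("condition ", i, " must have one norm per channel (", L, ")")
    }
    if (sum(norms > 0) < 2L) {
      stop("condition ", i, " must present at least 2 options")
    }
    oracle <- ideal_wta(norms)
    if (is.na(oracle$winner)) {
      stop("condition ", i, " has no unique oracle winner")
    }
    batch <- run_trial_batch(net, norms, n_trials, cond_seeds[i],
                             noise = noise, ...)
    wm <- batch$window_means
    trial_winners <- apply(wm, 2, which.max)
    data.frame(
      condition = i,
      n_options = sum(norms > 0),
      oracle_winner = oracle$winner,
      accuracy = mean(trial_winners == oracle$winner),
      winner_mean_output = mean(wm[oracle$winner, ])
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "config_hash") <- config_hash(net$config)
  attr(out, "seed") <- seed
  class(out) <- c("wta_multi_option", class(out))
  out
}

#' Unitary-choice assay: first-to-threshold statistics over noisy trials
#'
#' Runs `n_trials` noisy simulations of one norm vector and scores each with
#' [first_threshold_crossing()]: `p_unitary` is the fraction of trials in
#' which exactly one channel's output ever exceeds the functional threshold
#' (the circuit-level reading of "the selected option, and only that one,
#' triggers downstream consequences"); `accuracy` is the fraction whose
#' winner matches the idealized WTA oracle; reaction times are crossing
#' times relative to stimulus onset, over correct trials.
#'
#' @param net a `wta_network`.
#' @param norms numeric norm vector (length `n_channels`).
#' @param threshold functional output threshold, in `(0, r_max)`.
#' @param n_trials number of trials.
#' @param seed master seed.
#' @param duration,dt,onset,offset simulation protocol (ms).
#' @return an object of class `wta_choice_stats`: list with `p_unitary`,
#'   `accuracy`, `rt_mean`, `rt_sd`, `n_trials`, `threshold`, `trials` (data
#'   frame with per-trial `winner`, `rt`, `n_crossers`), `config_hash`,
#'   `seed`.
#' @export
unitary_choice_assay <- function(net, norms, threshold, n_trials, seed,
                                 duration = 400, dt = 0.1,
                                 onset = 50, offset = 350) {
  stopifnot(inherits(net, "wta_network"), n_trials >= 1)
  if (threshold <= 0 || threshold >= net$config$r_max) {
    stop("threshold must lie in (0, r_max)")
  }
  L <- net$n_channels
  if (length(norms) != L) stop("norms must have one entry per channel")
  oracle <- ideal_wta(norms)
  norms_m <- matrix(norms, L, n_trials)
  res <- with_seed(seed, sim_core(
    net, norms_m, duration, dt, onset = onset, offset = offset,
    noise = TRUE, record = "out", record_every = 2L))
  tm <- res$trace_steps * dt
  events <- lapply(seq_len(n_trials), function(tr) {
    out <- matrix(res$trace[, , tr], ncol = L)
    attr(out, "time") <- tm
    first_threshold_crossing(out, threshold)
  })
  winners <- vapply(events, function(e) as.integer(e$winner), integer(1))
  rts <- vapply(events, function(e) as.numeric(e$crossing_time), numeric(1)) -
    onset
  n_crossers <- vapply(events, function(e) e$n_crossers, integer(1))
  correct <- !is.na(winners) & winners == oracle$winner
  rt_correct <- rts[correct]
  structure(
    list(p_unitary = mean(n_crossers == 1L),
         accuracy = mean(correct),
         rt_mean = if (length(rt_correct)) mean(rt_correct) else NA_real_,
         rt_sd = if (length(rt_correct) > 1) stats::sd(rt_correct) else NA_real_,
         n_trials = n_trials,
         threshold = threshold,
         trials = data.frame(winner = winners, rt = rts,
                             n_crossers = n_crossers),
         config_hash = config_hash(net$config),
         seed = seed),
    class = "wta_choice_stats"
  )
}

#' @export
print.wta_choice_stats <- function(x, ...) {
  cat("Unitary choice assay (", x$n_trials, " trials, threshold ",
      format(x$threshold), " spikes/s):\n", sep = "")
  cat("  p_unitary = ", format(round(x$p_unitary, 3)),
      ", accuracy = ", format(round(x$accuracy, 3)),
      ", RT = ", format(round(x$rt_mean, 1)), " +/- ",
      format(round(x$rt_sd, 1)), " ms\n", sep = "")
  invisible(x)
}
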