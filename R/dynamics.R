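## Time evolution of network rates. All non-input units obey the leaky rate
## equation tau * dr/dt = -r + f(total input), integrated by explicit Euler;
## input-layer units are linear relays of the stimulus norms (clipped to
## [0, r_max]) so that the norm of each option is encoded veridically in the
## common currency of firing rate. Inhibition converging on a target from
## multiple source units is combined by the configured rule before entering
## the target's input.

#' Saturating rate nonlinearity
#'
#' A logistic sigmoid with threshold, slope and ceiling, shifted and rescaled
#' so that `f(0) = 0` exactly and `f(u) -> r_max` as `u -> Inf`; `f(u) = 0`
#' for all `u <= 0`. Strictly increasing on `u > 0`, so the circuit operates
#' with the soft (continuous) nonlinearity that real neurons implement rather
#' than the hard step of the idealized winner-take-all equation.
#'
#' @param u input drive (any numeric shape).
#' @param threshold sigmoid midpoint (a.u. of input drive).
#' @param slope sigmoid width; smaller is steeper.
#' @param r_max saturation rate (spikes/s).
#' @return rates, same shape as `u`, in `[0, r_max)`.
#' @export
rate_nonlinearity <- function(u, threshold, slope, r_max) {
  s0 <- stats::plogis(-threshold / slope)
  v <- r_max * (stats::plogis((u - threshold) / slope) - s0) / (1 - s0)
  v[u <= 0] <- 0
  v
}

#' Stimulus timeline: per-channel norms as a step function of time
#'
#' @param norms non-negative numeric vector of per-channel norms (a.u.,
#'   common currency), one entry per network channel.
#' @param onset,offset stimulus onset and offset times in ms
#'   (`offset > onset`).
#' @return an object of class `wta_stimulus`.
#' @export
stimulus_timeline <- function(norms, onset = 50, offset = 350) {
  norms <- as.numeric(norms)
  if (any(!is.finite(norms)) || any(norms < 0)) {
    stop("norms must be finite and non-negative")
  }
  if (!(offset > onset)) stop("offset must exceed onset")
  structure(list(norms = norms, onset = onset, offset = offset,
                 duration = offset - onset),
            class = "wta_stimulus")
}

# Combine inhibitory contributions s_k = w_k * r_k (>= 0) from the source
# units that project to each target.
#   linear          : sum_k s_k
#   max             : max_k s_k
#   softmax-weighted: sum_k s_k * exp(beta s_k) / sum_j exp(beta s_j),
#                     a smooth, max-dominated average (-> max as beta -> Inf,
#                     -> mean as beta -> 0). Non-projecting units are
#                     excluded so they cannot dilute the weights.
# Wabs: targets x sources magnitude matrix; rates: sources x n_trials.
combine_inhibition <- function(Wabs, rates, rule, beta) {
  n_t <- nrow(Wabs)
  n_trials <- ncol(rates)
  if (rule == "linear") return(Wabs %*% rates)
  out <- matrix(0, n_t, n_trials)
  for (t in seq_len(n_t)) {
    idx <- which(Wabs[t, ] > 0)
    if (length(idx) == 0L) next
    S <- rates[idx, , drop = FALSE] * Wabs[t, idx]
    if (length(idx) == 1L) {
      out[t, ] <- S
    } else if (rule == "max") {
      m <- S[1, ]
      for (k in 2:nrow(S)) m <- pmax(m, S[k, ])
      out[t, ] <- m
    } else {                      # softmax-weighted
      m <- S[1, ]
      for (k in 2:nrow(S)) m <- pmax(m, S[k, ])
      E <- exp(beta * sweep(S, 2, m, "-"))
      out[t, ] <- colSums(S * E) / colSums(E)
    }
  }
  out
}

# Core Euler integrator, vectorized across trials.
#
# norms: L x n_trials matrix (per-trial stimulus norms). Stimulus drive is
# `norms` during [onset, offset) and 0 elsewhere. When `noise` is FALSE the
# run is fully deterministic. Per-step input noise draws have sd
# sigma_step = sigma0 / sqrt(dt): sigma0 is the input-referred noise sd at
# 1 ms resolution, so the effective noise level is ~dt-invariant.
#
# record: "none", "out" (output-layer rates, decimated by record_every), or
# "all" (every unit).
sim_core <- function(net, norms, duration, dt,
                     onset = 0, offset = duration,
                     noise = TRUE, record = "none", record_every = 1L,
                     tol = NULL, check_every = 100L, max_steps = NULL) {
  cfg <- net$config
  L <- net$n_channels
  U <- net$n_inhibitory
  has_amp <- cfg$amplifiers
  n_trials <- ncol(norms)
  tau <- cfg$tau
  a <- dt / tau
  f <- function(u) rate_nonlinearity(u, cfg$threshold, cfg$slope, cfg$r_max)
  rule <- cfg$combination_rule
  beta <- cfg$combination_beta

  Wabs_out_inh <- -net$W_out_inh
  Wabs_amp_inh <- -net$W_amp_inh
  Wabs_inh_inh <- -net$W_inh_inh
  w_in_diag <- diag(net$W_out_in)
  w_amp_out_diag <- diag(net$W_amp_out)   # output -> amplifier
  w_out_amp_diag <- diag(net$W_out_amp)   # amplifier -> output
  M_inh_in <- net$W_inh_in
  any_inh_out <- any(Wabs_out_inh > 0)
  any_inh_amp <- any(Wabs_amp_inh > 0)
  any_inh_inh <- any(Wabs_inh_inh > 0)

  r_in <- matrix(0, L, n_trials)
  r_v <- matrix(0, U, n_trials)
  r_a <- matrix(0, L, n_trials)
  r_o <- matrix(0, L, n_trials)

  n_steps <- if (is.null(max_steps)) ceiling(duration / dt) else max_steps
  sigma_step <- cfg$sigma0 / sqrt(dt)
  sqrt_mean <- identical(cfg$noise_scaling, "sqrt-mean")

  rec <- NULL
  rec_idx <- NULL
  if (record != "none") {
    rec_idx <- seq(1L, n_steps, by = record_every)
    n_units <- if (record == "out") L else L + U + L + L
    rec <- array(NA_real_, dim = c(length(rec_idx), n_units, n_trials))
    rk <- 1L
  }

  noise_draw <- function(u) {
    if (!noise || cfg$sigma0 == 0) return(0)
    sd <- if (sqrt_mean) sigma_step * sqrt(pmax(u, 0) / 10) else sigma_step
    matrix(stats::rnorm(length(u)), nrow(u), ncol(u)) * sd
  }

  converged <- rep(FALSE, n_trials)
  step <- 0L
  while (step < n_steps) {
    step <- step + 1L
    t_now <- step * dt
    stim_on <- (t_now > onset) && (t_now <= offset)
    drive <- if (stim_on) norms else matrix(0, L, n_trials)

    u_in <- drive + noise_draw(drive)
    u_v <- M_inh_in %*% r_in
    if (any_inh_inh) u_v <- u_v - combine_inhibition(Wabs_inh_inh, r_v, rule, beta)
    u_v <- u_v + noise_draw(u_v)
    u_o <- w_in_diag * r_in
    if (has_amp) u_o <- u_o + w_out_amp_diag * r_a
    if (any_inh_out) u_o <- u_o - combine_inhibition(Wabs_out_inh, r_v, rule, beta)
    u_o <- u_o + noise_draw(u_o)

    r_in_new <- r_in + a * (-r_in + pmin(pmax(u_in, 0), cfg$r_max))
    r_v_new <- r_v + a * (-r_v + f(u_v))
    r_o_new <- r_o + a * (-r_o + f(u_o))
    if (has_amp) {
      u_a <- w_amp_out_diag * r_o
      if (any_inh_amp) u_a <- u_a - combine_inhibition(Wabs_amp_inh, r_v, rule, beta)
      u_a <- u_a + noise_draw(u_a)
      r_a_new <- r_a + a * (-r_a + f(u_a))
    } else {
      r_a_new <- r_a
    }

    if (!is.null(tol) && step %% check_every == 0L) {
      d <- max(abs(r_in_new - r_in), abs(r_v_new - r_v),
               abs(r_a_new - r_a), abs(r_o_new - r_o)) / dt
      if (d < tol) {
        r_in <- r_in_new; r_v <- r_v_new; r_a <- r_a_new; r_o <- r_o_new
        converged[] <- TRUE
        break
      }
    }

    r_in <- r_in_new; r_v <- r_v_new; r_a <- r_a_new; r_o <- r_o_new

    if (any(!is.finite(r_o)) || any(!is.finite(r_v))) {
      stop("simulation diverged (non-finite rates) at t = ",
           format(t_now), " ms")
    }

    if (!is.null(rec) && rk <= length(rec_idx) && step == rec_idx[rk]) {
      if (record == "out") {
        rec[rk, , ] <- r_o
      } else {
        rec[rk, , ] <- rbind(r_in, r_v, r_a, r_o)
      }
      rk <- rk + 1L
    }
  }

  list(r_in = r_in, r_v = r_v, r_a = r_a, r_out = r_o,
       trace = rec, trace_steps = rec_idx, dt = dt,
       converged = converged, steps_run = step)
}

#' Simulate a network under a stimulus timeline
#'
#' Evolves every unit's rate through time under the leaky rate equation with
#' the network's connectivity, the configured multi-source inhibition
#' combination rule, and seeded Gaussian input noise. Identical
#' `(net, stim, seed)` give identical traces.
#'
#' @param net a [build_network()] result.
#' @param stim a [stimulus_timeline()]; `length(stim$norms)` must equal the
#'   number of channels.
#' @param duration total simulated time in ms (must cover the stimulus
#'   offset).
#' @param dt Euler step in ms (default 0.1).
#' @param seed integer RNG seed for the noise draws.
#' @param record_every record every k-th step (thins the stored trace; the
#'   integration step is unaffected).
#' @return an object of class `wta_trace`: list with `time` (ms), `rates`
#'   (time x units matrix, spikes/s), `labels` (unit ids; outputs are
#'   `out1..outL`), `n_channels`, `dt`, `seed`, `config_hash`, `stim`.
#' @export
simulate_network <- function(net, stim, duration = 400, dt = 0.1,
                             seed = 1L, record_every = 1L) {
  stopifnot(inherits(net, "wta_network"), inherits(stim, "wta_stimulus"))
  if (length(stim$norms) != net$n_channels) {
    stop("stimulus has ", length(stim$norms), " norms but the network has ",
         net$n_channels, " channels")
  }
  if (dt <= 0) stop("dt must be > 0")
  if (duration < stim$offset) {
    stop("duration must cover the stimulus offset (", stim$offset, " ms)")
  }
  res <- with_seed(seed, sim_core(
    net, matrix(stim$norms, ncol = 1), duration, dt,
    onset = stim$onset, offset = stim$offset,
    noise = TRUE, record = "all", record_every = record_every))
  L <- net$n_channels
  U <- net$n_inhibitory
  labels <- c(paste0("in", seq_len(L)), paste0("inh", seq_len(U)),
              paste0("amp", seq_len(L)), paste0("out", seq_len(L)))
  structure(
    list(time = res$trace_steps * dt,
         rates = res$trace[, , 1, drop = TRUE],
         labels = labels,
         n_channels = L,
         dt = dt,
         seed = seed,
         config_hash = config_hash(net$config),
         stim = stim),
    class = "wta_trace"
  )
}

#' @export
print.wta_trace <- function(x, ...) {
  cat("Simulation trace: ", length(x$time), " samples x ", length(x$labels),
      " units (dt = ", x$dt, " ms, seed = ", x$seed, ", config ",
      x$config_hash, ")\n", sep = "")
  invisible(x)
}

#' Output-layer rates of a trace
#'
#' @param trace a `wta_trace`.
#' @return time x channels matrix of output rates.
#' @export
output_rates <- function(trace) {
  stopifnot(inherits(trace, "wta_trace"))
  idx <- grep("^out", trace$labels)
  trace$rates[, idx, drop = FALSE]
}

#' Write / read a trace as delimited text
#'
#' Long format: one row per (time, unit): columns `time`, `unit`, `rate`.
#' Round-trips losslessly through [read_trace_table()] up to numeric
#' formatting at full precision.
#'
#' @param trace a `wta_trace`.
#' @param path file path.
#' @return `write_trace_table` returns `path` invisibly; `read_trace_table`
#'   returns a data frame.
#' @export
write_trace_table <- function(trace, path) {
  stopifnot(inherits(trace, "wta_trace"))
  df <- data.frame(
    time = rep(trace$time, times = length(trace$labels)),
    unit = rep(trace$labels, each = length(trace$time)),
    rate = as.vector(trace$rates)
  )
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_table
#' @export
read_trace_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Noise-free steady-state output rates
#'
#' Simulates with noise disabled under a constant stimulus until the largest
#' rate derivative falls below `tol` (spikes/s per ms) or a step cap is
#' reached; non-convergence (e.g. oscillation) is flagged explicitly rather
#' than silently returning a spurious value.
#'
#' @param net a `wta_network`.
#' @param norms numeric vector of per-channel norms, or a channels x cases
#'   matrix to solve many norm vectors in one vectorized run.
#' @param seed unused (the run is noise-free); kept for interface symmetry.
#' @param tol convergence tolerance on `max |dr/dt|` (spikes/s per ms, default 1e-3).
#' @param dt Euler step (ms).
#' @param max_time step cap expressed as simulated time (ms).
#' @return an object of class `wta_steady`: list with `output` (vector or
#'   channels x cases matrix of output rates), `converged` (logical), and
#'   `winner` (argmax channel per case; `NA` on an exact tie).
#' @export
steady_state <- function(net, norms, seed = NULL, tol = 1e-3, dt = 0.1,
                         max_time = 2000) {
  stopifnot(inherits(net, "wta_network"))
  if (tol <= 0) stop("tol must be > 0")
  vec_in <- is.null(dim(norms))
  norms_m <- if (vec_in) matrix(as.numeric(norms), ncol = 1) else as.matrix(norms)
  if (nrow(norms_m) != net$n_channels) {
    stop("norms must have one entry per channel")
  }
  res <- sim_core(net, norms_m, duration = max_time, dt = dt,
                  noise = FALSE, record = "none",
                  tol = tol, check_every = 200L)
  out <- res$r_out
  winner <- apply(out, 2, function(r) {
    w <- which(r == max(r))
    if (length(w) == 1L) w else NA_integer_
  })
  if (!all(res$converged)) {
    warning("steady_state did not converge within ", max_time,
            " ms (tol = ", tol, "); returning partial result")
  }
  structure(
    list(output = if (vec_in) drop(out) else out,
         converged = all(res$converged),
         winner = winner),
    class = "wta_steady"
  )
}

#' @export
print.wta_steady <- function(x, ...) {
  cat("Steady state (", if (x$converged) "converged" else "NOT converged",
      ")\n", sep = "")
  print(x$output)
  invisible(x)
}

#' First-to-threshold choice readout of a trace
#'
#' The winning option is the one whose output rate first reaches the
#' functional threshold. Ties at the same time step are broken by the larger
#' rate at that step, then by the lower channel index; the tie-break used is
#' recorded in the event.
#'
#' @param trace a `wta_trace` (or a time x channels matrix of output rates
#'   with an accompanying `time` attribute as produced internally).
#' @param threshold functional output threshold (spikes/s, > 0).
#' @return an object of class `wta_choice`: list with `winner` (channel id or
#'   `NA` if no channel crosses), `crossing_time` (ms or `NA`), `margin`
#'   (winner output minus best loser output at the crossing step),
#'   `n_crossers` (channels whose output ever exceeds threshold), and
#'   `tie_break` (`"none"`, `"rate"`, or `"index"`).
#' @export
first_threshold_crossing <- function(trace, threshold) {
  if (threshold <= 0) stop("threshold must be > 0")
  if (inherits(trace, "wta_trace")) {
    out <- output_rates(trace)
    tm <- trace$time
  } else {
    out <- trace
    tm <- attr(trace, "time")
  }
  L <- ncol(out)
  first_idx <- rep(NA_integer_, L)
  for (ch in seq_len(L)) {
    hit <- which(out[, ch] >= threshold)
    if (length(hit)) first_idx[ch] <- hit[1]
  }
  n_crossers <- sum(!is.na(first_idx))
  if (n_crossers == 0L) {
    return(structure(list(winner = NA_integer_, crossing_time = NA_real_,
                          margin = NA_real_, n_crossers = 0L,
                          tie_break = "none"),
                     class = "wta_choice"))
  }
  t_min <- min(first_idx, na.rm = TRUE)
  cand <- which(!is.na(first_idx) & first_idx == t_min)
  tie_break <- "none"
  if (length(cand) > 1L) {
    rates_at <- out[t_min, cand]
    best <- which(rates_at == max(rates_at))
    if (length(best) == 1L) {
      tie_break <- "rate"
      cand <- cand[best]
    } else {
      tie_break <- "index"
      cand <- cand[best[1]]
    }
  }
  winner <- cand
  losers <- setdiff(seq_len(L), winner)
  margin <- if (length(losers)) {
    out[t_min, winner] - max(out[t_min, losers])
  } else {
    out[t_min, winner]
  }
  structure(
    list(winner = winner, crossing_time = tm[t_min], margin = margin,
         n_crossers = n_crossers, tie_break = tie_break),
    class = "wta_choice"
  )
}

#' @export
print.wta_choice <- function(x, ...) {
  if (is.na(x$winner)) {
    cat("Choice event: no channel crossed threshold\n")
  } else {
    cat("Choice event: winner channel ", x$winner, " at ",
        format(x$crossing_time), " ms (margin ", format(x$margin),
        " spikes/s, ", x$n_crossers, " crosser(s))\n", sep = "")
  }
  invisible(x)
}
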