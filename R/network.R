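## Construction, validation and perturbation of the canonical four-layer
## selection network: an input layer (one linear relay per channel), an
## inhibitory layer (one unit per channel, or the units of a combinatorial
## multilobe code), an optional bank of point-to-point recurrent amplifiers,
## and an output layer. Four motifs are independently toggleable:
##   * feedforward_inhibition -- input -> inhibitory -> output/amplifier,
##     global across channels (the comparison motif);
##   * donut                  -- the inhibitory drive of a channel projects to
##     every channel except its own (zero self-inhibition diagonal);
##   * feedback_inhibition    -- reciprocal inhibition among inhibitory units
##     of distinct channels (flexible selection boundary);
##   * amplifiers             -- per-channel recurrent excitatory loop with
##     the output unit, also a recipient of the competitive inhibition
##     (unitary choice generation).

#' Configuration of the canonical selection network
#'
#' All gains are non-negative; inhibitory weights are stored signed
#' (negative) in the built network. Defaults were calibrated once so that
#' competitive inhibition is comparable in magnitude to the stimulus drive
#' over the working norm range (roughly 0--20 a.u.), the regime in which the
#' motif-level arguments apply; see the package vignette for the rationale
#' behind each value.
#'
#' @param n_channels number of channels (options) `L >= 1`.
#' @param feedforward_inhibition,donut,feedback_inhibition,amplifiers motif
#'   toggles (all `TRUE` by default: the full canonical circuit).
#' @param w_in input -> output excitatory gain.
#' @param w_ei input -> inhibitory excitatory gain.
#' @param w_ie inhibitory -> output weight magnitude.
#' @param w_ii inhibitory -> inhibitory (feedback) weight magnitude.
#' @param w_amp output <-> amplifier recurrent excitatory gain.
#' @param w_ia inhibitory -> amplifier weight magnitude.
#' @param inhibition_gain_multiplier scalar multiplier on all
#'   inhibitory -> (output, amplifier) weights: the "high gain" knob used for
#'   unitary-choice generation.
#' @param threshold,slope,r_max parameters of the saturating output
#'   nonlinearity (see [rate_nonlinearity()]); `r_max > 0` (spikes/s).
#' @param sigma0 baseline standard deviation of the Gaussian input noise
#'   injected into every unit's input, expressed at 1 ms resolution (a.u. of
#'   input drive); per-step draws are scaled by `1/sqrt(dt)` so the effective
#'   noise level does not depend on the integration step.
#' @param noise_scaling `"constant"` (sd = sigma0) or `"sqrt-mean"`
#'   (sd = sigma0 * sqrt(mean drive), roughly rate-scaled variability).
#' @param combination_rule how inhibition from multiple source units is
#'   combined at a target: `"softmax-weighted"` (default; a smooth
#'   max-dominated average), `"linear"` (sum), or `"max"`.
#' @param combination_beta sharpness of the softmax-weighted rule.
#' @param cosmi_code optional [cosmi_code()] giving multilobe receptive
#'   fields for the inhibitory units; `NULL` means one inhibitory unit per
#'   channel (the copy-and-paste layout).
#' @param self_inhibition_fraction within-channel inhibition as a fraction of
#'   the mean off-channel inhibitory weight; must be 0 while `donut` is
#'   enabled (self-inhibition is introduced only via the
#'   [add_self_inhibition()] perturbation).
#' @param tau membrane time constant (ms) of the leaky rate equation.
#' @return an object of class `wta_config` (a validated named list).
#' @export
network_config <- function(n_channels,
                           feedforward_inhibition = TRUE,
                           donut = TRUE,
                           feedback_inhibition = TRUE,
                           amplifiers = TRUE,
                           w_in = 1,
                           w_ei = 3,
                           w_ie = 0.2,
                           w_ii = 0.5,
                           w_amp = 0.4,
                           w_ia = 0.45,
                           inhibition_gain_multiplier = 1,
                           threshold = 15,
                           slope = 3,
                           r_max = 100,
                           sigma0 = 0.5,
                           noise_scaling = c("constant", "sqrt-mean"),
                           combination_rule = c("softmax-weighted", "linear",
                                                "max"),
                           combination_beta = 0.5,
                           cosmi_code = NULL,
                           self_inhibition_fraction = 0,
                           tau = 10) {
  noise_scaling <- match.arg(noise_scaling)
  combination_rule <- match.arg(combination_rule)
  cfg <- list(
    n_channels = as.integer(n_channels),
    feedforward_inhibition = isTRUE(feedforward_inhibition),
    donut = isTRUE(donut),
    feedback_inhibition = isTRUE(feedback_inhibition),
    amplifiers = isTRUE(amplifiers),
    w_in = w_in, w_ei = w_ei, w_ie = w_ie, w_ii = w_ii,
    w_amp = w_amp, w_ia = w_ia,
    inhibition_gain_multiplier = inhibition_gain_multiplier,
    threshold = threshold, slope = slope, r_max = r_max,
    sigma0 = sigma0, noise_scaling = noise_scaling,
    combination_rule = combination_rule,
    combination_beta = combination_beta,
    cosmi_code = cosmi_code,
    self_inhibition_fraction = self_inhibition_fraction,
    tau = tau,
    schema_version = 1L
  )
  validate_config(cfg)
  structure(cfg, class = "wta_config")
}

validate_config <- function(cfg) {
  if (cfg$n_channels < 1L) stop("n_channels must be >= 1")
  gains <- c(cfg$w_in, cfg$w_ei, cfg$w_ie, cfg$w_ii, cfg$w_amp, cfg$w_ia,
             cfg$inhibition_gain_multiplier)
  if (any(!is.finite(gains)) || any(gains < 0)) {
    stop("all gains must be finite and non-negative")
  }
  if (!is.finite(cfg$r_max) || cfg$r_max <= 0) stop("r_max must be > 0")
  if (cfg$slope <= 0) stop("slope must be > 0")
  if (cfg$sigma0 < 0) stop("sigma0 must be >= 0")
  if (cfg$tau <= 0) stop("tau must be > 0")
  if (cfg$self_inhibition_fraction < 0 || cfg$self_inhibition_fraction > 1) {
    stop("self_inhibition_fraction must lie in [0, 1]")
  }
  if (cfg$donut && cfg$self_inhibition_fraction != 0) {
    stop("self_inhibition_fraction must be 0 while donut is enabled; ",
         "use add_self_inhibition() to perturb a built network")
  }
  if (!is.null(cfg$cosmi_code) && !inherits(cfg$cosmi_code, "cosmi_code")) {
    stop("cosmi_code must be NULL or a cosmi_code object")
  }
  if (!is.null(cfg$cosmi_code) &&
      cfg$cosmi_code$n_channels != cfg$n_channels) {
    stop("cosmi_code is defined over ", cfg$cosmi_code$n_channels,
         " channels but the network has ", cfg$n_channels)
  }
  invisible(cfg)
}

#' Build the canonical selection network from a configuration
#'
#' Returns a network whose signed connection matrices realize exactly the
#' enabled motifs. With all motifs disabled the channels are fully
#' independent feedforward chains (input -> output only). When a
#' `cosmi_code` is supplied, the inhibitory units are instantiated from its
#' receptive fields and (under the donut rule) project to exactly the
#' complement of their RF channels; the code must satisfy pairwise coverage.
#'
#' @param config a [network_config()].
#' @return an object of class `wta_network`: list with elements `config`,
#'   `n_channels`, `n_inhibitory`, `rf` (inhibitory membership matrix, units
#'   x channels), weight matrices (all target x source, inhibitory entries
#'   `<= 0`): `W_out_in`, `W_inh_in`, `W_out_inh`, `W_amp_inh`, `W_inh_inh`,
#'   `W_out_amp`, `W_amp_out`, unit `labels`, and `provenance` (character
#'   record of applied perturbations).
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "wta_config"))
  validate_config(config)
  L <- config$n_channels
  code <- config$cosmi_code
  if (is.null(code)) {
    member <- diag(TRUE, L)             # one inhibitory unit per channel
  } else {
    cov <- coverage_ok(code)
    if (!cov$ok) {
      p <- cov$uncovered[1, ]
      stop("cosmi_code fails pairwise coverage: no unit driven by channel ",
           p[1], " inhibits channel ", p[2])
    }
    member <- rf_membership(code)
  }
  U <- nrow(member)
  g <- config$inhibition_gain_multiplier

  W_out_in <- diag(config$w_in, L)

  if (config$feedforward_inhibition) {
    W_inh_in <- config$w_ei * (member * 1)
    proj <- t(member * 1)                # channels x units: 1 where unit's RF
    if (config$donut) {
      proj <- 1 - proj                   # project to complement of RF
    } else {
      proj <- matrix(1, L, U)            # global, self included
    }
    W_out_inh <- -config$w_ie * g * proj
    W_amp_inh <- -config$w_ia * g * proj
  } else {
    W_inh_in <- matrix(0, U, L)
    W_out_inh <- matrix(0, L, U)
    W_amp_inh <- matrix(0, L, U)
  }

  if (config$feedback_inhibition && config$feedforward_inhibition && U > 1) {
    # reciprocal inhibition of inhibition between units of distinct channels:
    # unit k inhibits unit l iff their receptive fields are disjoint (for the
    # one-unit-per-channel layout this is simply k != l).
    overlap <- (member * 1) %*% t(member * 1)
    fb <- (overlap == 0) * 1
    W_inh_inh <- -config$w_ii * fb
  } else {
    W_inh_inh <- matrix(0, U, U)
  }

  if (config$amplifiers) {
    W_out_amp <- diag(config$w_amp, L)   # strictly point-to-point
    W_amp_out <- diag(config$w_amp, L)
  } else {
    W_out_amp <- matrix(0, L, L)
    W_amp_out <- matrix(0, L, L)
  }

  net <- structure(
    list(
      config = config,
      n_channels = L,
      n_inhibitory = U,
      rf = member,
      W_out_in = W_out_in,
      W_inh_in = W_inh_in,
      W_out_inh = W_out_inh,
      W_amp_inh = W_amp_inh,
      W_inh_inh = W_inh_inh,
      W_out_amp = W_out_amp,
      W_amp_out = W_amp_out,
      provenance = character(0)
    ),
    class = "wta_network"
  )
  net
}

#' @export
print.wta_network <- function(x, ...) {
  cfg <- x$config
  motifs <- c("feedforward_inhibition", "donut", "feedback_inhibition",
              "amplifiers")
  on <- motifs[vapply(motifs, function(m) isTRUE(cfg[[m]]), logical(1))]
  cat("Canonical selection network: ", x$n_channels, " channels, ",
      x$n_inhibitory, " inhibitory units\n", sep = "")
  cat("  motifs: ", if (length(on)) paste(on, collapse = ", ") else "none",
      "\n", sep = "")
  if (length(x$provenance)) {
    cat("  perturbations:\n")
    for (p in x$provenance) cat("    - ", p, "\n", sep = "")
  }
  invisible(x)
}

#' Validate the structural invariants of a built network
#'
#' Checks (i) Dale-like sign consistency (inhibitory outgoing weights
#' `<= 0`, all others `>= 0`), (ii) the donut zero-diagonal (no within-channel
#' inhibition when the donut motif is enabled), (iii) the feedback invariant
#' (inhibitory-inhibitory weights nonzero between distinct channels iff
#' feedback is enabled), and (iv) strict point-to-point amplifier coupling.
#' Networks fresh from [build_network()] always pass; perturbed or
#' hand-edited networks may legitimately fail (e.g. after
#' [add_self_inhibition()] the donut check reports a violation by design).
#'
#' @param net a `wta_network`.
#' @return a data frame of class `wta_validation` with columns `check`,
#'   `pass`, `detail`.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "wta_network"))
  cfg <- net$config
  checks <- list()
  add <- function(check, pass, detail) {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, pass = pass, detail = detail, stringsAsFactors = FALSE)
  }

  bad_sign <- function(M, cmp) which(cmp(M), arr.ind = TRUE)
  pos_in_inh <- rbind(bad_sign(net$W_out_inh, function(m) m > 0),
                      bad_sign(net$W_amp_inh, function(m) m > 0),
                      bad_sign(net$W_inh_inh, function(m) m > 0))
  neg_in_exc <- rbind(bad_sign(net$W_out_in, function(m) m < 0),
                      bad_sign(net$W_inh_in, function(m) m < 0),
                      bad_sign(net$W_out_amp, function(m) m < 0),
                      bad_sign(net$W_amp_out, function(m) m < 0))
  n_bad <- nrow(pos_in_inh) + nrow(neg_in_exc)
  add("sign_consistency", n_bad == 0L,
      if (n_bad == 0L) "all inhibitory weights <= 0, excitatory >= 0" else {
        if (nrow(pos_in_inh) > 0) {
          sprintf("positive inhibitory weight at [target %d, source %d]",
                  pos_in_inh[1, 1], pos_in_inh[1, 2])
        } else {
          sprintf("negative excitatory weight at [target %d, source %d]",
                  neg_in_exc[1, 1], neg_in_exc[1, 2])
        }
      })

  if (cfg$donut && cfg$feedforward_inhibition) {
    within <- within_channel_weights(net)
    viol <- which(abs(within$out) > 0 | abs(within$amp) > 0)
    add("donut_zero_diagonal", length(viol) == 0L,
        if (length(viol) == 0L) {
          "within-channel effective inhibitory weight is 0 for every channel"
        } else {
          sprintf("within-channel inhibition present on channel(s) %s",
                  paste(viol, collapse = ", "))
        })
  } else {
    add("donut_zero_diagonal", TRUE, "not applicable (donut disabled)")
  }

  fb <- net$W_inh_inh
  overlap <- (net$rf * 1) %*% t(net$rf * 1)
  cross <- overlap == 0
  if (cfg$feedback_inhibition && cfg$feedforward_inhibition &&
      net$n_inhibitory > 1) {
    ok <- all(abs(fb[cross]) > 0) && all(fb[!cross] == 0)
    add("feedback_weights", ok,
        if (ok) "reciprocal inhibition present between all distinct channels"
        else "feedback block does not match the enabled feedback motif")
  } else {
    ok <- all(fb == 0)
    add("feedback_weights", ok,
        if (ok) "feedback disabled and inhibitory-inhibitory block is zero"
        else "nonzero inhibitory-inhibitory weights with feedback disabled")
  }

  off_amp <- net$W_out_amp - diag(diag(net$W_out_amp))
  off_out <- net$W_amp_out - diag(diag(net$W_amp_out))
  ok <- all(off_amp == 0) && all(off_out == 0)
  add("amplifier_point_to_point", ok,
      if (ok) "amplifier coupling strictly within-channel"
      else "cross-channel amplifier coupling detected")

  out <- do.call(rbind, checks)
  class(out) <- c("wta_validation", class(out))
  out
}

# Effective within-channel inhibitory weight received by each channel's
# output and amplifier units (summed over inhibitory units whose RF contains
# the channel).
within_channel_weights <- function(net) {
  L <- net$n_channels
  out <- numeric(L)
  amp <- numeric(L)
  for (ch in seq_len(L)) {
    own <- which(net$rf[, ch])
    out[ch] <- sum(net$W_out_inh[ch, own])
    amp[ch] <- sum(net$W_amp_inh[ch, own])
  }
  list(out = out, amp = amp)
}

#' Introduce self-inhibition (disrupt the donut motif)
#'
#' Each channel's output and amplifier units additionally receive inhibition
#' from their own channel's inhibitory drive at `fraction` times the mean
#' off-channel inhibitory weight magnitude. `fraction = 1` fills the donut
#' hole completely; `fraction = 0` is the identity.
#'
#' @param net a `wta_network` built with the donut motif enabled.
#' @param fraction real in `[0, 1]`.
#' @return a new perturbed `wta_network` (provenance updated).
#' @export
add_self_inhibition <- function(net, fraction) {
  stopifnot(inherits(net, "wta_network"))
  if (!net$config$donut || !net$config$feedforward_inhibition) {
    stop("add_self_inhibition requires a network with the donut motif enabled")
  }
  if (!is.finite(fraction) || fraction < 0 || fraction > 1) {
    stop("fraction must lie in [0, 1]")
  }
  if (fraction == 0) return(net)
  fill_in <- function(M) {
    off <- M[M < 0]
    mean_off <- if (length(off)) mean(abs(off)) else 0
    for (ch in seq_len(net$n_channels)) {
      own <- which(net$rf[, ch])
      M[ch, own] <- M[ch, own] - fraction * mean_off
    }
    M
  }
  net$W_out_inh <- fill_in(net$W_out_inh)
  net$W_amp_inh <- fill_in(net$W_amp_inh)
  cfg <- unclass(net$config)
  cfg$self_inhibition_fraction <- fraction
  net$config <- structure(cfg, class = "wta_config")
  net$provenance <- c(net$provenance,
                      sprintf("add_self_inhibition(fraction=%g)", fraction))
  net
}

#' Silence feedback inhibition between options
#'
#' Sets all inhibitory-to-inhibitory weights to zero while leaving the
#' inhibitory units (and their feedforward projections) intact -- the
#' recipient-side manipulation predicted to abolish the shifting of the
#' selection boundary while preserving the competitor-driven response
#' reduction. Idempotent.
#'
#' @param net a `wta_network`.
#' @return a new perturbed `wta_network`.
#' @export
silence_feedback <- function(net) {
  stopifnot(inherits(net, "wta_network"))
  if (!net$config$feedback_inhibition) {
    stop("silence_feedback requires a network with feedback inhibition enabled")
  }
  net$W_inh_inh[] <- 0
  net$provenance <- c(net$provenance, "silence_feedback()")
  net
}

#' Scale the recurrent amplifier gain of one channel
#'
#' Multiplies the amplifier <-> output recurrent weights of `channel` by
#' `multiplier`. `multiplier = 0` makes that channel behave as if its
#' amplifier were disabled; values > 1 emulate the experimental enhancement
#' of the amplifier output of (typically) the weaker option.
#'
#' @param net a `wta_network` with amplifiers enabled.
#' @param channel channel id in `1:n_channels`.
#' @param multiplier non-negative scalar.
#' @return a new perturbed `wta_network`.
#' @export
set_amplifier_gain <- function(net, channel, multiplier) {
  stopifnot(inherits(net, "wta_network"))
  if (!net$config$amplifiers) {
    stop("set_amplifier_gain requires a network with amplifiers enabled")
  }
  channel <- as.integer(channel)
  if (length(channel) != 1L || is.na(channel) ||
      channel < 1L || channel > net$n_channels) {
    stop("invalid channel id: ", channel)
  }
  if (!is.finite(multiplier) || multiplier < 0) {
    stop("multiplier must be a non-negative real")
  }
  net$W_out_amp[channel, channel] <- net$W_out_amp[channel, channel] * multiplier
  net$W_amp_out[channel, channel] <- net$W_amp_out[channel, channel] * multiplier
  net$provenance <- c(net$provenance,
                      sprintf("set_amplifier_gain(channel=%d, multiplier=%g)",
                              channel, multiplier))
  net
}

#' Export a network as an edge list
#'
#' One row per nonzero connection: source id, target id, weight, sign.
#' Suitable for inspection with standard graph tools.
#'
#' @param net a `wta_network`.
#' @param path optional file path; when given, the table is written as TSV.
#' @return a data frame with columns `source`, `target`, `weight`, `sign`.
#' @export
export_edges <- function(net, path = NULL) {
  stopifnot(inherits(net, "wta_network"))
  L <- net$n_channels
  U <- net$n_inhibitory
  ids <- list(
    input = paste0("in", seq_len(L)),
    inh = paste0("inh", seq_len(U)),
    amp = paste0("amp", seq_len(L)),
    out = paste0("out", seq_len(L))
  )
  rows <- list()
  emit <- function(M, src_ids, tgt_ids) {
    nz <- which(M != 0, arr.ind = TRUE)
    if (nrow(nz) == 0) return()
    w <- M[nz]
    rows[[length(rows) + 1L]] <<- data.frame(
      source = src_ids[nz[, 2]], target = tgt_ids[nz[, 1]],
      weight = w, sign = ifelse(w < 0, "inhibitory", "excitatory"),
      stringsAsFactors = FALSE)
  }
  emit(net$W_out_in, ids$input, ids$out)
  emit(net$W_inh_in, ids$input, ids$inh)
  emit(net$W_out_inh, ids$inh, ids$out)
  emit(net$W_amp_inh, ids$inh, ids$amp)
  emit(net$W_inh_inh, ids$inh, ids$inh)
  emit(net$W_out_amp, ids$amp, ids$out)
  emit(net$W_amp_out, ids$out, ids$amp)
  edges <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(source = character(0), target = character(0),
               weight = numeric(0), sign = character(0))
  }
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  if (!is.null(path)) {
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  edges
}

#' Read / write a network configuration as structured text (JSON)
#'
#' The on-disk schema mirrors the [network_config()] field names exactly and
#' carries an explicit `schema_version`; omitted fields take the documented
#' defaults, so a round trip through disk is lossless.
#'
#' @param config a `wta_config`.
#' @param path file path.
#' @return `read_network_config` returns a `wta_config`;
#'   `write_network_config` returns `path` invisibly.
#' @export
write_network_config <- function(config, path) {
  stopifnot(inherits(config, "wta_config"))
  x <- unclass(config)
  if (!is.null(x$cosmi_code)) {
    x$cosmi_code <- list(n_channels = x$cosmi_code$n_channels,
                         rfs = x$cosmi_code$rfs)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_network_config
#' @export
read_network_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$schema_version <- NULL
  code <- NULL
  if (!is.null(x$cosmi_code)) {
    rfs <- x$cosmi_code$rfs
    if (is.matrix(rfs)) rfs <- lapply(seq_len(nrow(rfs)), function(i) rfs[i, ])
    if (!is.list(rfs)) rfs <- as.list(rfs)
    code <- cosmi_code(rfs, x$cosmi_code$n_channels)
  }
  x$cosmi_code <- NULL
  do.call(network_config, c(x, list(cosmi_code = code)))
}

#' Provenance hash of a network configuration
#'
#' Deterministic short hash of the canonical serialization; embedded in every
#' assay output for provenance.
#'
#' @param config a `wta_config`.
#' @return 8-character hex string.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "wta_config"))
  x <- unclass(config)
  if (!is.null(x$cosmi_code)) {
    x$cosmi_code <- list(n_channels = x$cosmi_code$n_channels,
                         rfs = x$cosmi_code$rfs)
  }
  str_hash(canonical_json(x))
}
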