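## Synthetic stimulus/norm protocol generation, experiment configuration and
## the result-bundle writer behind the command-line interface.

#' Generate a synthetic norm protocol
#'
#' Produces the list of per-trial norm vectors used by the assays:
#' \describe{
#'   \item{`pair_sweep`}{the CRP grid: option A fixed at `params$norm_A` on
#'     channel 1, competitor swept over `params$competitor_norms` on channel
#'     2 (channels configurable via `params$probe_channel` /
#'     `params$competitor_channel`).}
#'   \item{`multi_option`}{norm vectors with `params$n_options` active
#'     options: the winner at `params$winner_norm` on channel 1 and
#'     distracters at `params$distracter_norm`; with `params$jitter > 0`,
#'     distracter norms are jittered uniformly by up to `jitter` while
#'     keeping the top-two gap at least `params$min_gap` (default 0.5).}
#'   \item{`single`}{one-option trials with the norm swept over
#'     `params$norms` on channel 1.}
#' }
#'
#' @param kind one of `"pair_sweep"`, `"multi_option"`, `"single"`.
#' @param params named list of kind-specific parameters (see above);
#'   `params$n_channels` sets the vector length (default: smallest that
#'   fits).
#' @param seed integer; all random draws are derived from it.
#' @return list of numeric norm vectors, one per trial/condition.
#' @export
make_norm_protocol <- function(kind = c("pair_sweep", "multi_option", "single"),
                               params = list(), seed = 1L) {
  kind <- match.arg(kind)
  p <- params
  if (kind == "pair_sweep") {
    norm_A <- p$norm_A %||% 8
    comp <- p$competitor_norms %||% seq(2, 14, by = 1)
    probe <- p$probe_channel %||% 1L
    compch <- p$competitor_channel %||% 2L
    L <- p$n_channels %||% max(probe, compch)
    if (is.unsorted(comp, strictly = TRUE)) {
      stop("competitor_norms must be strictly ascending")
    }
    lapply(comp, function(cv) {
      x <- numeric(L)
      x[probe] <- norm_A
      x[compch] <- cv
      x
    })
  } else if (kind == "multi_option") {
    n_opt <- p$n_options %||% 3L
    winner <- p$winner_norm %||% 10
    distract <- p$distracter_norm %||% 6
    jitter <- p$jitter %||% 0
    min_gap <- p$min_gap %||% 0.5
    L <- p$n_channels %||% n_opt
    n_cond <- p$n_conditions %||% 1L
    if (n_opt < 2L || n_opt > L) stop("need 2 <= n_options <= n_channels")
    if (winner - distract < min_gap) {
      stop("winner_norm must exceed distracter_norm by at least min_gap")
    }
    with_seed(seed, lapply(seq_len(n_cond), function(i) {
      x <- numeric(L)
      x[1] <- winner
      d <- rep(distract, n_opt - 1L)
      if (jitter > 0) {
        d <- d + stats::runif(n_opt - 1L, -jitter, jitter)
        d <- pmin(pmax(d, 0), winner - min_gap)
      }
      x[seq(2L, n_opt)] <- d
      x
    }))
  } else {
    norms <- p$norms %||% seq(2, 14, by = 2)
    L <- p$n_channels %||% 1L
    lapply(norms, function(v) {
      x <- numeric(L)
      x[1] <- v
      x
    })
  }
}

assay_registry <- c("crp", "flexibility", "multi_option", "unitary_choice")

#' Validate an experiment configuration
#'
#' An experiment configuration is a named list (or JSON file) with fields
#' `network` (arguments for [network_config()]), `assay` (one of
#' `r paste0('"', c("crp", "flexibility", "multi_option", "unitary_choice"), '"', collapse = ", ")`),
#' `params` (assay arguments), `seed` (non-negative integer) and `out_dir`.
#'
#' @param cfg named list or path to a JSON file.
#' @return the validated configuration (invisibly usable), with `network`
#'   replaced by a built `wta_config`.
#' @export
validate_experiment_config <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1L) {
    cfg <- jsonlite::read_json(cfg, simplifyVector = TRUE)
  }
  stopifnot(is.list(cfg))
  if (is.null(cfg$assay) || !cfg$assay %in% assay_registry) {
    stop("unknown assay: ", cfg$assay %||% "<missing>",
         " (registered: ", paste(assay_registry, collapse = ", "), ")")
  }
  if (is.null(cfg$seed) || cfg$seed < 0 || cfg$seed != floor(cfg$seed)) {
    stop("seed must be a non-negative integer")
  }
  if (is.null(cfg$out_dir)) stop("out_dir is required")
  net_args <- cfg$network %||% list()
  cfg$network <- do.call(network_config, net_args)
  cfg$params <- cfg$params %||% list()
  cfg
}

#' Run a configured experiment and write a result bundle
#'
#' Builds the network, runs the configured assay, and writes a tidy trial
#' table (`trials.csv`), a structured summary (`summary.json`), and the
#' resolved configuration (`config.json`) into `out_dir`. Every output
#' embeds the configuration hash, the master seed and the package version;
#' a rerun with the same configuration is byte-identical.
#'
#' @param cfg experiment configuration (list or JSON path), see
#'   [validate_experiment_config()].
#' @return invisibly, a list with the assay `result` and the output `files`.
#' @export
run_experiment <- function(cfg) {
  cfg <- validate_experiment_config(cfg)
  net <- build_network(cfg$network)
  seed <- as.integer(cfg$seed)
  p <- cfg$params
  hash <- config_hash(cfg$network)

  if (cfg$assay == "crp") {
    res <- measure_crp(net,
                       norm_A = p$norm_A %||% 8,
                       competitor_norms = p$competitor_norms %||% seq(2, 14, 1),
                       n_trials = p$n_trials %||% 20L,
                       seed = seed)
    trials <- data.frame(
      competitor_norm = rep(res$competitor_norms, res$n_trials),
      trial = rep(seq_len(res$n_trials), each = length(res$competitor_norms)),
      response = as.vector(res$trials))
    summary <- list(assay = "crp", norm_A = res$norm_A,
                    competitor_norms = res$competitor_norms,
                    mean_response = res$mean_response,
                    sd_response = res$sd_response,
                    categorization_index = tryCatch(
                      categorization_index(res), error = function(e) NULL),
                    transition_norm = tryCatch(
                      transition_norm(res), error = function(e) NULL))
  } else if (cfg$assay == "flexibility") {
    res <- flexibility_assay(net,
                             norm_A_low = p$norm_A_low %||% 8,
                             norm_A_high = p$norm_A_high %||% 11,
                             competitor_norms = p$competitor_norms %||%
                               seq(2, 16, 1),
                             n_trials = p$n_trials %||% 20L,
                             seed = seed)
    trials <- data.frame(
      norm_A = rep(c(res$crp_low$norm_A, res$crp_high$norm_A),
                   each = length(res$crp_low$competitor_norms)),
      competitor_norm = rep(res$crp_low$competitor_norms, 2),
      mean_response = c(res$crp_low$mean_response, res$crp_high$mean_response),
      sd_response = c(res$crp_low$sd_response, res$crp_high$sd_response))
    summary <- list(assay = "flexibility",
                    transition_low = res$transition_low,
                    transition_high = res$transition_high,
                    delta_A = res$delta_A, shift_ratio = res$shift_ratio)
  } else if (cfg$assay == "multi_option") {
    conditions <- p$conditions
    if (is.null(conditions)) {
      conditions <- make_norm_protocol("multi_option", p, seed)
    }
    if (is.matrix(conditions)) {
      conditions <- lapply(seq_len(nrow(conditions)),
                           function(i) conditions[i, ])
    }
    res <- multi_option_assay(net, conditions,
                              n_trials = p$n_trials %||% 20L,
                              seed = seed,
                              noise = p$noise %||% TRUE)
    trials <- as.data.frame(res)
    summary <- list(assay = "multi_option", conditions = conditions,
                    accuracy = res$accuracy,
                    winner_mean_output = res$winner_mean_output)
  } else {  # unitary_choice
    res <- unitary_choice_assay(net,
                                norms = p$norms %||% c(10, 2),
                                threshold = p$threshold %||% 50,
                                n_trials = p$n_trials %||% 100L,
                                seed = seed)
    trials <- res$trials
    summary <- list(assay = "unitary_choice", norms = p$norms %||% c(10, 2),
                    threshold = res$threshold, p_unitary = res$p_unitary,
                    accuracy = res$accuracy, rt_mean = res$rt_mean,
                    rt_sd = res$rt_sd)
  }

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  provenance <- list(config_hash = hash, seed = seed,
                     package = "wtacircuit",
                     version = as.character(utils::packageVersion("wtacircuit")))
  files <- c(
    trials = file.path(cfg$out_dir, "trials.csv"),
    summary = file.path(cfg$out_dir, "summary.json"),
    config = file.path(cfg$out_dir, "config.json")
  )
  utils::write.csv(trials, files[["trials"]], row.names = FALSE)
  jsonlite::write_json(c(summary, list(provenance = provenance)),
                       files[["summary"]], auto_unbox = TRUE, digits = NA,
                       null = "null")
  cfg_out <- list(network = unclass(cfg$network), assay = cfg$assay,
                  params = p, seed = seed, out_dir = cfg$out_dir,
                  provenance = provenance)
  if (!is.null(cfg_out$network$cosmi_code)) {
    cc <- cfg_out$network$cosmi_code
    cfg_out$network$cosmi_code <- list(n_channels = cc$n_channels,
                                       rfs = cc$rfs)
  }
  jsonlite::write_json(cfg_out, files[["config"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(list(result = res, files = files))
}
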