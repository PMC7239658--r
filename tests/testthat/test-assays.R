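test_that("CRP responses decrease with competitor norm when inhibition is on", {
  net <- default_net(2)
  crp <- fast_crp(net, 7, seq(2, 12, 1), n_trials = 15, seed = 3)
  # non-increasing within 2 x the sem of each adjacent difference
  sem <- crp$sd_response / sqrt(crp$n_trials)
  tol <- 2 * sqrt(sem[-1]^2 + sem[-length(sem)]^2)
  expect_true(all(diff(crp$mean_response) <= tol))
  # and the drop is real: far competitor suppresses the probed channel
  expect_gt(crp$mean_response[1], 5)
  expect_lt(crp$mean_response[length(crp$mean_response)], 1)
})

test_that("with all motifs off the CRP is flat (uncoupled channels)", {
  net <- default_net(2, feedforward_inhibition = FALSE, donut = FALSE,
                     feedback_inhibition = FALSE, amplifiers = FALSE,
                     sigma0 = 0)
  crp <- fast_crp(net, 7, seq(3, 11, 2), n_trials = 1, seed = 1)
  expect_equal(diff(range(crp$mean_response)), 0)
  # noise off, single trial: sd identically 0
  expect_true(all(crp$sd_response == 0 | is.na(crp$sd_response)))
  crp2 <- fast_crp(default_net(2, sigma0 = 0), 7, seq(3, 11, 2),
                   n_trials = 2, seed = 1)
  expect_true(all(crp2$sd_response == 0))
})

test_that("measure_crp validates its protocol", {
  net <- default_net(2)
  expect_error(measure_crp(net, 7, seq(8, 12), 2, 1), "span")
  expect_error(measure_crp(net, 7, c(3, 2, 9), 2, 1), "ascending")
  expect_error(measure_crp(net, 7, seq(2, 12), 2, 1, probe_channel = 9),
               "probe channel")
  expect_error(measure_crp(default_net(1), 7, seq(2, 12), 2, 1),
               "two channels")
})

test_that("categorization index is 1 for a step, ~0 for a linear profile", {
  cn <- 2:12
  sds <- rep(1, 11)
  step <- synthetic_crp(cn, ifelse(cn < 7, 30, 0), sds, norm_A = 7)
  expect_equal(categorization_index(step), 1)

  lin <- synthetic_crp(cn, seq(30, 10, length.out = 11), sds, norm_A = 7)
  # all adjacent d' equal -> between == within -> exactly 0
  expect_equal(categorization_index(lin), 0)

  # a steeper-at-boundary profile scores between the two
  sig <- synthetic_crp(cn, 30 * plogis(-(cn - 7) * 1.5), sds, norm_A = 7)
  cat_sig <- categorization_index(sig)
  expect_gt(cat_sig, 0)
  expect_lt(cat_sig, 1)

  expect_error(categorization_index(
    synthetic_crp(c(6, 7, 8, 9), c(3, 2, 1, 0), rep(1, 4), norm_A = 7)),
    "each side")
  expect_error(categorization_index(
    synthetic_crp(cn, ifelse(cn < 7, 30, 0), sds, 7, n_trials = 1L)),
    "n_trials")
})

test_that("self-inhibition makes the measured CRP less categorical", {
  net <- default_net(2)
  crp <- fast_crp(net, 7, seq(2, 12, 1), n_trials = 25, seed = 11)
  crp_si <- fast_crp(add_self_inhibition(net, 1), 7, seq(2, 12, 1),
                     n_trials = 25, seed = 11)
  expect_lt(categorization_index(crp_si), categorization_index(crp))
})

test_that("transition norm is recovered by plateau-midpoint interpolation", {
  cn <- seq(2, 12, 0.5)
  sig <- synthetic_crp(cn, 20 * plogis(-(cn - 7) * 2), rep(0.5, length(cn)),
                       norm_A = 7)
  expect_equal(transition_norm(sig), 7, tolerance = 0.05)

  flat <- synthetic_crp(cn, rep(12, length(cn)), rep(0.5, length(cn)), 7)
  expect_error(transition_norm(flat), class = "wta_no_transition")

  # full circuit: the boundary tracks the winner's norm
  crp <- fast_crp(default_net(2), 7, seq(2, 12, 1), n_trials = 15, seed = 2)
  expect_lt(abs(transition_norm(crp) - 7), 1)
})

test_that("the selection boundary shifts with feedback and freezes without", {
  net <- default_net(2)
  fx <- flexibility_assay(net, 5, 7, seq(1, 12, 1), n_trials = 10, seed = 1,
                          duration = fast$duration, onset = fast$onset,
                          offset = fast$offset)
  expect_gte(fx$shift_ratio, 0.8)
  expect_equal(fx$delta_A, 2)

  fx0 <- flexibility_assay(silence_feedback(net), 5, 7, seq(1, 12, 1),
                           n_trials = 10, seed = 1,
                           duration = fast$duration, onset = fast$onset,
                           offset = fast$offset)
  expect_lte(fx0$shift_ratio, 0.2)
  # the response reduction itself is left intact
  expect_gt(fx0$crp_low$mean_response[1], 1)
  expect_lt(min(fx0$crp_low$mean_response), 0.5)

  expect_error(flexibility_assay(net, 7, 5, seq(1, 12), 5, 1), "exceed")
})

test_that("an infinitesimal norm_A change leaves the transition in place", {
  net <- default_net(2, sigma0 = 0)
  fx <- flexibility_assay(net, 5, 5.2, seq(1, 12, 1), n_trials = 1, seed = 1,
                          duration = fast$duration, onset = fast$onset,
                          offset = fast$offset)
  # with a finite competitor grid the estimator can move the transition by
  # at most about one sample spacing for an infinitesimal norm_A change
  expect_lt(abs(fx$transition_high - fx$transition_low), 1)
})

test_that("multi-option assay is consistent with the two-option machinery", {
  net <- default_net(3, sigma0 = 0)
  res <- multi_option_assay(net, list(c(9, 4, 0)), n_trials = 1, seed = 1,
                            noise = FALSE)
  expect_equal(res$accuracy, 1)
  expect_equal(res$oracle_winner, 1L)
  ss <- steady_state(net, c(9, 4, 0))$output
  expect_equal(res$winner_mean_output, ss[1], tolerance = 0.05)
})

test_that("noise-free winner accuracy is perfect on a norm grid (N <= 4)", {
  set.seed(21)
  for (N in 2:4) {
    net <- default_net(N, sigma0 = 0)
    conds <- lapply(1:4, function(i) {
      x <- runif(N, 1, 14)
      top <- order(x, decreasing = TRUE)
      if (x[top[1]] - x[top[2]] < 0.5) x[top[1]] <- x[top[2]] + 0.6
      x
    })
    res <- multi_option_assay(net, conds, n_trials = 1, seed = 1,
                              noise = FALSE)
    expect_true(all(res$accuracy == 1), info = paste("N =", N))
  }
})

test_that("the winner's output does not grow as distracters are added", {
  net <- default_net(6, sigma0 = 0)
  conds <- lapply(1:5, function(k) {
    x <- numeric(6); x[1] <- 10; x[seq_len(k) + 1] <- 6; x
  })
  res <- multi_option_assay(net, conds, n_trials = 1, seed = 1, noise = FALSE)
  expect_equal(res$n_options, 2:6)
  expect_true(all(diff(res$winner_mean_output) <= 1e-6))
  expect_true(all(res$accuracy == 1))
})

test_that("multi-option assay rejects malformed conditions", {
  net <- default_net(3)
  expect_error(multi_option_assay(net, list(c(5, 5, 0)), 2, 1), "unique")
  expect_error(multi_option_assay(net, list(c(5, 0, 0)), 2, 1), "2 options")
  expect_error(multi_option_assay(net, list(c(5, 3)), 2, 1), "per channel")
})

test_that("the full circuit produces unitary, accurate, fast choices", {
  net <- default_net(2)
  uc <- unitary_choice_assay(net, c(10, 2), threshold = 50, n_trials = 40,
                             seed = 5, duration = fast$duration,
                             onset = fast$onset, offset = fast$offset)
  expect_gte(uc$p_unitary, 0.95)
  expect_gte(uc$accuracy, 0.95)
  expect_true(uc$rt_mean > 0 && uc$rt_mean < 200)

  # without amplification, high-gain inhibition leaves the winner subthreshold
  net_na <- default_net(2, amplifiers = FALSE, inhibition_gain_multiplier = 2)
  uc_na <- unitary_choice_assay(net_na, c(10, 2), threshold = 50,
                                n_trials = 20, seed = 5,
                                duration = fast$duration, onset = fast$onset,
                                offset = fast$offset)
  expect_lt(uc_na$p_unitary, 0.5)

  expect_error(unitary_choice_assay(net, c(10, 2), threshold = 200,
                                    n_trials = 5, seed = 1), "r_max")
})

test_that("a large amplifier boost raises the weaker option's selection probability", {
  net <- default_net(2)
  base <- unitary_choice_assay(net, c(10, 8), threshold = 50, n_trials = 30,
                               seed = 4, duration = fast$duration,
                               onset = fast$onset, offset = fast$offset)
  boosted <- unitary_choice_assay(set_amplifier_gain(net, 2, 10), c(10, 8),
                                  threshold = 50, n_trials = 30, seed = 4,
                                  duration = fast$duration,
                                  onset = fast$onset, offset = fast$offset)
  p_weak <- function(uc) mean(uc$trials$winner == 2, na.rm = TRUE)
  expect_gt(p_weak(boosted), p_weak(base))
})

test_that("reaction time shortens as the norm gap widens", {
  net <- default_net(2)
  uc_wide <- unitary_choice_assay(net, c(10, 2), 50, 60, seed = 6,
                                  duration = fast$duration,
                                  onset = fast$onset, offset = fast$offset)
  uc_narrow <- unitary_choice_assay(net, c(10, 8), 50, 60, seed = 6,
                                    duration = fast$duration,
                                    onset = fast$onset, offset = fast$offset)
  expect_lt(uc_wide$rt_mean, uc_narrow$rt_mean)
})
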