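test_that("full two-channel network realizes the donut zero-diagonal", {
  net <- default_net(2)
  expect_equal(net$n_channels, 2L)
  expect_equal(net$n_inhibitory, 2L)
  # inhibitory -> output weights nonzero only off-channel
  expect_equal(diag(net$W_out_inh), c(0, 0))
  expect_true(all(net$W_out_inh[col(net$W_out_inh) != row(net$W_out_inh)] < 0))
  expect_equal(diag(net$W_amp_inh), c(0, 0))
  # amplifier coupling strictly point-to-point
  expect_equal(net$W_amp_out, diag(0.4, 2))
  expect_equal(net$W_out_amp, diag(0.4, 2))
})

test_that("degenerate single-channel network has nothing to inhibit", {
  net <- default_net(1)
  expect_true(all(net$W_out_inh == 0))
  expect_true(all(net$W_amp_inh == 0))
  expect_true(all(net$W_inh_inh == 0))
})

test_that("with all motifs off channels are independent feedforward chains", {
  net <- default_net(3, feedforward_inhibition = FALSE, donut = FALSE,
                     feedback_inhibition = FALSE, amplifiers = FALSE)
  expect_true(all(net$W_out_inh == 0))
  expect_true(all(net$W_inh_in == 0))
  expect_true(all(net$W_inh_inh == 0))
  expect_true(all(net$W_out_amp == 0))
  expect_equal(net$W_out_in, diag(1, 3))
})

test_that("a multilobe code instantiates inhibitory units covering all pairs", {
  code <- antichain_code(6, 4)
  net <- build_network(network_config(6, cosmi_code = code))
  expect_equal(net$n_inhibitory, 4L)
  # exhaustive check over all 30 ordered pairs: some unit driven by i
  # projects (negatively) to j
  for (i in 1:6) {
    for (j in setdiff(1:6, i)) {
      expect_true(any(net$rf[, i] & net$W_out_inh[j, ] < 0),
                  info = sprintf("pair (%d, %d)", i, j))
    }
  }
  expect_true(all(validate_network(net)$pass))
})

test_that("a non-covering code is rejected with a diagnostic naming a pair", {
  cfg <- network_config(3, cosmi_code = cosmi_code(list(1L), 3))
  expect_error(build_network(cfg), "channel 2.*channel 1|coverage")
})

test_that("validate_network passes fresh builds and flags hand-edits", {
  net <- default_net(3)
  rep0 <- validate_network(net)
  expect_true(all(rep0$pass))

  # perturbation is the point: self-inhibition violates the donut invariant
  rep1 <- validate_network(add_self_inhibition(net, 0.5))
  expect_false(rep1$pass[rep1$check == "donut_zero_diagonal"])

  # hand-edited positive inhibitory weight -> sign failure naming the edge
  bad <- net
  bad$W_out_inh[1, 2] <- 0.3
  rep2 <- validate_network(bad)
  row <- rep2[rep2$check == "sign_consistency", ]
  expect_false(row$pass)
  expect_match(row$detail, "target 1, source 2")
})

test_that("add_self_inhibition fills the donut hole by the stated fraction", {
  net <- default_net(2)
  expect_identical(add_self_inhibition(net, 0), net)

  off_mean <- mean(abs(net$W_out_inh[net$W_out_inh < 0]))
  full <- add_self_inhibition(net, 1)
  expect_equal(diag(full$W_out_inh), rep(-off_mean, 2))

  half <- add_self_inhibition(net, 0.5)
  # exactly 2 new nonzero entries in the inhibitory -> output block
  expect_equal(sum(half$W_out_inh != 0) - sum(net$W_out_inh != 0), 2L)
  expect_equal(diag(half$W_out_inh), rep(-0.5 * off_mean, 2))
  # off-channel weights unchanged
  off <- row(net$W_out_inh) != col(net$W_out_inh)
  expect_equal(half$W_out_inh[off], net$W_out_inh[off])
  expect_match(half$provenance, "add_self_inhibition", all = FALSE)

  expect_error(add_self_inhibition(net, 1.5), "\\[0, 1\\]")
  no_donut <- default_net(2, donut = FALSE)
  expect_error(add_self_inhibition(no_donut, 0.5), "donut")
})

test_that("silence_feedback zeroes the inhibitory-inhibitory block, idempotently", {
  net <- default_net(3)
  expect_true(any(net$W_inh_inh < 0))
  sf <- silence_feedback(net)
  expect_true(all(sf$W_inh_inh == 0))
  expect_equal(silence_feedback(sf)$W_inh_inh, sf$W_inh_inh)
  # all other weights untouched
  expect_equal(sf$W_out_inh, net$W_out_inh)
  expect_equal(sf$W_inh_in, net$W_inh_in)
  # with a single option feedback carries no signal: steady state unchanged
  a <- steady_state(net, c(9, 0, 0))$output
  b <- steady_state(sf, c(9, 0, 0))$output
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("set_amplifier_gain rescales one channel's recurrent loop", {
  net <- default_net(2)
  expect_equal(set_amplifier_gain(net, 1, 1)$W_out_amp, net$W_out_amp)

  zero <- set_amplifier_gain(net, 2, 0)
  no_amp2 <- steady_state(zero, c(4, 6))$output
  # channel 2 with zero amplifier gain behaves as if amplifiers were absent
  ref <- steady_state(default_net(2, amplifiers = FALSE), c(4, 6))$output
  expect_equal(no_amp2[2], ref[2], tolerance = 1e-3)

  expect_error(set_amplifier_gain(net, 5, 2), "invalid channel")
  expect_error(set_amplifier_gain(default_net(2, amplifiers = FALSE), 1, 2),
               "amplifiers enabled")

  # boosting the recurrent gain of a non-suppressed channel strictly
  # increases its steady-state output (paired simulation)
  boosted <- set_amplifier_gain(net, 1, 3)
  s0 <- steady_state(net, c(7, 4))$output
  s1 <- steady_state(boosted, c(7, 4))$output
  expect_gt(s1[1], s0[1])
})

test_that("toggling one motif flag changes only its own connection block", {
  base <- default_net(3)
  no_fb <- default_net(3, feedback_inhibition = FALSE)
  expect_true(all(no_fb$W_inh_inh == 0))
  expect_equal(no_fb$W_out_inh, base$W_out_inh)
  expect_equal(no_fb$W_inh_in, base$W_inh_in)
  expect_equal(no_fb$W_out_amp, base$W_out_amp)

  no_donut <- default_net(3, donut = FALSE)
  expect_equal(no_donut$W_inh_inh, base$W_inh_inh)
  expect_equal(no_donut$W_out_amp, base$W_out_amp)
  # donut off: self-channel projections now present
  expect_true(all(diag(no_donut$W_out_inh) < 0))

  no_amp <- default_net(3, amplifiers = FALSE)
  expect_equal(no_amp$W_out_inh, base$W_out_inh)
  expect_equal(no_amp$W_inh_inh, base$W_inh_inh)
  expect_true(all(no_amp$W_out_amp == 0))
})

test_that("identical configurations build identical networks", {
  expect_identical(default_net(4), default_net(4))
  expect_identical(build_network(network_config(3, w_ie = 0.17)),
                   build_network(network_config(3, w_ie = 0.17)))
})

test_that("configuration invariants are enforced", {
  expect_error(network_config(0), "n_channels")
  expect_error(network_config(2, w_ie = -1), "non-negative")
  expect_error(network_config(2, r_max = 0), "r_max")
  expect_error(network_config(2, self_inhibition_fraction = 0.3),
               "self_inhibition_fraction")
  expect_silent(network_config(2, donut = FALSE,
                               self_inhibition_fraction = 0.3))
  expect_error(network_config(3, cosmi_code = copy_paste_code(4)),
               "4 channels")
})

test_that("configs round-trip through JSON and hash deterministically", {
  cfg <- network_config(4, w_ii = 0.33, combination_rule = "max",
                        cosmi_code = antichain_code(4, 4))
  path <- withr::local_tempfile(fileext = ".json")
  write_network_config(cfg, path)
  back <- read_network_config(path)
  expect_equal(unclass(back), unclass(cfg))
  expect_identical(config_hash(back), config_hash(cfg))
  expect_false(config_hash(cfg) == config_hash(network_config(4)))
  expect_match(config_hash(cfg), "^[0-9a-f]{8}$")
})

test_that("edge-list export reflects signs and the donut hole", {
  net <- default_net(2)
  edges <- export_edges(net)
  expect_named(edges, c("source", "target", "weight", "sign"))
  inh <- edges[edges$sign == "inhibitory", ]
  expect_true(all(inh$weight < 0))
  expect_true(all(startsWith(inh$source, "inh")))
  # no within-channel inhibitory edge under the donut motif
  expect_false(any(inh$source == "inh1" & inh$target %in% c("out1", "amp1")))
  path <- withr::local_tempfile(fileext = ".tsv")
  export_edges(net, path)
  expect_equal(read.delim(path, stringsAsFactors = FALSE)$weight, edges$weight)
})
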