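test_that("subthreshold network without drive or noise never spikes", {
  # negative applied current, all synapses silent: excitable, not oscillatory
  p <- quick_params(g_ee = 0, g_ei = 0, g_ie = 0, g_ii = 0,
                    g_de = 0, g_di = 0, b = -0.1, noise_rate = 0)
  net <- build_network("control", p)
  tr <- simulate_trial(net, make_stimulus(40, p, seed = 1), p, seed = 1)
  expect_equal(sum(lengths(tr$spikes)), 0)
  expect_true(all(abs(tr$meg) < 1e-12))
})

test_that("trial recordings keep their contract", {
  p <- quick_params()
  net <- build_network("control", p)
  tr <- simulate_trial(net, make_stimulus(40, p, seed = 2), p, seed = 2)
  expect_length(tr$time, p$n_steps)
  expect_length(tr$meg, p$n_steps)
  expect_equal(ncol(tr$theta_trace), net$n_cells + 1)
  expect_true(all(vapply(tr$spikes, function(s) !is.unsorted(s, strictly = TRUE),
                         logical(1))))
  expect_true(all(tr$s_trace >= 0 & tr$s_trace <= 1))
  expect_true(all(tr$theta_trace >= 0 & tr$theta_trace < 2 * pi))
})

test_that("identical configuration and seed give bit-identical recordings", {
  p <- quick_params()
  net <- scale_input(build_network("IPSC", p), 1.0)
  stim <- make_stimulus(40, p, seed = 17)
  t1 <- simulate_trial(net, stim, p, seed = 17)
  t2 <- simulate_trial(net, stim, p, seed = 17)
  expect_identical(t1$meg, t2$meg)
  expect_identical(t1$theta_trace, t2$theta_trace)
  expect_identical(t1$spikes, t2$spikes)
})

test_that("compiled and plain-R integrators agree", {
  p <- quick_params()
  net <- scale_input(build_network("IPSC", p), 1.0)
  stim <- make_stimulus(40, p, seed = 8)
  a <- simulate_trial(net, stim, p, seed = 8, engine = "cpp")
  b <- simulate_trial(net, stim, p, seed = 8, engine = "r")
  expect_equal(a$theta_trace, b$theta_trace, tolerance = 1e-10)
  expect_equal(a$s_trace, b$s_trace, tolerance = 1e-10)
  expect_equal(a$meg, b$meg, tolerance = 1e-10)
})

test_that("random initial phases are drawn per seed when requested", {
  p <- quick_params()
  net <- build_network("control", p)
  stim <- make_stimulus(40, p, seed = 4)
  r1 <- simulate_trial(net, stim, p, seed = 4, init = "random")
  r2 <- simulate_trial(net, stim, p, seed = 4, init = "random")
  r3 <- simulate_trial(net, stim, p, seed = 5, init = "random")
  expect_identical(r1$theta_trace[1, ], r2$theta_trace[1, ])
  expect_false(all(r1$theta_trace[1, 1:30] == r3$theta_trace[1, 1:30]))
  # rest start sits at the fixed point of each cell's applied current
  r4 <- simulate_trial(net, stim, p, seed = 4)
  expect_equal(unname(r4$theta_trace[1, 1:30]),
               unname(rest_phase(net$b_per_cell)))
})

test_that("spike detection finds interpolated upward pi crossings", {
  time <- 0:10
  expect_length(detect_spikes(rep(1, 11), time)[[1]], 0)
  # uniform advance through 2*pi: exactly one spike, at the pi crossing
  th <- seq(0, 2 * pi, length.out = 11) %% (2 * pi)
  sp <- detect_spikes(th, time)[[1]]
  expect_length(sp, 1)
  expect_equal(sp, 5, tolerance = 1e-9)
  # wrap from just below 2*pi to just above 0 is not a spike
  expect_length(detect_spikes(c(6.2, 0.1, 0.2), 0:2)[[1]], 0)
})

test_that("the pacemaker fires on the click train it implements", {
  p <- model_parameters(noise_rate = 0)
  net <- build_network("control", p)
  stim <- make_stimulus(40, p, seed = 1)
  tr <- simulate_trial(net, stim, p, seed = 1)
  pk <- detect_spikes(tr$theta_trace[, net$pacemaker], tr$time)[[1]]
  # the t = 0 click is the initial condition itself; later clicks match
  expect_equal(pk, stim$drive_spike_times[-1], tolerance = 1e-3)
})
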