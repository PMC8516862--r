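p <- model_parameters()

test_that("control network carries the published structure", {
  net <- build_network("control", p)
  expect_equal(net$n_E, 20L)
  expect_equal(net$n_I, 10L)
  inh <- net$sign < 0
  expect_true(all(net$tau_decay[inh] == 8))
  expect_true(all(net$tau_decay[!inh] == 2))
  expect_true(all(net$b_per_cell == -0.01))
  # signed weights: excitatory groups non-negative, inhibitory non-positive
  expect_true(all(net$W[!inh, ] >= 0))
  expect_true(all(net$W[inh, ] <= 0))
  pk <- net$pre == net$pacemaker
  expect_equal(unname(net$W[pk, 1:20]), rep(0.3, 20))
  expect_equal(unname(net$W[pk, 21:30]), rep(0.08, 10))
  # building twice is pure
  expect_identical(net, build_network("control", p))
})

test_that("IPSC variant differs from control only in inhibitory decay times", {
  ctrl <- build_network("control", p)
  ipsc <- build_network("IPSC", p)
  expect_true(all(ipsc$tau_decay[ipsc$sign < 0] == 28))
  expect_identical(ctrl$W, ipsc$W)
  expect_identical(ctrl$b_per_cell, ipsc$b_per_cell)
  expect_identical(ctrl$tau_decay[ctrl$sign > 0], ipsc$tau_decay[ipsc$sign > 0])
})

test_that("gGABA alteration scales only the inhibitory weights", {
  net <- build_network("IPSC+gGABA", p, gGABA_level = 0.5)
  inh <- net$sign < 0
  expect_equal(unique(net$W[inh, 1][net$W[inh, 1] != 0]), -0.0075)   # I -> E
  expect_equal(unique(net$W[inh, 30][net$W[inh, 30] != 0]), -0.01)   # I -> I
  expect_true(all(net$tau_decay[inh] == 28))
  ipsc <- build_network("IPSC", p)
  expect_identical(net$W[!inh, ], ipsc$W[ipsc$sign > 0, ])
  expect_identical(net$b_per_cell, ipsc$b_per_cell)
})

test_that("bInh alteration lowers only the interneuron applied current", {
  net <- build_network("IPSC+bInh", p, bInh_level = 0.2)
  expect_equal(net$b_per_cell[1:20], rep(-0.01, 20))
  expect_equal(net$b_per_cell[21:30], rep(-0.2, 10))
  ipsc <- build_network("IPSC", p)
  expect_identical(net$W, ipsc$W)
  # the mildest published level equals the control current
  mild <- build_network("IPSC+bInh", p, bInh_level = 0.01)
  expect_identical(mild$b_per_cell, ipsc$b_per_cell)
  expect_identical(mild$W, ipsc$W)
  expect_identical(mild$tau_decay, ipsc$tau_decay)
  # decrement reading available behind the flag
  dec <- build_network("IPSC+bInh", p, bInh_level = 0.2,
                       bInh_as_decrement = TRUE)
  expect_equal(dec$b_per_cell[21], -0.21)
})

test_that("the full model combines all three alterations", {
  net <- build_network("Full", p, gGABA_level = 0.5, bInh_level = 0.3)
  inh <- net$sign < 0
  expect_true(all(net$tau_decay[inh] == 28))
  expect_equal(unique(net$W[inh, 1][net$W[inh, 1] != 0]), -0.0075)
  expect_equal(net$b_per_cell[25], -0.3)
  expect_error(build_network("bogus", p))
})

test_that("input scaling touches exactly the pacemaker weights", {
  net <- build_network("IPSC", p)
  for (f in c(0.5, 1.5)) {
    sc <- scale_input(net, f)
    pk <- sc$pre == sc$pacemaker
    expect_equal(unname(sc$W[pk, 1:20]), rep(f * 0.3, 20))
    expect_equal(unname(sc$W[pk, 21:30]), rep(f * 0.08, 10))
    expect_identical(sc$W[!pk, ], net$W[!pk, ])
    expect_identical(sc$tau_decay, net$tau_decay)
    expect_identical(sc$b_per_cell, net$b_per_cell)
  }
})

test_that("optional structural flags behave as documented", {
  noauto <- build_network("control", p, autapses = FALSE)
  for (j in 1:30) expect_equal(noauto$W[j, j], 0)
  ie <- build_network("IPSC", p, ipsc_ie_only = TRUE)
  itaus <- ie$tau_decay[ie$sign < 0]
  expect_setequal(unique(itaus), c(28, 8))
  # I -> E groups carry 28 ms, I -> I groups the control 8 ms
  for (g in which(ie$sign < 0)) {
    targets_E <- any(ie$W[g, 1:20] != 0)
    expect_equal(ie$tau_decay[g], if (targets_E) 28 else 8)
  }
  withdrive <- build_network("control", p, include_drive_in_meg = TRUE)
  pk <- withdrive$pre == withdrive$pacemaker
  expect_equal(withdrive$meg_mult[pk], 20)
  nodrive <- build_network("control", p)
  expect_equal(nodrive$meg_mult[nodrive$pre == nodrive$pacemaker], 0)
  expect_equal(unname(nodrive$meg_mult[nodrive$sign < 0]), rep(0, 10))
  expect_equal(unname(nodrive$meg_mult[1:20]), rep(20, 20))
})

test_that("alteration grids match the published sweeps", {
  g <- alteration_grid("IPSC+gGABA")
  expect_equal(g$gGABA_level, seq(1, 0.1, by = -0.05))
  expect_equal(nrow(g), 19)
  b <- alteration_grid("IPSC+bInh")
  expect_equal(nrow(b), 20)
  expect_equal(min(b$bInh_level), 0.01)
  expect_equal(max(b$bInh_level), 0.6)
  expect_equal(b$bInh_level[1:10], seq(0.01, 0.1, by = 0.01))
  f <- alteration_grid("Full")
  expect_equal(nrow(f), 10)
  expect_equal(f$gGABA_level, seq(1, 0.1, by = -0.1))
  expect_true(all(diff(f$bInh_level) > 0))
  expect_equal(range(f$bInh_level), c(0.01, 0.6))
})
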