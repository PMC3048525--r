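test_that("the channel inventory is 6 synthesis + 11 degradation over 18 species", {
  p <- fast_params()
  pool <- gal_pool(Gal1p = 500, Gal4p = 100, Gal480p = 50)
  syn <- synthesis_propensities(scer_network(), pool, p)
  deg <- degradation_propensities(pool, p$sim$gamma)
  expect_length(syn, 6)
  expect_length(deg, 11)
  # 17 channels over 11 proteins + 6 genes + intracellular galactose = 18
  expect_length(c(syn, deg), 17)
  expect_length(galswitch:::GAL_SPECIES, 11)

  # degradation is first order with the published rate
  expect_equal(unname(deg["Gal1p"]), 500 * 0.002)
  expect_equal(unname(deg["Gal1p"]), 1.0)
  expect_equal(unname(degradation_propensities(gal_pool(), 0.002)),
               rep(0, 11))

  # absent genes contribute zero-propensity channels
  expect_equal(unname(syn[c("GAL13")]), 0)
  pre <- pre_wgd_ancestor()
  syn_pre <- synthesis_propensities(pre, pool, p)
  expect_equal(unname(syn_pre["GAL1"]), 0)
  expect_equal(unname(syn_pre["GAL3"]), 0)

  # constitutive GAL4 scales with copy number
  one <- synthesis_propensities(scer_network(), gal_pool(), p)[["GAL4"]]
  two <- synthesis_propensities(post_wgd_ancestor(), gal_pool(), p)[["GAL4"]]
  expect_equal(one, 0.06 * p$sim$synthesis_scale)
  expect_equal(two, 2 * one)
})

test_that("trajectories are reproducible and respect basic invariants", {
  p <- fast_params()
  r1 <- run_simulation(scer_network(), 1e-6, p, seed = 77, n_sample = 10)
  r2 <- run_simulation(scer_network(), 1e-6, p, seed = 77, n_sample = 10)
  expect_identical(r1$traj, r2$traj)
  expect_identical(as.numeric(r1$endpoint), as.numeric(r2$endpoint))
  r3 <- run_simulation(scer_network(), 1e-6, p, seed = 78)
  expect_false(identical(as.numeric(r1$endpoint), as.numeric(r3$endpoint)))

  expect_true(all(r1$traj >= 0))
  expect_true(all(as.numeric(r1$endpoint) >= 0))

  # zero horizon returns the initial pool untouched
  p0 <- gal_params(sim = list(t_end = 0))
  init <- gal_pool(Gal1p = 123, Gal4p = 45)
  r0 <- run_simulation(scer_network(), 1e-6, p0, init = init, seed = 1)
  expect_identical(as.numeric(r0$endpoint), as.numeric(init))
})

test_that("the constitutive gene matches the analytic birth-death mean", {
  # GAL4's synthesis is concentration-independent, so its family total
  # (free plus complexed, both degrading at gamma) is a birth-death process
  # with mean copies * 0.06 * scale * burst / gamma.
  p <- gal_params(sim = list(t_end = 4000))
  nrep <- 25
  ends <- vapply(seq_len(nrep), function(i) {
    e <- run_simulation(pre_wgd_ancestor(), 0, p, seed = 1000 + i)$endpoint
    e[["Gal4p"]] + e[["Gal480p"]]
  }, numeric(1))
  analytic <- 0.06 * p$sim$synthesis_scale * p$sim$burst / p$sim$gamma
  se <- sd(ends) / sqrt(nrep)
  expect_lt(abs(mean(ends) - analytic), 3 * se)
})

test_that("burst realization keeps counts integral with mean 2.5", {
  p <- fast_params()
  r <- run_simulation(scer_network(), 0, p, seed = 3)
  # integer mode deposits whole molecules (bursts of 2 or 3)
  expect_true(all(abs(r$syn_molecules - round(r$syn_molecules)) < 1e-9))
  expect_gt(sum(r$syn_molecules), 0)
  # fractional validation mode deposits exactly 2.5 per event
  pf <- gal_params(sim = list(t_end = 300, fractional_burst = TRUE))
  rf <- run_simulation(scer_network(), 0, pf, seed = 4)
  expect_true(all(abs((rf$syn_molecules * 2) %% 5) < 1e-9))
})

test_that("equilibrium summaries aggregate replicates correctly", {
  p <- fast_params()
  eq1 <- equilibrium_distribution(scer_network(), 1e-7, 1, p, seed = 9)
  expect_equal(eq1$sd, rep(0, 11))
  eq3 <- equilibrium_distribution(scer_network(), 1e-7, 3, p, seed = 9)
  expect_identical(nrow(eq3), 11L)
  expect_true(all(eq3$sd >= 0))
  reps <- attr(eq3, "replicates")
  expect_identical(dim(reps), c(3L, 11L))
  expect_equal(eq3$mean, unname(colMeans(reps)))
  # deterministic given seed
  eq3b <- equilibrium_distribution(scer_network(), 1e-7, 3, p, seed = 9)
  expect_identical(eq3$mean, eq3b$mean)
})

test_that("endpoint means are insensitive to the deterministic-skip scale", {
  pA <- gal_params(sim = list(t_end = 2500, det_skip_scale = 300))
  pB <- gal_params(sim = list(t_end = 2500, det_skip_scale = 3000))
  cfg <- pre_wgd_ancestor()
  mA <- equilibrium_distribution(cfg, 1e-5, 6, pA, seed = 21)
  mB <- equilibrium_distribution(cfg, 1e-5, 6, pB, seed = 22)
  a <- summary_family_mean(mA, GAL13_FAMILY)
  b <- summary_family_mean(mB, GAL13_FAMILY)
  expect_gt(a / b, 0.7)
  expect_lt(a / b, 1.4)
})

test_that("the extant network switches by at least an order of magnitude", {
  p <- gal_params(sim = list(t_end = 4000))
  lo <- equilibrium_distribution(scer_network(), 1e-8, 4, p, seed = 31)
  hi <- equilibrium_distribution(scer_network(), 0.1, 4, p, seed = 32)
  expect_gt(summary_family_mean(hi, "Gal1p") /
              summary_family_mean(lo, "Gal1p"), 10)
})
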