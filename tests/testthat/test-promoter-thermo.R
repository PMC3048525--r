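# Independent brute-force oracle: enumerate occupancy states by explicit
# nested loops and evaluate the weighted average directly from the energy
# definitions, sharing no code with the implementation.
brute_force_propensity <- function(arch, thermo, c4, c480) {
  n <- arch$n_uas
  if (n == 0) return(arch$constitutive)
  contr <- c(arch$c_empty, arch$c_gal4, arch$c_gal480)
  pairs <- if (arch$n_coop_pairs > 0)
    lapply(seq_len(arch$n_coop_pairs), function(i) c(i, i + 1)) else list()
  states <- expand.grid(rep(list(0:2), n))
  num <- den <- 0
  a4 <- c4 / thermo$conc_ref; a480 <- c480 / thermo$conc_ref
  for (i in seq_len(nrow(states))) {
    s <- as.integer(states[i, ])
    dG <- sum(s > 0) * thermo$dG_bind
    for (pr in pairs) {
      if (s[pr[1]] == 1 && s[pr[2]] == 1) dG <- dG + thermo$dG_coop_44
      if (s[pr[1]] == 2 && s[pr[2]] == 2) dG <- dG + thermo$dG_coop_8080
    }
    w <- a4^sum(s == 1) * a480^sum(s == 2) * exp(-dG / thermo$beta)
    num <- num + sum(contr[s + 1]) * w
    den <- den + w
  }
  max(0, num / den)
}

test_that("occupancy enumeration matches the architecture definitions", {
  p <- gal_params()
  occ3 <- enumerate_occupancies(promoter_arch(p, "GAL3"), p$thermo)
  expect_identical(nrow(occ3), 3L)
  expect_setequal(occ3$K, c(0.14, 9.00, 0.14))

  occ1 <- enumerate_occupancies(promoter_arch(p, "GAL1"), p$thermo)
  expect_identical(nrow(occ1), 27L)
  # the all-activator state: three bindings plus two cooperative pairs
  all4 <- occ1[occ1$n4 == 3, ]
  expect_equal(all4$dG, 3 * (-13.86) + 2 * (-2.00))
  expect_equal(all4$K, 63)
  # all-repressor state gains the stronger cooperative energy
  allR <- occ1[occ1$n480 == 3, ]
  expect_equal(allR$dG, 3 * (-13.86) + 2 * (-3.00))
  # reference state has zero free energy
  expect_equal(occ1$dG[occ1$n4 == 0 & occ1$n480 == 0][1], 0)

  occ4 <- enumerate_occupancies(promoter_arch(p, "GAL4"), p$thermo)
  expect_identical(nrow(occ4), 1L)
  expect_equal(occ4$K, 0.06)
  expect_equal(occ4$dG, 0)
})

test_that("propensity agrees with the brute-force oracle for all promoters", {
  p <- gal_params()
  set.seed(31)
  for (g in c("GAL1", "GAL2", "GAL3", "GAL4", "GAL80", "GAL13")) {
    arch <- promoter_arch(p, g)
    for (rep in 1:5) {
      c4 <- runif(1, 0, 2e-6); c480 <- runif(1, 0, 2e-6)
      expect_equal(promoter_propensity(arch, c4, c480, p$thermo),
                   brute_force_propensity(arch, p$thermo, c4, c480),
                   tolerance = 1e-12)
    }
  }
})

test_that("limiting propensities follow the occupancy model", {
  p <- gal_params()
  g3 <- promoter_arch(p, "GAL3")
  # no factors: only the empty state contributes
  expect_equal(promoter_propensity(g3, 0, 0, p$thermo), 0.14)
  # saturating activator: bound state dominates
  expect_equal(promoter_propensity(g3, 1e6, 0, p$thermo), 9.00,
               tolerance = 1e-6)
  # constitutive promoter ignores concentrations
  expect_equal(promoter_propensity(promoter_arch(p, "GAL4"), 0, 0, p$thermo),
               0.06)
  expect_equal(promoter_propensity(promoter_arch(p, "GAL4"), 1, 2, p$thermo),
               0.06)
  expect_error(promoter_propensity(g3, -1, 0, p$thermo), "non-negative")
})

test_that("propensity is bounded, monotone and repressor-competitive", {
  p <- gal_params()
  set.seed(99)
  for (g in c("GAL1", "GAL3", "GAL80", "GAL13")) {
    arch <- promoter_arch(p, g)
    occ <- enumerate_occupancies(arch, p$thermo)
    for (rep in 1:10) {
      c4 <- runif(1, 0, 1e-5); c480 <- runif(1, 0, 1e-5)
      f <- promoter_propensity(arch, c4, c480, p$thermo, clamp = FALSE)
      expect_gte(f, min(occ$K))
      expect_lte(f, max(occ$K))
    }
  }
  # single-UAS: non-decreasing in activator, and adding repressor never
  # increases output when its contribution is below the activator's
  g80 <- promoter_arch(p, "GAL80")
  c4s <- seq(0, 2e-6, length.out = 8)
  f_up <- vapply(c4s, function(c4)
    promoter_propensity(g80, c4, 5e-7, p$thermo), numeric(1))
  expect_true(all(diff(f_up) >= -1e-12))
  c480s <- seq(0, 2e-6, length.out = 8)
  f_dn <- vapply(c480s, function(c480)
    promoter_propensity(g80, 5e-7, c480, p$thermo), numeric(1))
  expect_true(all(diff(f_dn) <= 1e-12))
})

test_that("C++ and R promoter evaluations agree", {
  p <- gal_params()
  tabs <- galswitch:::promoter_state_tables(p)
  cf <- 1 / (galswitch:::AVOGADRO * p$volumes[["nuclear"]] * p$thermo$conc_ref)
  molar_per_count <- 1 / (galswitch:::AVOGADRO * p$volumes[["nuclear"]])
  set.seed(5)
  for (gi in seq_along(tabs)) {
    arch <- promoter_arch(p, galswitch:::GAL_GENES[gi])
    for (rep in 1:4) {
      n4 <- runif(1, 0, 2000); n480 <- runif(1, 0, 2000)
      expect_equal(
        galswitch:::cpp_promoter_f(tabs[[gi]], n4 * cf, n480 * cf),
        promoter_propensity(arch, n4 * molar_per_count,
                            n480 * molar_per_count, p$thermo),
        tolerance = 1e-12)
    }
  }
})
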