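cond_std <- conditions(T = 310.15, pH = 7, ionic_strength = 0.25)

test_that("species adjustment reduces to dfG0 when all corrections vanish", {
  c0 <- conditions(T = 298.15, pH = 0, ionic_strength = 0)
  adj <- adjust_species(dfG0 = -100, dfH0 = -120, z = 0, nH = 0,
                        phase = "aqueous", cond = c0, activity = 1)
  expect_equal(adj$mu, -100)
  expect_equal(adj$h, -120)
  # reference concentration contributes exactly zero for any species
  a1 <- adjust_species(-50, -60, z = -1, nH = 2, cond = cond_std,
                       activity = 1)
  a2 <- adjust_species(-50, -60, z = -1, nH = 2, cond = cond_std,
                       activity = exp(1))
  expect_equal(a2$mu - a1$mu, 8.314e-3 * 310.15, tolerance = 1e-10)
  expect_error(adjust_species(-50, -60, 0, 0, cond = cond_std, activity = 0),
               "nonpositive")
})

test_that("pseudoisomer weights normalize, are shift-invariant and symmetric", {
  one <- data.frame(dfG0 = -200, dfH0 = -210, z = 0, nH = 1)
  pa <- pseudoisomer_average(one, cond_std)
  expect_equal(pa$weights, 1)
  expect_equal(pa$h, adjust_species(-200, -210, 0, 1, cond = cond_std)$h)

  two <- data.frame(dfG0 = c(-300, -300), dfH0 = c(-310, -330),
                    z = c(0, 0), nH = c(0, 0))
  pa2 <- pseudoisomer_average(two, cond_std)
  expect_equal(pa2$weights, c(0.5, 0.5))
  expect_equal(pa2$h, -320)

  set.seed(42)
  grp <- data.frame(dfG0 = runif(4, -1200, -1000), dfH0 = runif(4, -1300, -1200),
                    z = c(0, -1, -2, -3), nH = 3:0)
  w <- pseudoisomer_average(grp, cond_std)$weights
  expect_equal(sum(w), 1, tolerance = 1e-12)
  shifted <- grp; shifted$dfG0 <- shifted$dfG0 + 500
  expect_equal(pseudoisomer_average(shifted, cond_std)$weights, w,
               tolerance = 1e-10)
})

test_that("phosphate group at pH 7 matches an independent binding-polynomial oracle", {
  tab <- read_species_table()
  po4 <- tab[tab$metabolite == "po4.Ext", ]
  pa <- pseudoisomer_average(po4, cond_std)
  orc <- oracle_group_potential(po4, T = 310.15, pH = 7, I = 0.25)
  expect_lt(abs(pa$mu - orc$mu), 0.5)            # kJ/mol
  expect_equal(pa$weights, orc$weights, tolerance = 1e-6,
               ignore_attr = TRUE)
  # dominant weight on the H2PO4-/HPO4-2 pair; mean charge in (-2, -1)
  expect_gt(sum(pa$weights[po4$species %in% c("H2PO4-", "HPO4-2")]), 0.99)
  expect_gt(pa$z_mean, -2)
  expect_lt(pa$z_mean, -1)
})

test_that("phase averaging interpolates between liquid and gas properties", {
  liq <- list(mu = -237.19, h = -285.83)
  gas <- list(mu = -228.57, h = -241.82)
  expect_equal(phase_average(liq, gas, 0), liq)
  expect_equal(phase_average(liq, gas, 1), gas)
  mix <- phase_average(liq, gas, 0.04)
  expect_equal(mix$mu, 0.96 * liq$mu + 0.04 * gas$mu)
  expect_equal(mix$h, 0.96 * liq$h + 0.04 * gas$h)
  expect_error(phase_average(liq, gas, 1.2), "gas fraction")
})

test_that("proton balance closes the charge balance of a mode", {
  ch <- c(ac.Ext = -1, glc.Ext = 0, nh4.Ext = 1)
  pb <- proton_balance(c(glc.Ext = -1, ac.Ext = 1), ch)
  expect_equal(pb$protons, 1)
  expect_equal(pb$stoich[["h.Ext"]], 1)
  expect_equal(proton_balance(c(glc.Ext = -1), ch)$protons, 0)
  # hand audit of a 3-species mode: consume 1 NH4+ (z +1), produce 1 acetate-
  # (z -1): signed charge sum = -1 - 1 = -2, protons = +2
  pb2 <- proton_balance(c(nh4.Ext = -1, ac.Ext = 1, glc.Ext = -1), ch)
  expect_equal(pb2$protons, 2)
  expect_error(proton_balance(c(unknown = 1), ch), "missing mean charge")
})

test_that("mode reaction properties obey the Gibbs relation and linearity", {
  props <- data.frame(metabolite = c("a.Ext", "b.Ext"),
                      g = c(-100, -150), h = c(-120, -140),
                      s = c((-120 + 100), (-140 + 150)) / 310.15 * 1000,
                      z_mean = 0, nH_mean = 0)
  # identity "reaction" A -> A nets to a zero coefficient
  both <- mode_reaction_properties(c(a.Ext = 0), props, cond_std)
  expect_equal(both$dg, 0)
  expect_equal(both$ds, 0)

  set.seed(7)
  for (i in 1:5) {
    st <- c(a.Ext = rnorm(1), b.Ext = rnorm(1))
    mt <- mode_reaction_properties(st, props, cond_std)
    expect_equal(mt$dg, mt$dh - 310.15 * mt$ds, tolerance = 1e-6)
    expect_equal(mt$affinity, -mt$dg)
    lam <- runif(1, 0.1, 3)
    mt2 <- mode_reaction_properties(st * lam, props, cond_std)
    expect_equal(mt2$ds, lam * mt$ds, tolerance = 1e-9)
    expect_equal(mt2$dg, lam * mt$dg, tolerance = 1e-9)
  }
})

test_that("aerobic glucose oxidation at culture conditions is spontaneous with positive entropy", {
  tab <- read_species_table()
  cond <- conditions(T = 310.15, pH = 7, ionic_strength = 0.25,
                     concentrations = c(glc.Ext = 0.00555, o2.Ext = 0.21,
                                        co2.Ext = 0.0004),
                     gas_fractions = c(o2.Ext = 1, co2.Ext = 1,
                                       h2o.Ext = 0.04))
  props <- adjusted_properties(tab, cond)
  resp <- c(glc.Ext = -1, o2.Ext = -6, co2.Ext = 6, h2o.Ext = 6)
  mt <- mode_reaction_properties(resp, props, cond)
  expect_lt(mt$dg, 0)
  expect_gt(mt$ds, 0)
  expect_equal(mt$dg, mt$dh - 310.15 * mt$ds, tolerance = 1e-6)
  # partially fermentative mode: still spontaneous, positive entropy
  ferm <- c(glc.Ext = -1, o2.Ext = -2, ac.Ext = 2, co2.Ext = 2,
            h2o.Ext = 2)
  mtf <- mode_reaction_properties(ferm, props, cond)
  expect_lt(mtf$dg, 0)
  expect_gt(mtf$ds, 0)
})

test_that("overall reaction properties are linear mixtures of mode properties", {
  sys <- synthetic_system(10, seed = 5)
  props <- data.frame(metabolite = names(sys$species_s),
                      g = -sys$species_s * 310.15 / 1000, h = 0,
                      s = sys$species_s, z_mean = 0, nH_mean = 0)
  cond <- conditions()
  m1 <- mode_reaction_properties(sys$ext_stoich[1, ], props, cond)
  m2 <- mode_reaction_properties(sys$ext_stoich[2, ], props, cond)
  # overall reaction equal to a single mode equals that mode's properties
  ov1 <- overall_reaction_properties(sys$ext_stoich[1, ], props, cond)
  expect_equal(ov1$dS_R, m1$ds)
  expect_equal(ov1$dG_R, m1$dg)
  # p-weighted mixture
  mix <- 0.3 * sys$ext_stoich[1, ] + 0.7 * sys$ext_stoich[2, ]
  ovm <- overall_reaction_properties(mix, props, cond)
  expect_equal(ovm$dS_R, 0.3 * m1$ds + 0.7 * m2$ds, tolerance = 1e-9)
  expect_equal(ovm$dG_R, 0.3 * m1$dg + 0.7 * m2$dg, tolerance = 1e-9)
})

test_that("zero-enthalpy thermodynamics make affinity/T equal reaction entropy", {
  th <- synthetic_thermo(30, dh_model = "zero", seed = 2)
  expect_equal(th$affinity / 310.15, th$ds, tolerance = 1e-12)
})
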