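test_that("zero uptake gives the uniform distribution and Z = n", {
  bp <- boltzmann_probabilities(c(1200, 1800, 2600, 990), xi_hat = 0, b = 0.4)
  expect_equal(bp$p, rep(0.25, 4))
  expect_equal(bp$Z, 4)
  expect_equal(bp$c, -log(4))
})

test_that("equal mode values share probability equally", {
  bp <- boltzmann_probabilities(c(1500, 1500), xi_hat = 0.01, b = 0.3)
  expect_equal(bp$p, c(0.5, 0.5))
})

test_that("three-mode hand case matches the closed-form evaluation", {
  # choose mode values so the Boltzmann factors are exactly 4, 2, 1
  b <- 0.5; xi_hat <- 0.02
  x <- -c(log(4), log(2), 0) * b * R_GAS / xi_hat
  bp <- boltzmann_probabilities(x, xi_hat, b)
  expect_equal(bp$p, c(4, 2, 1) / 7, tolerance = 1e-14)
  expect_equal(bp$Z, 7, tolerance = 1e-12)
  expect_equal(bp$c, -log(7), tolerance = 1e-12)
})

test_that("normalization holds to 1e-10 across six decades of xi_hat and b", {
  set.seed(1)
  x <- runif(200, 1000, 3000)
  for (xi_hat in 10^seq(-5, 1, by = 2)) {
    for (b in 10^seq(-3, 3, by = 2)) {
      bp <- boltzmann_probabilities(x, xi_hat, b)
      expect_lt(abs(sum(bp$p) - 1), 1e-10)
      expect_true(all(bp$p >= 0))
    }
  }
  # strict positivity at the physically relevant scales
  expect_true(all(boltzmann_probabilities(x, 0.012, 0.4)$p > 0))
})

test_that("probabilities decrease in the mode value and flatten as b grows", {
  x <- sort(runif(50, 1000, 3000))
  p <- boltzmann_probabilities(x, 0.012, 0.4)$p
  expect_true(all(diff(p) < 0))
  p_flat <- boltzmann_probabilities(x, 0.012, 40)$p
  expect_lt(max(p_flat) - min(p_flat), max(p) - min(p))
  expect_lt(max(abs(p_flat - 1 / 50)), 1e-3)
})

test_that("unit rescaling of mode values with matching R leaves p unchanged", {
  x <- runif(30, 1000, 3000)
  p_J <- boltzmann_probabilities(x, 0.012, 0.4, R = 8.314)$p
  p_kJ <- boltzmann_probabilities(x / 1000, 0.012, 0.4, R = 8.314e-3)$p
  expect_equal(p_J, p_kJ, tolerance = 1e-12)
})

test_that("log-probabilities against xi_hat*x/b have slope -1/R for every strain", {
  set.seed(2)
  x <- runif(40, 1000, 3000)
  slopes <- vapply(list(c(0.008, 0.3), c(0.012, 0.42), c(0.0125, 0.35)),
                   function(sc) {
    bp <- boltzmann_probabilities(x, sc[1], sc[2])
    unname(coef(lm(log(bp$p) ~ I(sc[1] * x / sc[2])))[2])
  }, 0)
  expect_equal(slopes, rep(-1 / R_GAS, 3), tolerance = 1e-9)
})

test_that("fit_b recovers the generating b and agrees with a grid-search oracle", {
  th <- synthetic_thermo(50, seed = 8)
  b_true <- 0.40
  xi_hat <- 0.012
  target <- sum(boltzmann_probabilities(th$ds, xi_hat, b_true)$p * th$ds)
  fit <- fit_b(th$ds, xi_hat, target)
  expect_equal(fit$b, b_true, tolerance = 1e-6)
  expect_lt(abs(sum(fit$p) - 1), 1e-10)
  expect_equal(fit$c, -log(fit$Z))
  b_grid <- grid_search_b(th$ds, xi_hat, target)
  expect_equal(fit$b, b_grid, tolerance = 0.01)
})

test_that("scalar root solve and Levenberg-Marquardt formulation agree", {
  th <- synthetic_thermo(60, seed = 12)
  for (b_true in c(0.1, 0.42, 2)) {
    target <- sum(boltzmann_probabilities(th$ds, 0.012, b_true)$p * th$ds)
    b_root <- fit_b(th$ds, 0.012, target, method = "root")$b
    b_lm <- fit_b(th$ds, 0.012, target, method = "lm")$b
    expect_equal(b_lm, b_root, tolerance = 1e-6)
  }
})

test_that("targets outside the attainable interval raise informative errors", {
  th <- synthetic_thermo(40, seed = 13)
  expect_error(fit_b(th$ds, 0.012, min(th$ds) - 1), "lower bound")
  expect_error(fit_b(th$ds, 0.012, mean(th$ds)), "uniform limit")
  expect_error(fit_b(th$ds, 0, 1500), "xi_hat")
})

test_that("maximum-rate predictions follow from the fraction b", {
  mr <- predict_max_rates(mu = 0.9, qs = 12, b = 1)
  expect_equal(mr$mu_max, 0.9)
  expect_equal(mr$qs_max, 12)
  expect_equal(mr$tau_min, log(2) / 0.9 * 60)
  mr2 <- predict_max_rates(mu = 0.886, qs = 11.57, b = 0.42324)
  expect_equal(mr2$mu_max, 0.886 / 0.42324)
  expect_error(predict_max_rates(0.9, 12, 0), "positive")
})

test_that("variant comparison coincides for zero enthalpy and differs otherwise", {
  thz <- synthetic_thermo(50, dh_model = "zero", seed = 14)
  p <- boltzmann_probabilities(thz$ds, 0.012, 0.45)$p
  obs <- list(mu = 0.9, qs = 12, dS_R = sum(p * thz$ds),
              dG_R = sum(p * thz$dg))
  cmpz <- compare_variants(thz, obs)
  expect_equal(cmpz$b[1], cmpz$b[2], tolerance = 1e-9)
  expect_equal(cmpz$tau_min[1], cmpz$tau_min[2], tolerance = 1e-6)

  # correlated enthalpies: each variant recovers its own generating b
  thc <- synthetic_thermo(50, dh_model = "correlated", seed = 15)
  p_s <- boltzmann_probabilities(thc$ds, 0.012, 0.4)$p
  obs_s <- list(mu = 0.9, qs = 12, dS_R = sum(p_s * thc$ds),
                dG_R = sum(p_s * thc$dg))
  cmp_s <- compare_variants(thc, obs_s)
  expect_equal(cmp_s$b[cmp_s$variant == "entropy"], 0.4, tolerance = 1e-6)
  p_a <- boltzmann_probabilities(thc$affinity / 310.15, 0.012, 0.4)$p
  obs_a <- list(mu = 0.9, qs = 12, dS_R = sum(p_a * thc$ds),
                dG_R = sum(p_a * thc$dg))
  cmp_a <- compare_variants(thc, obs_a)
  expect_equal(cmp_a$b[cmp_a$variant == "affinity"], 0.4, tolerance = 1e-6)
  expect_gt(abs(cmp_s$b[1] - cmp_s$b[2]) / cmp_s$b[1], 1e-4)
})
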