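test_that("growth rates follow the temperature-competition form", {
  # single species at its closed-form fixed point
  p1 <- demographic_params(theta_min = -1, g = 1, c = 1, l = 1e-12)
  expect_equal(ode_rhs(1, 0, p1), 0, tolerance = 1e-9)

  # hand-substituted two-species case: rate = 1*(0+1) - 0.5*1 - 0.25*2 = 0
  p2 <- demographic_params(theta_min = c(-1, -1), g = c(1, 1),
                           c = c(0.5, 0.5), l = c(0.25, 0.25))
  expect_equal(ode_rhs(c(1, 1), 0, p2), c(0, 0))

  # extinction is absorbing: zero biomass has zero derivative
  p3 <- toy_params(3)
  dB <- ode_rhs(c(0.5, 0, 0.2), 1, p3)
  expect_identical(dB[2], 0)
  expect_true(all(dB[c(1, 3)] != 0))

  # the community-biomass sum includes the focal species itself
  pA <- demographic_params(theta_min = 0, g = 1, c = 0.3, l = 0.2)
  B <- 1.7
  expect_equal(ode_rhs(B, 2, pA), B * (2 - 0.3 * B - 0.2 * B))
})

test_that("growth-rate evaluation validates its inputs", {
  p <- toy_params(3)
  expect_error(ode_rhs(c(1, 1), 0, p), class = "lvtraits_dimension_mismatch")
  expect_error(ode_rhs(c(1, NA, 1), 0, p), class = "lvtraits_invalid_state")
  expect_error(ode_rhs(c(1, -1, 1), 0, p), class = "lvtraits_invalid_state")
  expect_error(demographic_params(0, g = -1, c = 1, l = 1),
               class = "lvtraits_invalid_params")
  expect_error(demographic_params(c(0, 1), g = 1, c = 1, l = 1),
               class = "lvtraits_dimension_mismatch")
})

test_that("single-species integration reaches the closed-form equilibrium", {
  p <- demographic_params(theta_min = 0, g = 0.01, c = 0.005, l = 0.005)
  st <- integrate_to_equilibrium(p, theta = 2, b0 = 0.3,
                                 solver = solver_control(horizon = 1e5))
  # B* = g (theta - theta_min) / (c + l) = 0.02 / 0.01
  expect_equal(st$biomass, 2, tolerance = 1e-6)
  expect_true(st$converged)
  expect_equal(st$rel_abundance, 1)
  expect_equal(sum(st$rel_abundance), 1, tolerance = 1e-12)
})

test_that("species below their thermal threshold decay to extinction", {
  p <- demographic_params(theta_min = c(0, 1.5), g = c(0.01, 0.01),
                          c = c(0.005, 0.005), l = c(0.005, 0.005))
  st <- integrate_to_equilibrium(p, theta = 1, b0 = c(0.5, 0.5),
                                 solver = solver_control(horizon = 1e5))
  expect_lt(st$rel_abundance[2], 1e-10)
  expect_gt(st$biomass[2], 0)  # finite-time positivity
  expect_gt(st$biomass[1], 0)
})

test_that("equilibria are independent of the random initial biomass", {
  p <- toy_params(5, theta_min = c(-1, -0.5, 0, 0.5, 1))
  runs <- lapply(1:2, function(k)
    integrate_to_equilibrium(p, theta = 1.2, seed = k,
                             solver = solver_control(horizon = 1e5)))
  expect_equal(runs[[1]]$biomass, runs[[2]]$biomass, tolerance = 1e-6)
})

test_that("trajectories from positive initials stay strictly positive", {
  inst <- random_instance(3, S = 12)
  st <- integrate_to_equilibrium(inst$params, inst$theta, seed = 9)
  expect_true(all(st$biomass > 0))
})

test_that("analytic fixed point matches the closed forms", {
  # single species: T = B* = r / (c + l)
  p <- demographic_params(theta_min = 0, g = 0.01, c = 0.005, l = 0.005)
  st <- analytic_equilibrium(p, theta = 2)
  expect_equal(st$biomass, 2)
  expect_equal(st$total_biomass, 2)
  expect_lt(st$residual, 1e-12)

  # identical species: B* = r / (c + S l), verified by direct substitution
  S <- 6
  p2 <- toy_params(S)
  st2 <- analytic_equilibrium(p2, theta = 1)
  r <- 0.01 * 2
  expect_equal(st2$biomass, rep(r / (0.005 + S * 0.005), S))
  expect_equal(ode_rhs(st2$biomass, 1, p2), rep(0, S), tolerance = 1e-15)

  # all-nonviable community is degenerate
  st3 <- analytic_equilibrium(toy_params(3), theta = -2)
  expect_true(st3$degenerate)
  expect_identical(st3$biomass, rep(0, 3))
})

test_that("excluded species cannot invade the analytic equilibrium", {
  for (seed in 1:25) {
    inst <- random_instance(seed)
    st <- analytic_equilibrium(inst$params, inst$theta)
    if (st$degenerate) next
    r <- inst$params$g * (inst$theta - inst$params$theta_min)
    invasion <- r - inst$params$l * st$total_biomass
    expect_true(all(invasion[st$biomass == 0] <= 1e-12))
    expect_true(all(st$biomass[invasion > 1e-12] > 0))
  }
})

test_that("analytic and integrated equilibria agree on random instances", {
  worst <- 0
  for (seed in 1:20) {
    inst <- random_instance(seed)
    ae <- analytic_equilibrium(inst$params, inst$theta)
    if (ae$degenerate) next
    oe <- integrate_to_equilibrium(inst$params, inst$theta, seed = seed)
    worst <- max(worst, max(abs(ae$biomass - oe$biomass)) / max(ae$biomass))
  }
  expect_lt(worst, 1e-4)
})

test_that("single-species equilibrium grows with temperature above the
           threshold and vanishes below it", {
  p <- demographic_params(theta_min = 0.5, g = 0.01, c = 0.004, l = 0.006)
  thetas <- seq(-1, 2, by = 0.25)
  eq <- vapply(thetas, function(th) analytic_equilibrium(p, th)$biomass,
               numeric(1))
  above <- thetas > 0.5
  expect_true(all(diff(eq[above]) > 0))
  expect_true(all(eq[!above] == 0))
})

test_that("site standardization yields zero-mean unit-sd temperatures", {
  st <- site_table(sprintf("p%d", 1:9), c(4.55, 5, 5.5, 6, 6.5, 7, 7.5, 8,
                                          8.26))
  expect_equal(mean(st$theta), 0, tolerance = 1e-12)
  expect_equal(sd(st$theta), 1, tolerance = 1e-12)
  expect_error(site_table(c("a", "a"), c(1, 2)),
               class = "lvtraits_invalid_sites")
})
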