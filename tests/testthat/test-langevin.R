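test_that("phi0 matches its closed forms", {
  expect_equal(phi0(3.7, alpha = 0.4), 3.7)          # single taxon collapses
  expect_equal(phi0(c(1, 1), alpha = 0.5), sqrt(2))
  # k equal fitnesses f give f * k^(1 - alpha)
  for (alpha in c(0.25, 0.5, 0.75)) {
    expect_equal(phi0(rep(2.5, 8), alpha), 2.5 * 8^(1 - alpha))
  }
  expect_error(phi0(c(1, 2), alpha = 1), "alpha")
  expect_error(phi0(c(1, -1), alpha = 0.5), "> 0")
})

test_that("simulation respects the compositional constraint", {
  # single taxon: normalization forces x = 1 forever
  sim1 <- simulate_langevin(F = 2, V = 0.3, n_steps = 500, seed = 1,
                            record_every = 50)
  expect_equal(as.vector(sim1$x), rep(1, ncol(sim1$x)))
  # zero noise at the symmetric fixed point: composition frozen
  sim0 <- simulate_langevin(F = rep(1, 5), V = 0, n_steps = 500, seed = 1,
                            record_every = 100)
  expect_equal(sim0$x, matrix(0.2, 5, ncol(sim0$x),
                              dimnames = dimnames(sim0$x)),
               tolerance = 1e-12)
  # stochastic run: every recorded column sums to 1
  sim <- simulate_langevin(F = runif(10, 0.5, 3), V = 0.2, n_steps = 2000,
                           seed = 3, record_every = 100)
  expect_true(all(abs(colSums(sim$x) - 1) < 1e-9))
  expect_true(all(sim$x >= 0))
  # seeded runs are identical
  sim_b <- simulate_langevin(F = rep(1, 4), V = 0.1, n_steps = 300, seed = 11)
  sim_c <- simulate_langevin(F = rep(1, 4), V = 0.1, n_steps = 300, seed = 11)
  expect_identical(sim_b$x, sim_c$x)
})

test_that("too-large steps are rejected with a dt hint", {
  expect_error(
    simulate_langevin(F = c(5000, 1), V = 0, dt = 1, n_steps = 10, seed = 1),
    "reduce dt")
})

test_that("equal-branch stationary mode matches the analytic value", {
  ss <- steady_state_pdf(alpha = 0.5, beta = 0.75, F = 0.5, V = 0.5,
                         phi0_val = 0.5)
  expect_equal(ss$branch, "equal")
  expect_equal(ss$x_M, ((0.5 - 0.75 * 0.25) / 0.5)^(1 / 0.5),
               tolerance = 1e-9)  # 0.390625
  # grid argmax agrees with the refined mode
  expect_lt(abs(ss$grid[which.max(ss$density)] - ss$x_M) / ss$x_M, 0.05)
})

test_that("stationary density is normalized and concentrates as V -> 0", {
  ss <- steady_state_pdf(alpha = 0.75, beta = 0.75, F = 1, V = 0.15,
                         phi0_val = 2)
  g <- ss$grid
  mass <- sum(diff(g) * (ss$density[-1] + ss$density[-length(g)]) / 2)
  expect_equal(mass, 1, tolerance = 1e-6)
  # V -> 0+: mode approaches the deterministic fixed point (F/phi0)^(1/(1-alpha))
  xstar <- (1 / 2)^(1 / 0.25)
  ss_small <- steady_state_pdf(alpha = 0.75, beta = 0.75, F = 1, V = 0.01,
                               phi0_val = 2)
  expect_equal(ss_small$x_M, xstar, tolerance = 1e-3)
  # and the density mass concentrates around it
  g2 <- ss_small$grid
  d2 <- ss_small$density * (abs(g2 - xstar) / xstar < 0.2)
  mass_near <- sum(diff(g2) * (d2[-1] + d2[-length(g2)]) / 2)
  expect_gt(mass_near, 0.99)
})

test_that("generic branch converges to the equal branch at the boundary", {
  # 2 beta -> 1 + alpha: densities must agree pointwise after normalization
  eq <- steady_state_pdf(alpha = 0.5, beta = 0.75, F = 0.5, V = 0.5,
                         phi0_val = 0.5)
  near <- steady_state_pdf(alpha = 0.5 + 1e-7, beta = 0.75, F = 0.5, V = 0.5,
                           phi0_val = 0.5)
  expect_equal(near$branch, "generic")
  sel <- eq$grid > 1e-3
  expect_equal(near$density[sel], eq$density[sel], tolerance = 1e-3)
})

test_that("phase line follows the printed closed forms", {
  # beta = alpha, dominant taxon (phi0 = F): F_crit = 4 beta V^2 = 3 V^2
  expect_equal(critical_fitness(0.75, 0.75, V = 0.2), 0.12)
  # 2 beta = 1 + alpha: F_crit = beta V^2 independent of phi0
  expect_equal(critical_fitness(0.5, 0.75, V = 1, phi0_val = 2), 0.75)
  # bisection agrees with both closed forms to < 0.5 %
  for (V in c(0.1, 0.4)) {
    fc_bis <- critical_fitness(0.75, 0.75, V, method = "bisection")
    expect_lt(abs(fc_bis - 3 * V^2) / (3 * V^2), 0.005)
  }
  fc_eq <- critical_fitness(0.5, 0.75, V = 0.8, phi0_val = 1.3,
                            method = "bisection")
  expect_lt(abs(fc_eq - 0.75 * 0.64) / (0.75 * 0.64), 0.005)
})

test_that("interior mode appears and disappears across F = 3 V^2", {
  V <- 0.3
  above <- steady_state_pdf(0.75, 0.75, F = 3 * V^2 * 1.05, V = V,
                            phi0_val = 3 * V^2 * 1.05)
  below <- steady_state_pdf(0.75, 0.75, F = 3 * V^2 * 0.95, V = V,
                            phi0_val = 3 * V^2 * 0.95)
  expect_false(is.na(above$x_M))
  expect_true(is.na(below$x_M))
  d_above <- classify_phase(0.75, 0.75, F = 3 * V^2 * 1.05, V = V)
  d_below <- classify_phase(0.75, 0.75, F = 3 * V^2 * 0.95, V = V)
  expect_equal(d_above$phase, "ordered")
  expect_gt(d_above$margin, 0)
  expect_equal(d_below$phase, "disordered")
  expect_lt(d_below$margin, 0)
  # deep in the ordered phase
  deep <- classify_phase(0.75, 0.75, F = 50 * V^2, V = V)
  expect_equal(deep$phase, "ordered")
  expect_gt(deep$margin, 0)
})

test_that("stationary mode of a long simulation matches the Fokker-Planck mode", {
  F <- rep(1, 20)
  sim <- simulate_langevin(F, V = 0.1, dt = 0.002, n_steps = 150000,
                           seed = 7, record_every = 25)
  x <- sim$x[1, sim$times > 40]
  d <- stats::density(x)
  emp_mode <- d$x[which.max(d$y)]
  ss <- steady_state_pdf(0.75, 0.75, F = 1, V = 0.1,
                         phi0_val = phi0(F, 0.75))
  expect_lt(abs(emp_mode - ss$x_M) / ss$x_M, 0.10)
})

test_that("fitness is recovered from stationary fluctuations", {
  F <- rep(2, 10)
  p0 <- phi0(F, 0.75)
  sim <- simulate_langevin(F, V = 0.3, dt = 0.001, n_steps = 300000,
                           seed = 11, record_every = 100)
  keep <- sim$times > 50
  est <- infer_fitness(sim$x[1, keep], V = 0.3, phi0_val = p0)
  expect_false(est$boundary)
  expect_lt(abs(est$F - 2) / 2, 0.25)
  # identical series give identical estimates
  est2 <- infer_fitness(sim$x[1, keep], V = 0.3, phi0_val = p0)
  expect_identical(est$F, est2$F)
})

test_that("degenerate and bracket-limited inference are handled", {
  # a constant series still yields a finite interior optimum: the
  # self-consistent mode cannot sharpen indefinitely at a fixed location
  const <- rep(0.25, 50)
  est <- infer_fitness(const, V = 0.2)
  expect_true(is.finite(est$F))
  # a bracket that excludes the optimum is flagged
  expect_warning(est_b <- infer_fitness(const, V = 0.2,
                                        interval = c(10, 1e4)), "bracket")
  expect_true(est_b$boundary)
  expect_error(infer_fitness(c(0.1, 0.2), V = 0.2), "length >= 5")
  expect_error(infer_fitness(c(0.1, 0.2, 1.4, 0.2, 0.3), V = 0.2), "in \\(0, 1\\]")
})

test_that("autocorrelation estimator reads F as a relaxation rate", {
  set.seed(5)
  # AR(1) with lag-1 correlation exp(-F * dt): x_t around 0.5
  f_true <- 0.8
  dt <- 0.5
  rho <- exp(-f_true * dt)
  n <- 4000
  x <- numeric(n)
  x[1] <- 0.5
  for (i in 2:n) x[i] <- 0.5 + rho * (x[i - 1] - 0.5) + rnorm(1, 0, 0.02)
  x <- pmin(pmax(x, 1e-6), 1)
  est <- infer_fitness(x, V = 0.1, method = "autocorrelation", dt_obs = dt)
  expect_lt(abs(est$F - f_true) / f_true, 0.2)
})
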