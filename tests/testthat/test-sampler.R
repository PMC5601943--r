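test_that("theta = 0 gives the uniform law on the unit cube", {
  set.seed(10)
  sim <- sample_bounded_networks(c(0, 0), cgergm_spec(), n_nodes = 5,
                                 n_samples = 2000,
                                 control = sampler_control(burn_in = 300,
                                                           thin = 2))
  x <- as.numeric(sim$x)
  expect_equal(mean(x), 0.5, tolerance = 0.02)
  expect_equal(var(x), 1 / 12, tolerance = 0.01)
  expect_true(all(x >= 0 & x <= 1))
})

test_that("sampler mean matches the 1-D closed-form oracle (n = 2)", {
  # density proportional to e^x on [0, 1]: E[x] = 1 / (e - 1)
  set.seed(11)
  sim <- sample_bounded_networks(1, cgergm_spec("edges"), n_nodes = 2,
                                 n_samples = 20000,
                                 control = sampler_control(burn_in = 500,
                                                           thin = 2))
  target <- 1 / (exp(1) - 1)
  mc_se <- sd(sim$x) / sqrt(2000)   # conservative for autocorrelation
  expect_lt(abs(mean(sim$x) - target), 4 * mc_se)
})

test_that("sampler means match 3-D quadrature at n = 3 with both statistics", {
  theta <- c(-0.75, 0.34)
  k <- 120
  xs <- (seq_len(k) - 0.5) / k
  grid <- expand.grid(a = xs, b = xs, c = xs)
  P <- as.matrix(grid)^0.8
  H1 <- P[, 1] * P[, 2] + P[, 1] * P[, 3] + P[, 2] * P[, 3]
  H2 <- (grid$a * grid$b * grid$c)^0.4
  wts <- exp(theta[1] * H1 + theta[2] * H2)
  Eh <- c(sum(wts * H1), sum(wts * H2)) / sum(wts)
  set.seed(12)
  sim <- sample_bounded_networks(theta, cgergm_spec(), n_nodes = 3,
                                 n_samples = 20000,
                                 control = sampler_control(burn_in = 1000,
                                                           thin = 3))
  mc_se <- apply(sim$stats, 2, sd) / sqrt(2000)  # conservative
  expect_lt(abs(mean(sim$stats[, 1]) - Eh[1]), 4 * mc_se[1])
  expect_lt(abs(mean(sim$stats[, 2]) - Eh[2]), 4 * mc_se[2])
})

test_that("recorded statistics agree with statistic_vector recomputation", {
  set.seed(13)
  sp <- cgergm_spec()
  sim <- sample_bounded_networks(c(0.1, -0.1), sp, n_nodes = 6,
                                 n_samples = 20,
                                 control = sampler_control(burn_in = 100,
                                                           thin = 2))
  for (s in c(1, 10, 20))
    expect_equal(unname(sim$stats[s, ]),
                 unname(statistic_vector(sim$x[s, ], sp)),
                 tolerance = 1e-8)
})

test_that("sampling is reproducible given a seed", {
  sp <- cgergm_spec()
  a <- sample_bounded_networks(c(0.2, 0.1), sp, 5, n_samples = 50,
                               control = sampler_control(burn_in = 100),
                               seed = 99)
  b <- sample_bounded_networks(c(0.2, 0.1), sp, 5, n_samples = 50,
                               control = sampler_control(burn_in = 100),
                               seed = 99)
  expect_identical(a$x, b$x)
})

test_that("theta length must match the specification", {
  expect_error(sample_bounded_networks(c(1, 2, 3), cgergm_spec(), 4),
               "one entry per statistic")
})

test_that("simulated correlation networks are valid PSD matrices", {
  sims <- simulate_correlation_networks(8, c(-0.3, 0.2), beta = 0.4,
                                        alpha = 30, nsim = 5,
                                        control = sampler_control(burn_in = 300,
                                                                  thin = 2),
                                        seed = 14)
  for (rho in sims) {
    expect_equal(dim(rho), c(8, 8))
    expect_silent(validate_correlation(rho))
  }
})

test_that("theta = 0 generative marginals are the rescaled Beta law", {
  # with no topological tilt, (phi + 1)/2 ~ Beta(mu alpha, (1 - mu) alpha)
  out <- simulate_correlation_networks(10, c(0, 0), beta = 0.25,
                                       alpha = 38.28, nsim = 40,
                                       control = sampler_control(burn_in = 400,
                                                                 thin = 5),
                                       seed = 15, return_all = TRUE)
  w <- (as.numeric(out$phi) + 1) / 2
  mu <- plogis(0.25)
  ks <- suppressWarnings(ks.test(w, pbeta, mu * 38.28, (1 - mu) * 38.28))
  expect_gt(ks$p.value, 0.001)
})

test_that("max-entropy interval matches the hand-computed wedge bound", {
  # rho12 = rho23 = 0.8: feasible rho13 in [2 * 0.64 - 1, 1] = [0.28, 1]
  rho <- diag(3)
  rho[1, 2] <- rho[2, 1] <- 0.8
  rho[2, 3] <- rho[3, 2] <- 0.8
  rho[1, 3] <- rho[3, 1] <- 0.5
  d <- max_entropy_edge_draws(rho, c(1, 3), n_draws = 3000, seed = 16)
  int <- attr(d, "interval")
  expect_equal(int[1], 0.28, tolerance = 1e-6)
  expect_equal(int[2], 1, tolerance = 1e-6)
  expect_true(all(d >= int[1] & d <= int[2]))
  ks <- suppressWarnings(ks.test(d, punif, int[1], int[2]))
  expect_gt(ks$p.value, 0.001)
})

test_that("max_entropy_edge_draws accepts a dyad index and is seeded", {
  rho <- partial_to_correlation(c(0.3, 0.1, -0.2))
  a <- max_entropy_edge_draws(rho, 2, n_draws = 10, seed = 5)
  b <- max_entropy_edge_draws(rho, c(1, 3), n_draws = 10, seed = 5)
  expect_identical(as.numeric(a), as.numeric(b))
})

test_that("single-edge conditional chain only moves the chosen edge", {
  sp <- cgergm_spec()
  x0 <- rep(0.5, 10)   # n = 5
  d <- cgergm:::sample_single_edge(c(0.2, -0.1), sp, x0, edge = 3,
                                   n_samples = 50)
  expect_length(d, 50)
  expect_true(all(d >= 0 & d <= 1))
  expect_gt(var(d), 0)
})

test_that("the theta = 0 single-edge conditional is uniform", {
  set.seed(17)
  d <- cgergm:::sample_single_edge(0, cgergm_spec("edges"), rep(0.5, 6),
                                   edge = 2, n_samples = 4000,
                                   burn_in = 300, thin = 2)
  ks <- suppressWarnings(ks.test(d, punif))
  expect_gt(ks$p.value, 0.001)
})
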