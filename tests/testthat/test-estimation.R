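test_that("fit_beta_regression recovers known parameters within noise", {
  set.seed(20)
  mu <- plogis(0.5)
  w <- rbeta(500, mu * 40, (1 - mu) * 40)
  phi <- 2 * w - 1
  fit <- fit_beta_regression(phi)
  expect_lt(abs(fit$beta[["edges"]] - 0.5), 3 * fit$se_beta[["edges"]])
  expect_lt(abs(fit$alpha - 40), 3 * fit$se_alpha)
  expect_true(fit$converged)
})

test_that("fit_beta_regression agrees with an independent optimizer", {
  set.seed(21)
  z <- rnorm(300)
  design <- cbind(edges = 1, z = z)
  mu <- plogis(0.3 - 0.2 * z)
  w <- rbeta(300, mu * 25, (1 - mu) * 25)
  phi <- 2 * w - 1
  fit <- fit_beta_regression(phi, design)
  # independently coded negative log-likelihood, different optimizer
  nll <- function(par) {
    m <- plogis(drop(design %*% par[1:2]))
    -sum(dbeta(w, m * exp(par[3]), (1 - m) * exp(par[3]), log = TRUE))
  }
  alt <- optim(c(0, 0, log(10)), nll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  expect_equal(-alt$value, fit$logLik, tolerance = 1e-5)
  expect_equal(unname(alt$par[1:2]), unname(fit$beta), tolerance = 1e-3)
  expect_equal(exp(alt$par[3]), fit$alpha, tolerance = 1e-3)
})

test_that("fit_beta_regression validates its inputs", {
  expect_error(fit_beta_regression(rep(0, 10), design = matrix(1, 3, 1)),
               "match the number of dyads")
  expect_error(fit_beta_regression(rep(0, 10),
                                   design = cbind(1, rep(2, 10))),
               "rank deficient")
})

test_that("a statistics-free cgergm fit reduces to Beta regression", {
  set.seed(22)
  rho <- simulate_correlation_networks(10, c(0, 0), beta = 0.5, alpha = 40,
                                       nsim = 1, seed = 22)[[1]]
  fit <- cgergm(rho, statistics = character(0))
  breg <- fit_beta_regression(correlation_to_partial(rho))
  expect_equal(unname(fit$beta), unname(breg$beta), tolerance = 1e-6)
  expect_equal(fit$alpha, breg$alpha, tolerance = 1e-6)
  expect_equal(length(fit$theta), 0)
  expect_equal(unname(coef(fit)),
               unname(c(breg$beta, breg$alpha)), tolerance = 1e-6)
})

test_that("cgergm returns a complete classed fit and is seed-reproducible", {
  set.seed(23)
  rho <- simulate_correlation_networks(8, c(0, 0), beta = 0.4, alpha = 35,
                                       nsim = 1, seed = 23)[[1]]
  ctl <- cgergm_control(mc_samples = 100,
                        sampler = sampler_control(burn_in = 200, thin = 2))
  fit <- cgergm(rho, control = ctl, seed = 5)
  expect_s3_class(fit, "cgergm")
  expect_named(coef(fit), c("two_stars", "triads", "edges", "dispersion"))
  expect_true(all(is.finite(fit$std_errors)))
  expect_true(all(dim(vcov(fit)) == c(4, 4)))
  expect_equal(nrow(fit$reference_sample$x), 100)
  expect_output(print(fit), "Correlation GERGM fit")
  expect_output(print(summary(fit)), "two_stars")
  expect_length(residuals(fit), 28)
  fit2 <- cgergm(rho, control = ctl, seed = 5)
  expect_identical(coef(fit), coef(fit2))
})

test_that("cgergm honours a custom statistic specification", {
  set.seed(24)
  rho <- simulate_correlation_networks(8, 0, beta = 0.2, alpha = 30,
                                       spec = cgergm_spec("two_stars"),
                                       nsim = 1, seed = 24)[[1]]
  ctl <- cgergm_control(mc_samples = 100,
                        sampler = sampler_control(burn_in = 200, thin = 2))
  fit <- cgergm(rho, statistics = "two_stars", control = ctl, seed = 6)
  expect_named(coef(fit), c("two_stars", "edges", "dispersion"))
  expect_equal(fit$spec$statistics, "two_stars")
})

test_that("cgergm carries dyadic covariates through the regression", {
  set.seed(25)
  fx <- generate_fixture_dmn(n_nodes = 12, seed = 3)
  ctl <- cgergm_control(mc_samples = 100,
                        sampler = sampler_control(burn_in = 200, thin = 2))
  fit <- cgergm(fx$rho, covariates = fx$covariates, control = ctl, seed = 7)
  expect_named(coef(fit), c("two_stars", "triads", "edges", "hemisphere",
                            "distance", "dispersion"))
  expect_equal(ncol(fit$design), 3)
})

test_that("wald_tests reproduces hand-computed z statistics", {
  fake <- structure(list(coefficients = c(a = 0, b = 0.478, c = 0.033),
                         std_errors = c(a = 1, b = 0.033, c = 0)),
                    class = "cgergm")
  wt <- wald_tests(fake)
  expect_equal(wt$z[1], 0)
  expect_false(wt$significant[1])
  expect_equal(wt$z[2], 0.478 / 0.033, tolerance = 1e-12)
  expect_true(wt$significant[2])
  expect_gt(wt$z[2], 14.4)
  # zero s.e. -> NA flag, not an error
  expect_true(is.na(wt$significant[3]))
})

test_that("wald_tests flags the exact critical value as significant", {
  crit <- qnorm(0.975)
  fake <- structure(list(coefficients = c(a = crit), std_errors = c(a = 1)),
                    class = "cgergm")
  expect_true(wald_tests(fake)$significant[1])
})

test_that("simulate.cgergm draws valid networks from the fitted model", {
  set.seed(26)
  rho <- simulate_correlation_networks(7, c(0, 0), beta = 0.3, alpha = 30,
                                       nsim = 1, seed = 26)[[1]]
  ctl <- cgergm_control(mc_samples = 50,
                        sampler = sampler_control(burn_in = 100, thin = 2))
  fit <- cgergm(rho, control = ctl, seed = 8)
  sims <- simulate(fit, nsim = 3, seed = 9)
  expect_length(sims, 3)
  for (s in sims) expect_silent(validate_correlation(s))
})

test_that("the fitted intercept tracks the generative intercept at theta = 0", {
  set.seed(27)
  rho <- simulate_correlation_networks(20, c(0, 0), beta = 0.5, alpha = 40,
                                       nsim = 1, seed = 27)[[1]]
  ctl <- cgergm_control(mc_samples = 200,
                        sampler = sampler_control(burn_in = 300, thin = 3))
  fit <- cgergm(rho, control = ctl, seed = 10)
  expect_lt(abs(fit$beta[["edges"]] - 0.5), 3 * fit$std_errors[["edges"]])
  # theta estimates should be within noise of zero
  wt <- wald_tests(fit)
  expect_true(all(abs(wt$z[1:2]) < 4))
})
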