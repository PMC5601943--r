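test_that("dyad_pairs enumerates the row-major upper triangle", {
  expect_equal(cgergm:::dyad_pairs(4),
               cbind(i = c(1L, 1L, 1L, 2L, 2L, 3L),
                     j = c(2L, 3L, 4L, 3L, 4L, 4L)))
  expect_equal(nrow(cgergm:::dyad_pairs(20)), 190)
})

test_that("n_from_m inverts the dyad count and rejects impossible lengths", {
  for (n in 2:12) expect_equal(cgergm:::n_from_m(n * (n - 1) / 2), n)
  expect_error(cgergm:::n_from_m(4), "not n\\(n-1\\)/2")
})

test_that("vec_to_sym / sym_to_vec are inverse in the canonical order", {
  v <- c(12, 13, 14, 23, 24, 34)
  M <- cgergm:::vec_to_sym(v, 4)
  expect_equal(M[1, 2], 12)
  expect_equal(M[1, 4], 14)
  expect_equal(M[3, 4], 34)
  expect_true(isSymmetric(M))
  expect_equal(cgergm:::sym_to_vec(M), v)
})

test_that("validate_correlation rejects malformed inputs with specific errors", {
  expect_error(validate_correlation(matrix(1, 2, 3)), "square")
  A <- diag(3); A[1, 2] <- 0.5
  expect_error(validate_correlation(A), "not symmetric")
  B <- diag(3); B[1, 1] <- 0.9
  expect_error(validate_correlation(B), "is not 1")
  C <- matrix(c(1, 1.2, 1.2, 1), 2, 2)
  expect_error(validate_correlation(C), "outside")
  D <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(validate_correlation(D), "positive semidefinite")
  E <- diag(3); E[is.na(E)] <- 0; E[1, 2] <- E[2, 1] <- NA
  expect_error(validate_correlation(E), "non-finite")
})

test_that("partial_to_correlation reproduces the hand-computed n = 3 entry", {
  # phi = (phi12, phi13, phi23) = (0.6, 0.2, 0.5):
  # rho13 = rho12 rho23 + phi13 sqrt((1 - rho12^2)(1 - rho23^2))
  rho <- partial_to_correlation(c(0.6, 0.2, 0.5))
  expect_equal(rho[1, 2], 0.6)
  expect_equal(rho[2, 3], 0.5)
  expect_equal(rho[1, 3], 0.3 + 0.2 * sqrt(0.64 * 0.75))
  # zero partial for the wide band means the product alone
  rho0 <- partial_to_correlation(c(0.6, 0, 0.5))
  expect_equal(rho0[1, 3], 0.3)
})

test_that("any phi in (-1,1)^m yields a valid correlation matrix (PSD property)", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(3:8, 1)
    phi <- runif(n * (n - 1) / 2, -0.99, 0.99)
    rho <- partial_to_correlation(phi)
    expect_true(all(abs(rho) <= 1 + 1e-12))
    expect_equal(diag(rho), rep(1, n))
    lam <- min(eigen(rho, symmetric = TRUE, only.values = TRUE)$values)
    expect_gte(lam, -1e-10)
  }
})

test_that("correlation_to_partial inverts partial_to_correlation", {
  set.seed(7)
  for (n in 3:8) {
    phi <- runif(n * (n - 1) / 2, -0.95, 0.95)
    back <- correlation_to_partial(partial_to_correlation(phi))
    expect_equal(as.numeric(back), phi, tolerance = 1e-10)
  }
})

test_that("correlation_to_partial records the node ordering", {
  rho <- partial_to_correlation(c(0.3, 0.1, -0.2),
                                node_ids = c("a", "b", "c"))
  phi <- correlation_to_partial(rho)
  expect_equal(attr(phi, "ordering"), c("a", "b", "c"))
})

test_that("near-singular matrices are shrunk with a warning, not an error", {
  # a rank-deficient 3-node matrix: rho = outer(v, v) with unit diagonal
  v <- c(1, 1, 1)
  rho <- outer(v, v); diag(rho) <- 1
  r <- 1 - 1e-12
  rho[1, 2] <- rho[2, 1] <- r
  rho[1, 3] <- rho[3, 1] <- r
  rho[2, 3] <- rho[3, 2] <- r
  expect_warning(phi <- correlation_to_partial(rho), "singular")
  expect_true(all(abs(phi) < 1))
})

test_that("jacobian_log_det matches the analytic n = 3 value", {
  # only phi12 = 0.6 nonzero: det d rho / d phi = (1 - 0.36)^{(3-1-1)/2} = 0.8
  phi <- c(0.6, 0, 0)
  expect_equal(exp(jacobian_log_det(phi, "partial_to_correlation")), 0.8)
  expect_equal(exp(jacobian_log_det(phi, "correlation_to_partial")), 1.25)
})

test_that("jacobian_log_det matches a finite-difference determinant", {
  g <- function(phi) cgergm:::sym_to_vec(partial_to_correlation(phi))
  set.seed(3)
  for (n in 3:6) {
    m <- n * (n - 1) / 2
    phi <- runif(m, -0.7, 0.7)
    J <- matrix(NA_real_, m, m)
    h <- 1e-6
    for (e in seq_len(m)) {
      up <- phi; up[e] <- up[e] + h
      dn <- phi; dn[e] <- dn[e] - h
      J[, e] <- (g(up) - g(dn)) / (2 * h)
    }
    ld_num <- determinant(J, logarithm = TRUE)$modulus[1]
    ld <- jacobian_log_det(phi, "partial_to_correlation")
    expect_equal(ld, ld_num, tolerance = 1e-5)
  }
})

test_that("the widest band carries Jacobian exponent zero", {
  # n = 3: varying phi13 alone must not change the determinant
  expect_equal(jacobian_log_det(c(0.5, 0, 0.2)),
               jacobian_log_det(c(0.5, 0.9, 0.2)))
})

test_that("beta_cdf_map reproduces the closed-form Beta(1, 3) value", {
  # mu = 0.25, alpha = 4 -> shapes (1, 3); phi = 0 -> w = 0.5 ->
  # F(0.5) = 1 - (1 - 0.5)^3 = 0.875
  expect_equal(beta_cdf_map(0, mu = 0.25, alpha = 4), 0.875)
  # symmetric case: mu = 0.5 maps phi = 0 to 0.5 for any alpha
  expect_equal(beta_cdf_map(0, mu = 0.5, alpha = 17), 0.5)
})

test_that("beta_cdf_map and beta_cdf_inverse are inverse and monotone", {
  mu <- 0.62; alpha <- 38
  phi <- seq(-0.95, 0.95, length.out = 41)
  x <- beta_cdf_map(phi, mu, alpha)
  expect_true(all(diff(x) > 0))
  expect_true(all(x >= 0 & x <= 1))
  # qbeta loses a few digits where the density is tiny (deep tails)
  expect_equal(beta_cdf_inverse(x, mu, alpha), phi, tolerance = 1e-5)
})

test_that("beta parameter validation is strict", {
  expect_error(beta_cdf_map(0, mu = 0.5, alpha = -1), "positive")
  expect_error(beta_cdf_map(0, mu = 1.5, alpha = 2), "strictly in \\(0, 1\\)")
  expect_error(beta_cdf_inverse(2, mu = 0.5, alpha = 2), "\\[0, 1\\]")
})

test_that("link_mean applies the logit link over the design", {
  design <- cbind(1, c(-1, 0, 1))
  beta <- c(0.5, 0.3)
  expect_equal(link_mean(design, beta), plogis(c(0.2, 0.5, 0.8)))
  expect_error(link_mean(design, c(1, 2, 3)), "conformable")
})
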