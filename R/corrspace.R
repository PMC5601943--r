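#' @useDynLib cgergm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pbeta qbeta plogis qlogis optim cov median quantile
#'   pnorm runif rnorm sd ks.test ecdf dbeta rbeta integrate setNames
#' @importFrom utils read.csv write.csv read.delim
NULL

## Dyad ordering convention used throughout the package: row-major upper
## triangle of the canonical node order, i.e. (1,2), (1,3), ..., (1,n),
## (2,3), ..., (n-1,n).  Partial correlations phi[j, j+k] are defined
## relative to this node order (the conditioning set is the nodes strictly
## between j and j+k).

#' Dyad index helpers
#'
#' `dyad_pairs()` enumerates the m = n(n-1)/2 unordered node pairs in the
#' package's canonical order (row-major upper triangle); `n_from_m()` inverts
#' the count.
#'
#' @param n number of nodes.
#' @return `dyad_pairs()`: an m x 2 integer matrix with columns `i < j`.
#' @keywords internal
dyad_pairs <- function(n) {
  stopifnot(n >= 2)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n), use.names = FALSE)
  cbind(i = i, j = as.integer(j))
}

#' @rdname dyad_pairs
#' @param m number of dyads.
#' @keywords internal
n_from_m <- function(m) {
  n <- (1 + sqrt(1 + 8 * m)) / 2
  if (abs(n - round(n)) > 1e-8)
    stop("length ", m, " is not n(n-1)/2 for any integer n", call. = FALSE)
  as.integer(round(n))
}

## vector <-> symmetric matrix with zero/unit diagonal
vec_to_sym <- function(v, n, diag = 0) {
  M <- matrix(0, n, n)
  M[lower.tri(M)] <- v        # fill column-major lower = row-major upper of t(M)
  M <- t(M)
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  diag(M) <- diag
  M
}

sym_to_vec <- function(M) {
  t(M)[lower.tri(M)]           # row-major upper triangle
}

#' Validate a correlation matrix
#'
#' Checks symmetry, unit diagonal, entry bounds and positive
#' semidefiniteness.  Asymmetries below `tol_sym` are symmetrized silently;
#' larger ones are an error.
#'
#' @param rho square numeric matrix.
#' @param tol_eig eigenvalue tolerance: smallest eigenvalue must be
#'   `>= -tol_eig`.
#' @param tol_sym maximum absolute asymmetry symmetrized without error.
#' @return the validated (symmetrized) matrix, invisibly usable downstream.
#' @export
validate_correlation <- function(rho, tol_eig = 1e-8, tol_sym = 1e-12) {
  if (!is.matrix(rho) || !is.numeric(rho) || nrow(rho) != ncol(rho))
    stop("correlation input must be a square numeric matrix", call. = FALSE)
  if (anyNA(rho) || any(!is.finite(rho)))
    stop("correlation matrix contains non-finite values", call. = FALSE)
  asym <- max(abs(rho - t(rho)))
  if (asym > tol_sym)
    stop(sprintf("matrix is not symmetric (max |rho - t(rho)| = %.3g)", asym),
         call. = FALSE)
  rho <- (rho + t(rho)) / 2
  bad <- which(abs(rho) > 1 + 1e-12, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("entry [%d, %d] = %.4g lies outside [-1, 1]",
                 bad[1, 1], bad[1, 2], rho[bad[1, 1], bad[1, 2]]), call. = FALSE)
  dbad <- which(abs(diag(rho) - 1) > 1e-10)
  if (length(dbad) > 0)
    stop(sprintf("diagonal entry [%d, %d] = %.4g is not 1",
                 dbad[1], dbad[1], rho[dbad[1], dbad[1]]), call. = FALSE)
  lam <- min(eigen(rho, symmetric = TRUE, only.values = TRUE)$values)
  if (lam < -tol_eig)
    stop(sprintf("matrix is not positive semidefinite (min eigenvalue %.3g)",
                 lam), call. = FALSE)
  rho
}

#' Map partial correlations to a correlation matrix
#'
#' Reconstructs the n x n correlation matrix from the unconstrained vector of
#' partial correlations phi, where `phi[j, j+k]` is the partial correlation
#' of nodes j and j+k given the nodes strictly between them.  Any phi in
#' (-1, 1)^m yields a valid (positive semidefinite, unit-diagonal)
#' correlation matrix, which is what makes this parameterization the
#' backbone of the generative model.
#'
#' The recursion fills the matrix by increasing band k: for k = 1 the
#' correlation equals the partial correlation; for k >= 2,
#' `rho[j, j+k] = r1' D^{-1} r2 + phi[j, j+k] * C`, with r1, r2 the
#' correlations of j (resp. j+k) with the intermediate nodes, D their
#' correlation block, and `C^2 = (1 - r1' D^{-1} r1)(1 - r2' D^{-1} r2)`.
#'
#' @param phi numeric vector of length n(n-1)/2 with entries strictly in
#'   (-1, 1), in the canonical dyad order.
#' @param node_ids optional dimnames for the result.
#' @return the correlation matrix.
#' @seealso [correlation_to_partial()] for the inverse map.
#' @export
partial_to_correlation <- function(phi, node_ids = NULL) {
  n <- n_from_m(length(phi))
  if (any(abs(phi) >= 1))
    stop("all partial correlations must lie strictly in (-1, 1)", call. = FALSE)
  P <- vec_to_sym(phi, n, diag = 1)
  R <- diag(n)
  # band k = 1
  for (j in seq_len(n - 1)) R[j, j + 1] <- R[j + 1, j] <- P[j, j + 1]
  for (k in seq_len(n - 1)[-1]) {
    for (j in seq_len(n - k)) {
      idx <- (j + 1):(j + k - 1)
      r1 <- R[j, idx]
      r2 <- R[j + k, idx]
      D <- R[idx, idx, drop = FALSE]
      sol <- tryCatch(solve(D, cbind(r1, r2)), error = function(e) NULL)
      if (is.null(sol))
        stop(sprintf(
          "numerical degeneracy: conditioning block D for pair (%d, %d) is singular",
          j, j + k), call. = FALSE)
      c2 <- (1 - sum(r1 * sol[, 1])) * (1 - sum(r2 * sol[, 2]))
      C <- sqrt(max(c2, 0))
      R[j, j + k] <- R[j + k, j] <- sum(r1 * sol[, 2]) + phi_entry(P, j, j + k) * C
    }
  }
  if (!is.null(node_ids)) dimnames(R) <- list(node_ids, node_ids)
  R
}

phi_entry <- function(P, a, b) P[a, b]

#' Map a correlation matrix to partial correlations
#'
#' Inverts [partial_to_correlation()]: extracts, band by band, the partial
#' correlation of each pair given the nodes between them.  Requires a
#' strictly positive definite input; positive semidefinite but singular
#' matrices are shrunk toward the identity (`rho <- (1 - lambda) rho +
#' lambda I`, `lambda = 1e-8`) with a warning.
#'
#' @param rho validated correlation matrix.
#' @param tol_pd smallest eigenvalue below which shrinkage is applied.
#' @return numeric vector phi of length n(n-1)/2 in the canonical dyad order,
#'   with attribute `"ordering"` carrying the node labels the
#'   parameterization is relative to.
#' @export
correlation_to_partial <- function(rho, tol_pd = 1e-10) {
  rho <- validate_correlation(rho)
  n <- nrow(rho)
  lam <- min(eigen(rho, symmetric = TRUE, only.values = TRUE)$values)
  if (lam <= tol_pd) {
    warning("correlation matrix is (near-)singular; shrinking toward identity",
            call. = FALSE)
    lambda <- 1e-8
    rho <- (1 - lambda) * rho + lambda * diag(n)
  }
  P <- diag(n)
  for (j in seq_len(n - 1)) P[j, j + 1] <- P[j + 1, j] <- rho[j, j + 1]
  if (n > 2) {
    for (k in seq_len(n - 1)[-1]) {
      for (j in seq_len(n - k)) {
        idx <- (j + 1):(j + k - 1)
        r1 <- rho[j, idx]
        r2 <- rho[j + k, idx]
        D <- rho[idx, idx, drop = FALSE]
        sol <- solve(D, cbind(r1, r2))
        c2 <- (1 - sum(r1 * sol[, 1])) * (1 - sum(r2 * sol[, 2]))
        if (c2 <= 0)
          stop(sprintf(
            "numerical degeneracy at pair (%d, %d): conditional variance is zero",
            j, j + k), call. = FALSE)
        p <- (rho[j, j + k] - sum(r1 * sol[, 2])) / sqrt(c2)
        P[j, j + k] <- P[j + k, j] <- p
      }
    }
  }
  phi <- sym_to_vec(P)
  ord <- if (!is.null(rownames(rho))) rownames(rho) else as.character(seq_len(n))
  attr(phi, "ordering") <- ord
  phi
}

#' Log Jacobian determinant of the partial-correlation map
#'
#' The map g: phi -> rho is lower triangular when dyads are ordered by
#' increasing band, so its Jacobian determinant is the product of the
#' conditional-scale factors `C[j, j+k]`, which reduces to
#' `prod_{k=1}^{n-2} prod_j (1 - phi[j, j+k]^2)^{(n-k-1)/2}`.
#' The widest band (k = n-1) carries exponent zero.  The reported value is
#' validated in the test suite against a finite-difference determinant of g.
#'
#' @param phi partial-correlation vector, all entries strictly in (-1, 1).
#' @param direction `"partial_to_correlation"` returns log|det d rho / d phi|
#'   (non-positive); `"correlation_to_partial"` returns its negative, the
#'   Jacobian used when a density on phi is pushed to correlation space.
#' @return a single number, the log absolute Jacobian determinant.
#' @export
jacobian_log_det <- function(phi,
                             direction = c("partial_to_correlation",
                                           "correlation_to_partial")) {
  direction <- match.arg(direction)
  n <- n_from_m(length(phi))
  if (any(abs(phi) >= 1))
    stop("all partial correlations must lie strictly in (-1, 1)", call. = FALSE)
  pr <- dyad_pairs(n)
  k <- pr[, 2] - pr[, 1]
  expo <- (n - k - 1) / 2
  ld <- sum(expo * log1p(-phi^2))
  if (direction == "correlation_to_partial") -ld else ld
}

## numeric guard for open-interval quantities
.phi_eps <- 1e-9

clip_open <- function(x, lo = -1, hi = 1, eps = .phi_eps) {
  pmin(pmax(x, lo + eps), hi - eps)
}

check_beta_pars <- function(mu, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) || alpha <= 0)
    stop("dispersion alpha must be a single positive number", call. = FALSE)
  if (any(!is.finite(mu)) || any(mu <= 0) || any(mu >= 1))
    stop("all mean-surface entries must lie strictly in (0, 1)", call. = FALSE)
}

#' Beta-CDF map between partial-correlation and bounded space
#'
#' `beta_cdf_map()` sends each partial correlation phi_ij to
#' `x_ij = F((phi_ij + 1)/2; mu_ij * alpha, (1 - mu_ij) * alpha)`, the CDF of
#' a Beta distribution in the mean/precision parameterization.
#' `beta_cdf_inverse()` applies the quantile function and returns
#' `phi_ij = 2 * F^{-1}(x_ij) - 1`.  When the model has no topological
#' structure the bounded values are uniform, so the inverse map is exactly
#' the Beta-regression sampling step of the generative process.
#'
#' @param phi partial-correlation vector (entries clipped into
#'   `(-1 + 1e-9, 1 - 1e-9)` before the map).
#' @param x bounded vector in `[0, 1]` (boundary values return clipped phi).
#' @param mu mean surface, entries strictly in (0, 1); scalar recycled.
#' @param alpha Beta precision, `> 0`.
#' @return a vector the same length as the input.
#' @export
beta_cdf_map <- function(phi, mu, alpha) {
  check_beta_pars(mu, alpha)
  phi <- clip_open(phi)
  pbeta((phi + 1) / 2, shape1 = mu * alpha, shape2 = (1 - mu) * alpha)
}

#' @rdname beta_cdf_map
#' @export
beta_cdf_inverse <- function(x, mu, alpha) {
  check_beta_pars(mu, alpha)
  if (any(x < 0) || any(x > 1))
    stop("bounded-network values must lie in [0, 1]", call. = FALSE)
  w <- qbeta(x, shape1 = mu * alpha, shape2 = (1 - mu) * alpha)
  clip_open(2 * w - 1)
}

#' Dyadic mean surface from covariates
#'
#' Computes `mu_ij = logit^{-1}(beta0 + sum_r beta_r z_ij(r))` over all
#' dyads.  The first column of the design matrix is the intercept (the
#' "edges" feature of the model).
#'
#' @param design m x (q + 1) numeric design matrix; first column all ones.
#' @param beta coefficient vector of length q + 1.
#' @return mean surface vector, entries strictly in (0, 1).
#' @export
link_mean <- function(design, beta) {
  design <- as.matrix(design)
  if (any(!is.finite(design)))
    stop("covariate design contains non-finite values", call. = FALSE)
  if (ncol(design) != length(beta))
    stop("design and coefficient vector are not conformable", call. = FALSE)
  eta <- drop(design %*% beta)
  mu <- plogis(eta)
  pmin(pmax(mu, .phi_eps), 1 - .phi_eps)
}
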