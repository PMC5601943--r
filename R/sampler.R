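#' Sampler settings
#'
#' Settings for the Metropolis-Hastings sampler on the bounded network.  One
#' iteration is a systematic sweep over all m edges with a reflected
#' Gaussian random-walk proposal; the proposal scale is tuned during burn-in
#' toward ~25% acceptance and then frozen.
#'
#' @param burn_in sweeps discarded before retention.
#' @param thin retain every `thin`-th sweep.
#' @param proposal_sd initial random-walk standard deviation.
#' @param tune logical; adapt `proposal_sd` during burn-in.
#' @return a list of class `"cgergm_sampler_control"`.
#' @export
sampler_control <- function(burn_in = 1000, thin = 10, proposal_sd = 0.2,
                            tune = TRUE) {
  stopifnot(burn_in >= 0, thin >= 1, proposal_sd > 0)
  structure(list(burn_in = as.integer(burn_in), thin = as.integer(thin),
                 proposal_sd = proposal_sd, tune = isTRUE(tune)),
            class = "cgergm_sampler_control")
}

#' Sample bounded networks from the exponential-family density
#'
#' Draws from `f(x) = exp(theta' h(x)) / Z` on `[0, 1]^m` by
#' Metropolis-Hastings.  With `theta = 0` the stationary law is uniform on
#' the unit cube.
#'
#' @param theta coefficient vector aligned with `spec$statistics`.
#' @param spec a [cgergm_spec()].
#' @param n_nodes number of nodes n (m = n(n-1)/2 edges).
#' @param n_samples retained draws.
#' @param control a [sampler_control()].
#' @param init optional starting m-vector in `[0, 1]`; defaults to all 0.5.
#' @param seed optional integer seed (applied via `set.seed`).
#' @return list with `x` (n_samples x m matrix of draws), `stats`
#'   (n_samples x p statistic values), `acceptance` (post-burn-in per-edge
#'   acceptance rate) and `proposal_sd` (final, post-tuning).
#' @export
sample_bounded_networks <- function(theta, spec, n_nodes, n_samples = 500,
                                    control = sampler_control(),
                                    init = NULL, seed = NULL) {
  stopifnot(inherits(spec, "cgergm_spec"))
  p <- length(spec$statistics)
  if (length(theta) != p)
    stop("theta must have one entry per statistic in the specification",
         call. = FALSE)
  m <- n_nodes * (n_nodes - 1) / 2
  if (is.null(init)) init <- rep(0.5, m)
  if (!is.null(seed)) set.seed(seed)
  res <- mh_sample_cpp(as.integer(n_nodes), as.numeric(theta), stat_ids(spec),
                       unname(spec$downweights[spec$statistics]),
                       as.numeric(init), as.integer(n_samples),
                       control$burn_in, control$thin,
                       control$proposal_sd, control$tune, -1L)
  colnames(res$stats) <- spec$statistics
  res
}

## single-coordinate chain used by conditional edgewise prediction
sample_single_edge <- function(theta, spec, x_fixed, edge, n_samples,
                               burn_in = 200, thin = 2, proposal_sd = 0.2) {
  n <- n_from_m(length(x_fixed))
  res <- mh_sample_cpp(as.integer(n), as.numeric(theta), stat_ids(spec),
                       unname(spec$downweights[spec$statistics]),
                       as.numeric(x_fixed), as.integer(n_samples),
                       as.integer(burn_in), as.integer(thin),
                       proposal_sd, TRUE, as.integer(edge - 1L))
  res$x[, edge]
}

#' Simulate correlation networks from the generative model
#'
#' Runs the full generative process: draw bounded networks x from the
#' exponential-family density at `theta`, map each through the inverse
#' Beta-CDF transform (mean surface from the covariate regression, precision
#' `alpha`) to partial correlations, and reconstruct positive-semidefinite
#' correlation matrices via the recursion.  With `theta = 0` the partial
#' correlations are independent Beta draws rescaled to (-1, 1).
#'
#' @param n_nodes number of nodes.
#' @param theta topological coefficients (aligned with `spec`).
#' @param beta regression coefficients, intercept first.
#' @param alpha Beta precision (> 0).
#' @param spec a [cgergm_spec()].
#' @param design optional m x (q+1) design matrix (intercept column first);
#'   defaults to intercept-only.
#' @param nsim number of networks.
#' @param control a [sampler_control()].
#' @param seed optional integer seed.
#' @param return_all logical; also return the bounded and partial-correlation
#'   draws.
#' @return a list of `nsim` correlation matrices, or (with
#'   `return_all = TRUE`) a list with elements `rho`, `phi`, `x`.
#' @export
simulate_correlation_networks <- function(n_nodes, theta, beta, alpha,
                                          spec = cgergm_spec(),
                                          design = NULL, nsim = 1,
                                          control = sampler_control(),
                                          seed = NULL, return_all = FALSE) {
  m <- n_nodes * (n_nodes - 1) / 2
  if (is.null(design)) design <- matrix(1, m, 1)
  mu <- link_mean(design, beta)
  draws <- sample_bounded_networks(theta, spec, n_nodes, n_samples = nsim,
                                   control = control, seed = seed)
  phi <- t(apply(draws$x, 1, beta_cdf_inverse, mu = mu, alpha = alpha))
  if (nsim == 1) phi <- matrix(phi, nrow = 1)
  rho <- lapply(seq_len(nsim), function(s) partial_to_correlation(phi[s, ]))
  if (return_all) list(rho = rho, phi = phi, x = draws$x) else rho
}

#' Maximum-entropy conditional draws for a single correlation entry
#'
#' Holding every other entry of `rho` fixed, the values of entry
#' `(i, j)` that keep the matrix positive semidefinite form an interval;
#' the maximum-entropy distribution on it is uniform.  The interval is
#' located by bisection on the smallest eigenvalue.
#'
#' @param rho validated correlation matrix.
#' @param edge length-2 integer vector (i, j) or a single dyad index in the
#'   canonical order.
#' @param n_draws number of uniform draws.
#' @param seed optional integer seed.
#' @return numeric vector of draws with attribute `"interval" = c(l, u)`.
#' @export
max_entropy_edge_draws <- function(rho, edge, n_draws = 500, seed = NULL) {
  rho <- validate_correlation(rho)
  n <- nrow(rho)
  if (length(edge) == 1) {
    pr <- dyad_pairs(n)
    edge <- pr[edge, ]
  }
  i <- edge[1]; j <- edge[2]
  int <- feasible_edge_interval(rho, i, j)
  if (!is.null(seed)) set.seed(seed)
  if (diff(int) < 1e-10) {
    warning("feasible interval is degenerate; returning its single point",
            call. = FALSE)
    return(structure(rep(mean(int), n_draws), interval = int))
  }
  structure(runif(n_draws, int[1], int[2]), interval = int)
}

## feasible interval for rho[i, j] keeping PSD, others fixed; bisection on
## the smallest eigenvalue starting from the (feasible) observed value
feasible_edge_interval <- function(rho, i, j, tol = 1e-9) {
  minev <- function(v) {
    rho[i, j] <- v; rho[j, i] <- v
    min(eigen(rho, symmetric = TRUE, only.values = TRUE)$values)
  }
  v0 <- rho[i, j]
  if (minev(v0) < -1e-8) v0 <- 0   # fall back to a central feasible guess
  bound <- function(hi) {
    # PSD set in v is an interval containing v0; bisect toward hi
    lo <- v0
    if (minev(hi) >= -1e-12) return(hi)
    while (abs(hi - lo) > tol) {
      mid <- (lo + hi) / 2
      if (minev(mid) >= -1e-12) lo <- mid else hi <- mid
    }
    lo
  }
  c(bound(-1), bound(1))
}
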