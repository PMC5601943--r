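#' Beta regression of partial correlations on dyadic covariates
#'
#' Maximum-likelihood Beta regression with logit link for the mean and a
#' common precision `alpha`: `(phi_ij + 1)/2 ~ Beta(mu_ij alpha,
#' (1 - mu_ij) alpha)` with `logit(mu_ij) = z_ij' beta`.  The precision is
#' optimized on the log scale; its standard error is delta-method mapped
#' back to the raw scale.  Standard errors come from the inverse observed
#' information (numerical Hessian at the optimum).
#'
#' @param phi partial-correlation vector, entries strictly in (-1, 1).
#' @param design m x (q+1) design matrix, intercept column first; defaults
#'   to intercept-only.
#' @return list with `beta`, `alpha`, `log_alpha`, `se_beta`, `se_alpha`,
#'   `se_log_alpha`, `vcov` (on the (beta, log alpha) scale), `logLik`,
#'   `converged`.
#' @export
fit_beta_regression <- function(phi, design = NULL) {
  phi <- clip_open(as.numeric(phi))
  m <- length(phi)
  if (is.null(design)) design <- matrix(1, m, 1, dimnames = list(NULL, "edges"))
  design <- as.matrix(design)
  if (nrow(design) != m)
    stop("design rows must match the number of dyads", call. = FALSE)
  if (qr(design)$rank < ncol(design))
    stop("covariate design is rank deficient (constant or collinear column)",
         call. = FALSE)
  w <- (phi + 1) / 2
  q1 <- ncol(design)

  nll <- function(par) {
    mu <- link_mean(design, par[seq_len(q1)])
    a <- exp(par[q1 + 1])
    -sum(dbeta(w, mu * a, (1 - mu) * a, log = TRUE))
  }
  # moment-based start: logit-scale least squares + MoM precision
  beta0 <- tryCatch(qr.solve(design, qlogis(pmin(pmax(w, 1e-6), 1 - 1e-6))),
                    error = function(e) rep(0, q1))
  vbar <- stats::var(w)
  wbar <- mean(w)
  a0 <- max(wbar * (1 - wbar) / max(vbar, 1e-6) - 1, 2)
  fit <- optim(c(beta0, log(a0)), nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12), hessian = TRUE)
  if (fit$convergence != 0)
    stop("Beta-regression optimizer did not converge (code ",
         fit$convergence, ")", call. = FALSE)
  H <- fit$hessian
  V <- tryCatch(solve(H), error = function(e) {
    stop("Beta-regression information matrix is singular", call. = FALSE)
  })
  se <- sqrt(pmax(diag(V), 0))
  beta <- unname(fit$par[seq_len(q1)])
  la <- unname(fit$par[q1 + 1])
  names(beta) <- colnames(design)
  list(beta = beta, alpha = exp(la), log_alpha = la,
       se_beta = setNames(se[seq_len(q1)], colnames(design)),
       se_alpha = exp(la) * se[q1 + 1], se_log_alpha = se[q1 + 1],
       vcov = V, logLik = -fit$value, converged = TRUE)
}

#' Fit settings for the Monte-Carlo maximum-likelihood loop
#'
#' @param mc_samples retained simulated networks per theta update.
#' @param tol absolute parameter-change convergence tolerance for theta.
#' @param max_iter maximum outer iterations.
#' @param step_max Newton step coordinates are clamped to this magnitude
#'   (a trust region against Monte-Carlo overshoot).
#' @param mc_z additionally accept theta as converged when every step
#'   coordinate is below `mc_z` Monte-Carlo standard errors of the step (the
#'   estimate is then within simulation noise of the maximizer).
#' @param reburn burn-in (sweeps) for re-simulations after the first outer
#'   iteration, which warm-start from the previous chain state.
#' @param sampler a [sampler_control()].
#' @return list of class `"cgergm_control"`.
#' @export
cgergm_control <- function(mc_samples = 500, tol = 1e-4,
                           max_iter = 20, step_max = 1, mc_z = 2,
                           reburn = 250, sampler = sampler_control()) {
  stopifnot(mc_samples >= 10, tol > 0, max_iter >= 1)
  structure(list(mc_samples = as.integer(mc_samples), tol = tol,
                 max_iter = as.integer(max_iter),
                 step_max = step_max, mc_z = mc_z,
                 reburn = as.integer(reburn), sampler = sampler),
            class = "cgergm_control")
}

#' Fit a correlation generalized exponential random graph model
#'
#' Two-stage maximum-likelihood estimation.  The observed correlation
#' matrix is mapped to partial correlations and `(beta, alpha)` are
#' estimated by Beta regression ([fit_beta_regression()]); that transform
#' is then held fixed and `theta` is estimated by Monte-Carlo
#' Newton-Raphson on the exponential-family log-likelihood: each outer
#' iteration simulates `mc_samples` bounded networks at the current theta
#' and steps along `Cov[h]^{-1} (h_obs - mean h_sim)`, with `h_obs`
#' evaluated on the observed bounded network
#' `x = T((phi + 1)/2 | mu, alpha)`.  Iteration stops when the step is
#' below `tol` or within Monte-Carlo noise of zero.
#'
#' Re-estimating `(beta, alpha)` jointly with `theta` is deliberately
#' avoided: the joint likelihood in `(theta, beta, alpha)` has a long,
#' nearly flat ridge (the Beta transform can absorb most of the mean and
#' dispersion shift that a theta tilt induces), and coordinate-wise
#' re-maximization drifts along that ridge without settling.  The
#' first-stage transform makes the second stage a well-posed canonical
#' exponential-family problem.  Standard errors for theta are the usual
#' exponential-family ones, `sqrt(diag(Cov[h(x)]^{-1}))` at the final
#' simulated sample; for `(beta, alpha)` they come from the observed
#' information of the Beta regression.
#'
#' @param rho observed correlation matrix (validated internally).
#' @param statistics,downweights passed to [cgergm_spec()]; use
#'   `statistics = character(0)` for a pure Beta-regression fit.
#' @param covariates optional m x q matrix of dyadic covariates (no
#'   intercept column; one is added), or a [build_covariates()] result.
#' @param control a [cgergm_control()].
#' @param seed optional integer seed for the simulation steps.
#' @return an object of class `"cgergm"`.
#' @examples
#' fx <- generate_fixture_dmn(n_nodes = 8, seed = 1)
#' fit <- cgergm(fx$rho, control = cgergm_control(mc_samples = 100,
#'               sampler = sampler_control(burn_in = 200, thin = 2)), seed = 1)
#' summary(fit)
#' @export
cgergm <- function(rho, statistics = c("two_stars", "triads"),
                   downweights = NULL, covariates = NULL,
                   control = cgergm_control(), seed = NULL) {
  cl <- match.call()
  rho <- validate_correlation(rho)
  n <- nrow(rho)
  m <- n * (n - 1) / 2
  spec <- if (length(statistics) > 0) cgergm_spec(statistics, downweights) else NULL

  design <- covariate_design(covariates, m)
  phi <- correlation_to_partial(rho)

  ## initialization: theta = 0, (beta, alpha) from plain Beta regression
  ## (the theta = 0 case of the exogenous-block objective)
  breg0 <- fit_beta_regression(phi, design)
  exo <- list(par = c(breg0$beta, breg0$log_alpha), beta = breg0$beta,
              log_alpha = breg0$log_alpha, alpha = breg0$alpha,
              vcov = breg0$vcov)

  theta <- numeric(0); se_theta <- numeric(0); vcov_theta <- NULL
  trace <- NULL; iter <- 0L; converged <- TRUE; ref <- NULL
  acceptance <- NA_real_

  if (!is.null(spec)) {
    if (!is.null(seed)) set.seed(seed)
    p <- length(spec$statistics)
    q1 <- ncol(design)
    theta <- rep(0, p)
    trace <- matrix(NA_real_, control$max_iter, p + q1 + 1,
                    dimnames = list(NULL, c(spec$statistics,
                                            colnames(design), "log_alpha")))
    sctl <- control$sampler
    w_obs <- (clip_open(phi) + 1) / 2
    init <- beta_cdf_map(phi, link_mean(design, exo$beta), exo$alpha)
    outside <- 0L
    converged <- FALSE
    ## observed bounded network under the first-stage transform; the
    ## transform stays fixed while theta is estimated (see Details)
    h_obs <- statistic_vector(
      pbeta(w_obs, link_mean(design, exo$beta) * exo$alpha,
            (1 - link_mean(design, exo$beta)) * exo$alpha), spec)
    for (it in seq_len(control$max_iter)) {
      iter <- it
      ## (i) simulate a reference sample at the current theta
      ctl_it <- sctl
      if (it > 1) ctl_it$burn_in <- min(sctl$burn_in, control$reburn)
      sim <- sample_bounded_networks(theta, spec, n,
                                     n_samples = control$mc_samples,
                                     control = ctl_it, init = init)
      acceptance <- sim$acceptance
      init <- sim$x[nrow(sim$x), ]    # warm start for the next chain
      ref <- sim
      H <- sim$stats
      S <- cov(H)
      if (any(!is.finite(S)) || min(diag(S)) < 1e-12 ||
          inherits(try(ch <- chol(S), silent = TRUE), "try-error"))
        stop("model degeneracy: simulated statistics collapsed; ",
             "consider stronger geometric down-weighting", call. = FALSE)
      out_now <- any(h_obs < apply(H, 2, min) | h_obs > apply(H, 2, max))
      ## (ii) Monte-Carlo Newton-Raphson step on theta, clamped to the
      ## step_max trust region
      delta <- drop(chol2inv(ch) %*% (h_obs - colMeans(H)))
      delta <- pmin(pmax(delta, -control$step_max), control$step_max)
      theta <- theta + delta
      trace[it, ] <- c(theta, exo$par)
      ## degeneracy guard: observed statistics (at the current transform)
      ## outside the simulated range while the update can no longer make
      ## progress, for several successive iterations
      stuck <- out_now && max(abs(delta)) < 10 * control$tol
      outside <- if (stuck) outside + 1L else 0L
      if (outside >= 3L)
        stop("model degeneracy: observed statistics lie outside the ",
             "simulated range and the update cannot progress; consider ",
             "stronger geometric down-weighting", call. = FALSE)
      ## stop when the theta step is below tolerance or within Monte-Carlo
      ## noise of zero
      se_step <- sqrt(diag(chol2inv(ch)) / control$mc_samples)
      if (max(abs(delta)) < control$tol ||
          all(abs(delta) < control$mc_z * se_step)) {
        converged <- TRUE
        break
      }
    }
    trace <- trace[seq_len(iter), , drop = FALSE]
    ## theta covariance from a reference sample at theta-hat; on
    ## convergence the last in-loop sample is within Monte-Carlo noise of
    ## theta-hat and is reused
    if (!converged) {
      ctl <- sctl
      ctl$burn_in <- min(sctl$burn_in, control$reburn)
      sim <- sample_bounded_networks(theta, spec, n,
                                     n_samples = control$mc_samples,
                                     control = ctl, init = init)
      ref <- sim
      acceptance <- sim$acceptance
    }
    vcov_theta <- solve(cov(sim$stats))
    se_theta <- sqrt(diag(vcov_theta))
    names(theta) <- names(se_theta) <- spec$statistics
  }
  mu <- link_mean(design, exo$beta)
  x_obs <- beta_cdf_map(phi, mu, exo$alpha)

  ## exogenous-block standard errors from the observed information of its
  ## own objective (delta method for alpha = exp(log alpha))
  q1 <- ncol(design)
  se_exo <- sqrt(pmax(diag(exo$vcov), 0))
  se_beta <- setNames(se_exo[seq_len(q1)], colnames(design))
  se_log_alpha <- se_exo[q1 + 1]
  se_alpha <- exo$alpha * se_log_alpha

  coefs <- c(theta, exo$beta, dispersion = unname(exo$alpha))
  ses <- c(se_theta, se_beta, dispersion = unname(se_alpha))
  structure(list(
    call = cl, spec = spec, coefficients = coefs, std_errors = ses,
    theta = theta, beta = exo$beta, alpha = exo$alpha,
    log_alpha = exo$log_alpha, se_log_alpha = se_log_alpha,
    vcov_theta = vcov_theta, vcov_breg = exo$vcov,
    rho = rho, phi = phi, mu = mu, x_obs = x_obs, design = design,
    n_nodes = n, reference_sample = ref, acceptance = acceptance,
    n_outer_iterations = iter, converged = converged, trace = trace,
    logLik_beta = breg0$logLik, control = control, seed = seed),
    class = "cgergm")
}

covariate_design <- function(covariates, m) {
  if (is.null(covariates))
    return(matrix(1, m, 1, dimnames = list(NULL, "edges")))
  if (inherits(covariates, "cgergm_covariates")) {
    design <- covariates$design
  } else {
    Z <- as.matrix(covariates)
    if (is.null(colnames(Z)))
      colnames(Z) <- paste0("z", seq_len(ncol(Z)))
    design <- cbind(edges = 1, Z)
  }
  if (nrow(design) != m)
    stop("covariate rows must equal the number of dyads m", call. = FALSE)
  if (any(design[, 1] != 1))
    stop("first design column must be the intercept", call. = FALSE)
  design
}

#' Wald tests for fitted cGERGM coefficients
#'
#' Two-sided z tests of each coefficient against zero.  A |z| exactly at the
#' 0.05 critical value counts as significant (`>=` convention).  Zero
#' standard errors yield an `NA` flag rather than an error.
#'
#' @param fitted a `"cgergm"` object.
#' @param level test level.
#' @return data frame with estimate, s.e., z, p value and significance flag.
#' @export
wald_tests <- function(fitted, level = 0.05) {
  stopifnot(inherits(fitted, "cgergm"))
  est <- fitted$coefficients
  se <- fitted$std_errors
  z <- ifelse(se > 0, est / se, NA_real_)
  p <- 2 * pnorm(-abs(z))
  crit <- stats::qnorm(1 - level / 2)
  data.frame(feature = names(est), estimate = unname(est), se = unname(se),
             z = unname(z), p = unname(p),
             significant = ifelse(is.na(z), NA, abs(z) >= crit),
             row.names = NULL)
}

#' @export
coef.cgergm <- function(object, ...) object$coefficients

#' @export
vcov.cgergm <- function(object, ...) {
  nm <- names(object$coefficients)
  V <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  p <- length(object$theta)
  if (p > 0) V[seq_len(p), seq_len(p)] <- object$vcov_theta
  # (beta, log alpha) block mapped to (beta, alpha) by the delta method
  q1 <- length(object$beta)
  J <- diag(q1 + 1)
  J[q1 + 1, q1 + 1] <- object$alpha
  Vb <- J %*% object$vcov_breg %*% t(J)
  V[(p + 1):(p + q1 + 1), (p + 1):(p + q1 + 1)] <- Vb
  V
}

#' @export
print.cgergm <- function(x, ...) {
  cat("Correlation GERGM fit,", x$n_nodes, "nodes (",
      length(x$phi), "dyads )\n")
  if (!is.null(x$spec))
    cat("Statistics:", paste(sprintf("%s(%.2f)", x$spec$statistics,
                                     x$spec$downweights), collapse = ", "), "\n")
  cat("Coefficients:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.cgergm <- function(object, level = 0.05, ...) {
  tab <- wald_tests(object, level)
  structure(list(fit = object, table = tab, level = level),
            class = "summary.cgergm")
}

#' @export
print.summary.cgergm <- function(x, ...) {
  f <- x$fit
  cat("Correlation GERGM:", f$n_nodes, "nodes,",
      length(f$phi), "dyads\n")
  if (!is.null(f$spec))
    cat("Statistics:", paste(sprintf("%s(%.2f)", f$spec$statistics,
                                     f$spec$downweights), collapse = ", "), "\n")
  cat(sprintf("Outer iterations: %d (%s); MH acceptance %.2f\n",
              f$n_outer_iterations,
              if (f$converged) "converged" else "not converged",
              f$acceptance))
  tab <- x$table
  tab$estimate <- round(tab$estimate, 4)
  tab$se <- round(tab$se, 4)
  tab$z <- round(tab$z, 2)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Simulate correlation networks from a fitted model
#'
#' @param object a `"cgergm"` fit.
#' @param nsim number of networks.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return list of `nsim` correlation matrices.
#' @export
simulate.cgergm <- function(object, nsim = 1, seed = NULL, ...) {
  spec <- if (is.null(object$spec)) cgergm_spec("edges") else object$spec
  theta <- if (is.null(object$spec)) 0 else object$theta
  simulate_correlation_networks(object$n_nodes, theta, object$beta,
                                object$alpha, spec = spec,
                                design = object$design, nsim = nsim,
                                control = object$control$sampler, seed = seed)
}

#' Plot a cGERGM fit
#'
#' Left panel: image of the observed correlation matrix.  Right panel:
#' histogram of the observed partial correlations with the fitted marginal
#' density overlaid (the dyad-averaged Beta-regression density, exact when
#' `theta = 0`).
#'
#' @param x a `"cgergm"` fit.
#' @param ... passed to [graphics::hist()].
#' @export
plot.cgergm <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  n <- x$n_nodes
  graphics::image(seq_len(n), seq_len(n), x$rho[, n:1], zlim = c(-1, 1),
                  col = grDevices::hcl.colors(64, "Blue-Red 3", rev = TRUE),
                  xlab = "node", ylab = "node", main = "observed correlations")
  graphics::hist(x$phi, freq = FALSE, xlab = "partial correlation",
                 main = "dyad marginals", ...)
  grid <- seq(-1 + 1e-6, 1 - 1e-6, length.out = 301)
  dens <- vapply(grid, function(v) {
    mean(dbeta((v + 1) / 2, x$mu * x$alpha, (1 - x$mu) * x$alpha)) / 2
  }, numeric(1))
  graphics::lines(grid, dens, col = "red", lwd = 2)
  invisible(x)
}

#' Residuals of a cGERGM fit
#'
#' Dyad-level residuals on the bounded scale: `x_obs - E[x]` where under the
#' fitted exogenous part `E[x_ij] = 0.5` holds only for `theta = 0`; for the
#' general model residuals are reported against the simulated reference mean
#' when available.
#'
#' @param object a `"cgergm"` fit.
#' @param ... unused.
#' @return numeric vector of length m.
#' @export
residuals.cgergm <- function(object, ...) {
  if (!is.null(object$reference_sample))
    return(object$x_obs - colMeans(object$reference_sample$x))
  object$x_obs - 0.5
}
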