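#' Simulation-based goodness-of-fit
#'
#' Simulates `n_sims` networks from the fitted model and compares, for each
#' of the two-stars, triads, edges (sum of bounded weights) and intensity
#' statistics, the simulated distribution with the observed value through
#' the normalized statistic `t* = (mean_sim - observed) / sd_sim`.  The
#' edge-weight ("degree") distributions are compared by the
#' Kolmogorov-Smirnov distance between the pooled simulated
#' partial-correlation weights and the observed ones.  |t*| beyond the
#' two-sided 5% normal threshold flags misfit for that feature.
#'
#' Down-weights for the two topological statistics follow the fitted
#' specification (defaults 0.8 / 0.4 when the fit had none).  Intensity is
#' evaluated in correlation space, the scale on which networks are observed.
#'
#' @param fitted a `"cgergm"` fit.
#' @param observed correlation matrix to assess against (defaults to the
#'   fitted data).
#' @param n_sims number of simulated networks.
#' @param seed optional integer seed.
#' @return object of class `"cgergm_gof"`: a per-statistic table, the KS
#'   distance, and the simulated statistic draws.
#' @export
goodness_of_fit <- function(fitted, observed = fitted$rho, n_sims = 1000,
                            seed = NULL) {
  stopifnot(inherits(fitted, "cgergm"), n_sims >= 2)
  observed <- validate_correlation(observed)
  spec <- if (is.null(fitted$spec)) cgergm_spec() else fitted$spec
  gspec <- gof_spec(spec)

  sims <- simulate_fitted_all(fitted, n_sims, seed)
  phi_obs <- correlation_to_partial(observed)
  mu <- fitted$mu
  x_obs <- beta_cdf_map(phi_obs, mu, fitted$alpha)

  obs <- c(statistic_vector(x_obs, gspec), intensity = intensity(observed))
  sim_stats <- matrix(NA_real_, n_sims, length(obs),
                      dimnames = list(NULL, names(obs)))
  for (s in seq_len(n_sims)) {
    sim_stats[s, ] <- c(statistic_vector(sims$x[s, ], gspec),
                        intensity = intensity(sims$rho[[s]]))
  }
  mean_sim <- colMeans(sim_stats)
  sd_sim <- apply(sim_stats, 2, sd)
  t_star <- ifelse(sd_sim > 0, (mean_sim - obs) / sd_sim,
                   ifelse(mean_sim == obs, 0, Inf))
  if (any(!is.finite(t_star)))
    warning("zero simulated spread for some statistic; t* set to Inf",
            call. = FALSE)
  crit <- stats::qnorm(0.975)
  tab <- data.frame(statistic = names(obs), observed = unname(obs),
                    sim_mean = unname(mean_sim), sim_sd = unname(sd_sim),
                    t_star = unname(t_star),
                    misfit = unname(abs(t_star) >= crit), row.names = NULL)
  ks <- ks_distance(as.numeric(sims$phi), phi_obs)
  structure(list(table = tab, degree_ks = ks, n_sims = n_sims, seed = seed,
                 sim_stats = sim_stats, sim_phi = sims$phi,
                 phi_obs = phi_obs),
            class = "cgergm_gof")
}

## statistics tracked by GOF: model's own + edges, with model downweights
gof_spec <- function(spec) {
  stats <- union(spec$statistics, c("two_stars", "triads", "edges"))
  dw <- c(two_stars = 0.8, triads = 0.4, edges = 1)
  dw[spec$statistics] <- spec$downweights
  cgergm_spec(stats, dw[stats])
}

simulate_fitted_all <- function(fitted, nsim, seed) {
  spec <- if (is.null(fitted$spec)) cgergm_spec("edges") else fitted$spec
  theta <- if (is.null(fitted$spec)) 0 else fitted$theta
  simulate_correlation_networks(fitted$n_nodes, theta, fitted$beta,
                                fitted$alpha, spec = spec,
                                design = fitted$design, nsim = nsim,
                                control = fitted$control$sampler,
                                seed = seed, return_all = TRUE)
}

#' @export
print.cgergm_gof <- function(x, ...) {
  cat("Goodness of fit (", x$n_sims, "simulated networks )\n")
  tab <- x$table
  tab$observed <- round(tab$observed, 3)
  tab$sim_mean <- round(tab$sim_mean, 3)
  tab$sim_sd <- round(tab$sim_sd, 3)
  tab$t_star <- round(tab$t_star, 2)
  print(tab, row.names = FALSE)
  cat(sprintf("Degree (edge-weight) KS distance: %.3f\n", x$degree_ks))
  invisible(x)
}

#' Box-plot display of goodness of fit
#'
#' One box per tracked statistic (simulated draws, standardized), with the
#' observed value overlaid, plus the simulated vs observed edge-weight
#' distributions.
#'
#' @param x a `"cgergm_gof"` object.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.cgergm_gof <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 2, 1))
  on.exit(graphics::par(op))
  Z <- scale(x$sim_stats)
  graphics::boxplot(Z, las = 2, ylab = "standardized statistic",
                    main = "simulated vs observed", ...)
  obs_z <- (x$table$observed - colMeans(x$sim_stats)) /
    apply(x$sim_stats, 2, sd)
  graphics::points(seq_along(obs_z), obs_z, col = "blue", pch = 19)
  graphics::plot(ecdf(as.numeric(x$sim_phi)), col = "red",
                 main = "edge-weight distribution", xlab = "partial correlation")
  graphics::lines(ecdf(x$phi_obs), col = "blue")
  graphics::legend("topleft", legend = c("simulated", "observed"),
                   col = c("red", "blue"), lty = 1, bty = "n")
  invisible(x)
}

#' Write a goodness-of-fit report
#'
#' @param gof a `"cgergm_gof"` object.
#' @param path_json,path_tsv output paths (either may be `NULL`).
#' @return `gof`, invisibly.
#' @export
write_gof_report <- function(gof, path_json = NULL, path_tsv = NULL) {
  if (!is.null(path_tsv))
    utils::write.table(gof$table, path_tsv, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  if (!is.null(path_json)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is required for JSON output", call. = FALSE)
    jsonlite::write_json(
      list(table = gof$table, degree_ks = gof$degree_ks, n_sims = gof$n_sims),
      path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(gof)
}
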