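#' Model specification for topological statistics
#'
#' Bundles the ordered list of topological statistics and their geometric
#' down-weights.  Down-weighting raises each configuration product to a
#' fractional power, the standard device against degeneracy in
#' exponential-family network models; the defaults 0.8 (two-stars) and 0.4
#' (triads) are the values used throughout the package's reference analyses.
#'
#' @param statistics character vector drawn from `"two_stars"`, `"triads"`,
#'   `"edges"` (unique, order preserved).
#' @param downweights named or positional numeric vector of per-statistic
#'   exponents in (0, 1]; unnamed defaults are 0.8 for two-stars, 0.4 for
#'   triads, 1 for edges.
#' @return an object of class `"cgergm_spec"`.
#' @export
cgergm_spec <- function(statistics = c("two_stars", "triads"),
                        downweights = NULL) {
  known <- c(two_stars = 0.8, triads = 0.4, edges = 1)
  bad <- setdiff(statistics, names(known))
  if (length(bad) > 0)
    stop("unknown statistic name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(statistics))
    stop("statistic names must be unique", call. = FALSE)
  dw <- known[statistics]
  if (!is.null(downweights)) {
    if (is.null(names(downweights))) {
      if (length(downweights) != length(statistics))
        stop("unnamed downweights must match statistics in length", call. = FALSE)
      dw[] <- downweights
    } else {
      extra <- setdiff(names(downweights), statistics)
      if (length(extra) > 0)
        stop("downweights given for absent statistic(s): ",
             paste(extra, collapse = ", "), call. = FALSE)
      dw[names(downweights)] <- downweights
    }
  }
  if (any(dw <= 0) || any(dw > 1))
    stop("downweights must lie in (0, 1]", call. = FALSE)
  structure(list(statistics = statistics, downweights = dw),
            class = "cgergm_spec")
}

#' @export
print.cgergm_spec <- function(x, ...) {
  cat("cGERGM statistic specification:\n")
  for (s in x$statistics)
    cat(sprintf("  %-10s (downweight %.2f)\n", s, x$downweights[[s]]))
  invisible(x)
}

stat_weight <- function(weight) {
  if (!is.numeric(weight) || length(weight) != 1 ||
      !is.finite(weight) || weight <= 0 || weight > 1)
    stop("downweight must be a single number in (0, 1]", call. = FALSE)
  weight
}

as_bounded_matrix <- function(x) {
  if (is.matrix(x)) {
    X <- x
  } else {
    X <- vec_to_sym(x, n_from_m(length(x)), diag = 0)
  }
  if (any(X < -1e-12) || any(X > 1 + 1e-12))
    stop("bounded-network values must lie in [0, 1]", call. = FALSE)
  diag(X) <- 0
  X
}

#' Topological statistics of a bounded network
#'
#' `two_stars()` sums, over all unordered pairs of edges sharing a node, the
#' down-weighted product of the two edge weights: a weighted measure of
#' preferential attachment (hub usage).  `triads()` sums the down-weighted
#' triple products over all closed node triples: a weighted measure of
#' clustering.  `edges_stat()` is the down-weighted sum of edge weights.
#'
#' @param x bounded network as an m-vector (canonical dyad order) or a
#'   symmetric matrix with values in `[0, 1]`.
#' @param weight geometric down-weight in (0, 1].
#' @return a single non-negative number.
#' @export
two_stars <- function(x, weight = 0.8) {
  weight <- stat_weight(weight)
  P <- as_bounded_matrix(x)^weight
  diag(P) <- 0
  rs <- rowSums(P)
  sum(rs^2 - rowSums(P^2)) / 2
}

#' @rdname two_stars
#' @export
triads <- function(x, weight = 0.4) {
  weight <- stat_weight(weight)
  P <- as_bounded_matrix(x)^weight
  diag(P) <- 0
  sum(diag(P %*% P %*% P)) / 6
}

#' @rdname two_stars
#' @export
edges_stat <- function(x, weight = 1) {
  weight <- stat_weight(weight)
  P <- as_bounded_matrix(x)^weight
  sum(P[upper.tri(P)])
}

#' Intensity of a network
#'
#' The sum of absolute deviations of the m off-diagonal edge values from
#' their mean; zero iff all edges are equal.  Applies to correlation or
#' bounded networks alike.
#'
#' @param net an m-vector of edge values or a symmetric matrix (diagonal
#'   ignored).
#' @return a single non-negative number.
#' @export
intensity <- function(net) {
  v <- if (is.matrix(net)) sym_to_vec(net) else as.numeric(net)
  sum(abs(v - mean(v)))
}

#' Edge-weight distribution of a partial-correlation network
#'
#' Returns the sorted multiset of edge weights together with the
#' right-continuous empirical CDF.  This is the "degree distribution" used
#' by the goodness-of-fit comparison (the field convention for these models
#' compares edge-weight distributions, not integer degrees); a weighted
#' node-degree variant is available via `node_strengths()`.
#'
#' @param phi numeric vector of edge weights (typically partial
#'   correlations).
#' @return a list with `weights` (sorted) and `cdf` (a function).
#' @export
degree_distribution <- function(phi) {
  w <- sort(as.numeric(phi))
  list(weights = w, cdf = ecdf(w))
}

#' @rdname degree_distribution
#' @param net symmetric matrix of edge weights.
#' @export
node_strengths <- function(net) {
  M <- as.matrix(net)
  diag(M) <- 0
  rowSums(M)
}

#' Two-sample Kolmogorov-Smirnov distance
#'
#' Sup-norm distance between the empirical CDFs of two weight samples; in
#' `[0, 1]`, zero iff the empirical distributions coincide.
#'
#' @param a,b numeric vectors.
#' @return a single number in `[0, 1]`.
#' @export
ks_distance <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
}

#' Evaluate the statistic vector h(x)
#'
#' @param x bounded network (m-vector or matrix).
#' @param spec a [cgergm_spec()].
#' @return named numeric vector aligned with `spec$statistics`.
#' @export
statistic_vector <- function(x, spec) {
  stopifnot(inherits(spec, "cgergm_spec"))
  vapply(spec$statistics, function(s) {
    w <- spec$downweights[[s]]
    switch(s,
           two_stars = two_stars(x, w),
           triads = triads(x, w),
           edges = edges_stat(x, w))
  }, numeric(1))
}

## integer codes shared with the C++ sampler
stat_ids <- function(spec) {
  unname(vapply(spec$statistics,
                function(s) switch(s, two_stars = 1L, triads = 2L, edges = 3L),
                integer(1)))
}
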