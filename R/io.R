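#' Read and write correlation matrices as CSV
#'
#' The CSV is square and numeric with a header row of node ids (and the
#' same ids as first column on write).  The matrix is validated on read:
#' asymmetries under 1e-12 are symmetrized silently, anything else
#' (non-square, out-of-bounds entries, non-unit diagonal, non-PSD) is a
#' specific error.
#'
#' @param path file path.
#' @param tol_eig eigenvalue tolerance for the PSD check.
#' @return `read_correlation_csv()`: the validated correlation matrix with
#'   node ids as dimnames.
#' @export
read_correlation_csv <- function(path, tol_eig = 1e-8) {
  df <- read.csv(path, check.names = FALSE)
  first_is_label <- !is.numeric(df[[1]])
  ids <- if (first_is_label) as.character(df[[1]]) else colnames(df)
  if (first_is_label) df <- df[, -1, drop = FALSE]
  M <- as.matrix(df)
  if (nrow(M) != ncol(M))
    stop("correlation CSV is not square: ", nrow(M), " x ", ncol(M),
         call. = FALSE)
  storage.mode(M) <- "double"
  dimnames(M) <- list(ids, colnames(df))
  validate_correlation(M, tol_eig = tol_eig)
}

#' @rdname read_correlation_csv
#' @param rho correlation matrix.
#' @export
write_correlation_csv <- function(rho, path) {
  ids <- rownames(rho)
  if (is.null(ids)) ids <- paste0("n", seq_len(nrow(rho)))
  df <- data.frame(node_id = ids, rho, check.names = FALSE)
  colnames(df) <- c("node_id", ids)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a node attribute table
#'
#' Tab-separated with columns `node_id`, `hemisphere` (one of L, R, M) and
#' centroid coordinates `x`, `y`, `z` in mm.
#'
#' @param path file path.
#' @return data frame with validated columns.
#' @export
read_node_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("node_id", "hemisphere", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("node table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$node_id))
    stop("node ids must be unique", call. = FALSE)
  if (!all(df$hemisphere %in% c("L", "R", "M")))
    stop("hemisphere labels must be L, R or M", call. = FALSE)
  if (any(!is.finite(as.matrix(df[, c("x", "y", "z")]))))
    stop("node coordinates must be finite", call. = FALSE)
  df
}

#' Build dyadic covariates from node attributes
#'
#' The hemisphere covariate is 1 when both nodes share a hemisphere label
#' (L-L, R-R or M-M), else 0.  The distance covariate is the Euclidean
#' distance between centroids, standardized to mean 0 / s.d. 1 across dyads
#' (recorded in the result so raw-scale effects can be recovered).  The
#' intercept column comes first; a covariate constant across dyads is
#' rejected as collinear with it.
#'
#' @param nodes a node table (see [read_node_table()]), ordered as the
#'   correlation matrix rows.
#' @param which covariates to build, subset of `c("hemisphere",
#'   "distance")`.
#' @param standardize_distance logical.
#' @return object of class `"cgergm_covariates"`: list with `design`
#'   (m x (q+1), intercept first), `names`, `distance_center`,
#'   `distance_scale`.
#' @export
build_covariates <- function(nodes, which = c("hemisphere", "distance"),
                             standardize_distance = TRUE) {
  which <- match.arg(which, several.ok = TRUE)
  n <- nrow(nodes)
  pr <- dyad_pairs(n)
  cols <- list(edges = rep(1, nrow(pr)))
  ctr <- NA_real_; scl <- NA_real_
  if ("hemisphere" %in% which) {
    h <- nodes$hemisphere
    cols$hemisphere <- as.numeric(h[pr[, 1]] == h[pr[, 2]])
  }
  if ("distance" %in% which) {
    if (any(!is.finite(as.matrix(nodes[, c("x", "y", "z")]))))
      stop("distance covariate requires finite coordinates", call. = FALSE)
    xyz <- as.matrix(nodes[, c("x", "y", "z")])
    d <- sqrt(rowSums((xyz[pr[, 1], , drop = FALSE] -
                       xyz[pr[, 2], , drop = FALSE])^2))
    if (standardize_distance) {
      ctr <- mean(d); scl <- sd(d)
      d <- (d - ctr) / scl
    }
    cols$distance <- d
  }
  design <- do.call(cbind, cols)
  colnames(design) <- names(cols)
  if (qr(design)$rank < ncol(design))
    stop("covariate design is rank deficient: a covariate is constant ",
         "across dyads (collinear with the intercept)", call. = FALSE)
  structure(list(design = design, names = colnames(design),
                 distance_center = ctr, distance_scale = scl),
            class = "cgergm_covariates")
}

#' Generate a synthetic 20-node resting-state style fixture
#'
#' Produces a synthetic node table (left/right hemispheres plus midline,
#' mm-scale mirrored centroids) and a correlation network simulated from a
#' two-stars + triads parameterization with a positive hemisphere effect and
#' a negative distance effect — the qualitative regime reported for the
#' default mode network (clustering, anti-preferential attachment,
#' within-hemisphere homophily, distance decay).  Entirely synthetic: no
#' acquisition data enters.
#'
#' Generating parameters: `theta = (-0.75, 0.34)` with down-weights
#' (0.8, 0.4), `beta = (0.25, 0.15, -0.10)` for (edges, hemisphere,
#' distance), `alpha = 40`.
#'
#' @param n_nodes number of nodes (>= 3).
#' @param seed integer seed.
#' @return list with `nodes` (node table), `rho` (correlation matrix),
#'   `covariates` (a [build_covariates()] result) and `params` (the
#'   generating parameters).
#' @export
generate_fixture_dmn <- function(n_nodes = 20, seed = 1) {
  stopifnot(n_nodes >= 3)
  set.seed(seed)
  n_mid <- if (n_nodes >= 6) 2 else 0
  n_side <- (n_nodes - n_mid) %/% 2
  n_left <- n_side
  n_right <- n_nodes - n_mid - n_left
  hemi <- c(rep("L", n_left), rep("R", n_right), rep("M", n_mid))
  # mirrored lateral coordinates, midline on x = 0; ranges in mm are typical
  # of medial prefrontal / posterior cingulate / angular parcellations
  yl <- runif(n_left, -80, 60); zl <- runif(n_left, -10, 50)
  xl <- runif(n_left, -55, -20)
  yr <- yl[seq_len(n_right)] + rnorm(n_right, 0, 4)
  zr <- zl[seq_len(n_right)] + rnorm(n_right, 0, 4)
  xr <- -xl[seq_len(n_right)] + rnorm(n_right, 0, 3)
  xyz <- rbind(cbind(xl, yl, zl), cbind(xr, yr, zr),
               if (n_mid > 0) cbind(rnorm(n_mid, 0, 2),
                                    runif(n_mid, -70, 50),
                                    runif(n_mid, 10, 45)))
  nodes <- data.frame(node_id = paste0("roi", seq_len(n_nodes)),
                      hemisphere = hemi, x = xyz[, 1], y = xyz[, 2],
                      z = xyz[, 3], stringsAsFactors = FALSE)
  cov <- build_covariates(nodes)
  params <- list(theta = c(two_stars = -0.75, triads = 0.34),
                 beta = c(edges = 0.25, hemisphere = 0.15, distance = -0.10),
                 alpha = 40)
  rho <- simulate_correlation_networks(
    n_nodes, params$theta, params$beta, params$alpha,
    spec = cgergm_spec(), design = cov$design, nsim = 1,
    seed = seed + 1L)[[1]]
  dimnames(rho) <- list(nodes$node_id, nodes$node_id)
  list(nodes = nodes, rho = rho, covariates = cov, params = params)
}

#' Write node table as TSV
#'
#' @param nodes node table data frame.
#' @param path output file.
#' @export
write_node_table <- function(nodes, path) {
  utils::write.table(nodes, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a coefficient table as TSV
#'
#' Tab-separated columns: feature, estimate, s.e., z, p, significant.
#'
#' @param fitted a `"cgergm"` fit.
#' @param path output file.
#' @param level Wald test level.
#' @export
write_fit_table <- function(fitted, path, level = 0.05) {
  utils::write.table(wald_tests(fitted, level), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
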