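# Diffusion kernel S = D^{-1/2} A D^{-1/2}; zero-degree genes get coefficient
# 0 (no propagation through isolated nodes, their columns are only rescaled
# by the restart term).
diffusion_kernel <- function(net) {
  d <- as.numeric(net$degree)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  Dm <- Matrix::Diagonal(x = dinv)
  Dm %*% net$adjacency %*% Dm
}

as_profile_matrix <- function(x) {
  if (inherits(x, "mutation_matrix")) return(x$X)
  if (inherits(x, "smoothed_matrix")) return(x$X)
  assert_matrix_like(x)
  as.matrix(x)
}

new_smoothed_matrix <- function(X, alpha, iterations, converged = TRUE) {
  structure(
    list(X = X, alpha = alpha, iterations = iterations, converged = converged),
    class = "smoothed_matrix"
  )
}

#' @export
print.smoothed_matrix <- function(x, ...) {
  cat(sprintf(
    "<smoothed_matrix> %d x %d, alpha = %g, %d iteration(s)%s\n",
    nrow(x$X), ncol(x$X), x$alpha, x$iterations,
    if (x$converged) "" else " [not converged]"
  ))
  invisible(x)
}

#' Network smoothing of mutation profiles
#'
#' Diffuses binary mutation profiles over the network by iterating
#' \deqn{X_{t+1} = \alpha X_t D^{-1/2} A D^{-1/2} + (1-\alpha) X_0}
#' until the relative Frobenius change drops below `tol` or `max_iter` is
#' reached. `alpha` controls the length of the diffusion paths: `alpha = 0`
#' returns the input unchanged, values near 1 spread mutation mass far over
#' the graph.
#'
#' @param m a [mutation_matrix()] aligned to `net$genes`, a
#'   `smoothed_matrix`, or a plain numeric matrix with one row per patient.
#' @param net a [gene_network()].
#' @param alpha diffusion weight in `[0, 1)`.
#' @param tol relative Frobenius-change convergence tolerance.
#' @param max_iter iteration cap; hitting it raises a warning and sets
#'   `converged = FALSE` on the result.
#' @return a `smoothed_matrix` (fields `X`, `alpha`, `iterations`,
#'   `converged`).
#' @export
network_smooth <- function(m, net, alpha = 0.5, tol = 1e-6, max_iter = 500L) {
  stopifnot(inherits(net, "gene_network"))
  if (alpha < 0 || alpha >= 1) abort("`alpha` must lie in [0, 1) for iterative smoothing")
  X0 <- as_profile_matrix(m)
  if (ncol(X0) != length(net$genes)) abort("matrix is not aligned to the network genes")
  if (alpha == 0) return(new_smoothed_matrix(X0, 0, 1L))
  S <- diffusion_kernel(net)
  Xt <- X0
  for (it in seq_len(max_iter)) {
    Xn <- alpha * as.matrix(Xt %*% S) + (1 - alpha) * X0
    dimnames(Xn) <- dimnames(X0)
    delta <- frob(Xn - Xt) / max(frob(Xt), .Machine$double.eps)
    Xt <- Xn
    if (delta < tol) return(new_smoothed_matrix(Xt, alpha, it))
  }
  warn(sprintf("network smoothing did not converge in %d iterations", max_iter))
  new_smoothed_matrix(Xt, alpha, max_iter, converged = FALSE)
}

#' Quantile-normalize profiles to their mean distribution
#'
#' Forces every row (patient) to have the same value distribution: the
#' reference is the entrywise mean of all rows' sorted values, and each row's
#' values are replaced by the reference values at their ranks. Tie handling
#' is consequential because smoothed binary profiles contain many exact
#' ties. The default (`ties = "first"`) assigns tied entries distinct
#' consecutive reference values in column order, so every row ends up with
#' exactly the reference multiset — all patients share the same value
#' distribution. `ties = "average"` instead gives tied entries the mean of
#' the reference values they span (no within-tie ordering is invented, but
#' rows with different tie patterns then differ slightly in distribution).
#'
#' @param m a `smoothed_matrix`, [mutation_matrix()] or plain matrix.
#' @param ties `"first"` (default, exact common distribution) or
#'   `"average"`.
#' @return same class as the input wrapper (`smoothed_matrix` for matrix
#'   input too).
#' @export
quantile_normalize <- function(m, ties = c("first", "average")) {
  ties <- match.arg(ties)
  X <- as_profile_matrix(m)
  if (anyNA(X)) abort("quantile normalization requires a complete matrix (no NA)")
  ref <- colMeans(t(apply(X, 1, sort)))
  Xq <- t(apply(X, 1, function(x) {
    v <- ref[rank(x, ties.method = "first")]
    if (ties == "average") v <- stats::ave(v, match(x, x), FUN = mean)
    v
  }))
  dimnames(Xq) <- dimnames(X)
  if (inherits(m, "smoothed_matrix")) {
    new_smoothed_matrix(Xq, m$alpha, m$iterations, m$converged)
  } else {
    new_smoothed_matrix(Xq, alpha = 0, iterations = 0L)
  }
}

#' Network smoothing with quantile normalization (NSQN)
#'
#' Runs [network_smooth()] to convergence, then [quantile_normalize()], so
#' all patients share the mean smoothed value distribution.
#'
#' @inheritParams network_smooth
#' @return a `smoothed_matrix`.
#' @export
nsqn <- function(m, net, alpha = 0.5, tol = 1e-6, max_iter = 500L) {
  quantile_normalize(network_smooth(m, net, alpha, tol, max_iter))
}

#' One-step network smoothing with quantile normalization (SimpNSQN)
#'
#' Applies the diffusion update exactly once —
#' \eqn{X = \alpha X_0 D^{-1/2} A D^{-1/2} + (1-\alpha) X_0} —
#' then quantile-normalizes. A gene's pre-normalization score is its mutated
#' neighbour count rescaled by the degrees, plus a constant if the gene
#' itself is mutated, i.e. diffusion restricted to order-1 neighbours.
#'
#' @inheritParams network_smooth
#' @param alpha diffusion weight in `[0, 1]`.
#' @return a `smoothed_matrix`.
#' @export
simp_nsqn <- function(m, net, alpha = 0.5) {
  stopifnot(inherits(net, "gene_network"))
  if (alpha < 0 || alpha > 1) abort("`alpha` must lie in [0, 1]")
  X0 <- as_profile_matrix(m)
  if (ncol(X0) != length(net$genes)) abort("matrix is not aligned to the network genes")
  S <- diffusion_kernel(net)
  X1 <- alpha * as.matrix(X0 %*% S) + (1 - alpha) * X0
  dimnames(X1) <- dimnames(X0)
  quantile_normalize(new_smoothed_matrix(X1, alpha, 1L))
}
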