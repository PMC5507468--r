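#' Nonnegative matrix factorisation by multiplicative updates
#'
#' Approximately minimizes `||X - W H||_F^2` over nonnegative `W` (n x N
#' loadings) and `H` (N x p "metapatients") with Lee-Seung multiplicative
#' updates from a seeded uniform random initialization. Iterations stop when
#' the relative decrease of the reconstruction error falls below `tol`.
#'
#' @param X nonnegative numeric matrix (patients x genes).
#' @param N number of components (subtypes), `N >= 1`.
#' @param seed seed for the random initialization.
#' @param max_iter,tol stopping rule (defaults 200 and 1e-4).
#' @return object of class `nmf_fit` with `W`, `H`, `N`, `iterations`,
#'   `loss` (final squared Frobenius error).
#' @export
nmf_fit <- function(X, N, seed = 1L, max_iter = 200L, tol = 1e-4) {
  assert_matrix_like(X, "X")
  X <- as.matrix(X)
  if (any(X < 0)) abort("NMF requires a nonnegative matrix")
  n <- nrow(X)
  p <- ncol(X)
  N <- as.integer(N)
  if (N < 1 || N > min(n, p)) abort("`N` must lie in 1..min(dim(X))")
  eps <- 1e-10
  sc <- sqrt(mean(X) / N + eps)
  init <- with_seed(seed, list(W = matrix(runif(n * N), n, N) * sc,
                               H = matrix(runif(N * p), N, p) * sc))
  W <- init$W
  H <- init$H
  loss <- frob(X - W %*% H)^2
  it <- 0L
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, X) / (crossprod(W) %*% H + eps))
    W <- W * (tcrossprod(X, H) / (W %*% tcrossprod(H) + eps))
    new_loss <- frob(X - W %*% H)^2
    done <- (loss - new_loss) / max(loss, eps) < tol
    loss <- new_loss
    if (done) break
  }
  rownames(W) <- rownames(X)
  colnames(H) <- colnames(X)
  structure(list(W = W, H = H, N = N, iterations = it, loss = loss),
            class = "nmf_fit")
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("<nmf_fit> %d x %d into N = %d components, loss %.4g (%d iterations)\n",
              nrow(x$W), ncol(x$H), x$N, x$loss, x$iterations))
  invisible(x)
}

#' Hard subtype labels from an NMF loading matrix
#'
#' Patient `i` is assigned to the component that represents it best,
#' `argmax_j W[i, j]`, ties going to the lowest component index.
#'
#' @param X nonnegative patients x genes matrix.
#' @param N number of subtypes.
#' @param seed,max_iter,tol passed to [nmf_fit()].
#' @return integer label vector in `1..N` (named when `X` has row names).
#' @export
nmf_cluster <- function(X, N, seed = 1L, max_iter = 200L, tol = 1e-4) {
  fit <- nmf_fit(X, N, seed = seed, max_iter = max_iter, tol = tol)
  setNames(max.col(fit$W, ties.method = "first"), rownames(fit$W))
}

#' Proportion of ambiguous clustering
#'
#' The fraction of unordered distinct patient pairs whose consensus
#' co-clustering frequency is ambiguous, i.e. lies in `[lower, upper]`
#' (default `[0.25, 0.75]`). 0 means every pair is crisply together or
#' apart; 1 means every pair is ambiguous.
#'
#' @param Cmat symmetric consensus matrix with entries in `[0, 1]`.
#' @param lower,upper ambiguity band bounds.
#' @return PAC value in `[0, 1]`.
#' @export
pac <- function(Cmat, lower = 0.25, upper = 0.75) {
  assert_matrix_like(Cmat, "Cmat")
  Cmat <- as.matrix(Cmat)
  v <- Cmat[upper.tri(Cmat)]
  if (length(v) == 0) abort("PAC needs at least two patients")
  mean(v >= lower & v <= upper)
}

#' NMF consensus clustering with PAC stability
#'
#' Applies [nmf_cluster()] to `n_samplings` random subsamples of the cohort
#' (by default 80% of patients and 80% of genes, drawn without replacement),
#' accumulates how often each patient pair is clustered together over the
#' samplings where both were retained, and derives (i) final subtype labels
#' by average-linkage hierarchical clustering (euclidean distance) of the
#' consensus matrix rows, cut into `N` clusters, and (ii) the PAC stability
#' score.
#'
#' @param X nonnegative patients x genes matrix (raw binary, NetNorM or
#'   smoothed profiles).
#' @param N number of subtypes.
#' @param n_samplings number of random subsamples (default 1000).
#' @param row_frac,col_frac fraction of patients / genes retained per
#'   subsample.
#' @param seed master seed; the whole procedure is deterministic given it.
#' @param max_iter,tol per-subsample NMF stopping rule.
#' @return object of class `consensus_result`: `Cmat` (co-clustering
#'   frequencies, diagonal 1), `counts` (co-retention counts), `assignments`
#'   (final labels `1..N`), `PAC`, and `n_never_coretained` (pairs whose
#'   frequency was undefined and set to 0.5).
#' @export
consensus_cluster <- function(X, N, n_samplings = 1000L, row_frac = 0.8,
                              col_frac = 0.8, seed = 1L, max_iter = 200L,
                              tol = 1e-4) {
  assert_matrix_like(X, "X")
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  nr <- max(N, floor(row_frac * n))
  nc <- max(1L, floor(col_frac * p))
  co <- matrix(0, n, n)
  ret <- matrix(0, n, n)
  with_seed(seed, {
    for (b in seq_len(n_samplings)) {
      rows <- sample(n, nr)
      cols <- sample(p, nc)
      labels <- nmf_cluster(X[rows, cols, drop = FALSE], N,
                            seed = sample.int(2147483646L, 1L),
                            max_iter = max_iter, tol = tol)
      G <- outer(labels, labels, `==`) * 1
      co[rows, rows] <- co[rows, rows] + G
      ret[rows, rows] <- ret[rows, rows] + 1
    }
  })
  never <- ret == 0 & upper.tri(ret)
  Cmat <- ifelse(ret > 0, co / pmax(ret, 1), 0.5)
  diag(Cmat) <- 1
  dimnames(Cmat) <- dimnames(ret) <- list(rownames(X), rownames(X))
  if (any(never)) {
    warn(sprintf("%d patient pair(s) never co-retained; consensus set to 0.5", sum(never)))
  }
  hc <- hclust(dist(Cmat), method = "average")
  assignments <- setNames(unname(cutree(hc, k = N)), rownames(X))
  structure(
    list(Cmat = Cmat, counts = ret, assignments = assignments,
         PAC = pac(Cmat), N = N, n_samplings = n_samplings,
         n_never_coretained = sum(never), hclust = hc),
    class = "consensus_result"
  )
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf(
    "<consensus_result> %d patients into N = %d subtypes over %d samplings; PAC = %.3f\n",
    length(x$assignments), x$N, x$n_samplings, x$PAC
  ))
  print(table(subtype = x$assignments))
  invisible(x)
}

#' @method tidy consensus_result
#' @export
tidy.consensus_result <- function(x, ...) {
  tibble(patient = names(x$assignments) %||% as.character(seq_along(x$assignments)),
         subtype = unname(x$assignments))
}

#' @method glance consensus_result
#' @export
glance.consensus_result <- function(x, ...) {
  sizes <- table(x$assignments)
  tibble(N = x$N, PAC = x$PAC, n_samplings = x$n_samplings,
         largest_cluster_frac = max(sizes) / length(x$assignments),
         n_never_coretained = x$n_never_coretained)
}

# kmeans++ seeding for a 1-d feature
kmeanspp_init <- function(values, N) {
  centers <- numeric(N)
  centers[1] <- values[sample.int(length(values), 1L)]
  if (N > 1) {
    for (j in 2:N) {
      d2 <- vapply(values, function(v) min((v - centers[1:(j - 1)])^2), 0)
      centers[j] <- if (sum(d2) > 0) {
        values[sample.int(length(values), 1L, prob = d2)]
      } else {
        values[sample.int(length(values), 1L)]
      }
    }
  }
  centers
}

#' Restarted kmeans++ clustering of a scalar feature
#'
#' One-dimensional k-means (Lloyd iterations) with kmeans++ initialization
#' and many restarts, keeping the lowest-inertia solution — the fallback
#' stratifier when only a single scalar per patient (e.g. the total mutation
#' count) is available and NMF does not apply. Clusters are renumbered by
#' increasing center so labels are deterministic.
#'
#' @param values numeric patient vector.
#' @param N number of clusters.
#' @param restarts number of seeded restarts (default 1000).
#' @param seed master seed.
#' @return integer labels in `1..N` (constant input yields a single
#'   effective cluster).
#' @export
scalar_kmeans <- function(values, N, restarts = 1000L, seed = 1L) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 1) abort("`values` must be nonempty")
  N <- as.integer(N)
  best <- NULL
  best_inertia <- Inf
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      centers <- kmeanspp_init(values, N)
      labels <- rep(1L, n)
      for (it in 1:100) {
        d <- abs(outer(values, centers, `-`))
        new_labels <- max.col(-d, ties.method = "first")
        if (it > 1 && all(new_labels == labels)) break
        labels <- new_labels
        for (j in seq_len(N)) {
          if (any(labels == j)) centers[j] <- mean(values[labels == j])
        }
      }
      inertia <- sum((values - centers[labels])^2)
      if (inertia < best_inertia - 1e-12) {
        best_inertia <- inertia
        best <- list(labels = labels, centers = centers)
      }
    }
  })
  # renumber clusters by increasing center for determinism across restarts
  used <- sort(unique(best$labels))
  remap <- integer(N)
  remap[used[order(best$centers[used])]] <- seq_along(used)
  setNames(remap[best$labels], names(values))
}
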