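as_survival <- function(surv) {
  if (!is.data.frame(surv) || !all(c("time", "event") %in% names(surv))) {
    abort("`surv` must be a data frame with columns `time` and `event`")
  }
  y <- as.numeric(surv$time)
  d <- as.numeric(surv$event)
  if (any(!is.finite(y)) || any(y < 0)) abort("survival times must be finite and >= 0")
  if (!all(d %in% c(0, 1))) abort("`event` must be 0 (censored) or 1 (deceased)")
  list(y = y, delta = d)
}

#' Comparable patient pairs under right censoring
#'
#' A pair is comparable when its survival ordering is identifiable: the
#' earlier time is an event, or the times are tied with at least one event.
#' Formally `Z[i, j] = 1` iff `(y_i < y_j & d_i = 1)` or
#' `(y_j < y_i & d_j = 1)` or `(y_i = y_j & (d_i = 1 | d_j = 1))`.
#'
#' @param surv data frame with columns `time` (observed survival time) and
#'   `event` (1 = deceased, 0 = censored); an optional `patient` column names
#'   the rows.
#' @return binary symmetric n x n matrix `Z` with zero diagonal.
#' @export
comparable_pairs <- function(surv) {
  s <- as_survival(surv)
  y <- s$y
  d <- s$delta
  lt <- outer(y, y, `<`)
  eq <- outer(y, y, `==`)
  Z <- (lt & d == 1) | t(lt & d == 1) | (eq & outer(d == 1, d == 1, `|`))
  diag(Z) <- FALSE
  Z <- Z * 1
  if (!is.null(surv$patient)) dimnames(Z) <- list(surv$patient, surv$patient)
  Z
}

# ordered comparable pairs (i, j) with y_i <= y_j and Z_ij = 1; tied pairs
# appear in both orientations, exactly the index set of the CI sum
ordered_pairs <- function(y, Z) {
  le <- outer(y, y, `<=`)
  idx <- which(le & Z == 1, arr.ind = TRUE)
  list(i = idx[, 1], j = idx[, 2])
}

#' Concordance index with half-credit ties
#'
#' `CI = (1/|Z|) * sum over comparable ordered pairs (y_i <= y_j) of
#' I(s_j - s_i)` with `I(x) = 1` for `x > 0`, `1/2` for `x = 0`, `0`
#' otherwise. Higher scores must mean longer predicted survival. Tied-time
#' comparable pairs enter in both orientations and therefore always
#' contribute exactly 1/2 on average.
#'
#' @param surv data frame with columns `time` and `event`.
#' @param scores numeric predicted scores, one per patient.
#' @return concordance index in `[0, 1]`.
#' @export
concordance_index <- function(surv, scores) {
  s <- as_survival(surv)
  if (length(scores) != length(s$y)) abort("`scores` length must match the patient count")
  if (any(!is.finite(scores))) abort("`scores` must be finite")
  Z <- comparable_pairs(surv)
  pr <- ordered_pairs(s$y, Z)
  nz <- length(pr$i)
  if (nz == 0) abort("no comparable pairs; the concordance index is undefined")
  diff <- scores[pr$j] - scores[pr$i]
  sum((diff > 0) + 0.5 * (diff == 0)) / nz
}

#' Solver settings for the sparse ranking SVM
#'
#' The solver minimizes the nonsmooth objective by accelerated proximal
#' gradient (soft-thresholding the L1 term) on a Nesterov-smoothed hinge,
#' tightening the smoothing over a homotopy of stages and keeping the best
#' iterate under the true (unsmoothed) objective. Smaller `gamma_min` and
#' larger `max_iter` buy accuracy at linear cost.
#'
#' @param gamma_init,gamma_min first and last hinge-smoothing widths; stages
#'   shrink by factors of 10.
#' @param max_iter FISTA iterations per stage.
#' @param pair_cap maximum number of comparable pairs used in the loss; a
#'   seeded uniform subsample is taken above the cap.
#' @param seed seed for the pair subsample.
#' @return list of class `svm_control`.
#' @export
svm_control <- function(gamma_init = 0.5, gamma_min = 5e-4, max_iter = 150L,
                        pair_cap = 200000L, seed = 1L) {
  structure(list(gamma_init = gamma_init, gamma_min = gamma_min,
                 max_iter = as.integer(max_iter), pair_cap = as.integer(pair_cap),
                 seed = as.integer(seed)), class = "svm_control")
}

# true objective: 0.5 * ||w||_1 + C * sum hinge(1 - Dw)
svm_objective <- function(w, D, C) {
  0.5 * sum(abs(w)) + C * sum(pmax(1 - drop(D %*% w), 0))
}

# value and gradient of the Huber-smoothed hinge sum at margins u = Dw
smoothed_hinge_grad <- function(u, gamma) {
  g <- numeric(length(u))
  lo <- u <= 1 - gamma
  mid <- !lo & u < 1
  g[lo] <- -1
  g[mid] <- -(1 - u[mid]) / gamma
  g
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Fit the sparse L1 ranking survival SVM
#'
#' Minimizes `0.5 * ||w||_1 + C * sum over comparable pairs of
#' hinge(w' (x_j - x_i))`, where each comparable pair is oriented so that the
#' later survivor `j` should receive the larger score. Pairs with tied times
#' have no preferred orientation and are excluded from the loss (they still
#' count in the concordance index). The L1 penalty drives most gene
#' coefficients to exactly zero, performing gene selection.
#'
#' @param X numeric patients x genes matrix (any representation: raw binary,
#'   NetNorM output, smoothed profiles).
#' @param surv data frame with columns `time` and `event`.
#' @param C regularization constant (> 0); larger values fit the ranking
#'   loss harder.
#' @param control a [svm_control()].
#' @return object of class `rank_svm`: coefficients `w` (named), `C`,
#'   `support` (genes with nonzero weight), `objective`, `n_pairs`.
#' @export
fit_rank_svm <- function(X, surv, C, control = svm_control()) {
  assert_matrix_like(X, "X")
  X <- as.matrix(X)
  s <- as_survival(surv)
  if (nrow(X) != length(s$y)) abort("rows of `X` must match the patients in `surv`")
  if (!is.numeric(C) || C <= 0) abort("`C` must be a positive number")
  # strictly ordered comparable pairs: earlier patient i had an event
  Z <- comparable_pairs(surv)
  lt <- outer(s$y, s$y, `<`)
  idx <- which(lt & Z == 1, arr.ind = TRUE)
  if (nrow(idx) == 0) abort("no strictly ordered comparable pairs to fit on")
  if (nrow(idx) > control$pair_cap) {
    keep <- with_seed(control$seed, sample(nrow(idx), control$pair_cap))
    idx <- idx[keep, , drop = FALSE]
  }
  p <- ncol(X)
  n <- nrow(X)
  ii <- idx[, 1]
  jj <- idx[, 2]
  # margins u = X[jj, ] w - X[ii, ] w are computed through the per-patient
  # scores s = X w, so no pairs x genes difference matrix is materialized:
  # cost per iteration is O(np + |pairs|) rather than O(|pairs| p)
  margins <- function(s) s[jj] - s[ii]
  # gradient back-map: per-patient pair-weight accumulation, then one crossprod
  grad_w <- function(g) {
    wpat <- numeric(n)
    acc <- rowsum(c(g, -g), c(jj, ii))
    wpat[as.integer(rownames(acc))] <- acc[, 1]
    drop(crossprod(X, wpat))
  }
  objective <- function(w) {
    0.5 * sum(abs(w)) + C * sum(pmax(1 - margins(drop(X %*% w)), 0))
  }

  # spectral norm of the pair-difference operator via power iteration; the
  # start vector must not be constant — for row-sum-normalized designs
  # (every NetNorM profile sums to k) constant coefficient vectors lie in
  # the operator's null space
  v <- seq_len(p) - (p + 1) / 2
  v <- v / sqrt(sum(v^2))
  op <- 0
  for (it in 1:30) {
    u <- margins(drop(X %*% v))
    v2 <- grad_w(u)
    nv <- sqrt(sum(v2^2))
    if (nv == 0) break
    v <- v2 / nv
    op <- sqrt(sum(margins(drop(X %*% v))^2))
  }
  if (op < 1e-8) {
    # degenerate start: fall back to the (safe, larger) Frobenius bound
    op <- sqrt(sum((X[jj, , drop = FALSE] - X[ii, , drop = FALSE])^2))
  }
  op2 <- max(op, 1e-12)^2

  gammas <- control$gamma_init * 10^(-(0:50))
  gammas <- c(gammas[gammas > control$gamma_min], control$gamma_min)
  w <- numeric(p)
  best_w <- w
  best_f <- objective(w)
  for (gamma in gammas) {
    L <- C * op2 / gamma
    step <- 1 / L
    z <- w
    tt <- 1
    for (iter in seq_len(control$max_iter)) {
      u <- margins(drop(X %*% z))
      grad <- C * grad_w(smoothed_hinge_grad(u, gamma))
      w_new <- soft_threshold(z - step * grad, 0.5 * step)
      t_new <- (1 + sqrt(1 + 4 * tt^2)) / 2
      z <- w_new + ((tt - 1) / t_new) * (w_new - w)
      w <- w_new
      tt <- t_new
    }
    f <- objective(w)
    if (f < best_f) {
      best_f <- f
      best_w <- w
    }
  }
  w <- best_w
  names(w) <- colnames(X)
  structure(
    list(w = w, C = C, support = colnames(X)[w != 0], objective = best_f,
         n_pairs = nrow(idx), control = control),
    class = "rank_svm"
  )
}

#' @export
print.rank_svm <- function(x, ...) {
  cat(sprintf(
    "<rank_svm> C = %g, %d/%d nonzero coefficients, objective %.6g (%d pairs)\n",
    x$C, length(x$support), length(x$w), x$objective, x$n_pairs
  ))
  invisible(x)
}

#' Predict ranking scores
#'
#' @param object a `rank_svm`.
#' @param newdata patients x genes matrix aligned to the training columns.
#' @param ... unused.
#' @return numeric score vector; higher means longer predicted survival.
#' @export
predict.rank_svm <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$w)
}

#' @method tidy rank_svm
#' @export
tidy.rank_svm <- function(x, ...) {
  tibble(gene = names(x$w) %||% as.character(seq_along(x$w)),
         estimate = unname(x$w))[x$w != 0, ]
}

#' @method glance rank_svm
#' @export
glance.rank_svm <- function(x, ...) {
  tibble(C = x$C, n_support = length(x$support), objective = x$objective,
         n_pairs = x$n_pairs)
}
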