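#' Default hyperparameter grids
#'
#' `default_c_grid()` spans 1e-4 to 1e2 on a log scale (7 points).
#' `default_alpha_grid()` is 0.1 to 0.9 in steps of 0.1. `k_grid()` spans the
#' first to third quartile of the cohort burden distribution in steps of 2.
#'
#' @return numeric grid vector.
#' @export
default_c_grid <- function() 10^seq(-4, 2, length.out = 7)

#' @rdname default_c_grid
#' @export
default_alpha_grid <- function() seq(0.1, 0.9, by = 0.1)

#' @rdname default_c_grid
#' @param m a [mutation_matrix()].
#' @param step grid step (default 2).
#' @export
k_grid <- function(m, step = 2) {
  stopifnot(inherits(m, "mutation_matrix"))
  q <- quantile(m$totals, c(0.25, 0.75), names = FALSE)
  lo <- max(1L, as.integer(round(q[1])))
  hi <- max(lo, as.integer(round(q[2])))
  seq(lo, hi, by = step)
}

#' Build a named list of candidate representations
#'
#' Precomputes the patients-by-genes design matrix for every value of the
#' representation hyperparameter (k for NetNorM, alpha for the diffusion
#' methods) so that cross-validation can select over it jointly with C. The
#' transforms are unsupervised, so by default they are computed once on the
#' full cohort (transductive); pass individual training submatrices through
#' this helper for a strictly per-fold protocol.
#'
#' @param m a [mutation_matrix()] aligned to `net$genes`.
#' @param net a [gene_network()]; unused for `method = "raw"`.
#' @param method one of `"raw"`, `"netnorm"`, `"ns"`, `"nsqn"`, `"simpnsqn"`.
#' @param values hyperparameter values (k or alpha); defaults to
#'   [k_grid()] / [default_alpha_grid()]; ignored for `"raw"`.
#' @return named list of numeric matrices.
#' @export
representation_grid <- function(m, net = NULL,
                                method = c("raw", "netnorm", "ns", "nsqn", "simpnsqn"),
                                values = NULL) {
  method <- match.arg(method)
  if (method == "raw") return(list(raw = m$X))
  stopifnot(inherits(net, "gene_network"))
  if (is.null(values)) {
    values <- if (method == "netnorm") k_grid(m) else default_alpha_grid()
  }
  out <- lapply(values, function(v) {
    switch(method,
      netnorm = netnorm(m, net, k = v)$Xk,
      ns = network_smooth(m, net, alpha = v)$X,
      nsqn = nsqn(m, net, alpha = v)$X,
      simpnsqn = simp_nsqn(m, net, alpha = v)$X
    )
  })
  names(out) <- as.character(values)
  out
}

# split n indices into `folds` near-equal groups, seeded
make_folds <- function(n, folds, seed) {
  perm <- with_seed(seed, sample(n))
  split(perm, rep_len(seq_len(folds), n))
}

safe_ci <- function(surv, scores) {
  tryCatch(concordance_index(surv, scores), error = function(e) NA_real_)
}

#' Nested cross-validation for the sparse ranking survival SVM
#'
#' Repeats a k-fold split of the cohort; within each outer training set an
#' inner cross-validation selects the `(representation value, C)` pair with
#' the best mean validation concordance index (ties broken towards the
#' smallest C, then the smallest representation value — the sparser, smoother
#' model). The winning model is refit on the full outer training set and
#' scored on the held-out fold. Outer folds whose test set has no comparable
#' pairs are flagged (`test_ci = NA`) and excluded from summaries.
#'
#' @param X a numeric patients x genes matrix, or a named list of such
#'   matrices — one per representation-hyperparameter value (see
#'   [representation_grid()]).
#' @param surv data frame with columns `time` and `event`, rows aligned to
#'   `X`.
#' @param c_grid regularization grid (default [default_c_grid()]).
#' @param repeats,outer_folds,inner_folds cross-validation layout; the
#'   default 4 x 5-fold layout yields 20 outer test evaluations.
#' @param seed master seed; all fold assignments derive from it.
#' @param control a [svm_control()].
#' @return object of class `netnorm_cv`: tibble `results` (one row per outer
#'   fold: repeat, fold, selected representation value and C, test CI,
#'   support size and gene set) plus the layout settings.
#' @export
nested_cv <- function(X, surv, c_grid = default_c_grid(), repeats = 4L,
                      outer_folds = 5L, inner_folds = 5L, seed = 1L,
                      control = svm_control()) {
  reps <- if (is.list(X)) X else list(X)
  if (is.null(names(reps))) names(reps) <- as.character(seq_along(reps))
  n <- nrow(reps[[1]])
  stopifnot(all(vapply(reps, nrow, 0L) == n), nrow(surv) == n)
  if (length(c_grid) == 0) abort("`c_grid` must be nonempty")
  rows <- list()
  for (r in seq_len(repeats)) {
    folds <- make_folds(n, outer_folds, derive_seed(seed, paste0("outer", r)))
    for (f in seq_len(outer_folds)) {
      test_idx <- folds[[f]]
      train_idx <- setdiff(seq_len(n), test_idx)
      inner <- make_folds(length(train_idx), inner_folds,
                          derive_seed(seed, paste0("inner", r, "_", f)))
      grid <- tidyr::expand_grid(rep_value = names(reps), C = c_grid)
      grid$mean_ci <- vapply(seq_len(nrow(grid)), function(g) {
        Xg <- reps[[grid$rep_value[g]]]
        cis <- vapply(inner, function(val_pos) {
          val_idx <- train_idx[val_pos]
          fit_idx <- setdiff(train_idx, val_idx)
          fit <- tryCatch(
            fit_rank_svm(Xg[fit_idx, , drop = FALSE], surv[fit_idx, , drop = FALSE],
                         C = grid$C[g], control = control),
            error = function(e) NULL
          )
          if (is.null(fit)) return(NA_real_)
          safe_ci(surv[val_idx, , drop = FALSE],
                  predict(fit, Xg[val_idx, , drop = FALSE]))
        }, 0)
        mean(cis, na.rm = TRUE)
      }, 0)
      # best mean CI; ties -> smallest C, then earliest representation value
      ord <- order(-grid$mean_ci, grid$C, match(grid$rep_value, names(reps)))
      best <- grid[ord[1], ]
      Xb <- reps[[best$rep_value]]
      fit <- fit_rank_svm(Xb[train_idx, , drop = FALSE],
                          surv[train_idx, , drop = FALSE],
                          C = best$C, control = control)
      rows[[length(rows) + 1]] <- tibble(
        repeat_ = r, fold = f,
        rep_value = best$rep_value, C = best$C,
        inner_mean_ci = best$mean_ci,
        test_ci = safe_ci(surv[test_idx, , drop = FALSE],
                          predict(fit, Xb[test_idx, , drop = FALSE])),
        n_support = length(fit$support),
        support = list(fit$support)
      )
    }
  }
  structure(
    list(
      results = dplyr::bind_rows(rows),
      repeats = repeats, outer_folds = outer_folds, inner_folds = inner_folds,
      c_grid = c_grid, rep_values = names(reps), seed = seed
    ),
    class = "netnorm_cv"
  )
}

#' @export
print.netnorm_cv <- function(x, ...) {
  ok <- x$results$test_ci[!is.na(x$results$test_ci)]
  cat(sprintf(
    "<netnorm_cv> %d outer folds (%d repeats x %d folds); mean test CI %.3f, median %.3f\n",
    nrow(x$results), x$repeats, x$outer_folds, mean(ok), median(ok)
  ))
  invisible(x)
}

#' @method tidy netnorm_cv
#' @export
tidy.netnorm_cv <- function(x, ...) x$results

#' @method glance netnorm_cv
#' @export
glance.netnorm_cv <- function(x, ...) {
  ok <- x$results$test_ci[!is.na(x$results$test_ci)]
  tibble(
    n_folds = nrow(x$results),
    n_flagged = sum(is.na(x$results$test_ci)),
    mean_test_ci = mean(ok),
    median_test_ci = median(ok),
    sd_test_ci = sd(ok),
    mean_n_support = mean(x$results$n_support)
  )
}

# per-column concordance index on a patient subset, chunked to bound memory
ci_by_column <- function(X, surv, chunk = 200L) {
  s <- as_survival(surv)
  Z <- comparable_pairs(surv)
  pr <- ordered_pairs(s$y, Z)
  if (length(pr$i) == 0) abort("no comparable pairs; the concordance index is undefined")
  out <- numeric(ncol(X))
  for (start in seq(1, ncol(X), by = chunk)) {
    cols <- start:min(start + chunk - 1L, ncol(X))
    Xi <- X[pr$i, cols, drop = FALSE]
    Xj <- X[pr$j, cols, drop = FALSE]
    out[cols] <- colMeans((Xj > Xi) + 0.5 * (Xj == Xi))
  }
  names(out) <- colnames(X)
  out
}

#' Single-best-gene survival baseline
#'
#' For each cross-validation fold, selects the one gene whose values give
#' the best concordance index on the training set (ties broken towards the
#' lowest column index) and evaluates it on the test fold — the baseline any
#' multivariate model must beat.
#'
#' @param X numeric patients x genes matrix.
#' @param surv data frame with `time` and `event` columns.
#' @param repeats,folds cross-validation layout (default 4 x 5).
#' @param seed fold seed, matching [nested_cv()] fold construction.
#' @return tibble with one row per fold: selected gene, train CI, test CI.
#' @export
best_single_gene <- function(X, surv, repeats = 4L, folds = 5L, seed = 1L) {
  assert_matrix_like(X, "X")
  X <- as.matrix(X)
  n <- nrow(X)
  rows <- list()
  for (r in seq_len(repeats)) {
    fold_idx <- make_folds(n, folds, derive_seed(seed, paste0("outer", r)))
    for (f in seq_len(folds)) {
      test_idx <- fold_idx[[f]]
      train_idx <- setdiff(seq_len(n), test_idx)
      train_ci <- ci_by_column(X[train_idx, , drop = FALSE],
                               surv[train_idx, , drop = FALSE])
      g <- which.max(train_ci) # which.max takes the first (lowest index) tie
      rows[[length(rows) + 1]] <- tibble(
        repeat_ = r, fold = f,
        gene = colnames(X)[g] %||% as.character(g),
        train_ci = unname(train_ci[g]),
        test_ci = safe_ci(surv[test_idx, , drop = FALSE], X[test_idx, g])
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Low-burden "proxies" summary feature
#'
#' A single per-patient covariate equal to the total mutation count for
#' patients below the NetNorM target `k` (the patients that receive proxy
#' mutations) and 0 otherwise, scaled to unit variance. Concatenating it to
#' a design matrix lets a linear model read the low-burden signal directly.
#'
#' @param m a [mutation_matrix()].
#' @param k NetNorM target mutation count.
#' @return numeric patient vector (unit variance unless degenerate).
#' @export
proxies_feature <- function(m, k) {
  stopifnot(inherits(m, "mutation_matrix"))
  v <- ifelse(m$totals < k, as.numeric(m$totals), 0)
  scale_unit_var(setNames(v, m$patients))
}

#' Average two prediction score vectors
#'
#' Each score vector is standardized (zero-variance vectors become all
#' zeros, with a warning) and the two are averaged entrywise — the simple
#' late-fusion rule for combining a mutation-based model with a second model
#' (e.g. one fit on clinical covariates).
#'
#' @param scores_a,scores_b numeric vectors of equal length.
#' @return numeric vector of combined scores.
#' @export
combine_predictions <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) abort("score vectors must have equal length")
  (standardize(scores_a) + standardize(scores_b)) / 2
}
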