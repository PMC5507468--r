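test_that("comparable_pairs implements the three-case rule", {
  # earlier patient had an event -> comparable
  Z <- comparable_pairs(data.frame(time = c(1, 2), event = c(1, 0)))
  expect_equal(Z[1, 2], 1)
  expect_equal(Z[2, 1], 1)
  # earlier patient censored -> not comparable
  Z2 <- comparable_pairs(data.frame(time = c(1, 2), event = c(0, 1)))
  expect_equal(sum(Z2), 0)
  # tie with at least one event -> comparable
  Z3 <- comparable_pairs(data.frame(time = c(3, 3), event = c(0, 1)))
  expect_equal(Z3[1, 2], 1)
  expect_equal(Z3[2, 1], 1)
  # tie with no event -> not comparable; diagonal always zero
  Z4 <- comparable_pairs(data.frame(time = c(3, 3), event = c(0, 0)))
  expect_equal(sum(Z4), 0)
  s <- rand_surv(30, seed = 5)
  Zr <- comparable_pairs(s)
  expect_identical(Zr, t(Zr))
  expect_true(all(diag(Zr) == 0))
})

test_that("concordance index hits the perfect / reversed / constant fixtures exactly", {
  surv <- data.frame(time = c(1, 2, 3), event = c(1, 1, 1))
  expect_identical(concordance_index(surv, c(1, 2, 3)), 1)
  expect_identical(concordance_index(surv, c(3, 2, 1)), 0)
  expect_identical(concordance_index(surv, c(7, 7, 7)), 0.5)
  expect_error(concordance_index(data.frame(time = c(1, 2), event = c(0, 0)), c(1, 2)),
               "comparable")
})

test_that("concordance index agrees with the brute-force pair count on censored data with ties", {
  for (s in 1:25) {
    n <- withr::with_seed(s, sample(5:60, 1))
    surv <- rand_surv(n, seed = s)
    scores <- withr::with_seed(s + 100, round(rnorm(n), 1)) # score ties too
    if (sum(comparable_pairs(surv)) == 0) next
    expect_equal(concordance_index(surv, scores), oracle_ci(surv, scores),
                 tolerance = 1e-12)
  }
})

test_that("concordance index is invariant under strictly increasing score transforms", {
  surv <- rand_surv(40, seed = 9)
  scores <- withr::with_seed(9, rnorm(40))
  ci <- concordance_index(surv, scores)
  expect_equal(concordance_index(surv, exp(scores)), ci)
  expect_equal(concordance_index(surv, 3 * scores - 10), ci)
})

test_that("ranking SVM reaches the brute-force grid minimum on 2-D toys", {
  toys <- list(
    list(seed = 1, C = 1), list(seed = 2, C = 0.3), list(seed = 3, C = 5)
  )
  for (toy in toys) {
    n <- 14
    surv <- withr::with_seed(toy$seed, data.frame(time = runif(n), event = 1))
    X <- withr::with_seed(toy$seed + 10,
                          cbind(a = surv$time + 0.3 * rnorm(n), b = rnorm(n)))
    fit <- fit_rank_svm(X, surv, C = toy$C,
                        control = svm_control(gamma_min = 1e-7, max_iter = 4000))
    Z <- comparable_pairs(surv)
    idx <- which(outer(surv$time, surv$time, `<`) & Z == 1, arr.ind = TRUE)
    D <- X[idx[, 2], ] - X[idx[, 1], ]
    oracle <- oracle_svm_grid_min(D, toy$C)
    f_hat <- netnorm:::svm_objective(fit$w, D, toy$C)
    expect_lte(f_hat, netnorm:::svm_objective(c(0, 0), D, toy$C))
    expect_lt(abs(f_hat - oracle$value), 1e-4 * max(1, abs(oracle$value)))
  }
})

test_that("separable ranking is fit perfectly at large C and collapses to zero as C -> 0", {
  n <- 30
  surv <- data.frame(time = (1:n) / n, event = 1) # bounded ranking margins
  X <- cbind(signal = surv$time, noise = withr::with_seed(5, rnorm(n)))
  fit <- fit_rank_svm(X, surv, C = 100,
                      control = svm_control(gamma_min = 1e-6, max_iter = 3000))
  expect_gt(fit$w["signal"], 0)
  expect_equal(concordance_index(surv, predict(fit, X)), 1)
  fit0 <- fit_rank_svm(X, surv, C = 1e-8)
  expect_equal(unname(fit0$w), c(0, 0))
  expect_error(fit_rank_svm(X, surv, C = -1), "positive")
})

test_that("informative gene outweighs pure noise at moderate C", {
  n <- 40
  surv <- withr::with_seed(6, data.frame(time = rexp(n), event = 1))
  X <- cbind(inf = surv$time + withr::with_seed(7, 0.1 * rnorm(n)),
             noise = withr::with_seed(8, rnorm(n)))
  fit <- fit_rank_svm(X, surv, C = 1,
                      control = svm_control(gamma_min = 1e-6, max_iter = 2000))
  expect_gt(abs(fit$w["inf"]), abs(fit$w["noise"]))
})

test_that("training concordance is non-decreasing in C on a separable fixture", {
  n <- 25
  surv <- data.frame(time = (1:n) / n, event = 1)
  X <- cbind(g = surv$time, h = withr::with_seed(12, rnorm(n)))
  ctl <- svm_control(gamma_min = 1e-6, max_iter = 3000)
  cis <- vapply(c(1e-4, 1e-2, 1, 100), function(C) {
    concordance_index(surv, predict(fit_rank_svm(X, surv, C = C, control = ctl), X))
  }, 0)
  expect_true(all(diff(cis) >= -1e-6))
})

test_that("fitting is deterministic and pair subsampling respects the cap", {
  surv <- rand_surv(30, seed = 13, censor = 0.2)
  X <- withr::with_seed(13, matrix(rnorm(30 * 5), 30, 5,
                                   dimnames = list(NULL, paste0("g", 1:5))))
  f1 <- fit_rank_svm(X, surv, C = 0.5)
  f2 <- fit_rank_svm(X, surv, C = 0.5)
  expect_identical(f1$w, f2$w)
  f3 <- fit_rank_svm(X, surv, C = 0.5, control = svm_control(pair_cap = 20L))
  expect_equal(f3$n_pairs, 20L)
  expect_identical(tidy(f1)$gene, names(f1$w)[f1$w != 0])
  expect_equal(glance(f1)$C, 0.5)
})
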