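# star H-{g1,g2,g3} plus pendant edge g1-g4; gene order H,g1,g2,g3,g4
star_net <- function() {
  gene_network(data.frame(from = c("H", "H", "H", "g1"),
                          to = c("g1", "g2", "g3", "g4")))
}

star_profile <- function(genes_mutated) {
  net <- star_net()
  as.numeric(net$genes %in% genes_mutated)
}

test_that("rank_genes orders by status, then degree / mutated-neighbour count, then column", {
  net <- star_net()
  expect_identical(net$genes, c("H", "g1", "g2", "g3", "g4"))
  # mutated {g1,g2,g3}: g1 (degree 2) first, then g2, g3 (degree 1, column order);
  # non-mutated: H (3 mutated neighbours) before g4 (1)
  ord <- rank_genes(star_profile(c("g1", "g2", "g3")), net)
  expect_identical(net$genes[ord], c("g1", "g2", "g3", "H", "g4"))
  # all-zero profile: pure column order
  expect_identical(rank_genes(rep(0, 5), net), 1:5)
  # all-ones profile: descending degree with column-order ties
  ord1 <- rank_genes(rep(1, 5), net)
  expect_identical(net$genes[ord1], c("H", "g1", "g2", "g3", "g4"))
})

test_that("netnorm reproduces the hand-worked removal and proxy examples", {
  net <- star_net()
  # removal: patient {g1,g2,g3}, k=2 -> keep {g1,g2} (g2/g3 degree tie -> column order)
  m <- mutation_matrix(matrix(star_profile(c("g1", "g2", "g3")), 1, 5,
                              dimnames = list("P1", net$genes)))
  res <- netnorm(m, net, k = 2)
  expect_equal(unname(res$Xk[1, ]), c(0, 1, 1, 0, 0))
  expect_identical(res$removed[["P1"]], "g3")
  expect_identical(res$added[["P1"]], character(0))
  # proxy addition: patient {g2}, k=2 -> {g2, H}
  m2 <- mutation_matrix(matrix(star_profile("g2"), 1, 5,
                               dimnames = list("P1", net$genes)))
  res2 <- netnorm(m2, net, k = 2)
  expect_equal(unname(res2$Xk[1, ]), c(1, 0, 1, 0, 0))
  expect_identical(res2$added[["P1"]], "H")
  # exact-k patient unchanged
  m3 <- mutation_matrix(matrix(star_profile(c("g2", "g4")), 1, 5,
                               dimnames = list("P1", net$genes)))
  res3 <- netnorm(m3, net, k = 2)
  expect_equal(res3$Xk[1, ], m3$X[1, ])
  expect_identical(res3$added[["P1"]], character(0))
  expect_identical(res3$removed[["P1"]], character(0))
})

test_that("default_k floors the half-integral median", {
  mk <- function(totals) {
    p <- max(totals) + 1
    X <- t(vapply(totals, function(t) c(rep(1, t), rep(0, p - t)), numeric(p)))
    dimnames(X) <- list(sprintf("P%d", seq_along(totals)), sprintf("g%d", 1:p))
    mutation_matrix(X)
  }
  expect_equal(default_k(mk(c(1, 5, 9))), 5L)
  expect_equal(default_k(mk(c(2, 4))), 3L)
  expect_equal(default_k(mk(7)), 7L)
  expect_equal(default_k(mk(c(2, 3))), 2L) # 2.5 rounds down
})

test_that("every normalized row sums to k, with monotone support containment", {
  for (s in 1:8) {
    net <- rand_network(30, seed = s)
    m <- rand_mutations(12, net, density = 0.25, seed = s)
    k <- withr::with_seed(s, sample(1:30, 1))
    res <- suppressWarnings(netnorm(m, net, k = k))
    expect_equal(unname(rowSums(res$Xk)), rep(k, 12))
    for (i in 1:12) {
      orig <- which(m$X[i, ] == 1)
      new <- which(res$Xk[i, ] == 1)
      if (m$totals[i] > k) expect_true(all(new %in% orig))
      if (m$totals[i] < k) expect_true(all(orig %in% new))
      # added/removed bookkeeping is consistent and disjoint
      expect_length(intersect(res$added[[i]], m$genes[orig]), 0)
      expect_true(all(res$removed[[i]] %in% m$genes[orig]))
      expect_true(length(res$added[[i]]) == 0 || length(res$removed[[i]]) == 0)
    }
  }
})

test_that("netnorm matches the brute-force triple-sort oracle", {
  for (s in 1:6) {
    net <- rand_network(20, edge_prob = 0.2, seed = s)
    m <- rand_mutations(8, net, density = 0.3, seed = s + 50)
    k <- withr::with_seed(s, sample(1:20, 1))
    res <- suppressWarnings(netnorm(m, net, k = k))
    expect_identical(res$Xk, oracle_netnorm(m, net, k))
  }
})

test_that("netnorm is idempotent on its own output", {
  for (s in 1:4) {
    net <- rand_network(25, seed = s)
    m <- rand_mutations(10, net, seed = s)
    k <- 6
    res <- suppressWarnings(netnorm(m, net, k = k))
    m2 <- mutation_matrix(res$Xk)
    res2 <- netnorm(m2, net, k = k)
    expect_identical(res2$Xk, res$Xk)
  }
})

test_that("netnorm validates k and warns on zero-burden patients", {
  net <- star_net()
  m <- mutation_matrix(matrix(star_profile("g2"), 1, 5,
                              dimnames = list("P1", net$genes)))
  expect_error(netnorm(m, net, k = 6), "1..5")
  m0 <- mutation_matrix(matrix(0, 1, 5, dimnames = list("P1", net$genes)))
  expect_warning(res <- netnorm(m0, net, k = 2), "zero mutations")
  expect_equal(sum(res$Xk), 2) # first columns by tie-break order
  expect_equal(unname(res$Xk[1, 1:2]), c(1, 1))
})

test_that("tidy and proxy_summary report the audit trail", {
  net <- star_net()
  X <- rbind(P1 = star_profile(c("g1", "g2", "g3")), P2 = star_profile("g2"))
  colnames(X) <- net$genes
  m <- mutation_matrix(X)
  res <- netnorm(m, net, k = 2)
  td <- tidy(res)
  expect_equal(td$n_removed, c(1L, 0L))
  expect_equal(td$n_added, c(0L, 1L))
  ps <- proxy_summary(res)
  expect_equal(ps$n_proxy[ps$gene == "H"], 1L)
  expect_equal(sum(ps$n_mutated), 4L)
})
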