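test_that("log-rank test agrees with survdiff-independent textbook formula", {
  for (s in 1:10) {
    n <- withr::with_seed(s, sample(10:40, 1))
    surv <- rand_surv(n, seed = s)
    groups <- withr::with_seed(s + 40, rbinom(n, 1, 0.5))
    if (length(unique(groups)) < 2 || sum(surv$event) == 0) next
    res <- logrank_test(surv, groups)
    expect_equal(res$statistic, oracle_logrank_2group(surv$time, surv$event, groups == 1),
                 tolerance = 1e-9)
    # vectorized internal used for nulls agrees too
    expect_equal(
      unname(netnorm:::logrank_stat_2group(surv$time, surv$event,
                                           matrix(groups == 1, ncol = 1))),
      res$statistic, tolerance = 1e-9
    )
  }
})

test_that("log-rank statistic is near zero for exchangeable groups and large for separated ones", {
  y <- rep(c(1, 2, 3, 4, 5), each = 2)
  d <- rep(1, 10)
  g <- rep(c(1, 2), 5) # identical (y, d) multisets interleaved
  expect_lt(logrank_test(data.frame(time = y, event = d), g)$statistic, 1e-9)
  surv2 <- data.frame(time = c(1:8, 101:108),
                      event = c(rep(1, 8), rep(0, 8)))
  res2 <- logrank_test(surv2, rep(c("bad", "good"), each = 8))
  expect_lt(res2$p_value, 0.01)
  # invariances: group relabelling and common time rescaling
  surv <- rand_surv(30, seed = 3)
  g2 <- withr::with_seed(4, sample(1:2, 30, replace = TRUE))
  a <- logrank_test(surv, g2)$statistic
  expect_equal(logrank_test(surv, 3 - g2)$statistic, a)
  surv_scaled <- transform(surv, time = time * 7.3)
  expect_equal(logrank_test(surv_scaled, g2)$statistic, a)
  expect_error(logrank_test(surv, rep(1, 30)), "two")
})

test_that("proxy reallocation weights follow (k - T) and the weight example", {
  # eligible burdens (2, 6), k = 10 -> probabilities (8/12, 4/12)
  w <- 10 - c(2, 6)
  expect_equal(w / sum(w), c(2 / 3, 1 / 3))
  # build a cohort where one gene holds proxies and check sampler frequencies
  net <- rand_network(12, edge_prob = 0.35, seed = 21)
  m <- rand_mutations(30, net, density = 0.25, seed = 21)
  res <- suppressWarnings(netnorm(m, net, k = default_k(m)))
  ps <- proxy_summary(res)
  gene <- ps$gene[which.max(ps$n_proxy)]
  surv <- rand_surv(30, seed = 22)
  pn <- simulate_proxy_null(gene, res, surv, draws = 4000, seed = 1)
  expect_length(pn$null_statistics, 4000)
  expect_true(pn$p > 0 && pn$p <= 1)
  # selection counts concentrate on high-weight (low-burden) patients
  expect_equal(sum(pn$selection_counts), 4000 * length(pn$M_p))
  expect_identical(names(pn$weights), names(pn$selection_counts))
  # determinism
  pn2 <- simulate_proxy_null(gene, res, surv, draws = 100, seed = 9)
  pn3 <- simulate_proxy_null(gene, res, surv, draws = 100, seed = 9)
  expect_identical(pn2$null_statistics, pn3$null_statistics)
  expect_error(simulate_proxy_null("nonexistent", res, surv), "not in the result")
})

test_that("metapatient gene clustering filters by variance and splits planted groups", {
  H <- cbind(
    rbind(rep(10, 6), rep(0, 6)), # genes loading on metapatient 1
    rbind(rep(0, 6), rep(10, 6)), # genes loading on metapatient 2
    matrix(0.001, 2, 4) # below the variance threshold
  )
  colnames(H) <- sprintf("g%02d", 1:16)
  cs <- cluster_metapatients(H, var_threshold = 0.01, cut_height = 5.5)
  expect_equal(nrow(cs$clusters), 12) # low-variance genes dropped
  expect_equal(length(unique(cs$clusters$cluster)), 2)
  grp1 <- cs$clusters$cluster[cs$clusters$gene %in% sprintf("g%02d", 1:6)]
  expect_equal(length(unique(grp1)), 1)
  # duplicated columns always co-cluster
  expect_equal(cs$clusters$cluster[1], cs$clusters$cluster[2])
  # clusters are numbered left-to-right in dendrogram order
  expect_equal(sort(unique(cs$clusters$cluster)), 1:2)
  expect_warning(empty <- cluster_metapatients(matrix(0.001, 2, 5)), "variance")
  expect_equal(nrow(empty$clusters), 0)
})

test_that("dense subgraph embedding respects the 90% adjacency threshold", {
  # clique {a,b,c} plus d adjacent to all three
  net <- gene_network(data.frame(
    from = c("a", "a", "b", "d", "d", "d"),
    to = c("b", "c", "c", "a", "b", "c")
  ))
  expect_setequal(dense_subgraph_embedding(c("a", "b", "c"), net), c("a", "b", "c", "d"))
  # isolated cluster gains nothing
  net2 <- gene_network(data.frame(from = c("a", "x"), to = c("b", "y")))
  expect_setequal(dense_subgraph_embedding(c("a", "b"), net2), c("a", "b"))
  # boundary: adjacent to 8 of 10 cluster genes misses ceil(0.9 * 10) = 9
  cl <- sprintf("c%02d", 1:10)
  edges <- data.frame(from = rep("out", 8), to = cl[1:8])
  ring <- data.frame(from = cl, to = cl[c(2:10, 1)])
  net3 <- gene_network(rbind(edges, ring))
  expect_false("out" %in% dense_subgraph_embedding(cl, net3))
  # monotone in link_frac: lower threshold gives a superset
  e9 <- dense_subgraph_embedding(cl, net3, link_frac = 0.8)
  expect_true(all(dense_subgraph_embedding(cl, net3, link_frac = 0.9) %in% e9))
  expect_true("out" %in% e9)
})

test_that("chi-square enrichment matches the Pearson formula and flags small cells", {
  # printed 2x2 toy {{10,20},{30,40}}
  toy <- matrix(c(10, 30, 20, 40), 2, 2)
  expect_equal(oracle_chisq(toy), unname(chisq.test(toy, correct = FALSE)$statistic))
  # random small tables: package path vs literal formula
  for (s in 1:10) {
    tab <- withr::with_seed(s, matrix(sample(5:50, 8, replace = TRUE), 2, 4))
    X <- matrix(0, sum(tab), 2, dimnames = list(NULL, c("inside", "outside")))
    # build a cohort realizing the table: one patient per mutation
    subtype <- rep(rep(1:4, 2), times = as.vector(t(tab)))
    inside <- rep(rep(c(1, 0), each = 4), times = as.vector(t(tab)))
    X[, 1] <- inside
    X[, 2] <- 1 - inside
    rownames(X) <- sprintf("P%04d", seq_len(nrow(X)))
    m <- mutation_matrix(X)
    res <- chisq_enrichment("inside", m, subtype)
    expect_equal(res$statistic, oracle_chisq(rbind(
      tapply(inside, subtype, sum),
      tapply(1 - inside, subtype, sum)
    )), tolerance = 1e-9)
    expect_equal(res$df, 3)
  }
  # proportional rows give statistic 0: both subtypes half inside, half outside
  Xp <- matrix(0, 40, 2, dimnames = list(sprintf("P%02d", 1:40), c("a", "b")))
  Xp[c(1:10, 21:30), 1] <- 1
  Xp[c(11:20, 31:40), 2] <- 1
  res0 <- chisq_enrichment("a", mutation_matrix(Xp), rep(1:2, each = 20))
  expect_lt(res0$statistic, 1e-9)
  # small expected counts are flagged
  Xs <- matrix(0, 8, 2, dimnames = list(sprintf("P%d", 1:8), c("a", "b")))
  Xs[1:2, 1] <- 1
  Xs[3:8, 2] <- 1
  expect_true(chisq_enrichment("a", mutation_matrix(Xs), rep(1:2, 4))$low_expected)
})

test_that("replication-time permutation test is extreme for latest replicators and degenerate on constants", {
  rt <- setNames(seq_len(200) / 10, sprintf("g%03d", 1:200))
  late <- names(rt)[191:200]
  res <- replication_time_test(late, rt, samplings = 1000, seed = 1)
  expect_lte(res$p_value, 2 / 1001)
  # constant replication times -> p = 1
  rt_const <- setNames(rep(5, 50), sprintf("g%03d", 1:50))
  expect_equal(replication_time_test(rt_const[1:5] |> names(), rt_const,
                                     samplings = 200, seed = 2)$p_value, 1)
  # a cluster drawn from the null is not flagged
  null_cl <- withr::with_seed(3, sample(names(rt), 15))
  expect_gt(replication_time_test(null_cl, rt, samplings = 500, seed = 4)$p_value, 0.01)
  expect_error(replication_time_test("zz", rt), "replication-time")
})

test_that("cluster typing uses the 80% proxy-load boundary inclusively", {
  net <- rand_network(15, edge_prob = 0.3, seed = 31)
  m <- rand_mutations(20, net, density = 0.2, seed = 31)
  res <- suppressWarnings(netnorm(m, net, k = default_k(m)))
  ps <- proxy_summary(res)
  # all-proxy gene set -> proxy type; no-proxy set -> mutation type
  proxy_gene <- ps$gene[ps$n_proxy > 0 & ps$n_proxy == ps$n_mutated][1]
  pure_gene <- ps$gene[ps$n_proxy == 0 & ps$n_mutated > 0][1]
  if (!is.na(proxy_gene)) {
    expect_equal(classify_cluster_type(proxy_gene, res, net)$type, "proxy")
  }
  expect_equal(classify_cluster_type(pure_gene, res, net)$type, "mutation")
  # synthetic exact-80% case via direct construction
  fake <- res
  fake$Xk <- matrix(1, 5, 2, dimnames = list(sprintf("P%d", 1:5), c("a", "b")))
  fake$genes <- c("a", "b")
  fake$added <- list(P1 = c("a", "b"), P2 = c("a", "b"), P3 = c("a", "b"),
                     P4 = c("a", "b"), P5 = character(0))
  net_ab <- gene_network(data.frame(from = "a", to = "b"))
  expect_equal(classify_cluster_type(c("a", "b"), fake, net_ab)$type, "proxy")
  expect_equal(classify_cluster_type(c("a", "b"), fake, net_ab)$proxy_fraction, 0.8)
})

test_that("characterize_gene_clusters assembles per-cluster reports", {
  blk <- two_block_cohort(n_per = 12, p_per = 8, p_in = 0.6, p_out = 0.05, seed = 41)
  genes <- colnames(blk$X)
  net <- gene_network(data.frame(from = genes[1:15], to = genes[2:16]),
                      genes = genes)
  m <- mutation_matrix(blk$X)
  res <- suppressWarnings(netnorm(m, net, k = default_k(m)))
  fit <- nmf_fit(res$Xk, 2, seed = 5)
  cs <- cluster_metapatients(fit$H, var_threshold = 0.0005, cut_height = 2)
  expect_gt(nrow(cs$clusters), 0)
  rt <- setNames(runif(length(genes)), genes)
  rep_tbl <- characterize_gene_clusters(cs, res, net, m, blk$truth, rep_times = rt)
  expect_true(all(c("cluster", "type", "proxy_fraction", "chisq_p", "reptime_p")
                  %in% names(rep_tbl)))
  expect_equal(nrow(rep_tbl), length(unique(cs$clusters$cluster)))
  expect_true(all(rep_tbl$proxy_fraction >= 0 & rep_tbl$proxy_fraction <= 1))
})
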