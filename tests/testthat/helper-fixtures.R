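# Fixture builders and independent oracles used across the suite. Oracles are
# deliberately written as plain loops / closed forms, independent of the
# package's vectorized implementations.

# random Erdos-Renyi-ish network over p genes (connected not guaranteed)
rand_network <- function(p, edge_prob = 0.15, seed = 1) {
  withr::with_seed(seed, {
    genes <- sprintf("g%03d", seq_len(p))
    pairs <- t(combn(p, 2))
    keep <- runif(nrow(pairs)) < edge_prob
    if (!any(keep)) keep[1] <- TRUE
    gene_network(
      data.frame(from = genes[pairs[keep, 1]], to = genes[pairs[keep, 2]]),
      genes = genes
    )
  })
}

# random connected network: random spanning tree plus extra edges
rand_connected_network <- function(p, extra = p, seed = 1) {
  withr::with_seed(seed, {
    genes <- sprintf("g%03d", seq_len(p))
    from <- to <- character(0)
    for (i in 2:p) {
      from <- c(from, genes[sample(i - 1, 1)])
      to <- c(to, genes[i])
    }
    for (e in seq_len(extra)) {
      ij <- sample(p, 2)
      from <- c(from, genes[ij[1]])
      to <- c(to, genes[ij[2]])
    }
    gene_network(data.frame(from = from, to = to), genes = genes)
  })
}

rand_mutations <- function(n, net, density = 0.2, seed = 1) {
  withr::with_seed(seed, {
    p <- length(net$genes)
    X <- matrix(rbinom(n * p, 1, density), n, p,
                dimnames = list(sprintf("P%03d", seq_len(n)), net$genes))
    mutation_matrix(X)
  })
}

rand_surv <- function(n, seed = 1, tie_frac = 0.3, censor = 0.3) {
  withr::with_seed(seed, {
    time <- sample(seq_len(max(3, round(n * (1 - tie_frac)))), n, replace = TRUE)
    data.frame(patient = sprintf("P%03d", seq_len(n)),
               time = as.numeric(time),
               event = rbinom(n, 1, 1 - censor))
  })
}

# --- NetNorM oracle: explicit (status, score, index) triple sort ------------
oracle_netnorm <- function(m, net, k) {
  p <- length(net$genes)
  Xk <- matrix(0, nrow(m$X), p, dimnames = dimnames(m$X))
  for (i in seq_len(nrow(m$X))) {
    x <- m$X[i, ]
    triples <- data.frame(idx = seq_len(p), status = x, score = NA_real_)
    for (g in seq_len(p)) {
      neigh <- which(net$adjacency[g, ] != 0)
      triples$score[g] <- if (x[g] == 1) length(neigh) else sum(x[neigh])
    }
    ord <- order(-triples$status, -triples$score, triples$idx)
    Xk[i, ord[seq_len(k)]] <- 1
  }
  Xk
}

# --- concordance index oracle: literal double loop over the printed formula -
oracle_ci <- function(surv, scores) {
  y <- surv$time
  d <- surv$event
  n <- length(y)
  num <- 0
  nz <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || y[i] > y[j]) next
      zij <- (y[i] < y[j] && d[i] == 1) ||
        (y[j] < y[i] && d[j] == 1) ||
        (y[i] == y[j] && (d[i] == 1 || d[j] == 1))
      if (!zij) next
      nz <- nz + 1
      diff <- scores[j] - scores[i]
      num <- num + if (diff > 0) 1 else if (diff == 0) 0.5 else 0
    }
  }
  num / nz
}

# --- stationary diffusion solution: X = (1-a) X0 (I - a S)^{-1} -------------
oracle_smooth_closed_form <- function(X0, net, alpha) {
  d <- as.numeric(net$degree)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  S <- diag(dinv) %*% as.matrix(net$adjacency) %*% diag(dinv)
  (1 - alpha) * X0 %*% solve(diag(ncol(X0)) - alpha * S)
}

# --- textbook two-group log-rank: loop over distinct event times ------------
oracle_logrank_2group <- function(time, event, group1) {
  stat_num <- 0
  stat_var <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n1_t <- sum(at_risk & group1)
    d_t <- sum(time == t & event == 1)
    d1_t <- sum(time == t & event == 1 & group1)
    stat_num <- stat_num + (d1_t - d_t * n1_t / n_t)
    if (n_t > 1) {
      stat_var <- stat_var +
        d_t * (n1_t / n_t) * (1 - n1_t / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  stat_num^2 / stat_var
}

# --- Pearson chi-square from marginals: literal formula ---------------------
oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# --- hinge + L1 objective minimum by refined grid search (2-D only) ---------
oracle_svm_grid_min <- function(D, C, lim = 5, steps = 41L, refinements = 4L) {
  obj <- function(w1, w2) {
    u <- D %*% c(w1, w2)
    0.5 * (abs(w1) + abs(w2)) + C * sum(pmax(1 - u, 0))
  }
  c1 <- c2 <- 0
  half <- lim
  best <- Inf
  for (r in seq_len(refinements)) {
    g1 <- seq(c1 - half, c1 + half, length.out = steps)
    g2 <- seq(c2 - half, c2 + half, length.out = steps)
    vals <- outer(g1, g2, Vectorize(obj))
    ij <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    c1 <- g1[ij[1]]
    c2 <- g2[ij[2]]
    best <- min(vals)
    half <- half * 2.2 / (steps - 1) # a couple of old grid cells wide
  }
  list(value = best, w = c(c1, c2))
}

# adjusted Rand index between two labelings
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# two-block mutation cohort for stratification tests
two_block_cohort <- function(n_per = 30, p_per = 20, p_in = 0.35, p_out = 0.05,
                             seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per
    p <- 2 * p_per
    X <- matrix(rbinom(n * p, 1, p_out), n, p)
    X[1:n_per, 1:p_per] <- rbinom(n_per * p_per, 1, p_in)
    X[(n_per + 1):n, (p_per + 1):p] <- rbinom(n_per * p_per, 1, p_in)
    dimnames(X) <- list(sprintf("P%03d", 1:n), sprintf("g%03d", 1:p))
    list(X = X, truth = rep(1:2, each = n_per))
  })
}
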