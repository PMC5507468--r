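#' Log-rank test for survival differences between groups
#'
#' Standard (G-1)-degree-of-freedom log-rank chi-square over the pooled risk
#' sets, as computed by [survival::survdiff()], with the p-value from the
#' chi-square tail.
#'
#' @param surv data frame with columns `time` and `event`.
#' @param groups group labels, one per patient (>= 2 nonempty groups).
#' @return tibble with columns `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(surv, groups) {
  s <- as_survival(surv)
  groups <- as.factor(groups)
  if (length(groups) != length(s$y)) abort("`groups` length must match the patient count")
  if (nlevels(droplevels(groups)) < 2) abort("log-rank test needs at least two nonempty groups")
  fit <- survival::survdiff(survival::Surv(s$y, s$delta) ~ g,
                            data = data.frame(g = droplevels(groups)))
  df <- length(fit$n) - 1
  tibble(statistic = unname(fit$chisq), df = df,
         p_value = pchisq(unname(fit$chisq), df, lower.tail = FALSE))
}

# Vectorized two-group log-rank chi-square statistics for B candidate group
# memberships at once. `membership` is an n x B logical/0-1 matrix (TRUE =
# group 1). Used for the 1000-draw reallocation nulls, where survdiff call
# overhead would dominate; unit-tested against survdiff.
logrank_stat_2group <- function(time, event, membership) {
  membership <- as.matrix(membership) * 1
  n <- length(time)
  stopifnot(nrow(membership) == n)
  ord <- order(time)
  time <- time[ord]
  event <- event[ord]
  M <- membership[ord, , drop = FALSE]
  # at-risk counts counting from the bottom (later times)
  n_at_risk <- n - seq_len(n) + 1L
  rc <- matrixStats::colCumsums(M[n:1, , drop = FALSE])[n:1, , drop = FALSE]
  ut <- unique(time[event == 1])
  first_idx <- match(ut, time) # first row with each event time = risk-set head
  U <- numeric(ncol(M))
  V <- numeric(ncol(M))
  for (tpos in seq_along(ut)) {
    rows_t <- which(time == ut[tpos] & event == 1)
    d <- length(rows_t)
    nt <- n_at_risk[first_idx[tpos]]
    n1 <- rc[first_idx[tpos], ]
    d1 <- colSums(M[rows_t, , drop = FALSE])
    U <- U + (d1 - d * n1 / nt)
    if (nt > 1) {
      V <- V + d * (n1 / nt) * (1 - n1 / nt) * (nt - d) / (nt - 1)
    }
  }
  ifelse(V > 0, U^2 / V, 0)
}

#' Burden-only reallocation null for a proxy gene
#'
#' NetNorM proxy mutations mark both low total burden and a high
#' neighbourhood mutational burden. To test whether a proxy gene's survival
#' association is explained by burden alone, the proxy mutations are redrawn
#' under a model that depends only on the totals: original mutations `M_o`
#' stay fixed, and `|M_p|` distinct eligible patients (burden `T_i < k`, not
#' in `M_o`) are redrawn without replacement with weights proportional to
#' `k - T_i`. For each of `draws` reallocations the two-group log-rank
#' statistic (mutated after normalization vs not) is computed; the empirical
#' tail probability of the observed statistic uses the +1 correction,
#' `p = (1 + #\{null >= observed\}) / (1 + draws)`.
#'
#' @param gene gene symbol with at least one proxy mutation in `result`.
#' @param result a [netnorm()] result.
#' @param surv data frame with columns `time` and `event`, aligned to the
#'   patients of `result`.
#' @param draws number of null reallocations (default 1000).
#' @param seed seed for the draws.
#' @param replace draw eligible patients with replacement instead (a
#'   sensitivity variant; the default matches the without-replacement
#'   reading of the single-inclusion probabilities).
#' @return object of class `proxy_null`: `gene`, `observed_statistic`,
#'   `null_statistics`, `p`, the patient sets used, the eligible patients
#'   with their reallocation `weights`, and per-patient `selection_counts`
#'   over the draws (for checking the sampler's frequencies).
#' @export
simulate_proxy_null <- function(gene, result, surv, draws = 1000L, seed = 1L,
                                replace = FALSE) {
  stopifnot(inherits(result, "netnorm_result"))
  if (!gene %in% result$genes) abort(sprintf("gene '%s' is not in the result", gene))
  s <- as_survival(surv)
  n <- length(result$patients)
  stopifnot(length(s$y) == n)
  g <- match(gene, result$genes)
  mutated <- which(result$Xk[, g] == 1)
  proxy_patients <- which(result$patients %in%
    names(which(vapply(result$added, function(a) gene %in% a, TRUE))))
  M_p <- intersect(mutated, proxy_patients)
  M_o <- setdiff(mutated, M_p)
  if (length(M_p) == 0) abort(sprintf("gene '%s' has no proxy mutations", gene))
  k <- result$k
  eligible <- setdiff(which(result$totals < k), M_o)
  if (!replace && length(eligible) < length(M_p)) {
    abort("fewer eligible patients than proxy mutations to reallocate")
  }
  w <- k - as.numeric(result$totals[eligible])
  observed <- logrank_stat_2group(s$y, s$delta,
                                  matrix(seq_len(n) %in% mutated, ncol = 1))
  member <- matrix(FALSE, n, draws)
  member[M_o, ] <- TRUE
  with_seed(seed, {
    for (b in seq_len(draws)) {
      pick <- eligible[sample.int(length(eligible), length(M_p),
                                  replace = replace, prob = w)]
      member[pick, b] <- TRUE
    }
  })
  null_stats <- logrank_stat_2group(s$y, s$delta, member)
  sel <- rowSums(member)
  sel[M_o] <- 0 # original mutations are fixed, not selections
  structure(
    list(gene = gene, observed_statistic = unname(observed),
         null_statistics = unname(null_stats),
         p = (1 + sum(null_stats >= observed)) / (1 + draws),
         M_o = result$patients[M_o], M_p = result$patients[M_p],
         eligible = result$patients[eligible], weights = setNames(w, result$patients[eligible]),
         selection_counts = setNames(sel[eligible], result$patients[eligible]),
         draws = draws),
    class = "proxy_null"
  )
}

#' @export
print.proxy_null <- function(x, ...) {
  cat(sprintf(
    "<proxy_null> %s: observed log-rank %.3f vs %d burden-only reallocations; p = %.4g\n",
    x$gene, x$observed_statistic, x$draws, x$p
  ))
  invisible(x)
}

#' @method glance proxy_null
#' @export
glance.proxy_null <- function(x, ...) {
  tibble(gene = x$gene, observed_statistic = x$observed_statistic,
         null_median = median(x$null_statistics), p = x$p,
         n_original = length(x$M_o), n_proxy = length(x$M_p))
}
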