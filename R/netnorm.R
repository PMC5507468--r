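#' Per-patient NetNorM gene ranking
#'
#' Orders all genes for one patient: mutated genes first, among them by
#' decreasing network degree; non-mutated genes next, by decreasing number of
#' mutated neighbours. Ties are broken by ascending column position in the
#' (deterministic, lexicographic) gene order of the network, which stands in
#' for "the order in which genes occur in the mutation matrix".
#'
#' @param profile binary 0/1 vector aligned to `net$genes`.
#' @param net a [gene_network()].
#' @return integer permutation of `seq_along(net$genes)`: first element is
#'   the top-ranked gene's column index.
#' @export
rank_genes <- function(profile, net) {
  stopifnot(inherits(net, "gene_network"))
  if (length(profile) != length(net$genes)) {
    abort("profile length does not match the network gene count")
  }
  profile <- as.numeric(profile)
  nmb <- as.vector(net$adjacency %*% profile)
  score <- ifelse(profile == 1, net$degree, nmb)
  order(-profile, -score, seq_along(profile))
}

#' Median-burden default for the NetNorM target k
#'
#' The cohort-level default for the target mutation count: the median of the
#' per-patient burdens, with half-integral medians (even cohort sizes)
#' rounded down.
#'
#' @param m a [mutation_matrix()].
#' @return positive integer.
#' @export
default_k <- function(m) {
  stopifnot(inherits(m, "mutation_matrix"))
  if (length(m$totals) == 0) abort("empty cohort")
  max(1L, as.integer(floor(median(m$totals))))
}

#' NetNorM: normalize every mutation profile to exactly k mutated genes
#'
#' For each patient the genes are ranked by [rank_genes()] and the top `k`
#' are marked mutated. Patients with more than `k` mutations therefore lose
#' their lowest-degree mutated genes; patients with fewer gain "proxy"
#' mutations in the non-mutated genes with the most mutated neighbours. The
#' output rows all sum to exactly `k`, so every patient has the same value
#' distribution by construction.
#'
#' @param m a [mutation_matrix()] aligned to `net$genes` (see
#'   [restrict_to_network()]).
#' @param net a [gene_network()].
#' @param k target mutation count; `NULL` (default) uses [default_k()].
#' @return object of class `netnorm_result`: `Xk` (binary matrix, every row
#'   summing to `k`), `k`, `totals` (original burdens), `added` and `removed`
#'   (named lists of per-patient proxy / removed gene symbols).
#' @examples
#' net <- gene_network(data.frame(from = c("H", "H", "H"), to = c("g1", "g2", "g3")))
#' m <- restrict_to_network(
#'   mutation_matrix(matrix(1, 1, 1, dimnames = list("P1", "g2"))), net
#' )
#' netnorm(m, net, k = 2)$Xk # proxy added at the hub H
#' @export
netnorm <- function(m, net, k = NULL) {
  stopifnot(inherits(m, "mutation_matrix"), inherits(net, "gene_network"))
  if (!identical(m$genes, net$genes)) {
    abort("mutation matrix is not aligned to the network; call restrict_to_network() first")
  }
  if (is.null(k)) k <- default_k(m)
  k <- as.integer(k)
  p <- length(net$genes)
  if (k < 1 || k > p) {
    abort(sprintf("k = %d must lie in 1..%d (the gene count)", k, p))
  }
  if (any(m$totals == 0)) {
    warn(sprintf(
      "%d patient(s) carry zero mutations; their %d proxies are chosen by tie-break order only",
      sum(m$totals == 0), k
    ))
  }
  NMB <- nmb_matrix(m$X, net) # patients x genes mutated-neighbour counts
  deg <- as.numeric(net$degree)
  Xk <- matrix(0, nrow(m$X), p, dimnames = dimnames(m$X))
  added <- removed <- vector("list", nrow(m$X))
  names(added) <- names(removed) <- m$patients
  col_idx <- seq_len(p)
  for (i in seq_len(nrow(m$X))) {
    x <- m$X[i, ]
    score <- ifelse(x == 1, deg, NMB[i, ])
    ord <- order(-x, -score, col_idx)
    top <- ord[seq_len(k)]
    Xk[i, top] <- 1
    if (m$totals[i] > k) {
      removed[[i]] <- m$genes[x == 1 & Xk[i, ] == 0]
      added[[i]] <- character(0)
    } else {
      added[[i]] <- m$genes[x == 0 & Xk[i, ] == 1]
      removed[[i]] <- character(0)
    }
  }
  structure(
    list(Xk = Xk, k = k, totals = m$totals, added = added, removed = removed,
         genes = m$genes, patients = m$patients),
    class = "netnorm_result"
  )
}

#' @export
print.netnorm_result <- function(x, ...) {
  n_add <- sum(lengths(x$added) > 0)
  n_rem <- sum(lengths(x$removed) > 0)
  cat(sprintf(
    "<netnorm_result> %d patients x %d genes normalized to k = %d (%d gained proxies, %d lost mutations)\n",
    length(x$patients), length(x$genes), x$k, n_add, n_rem
  ))
  invisible(x)
}

#' Summarize proxy and removed mutations per patient
#'
#' @param x a `netnorm_result`.
#' @param ... unused.
#' @return tibble with one row per patient: original burden, counts of
#'   proxies added and mutations removed, and list-columns of the genes.
#' @method tidy netnorm_result
#' @export
tidy.netnorm_result <- function(x, ...) {
  tibble(
    patient = x$patients,
    burden = unname(x$totals),
    k = x$k,
    n_added = unname(lengths(x$added)),
    n_removed = unname(lengths(x$removed)),
    added = unname(x$added),
    removed = unname(x$removed)
  )
}

#' Per-gene proxy counts of a NetNorM result
#'
#' @param x a `netnorm_result`.
#' @return tibble: gene, number of patients mutated after normalization,
#'   number of those that are proxies.
#' @export
proxy_summary <- function(x) {
  stopifnot(inherits(x, "netnorm_result"))
  tab <- table(factor(unlist(x$added), levels = x$genes))
  tibble(
    gene = x$genes,
    n_mutated = as.integer(colSums(x$Xk)),
    n_proxy = as.integer(tab)
  )
}
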