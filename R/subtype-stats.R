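#' Cluster genes by their metapatient weight profiles
#'
#' Restricts the NMF basis matrix `H` (metapatients x genes) to the genes
#' whose weight variance across basis vectors exceeds `var_threshold` — the
#' genes most differentially mutated across subtypes — and clusters them
#' hierarchically with centroid linkage and euclidean distance, cutting the
#' tree at `cut_height`. Because R's centroid linkage operates on squared
#' euclidean distances, the tree is built on squared distances and the cut
#' applied at `cut_height^2`, so `cut_height` stays on the euclidean scale.
#' Clusters are numbered left to right in dendrogram leaf order.
#'
#' @param H metapatients x genes matrix (e.g. `nmf_fit()$H`).
#' @param var_threshold minimum weight variance for a gene to be kept
#'   (default 0.01).
#' @param cut_height tree cut height, euclidean scale (default 5.5).
#' @return object of class `gene_cluster_set`: tibble `clusters` (columns
#'   `gene`, `cluster`), the `hclust` tree, and the filter settings. Empty
#'   (with a warning) when no gene passes the variance filter.
#' @export
cluster_metapatients <- function(H, var_threshold = 0.01, cut_height = 5.5) {
  assert_matrix_like(H, "H")
  H <- as.matrix(H)
  if (is.null(colnames(H))) colnames(H) <- paste0("g", seq_len(ncol(H)))
  v <- apply(H, 2, var)
  keep <- which(v > var_threshold)
  if (length(keep) == 0) {
    warn("no gene exceeds the variance threshold; returning an empty cluster set")
    return(structure(list(clusters = tibble(gene = character(), cluster = integer()),
                          hclust = NULL, var_threshold = var_threshold,
                          cut_height = cut_height),
                     class = "gene_cluster_set"))
  }
  Hf <- H[, keep, drop = FALSE]
  if (length(keep) == 1) {
    return(structure(list(clusters = tibble(gene = colnames(Hf), cluster = 1L),
                          hclust = NULL, var_threshold = var_threshold,
                          cut_height = cut_height),
                     class = "gene_cluster_set"))
  }
  hc <- hclust(dist(t(Hf))^2, method = "centroid")
  raw <- cutree(hc, h = cut_height^2)
  # renumber left-to-right along the dendrogram
  leaf_order <- hc$order
  first_seen <- unique(raw[leaf_order])
  cl <- match(raw, first_seen)
  structure(
    list(clusters = tibble(gene = colnames(Hf), cluster = as.integer(cl)),
         hclust = hc, var_threshold = var_threshold, cut_height = cut_height),
    class = "gene_cluster_set"
  )
}

#' @export
print.gene_cluster_set <- function(x, ...) {
  cat(sprintf("<gene_cluster_set> %d genes in %d cluster(s) (variance > %g, cut %g)\n",
              nrow(x$clusters), length(unique(x$clusters$cluster)),
              x$var_threshold, x$cut_height))
  invisible(x)
}

#' Embed a gene cluster into its dense subgraph
#'
#' Augments a gene set with every outside gene adjacent to at least
#' `link_frac` of the cluster members (count threshold
#' `ceiling(link_frac * |cluster|)`), i.e. the genes lying in the same dense
#' subgraph. Used before mutation-enrichment testing of proxy-dominated
#' clusters, whose signal lives in the whole subgraph rather than the
#' cluster alone.
#'
#' @param cluster character vector of gene symbols.
#' @param net a [gene_network()].
#' @param link_frac required fraction of cluster genes an outside gene must
#'   touch (default 0.9).
#' @return character vector: the cluster plus its embedding.
#' @export
dense_subgraph_embedding <- function(cluster, net, link_frac = 0.9) {
  stopifnot(inherits(net, "gene_network"))
  cluster <- intersect(cluster, net$genes)
  if (length(cluster) == 0) return(character(0))
  need <- ceiling(link_frac * length(cluster))
  counts <- as.vector(net$adjacency %*% (net$genes %in% cluster))
  extra <- net$genes[counts >= need & !(net$genes %in% cluster)]
  sort_genes(union(cluster, extra))
}

#' Chi-square enrichment of raw mutations in a gene set across subtypes
#'
#' Builds the 2 x G contingency table of raw mutation counts inside vs
#' outside the gene set per subtype and applies Pearson's chi-square test
#' with G - 1 degrees of freedom (no continuity correction). Signed per-cell
#' contributions (`sign(O - E) * (O - E)^2 / E` for the inside row) show
#' which subtypes are enriched (positive) or depleted (negative).
#'
#' @param gene_set character vector of gene symbols.
#' @param m_raw the raw [mutation_matrix()] (before normalization).
#' @param subtypes subtype labels, one per patient.
#' @return list of class `chisq_enrichment`: `statistic`, `df`, `p_value`,
#'   `table` (2 x G), `contributions` tibble, `low_expected` flag (any
#'   expected cell < 5).
#' @export
chisq_enrichment <- function(gene_set, m_raw, subtypes) {
  stopifnot(inherits(m_raw, "mutation_matrix"))
  subtypes <- as.factor(subtypes)
  if (length(subtypes) != length(m_raw$patients)) {
    abort("`subtypes` length must match the patient count")
  }
  inside_genes <- intersect(gene_set, m_raw$genes)
  inside <- if (length(inside_genes)) {
    rowSums(m_raw$X[, inside_genes, drop = FALSE])
  } else {
    rep(0, length(m_raw$patients))
  }
  total <- rowSums(m_raw$X)
  tab <- rbind(
    inside = tapply(inside, subtypes, sum, default = 0),
    outside = tapply(total - inside, subtypes, sum, default = 0)
  )
  res <- suppressWarnings(chisq.test(tab, correct = FALSE))
  contrib <- sign(res$observed - res$expected) * (res$observed - res$expected)^2 / res$expected
  structure(
    list(
      statistic = unname(res$statistic), df = unname(res$parameter),
      p_value = unname(res$p.value), table = tab,
      contributions = tibble(
        subtype = colnames(tab),
        inside_observed = unname(tab["inside", ]),
        inside_expected = unname(res$expected["inside", ]),
        contribution = unname(contrib["inside", ])
      ),
      low_expected = any(res$expected < 5)
    ),
    class = "chisq_enrichment"
  )
}

#' @export
print.chisq_enrichment <- function(x, ...) {
  cat(sprintf("<chisq_enrichment> X-squared = %.3f, df = %d, p = %.4g%s\n",
              x$statistic, x$df, x$p_value,
              if (x$low_expected) " [expected cell < 5]" else ""))
  invisible(x)
}

#' @method glance chisq_enrichment
#' @export
glance.chisq_enrichment <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
         low_expected = x$low_expected)
}

#' Replication-time permutation test for a gene cluster
#'
#' Compares the median replication time of a gene cluster against
#' size-matched gene sets drawn uniformly at random without replacement from
#' all genes with replication-time information. The two-sided empirical
#' p-value (with the +1 correction) is the doubled smaller tail probability,
#' capped at 1 — late- and early-replicating clusters both count as extreme.
#'
#' @param cluster character vector of gene symbols.
#' @param rep_times named numeric vector of per-gene replication times, or a
#'   data frame with columns `gene` and `time`.
#' @param samplings number of random gene sets (default 1000).
#' @param seed seed for the draws.
#' @return list of class `reptime_test`: `observed_median`,
#'   `null_medians`, `p_value`, `n_genes`.
#' @export
replication_time_test <- function(cluster, rep_times, samplings = 1000L, seed = 1L) {
  if (is.data.frame(rep_times)) {
    rep_times <- setNames(as.numeric(rep_times$time), as.character(rep_times$gene))
  }
  genes <- intersect(cluster, names(rep_times))
  if (length(genes) == 0) abort("no cluster gene has replication-time information")
  obs <- median(rep_times[genes])
  l <- length(genes)
  null_medians <- with_seed(seed, vapply(seq_len(samplings), function(b) {
    median(rep_times[sample.int(length(rep_times), l)])
  }, 0))
  p_hi <- (1 + sum(null_medians >= obs)) / (1 + samplings)
  p_lo <- (1 + sum(null_medians <= obs)) / (1 + samplings)
  structure(
    list(observed_median = obs, null_medians = null_medians,
         p_value = min(1, 2 * min(p_hi, p_lo)), n_genes = l),
    class = "reptime_test"
  )
}

#' @export
print.reptime_test <- function(x, ...) {
  cat(sprintf("<reptime_test> median replication time %.3f over %d genes; two-sided p = %.4g\n",
              x$observed_median, x$n_genes, x$p_value))
  invisible(x)
}

#' Classify a gene cluster as proxy-type or mutation-type
#'
#' A cluster is proxy-type when proxy mutations account for at least 80% of
#' its total mutational load after normalization (boundary inclusive);
#' proxy-type clusters sit in dense subgraphs and are enrichment-tested on
#' their [dense_subgraph_embedding()], mutation-type clusters directly. The
#' within-cluster subgraph density is reported alongside.
#'
#' @param cluster character vector of gene symbols.
#' @param result a [netnorm()] result.
#' @param net a [gene_network()].
#' @param proxy_threshold proxy fraction boundary (default 0.8).
#' @return tibble with one row: `type`, `proxy_fraction`, `total_load`,
#'   `density`.
#' @export
classify_cluster_type <- function(cluster, result, net, proxy_threshold = 0.8) {
  stopifnot(inherits(result, "netnorm_result"), inherits(net, "gene_network"))
  genes <- intersect(cluster, result$genes)
  total <- sum(result$Xk[, genes, drop = FALSE])
  proxy <- sum(vapply(result$added, function(a) length(intersect(a, genes)), 0L))
  frac <- if (total > 0) proxy / total else 0
  members <- which(net$genes %in% genes)
  density <- if (length(members) >= 2) {
    sum(net$adjacency[members, members]) / (length(members) * (length(members) - 1))
  } else {
    NA_real_
  }
  tibble(
    type = if (frac >= proxy_threshold) "proxy" else "mutation",
    proxy_fraction = frac, total_load = total, density = density
  )
}

#' Characterize gene clusters across patient subtypes
#'
#' Convenience wrapper running, for every cluster of a
#' [cluster_metapatients()] result: type classification, the chi-square
#' mutation-enrichment test (on the dense-subgraph embedding for proxy-type
#' clusters, on the cluster itself otherwise) and, when replication times
#' are supplied, the replication-time permutation test.
#'
#' @param cluster_set a `gene_cluster_set`.
#' @param result a [netnorm()] result.
#' @param net a [gene_network()].
#' @param m_raw the raw [mutation_matrix()].
#' @param subtypes subtype labels, one per patient.
#' @param rep_times optional replication times (see
#'   [replication_time_test()]).
#' @param seed seed for the replication-time draws.
#' @return tibble with one row per cluster.
#' @export
characterize_gene_clusters <- function(cluster_set, result, net, m_raw, subtypes,
                                       rep_times = NULL, seed = 1L) {
  stopifnot(inherits(cluster_set, "gene_cluster_set"))
  ids <- sort(unique(cluster_set$clusters$cluster))
  purrr::map_dfr(ids, function(id) {
    genes <- cluster_set$clusters$gene[cluster_set$clusters$cluster == id]
    cls <- classify_cluster_type(genes, result, net)
    tested <- if (cls$type == "proxy") dense_subgraph_embedding(genes, net) else genes
    chi <- chisq_enrichment(tested, m_raw, subtypes)
    rt_p <- if (!is.null(rep_times)) {
      tryCatch(replication_time_test(genes, rep_times, seed = derive_seed(seed, id))$p_value,
               error = function(e) NA_real_)
    } else {
      NA_real_
    }
    tibble(
      cluster = id, n_genes = length(genes), type = cls$type,
      proxy_fraction = cls$proxy_fraction, density = cls$density,
      n_tested_genes = length(tested),
      chisq = chi$statistic, chisq_p = chi$p_value,
      low_expected = chi$low_expected, reptime_p = rt_p
    )
  })
}
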