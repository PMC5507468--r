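#' Construct an undirected gene network
#'
#' Builds the network container used throughout the package: an ordered gene
#' vocabulary, a sparse symmetric 0/1 adjacency matrix aligned to it, and the
#' per-gene degree. Self-loops are dropped and duplicate (or reversed) edges
#' collapse to a single undirected edge. Genes are ordered lexicographically
#' at construction time so that every matrix built against the network has a
#' reproducible column order — the NetNorM tie-break depends on this order,
#' so it must be deterministic.
#'
#' @param edges a data frame whose first two columns are gene symbols (one
#'   edge per row), or a two-column character matrix.
#' @param genes optional character vector of additional gene symbols to keep
#'   as isolated nodes (degree 0).
#' @return an object of class `gene_network` with elements `genes`,
#'   `adjacency` (sparse symmetric `dgCMatrix`), `degree` (named integer) and
#'   `edges` (tibble with columns `from`, `to`, `from < to`).
#' @examples
#' net <- gene_network(data.frame(from = c("A", "B"), to = c("B", "C")))
#' net$degree
#' @export
gene_network <- function(edges, genes = NULL) {
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!is.data.frame(edges) || ncol(edges) < 2) {
    abort("`edges` must be a data frame (or matrix) with at least two columns")
  }
  from <- as.character(edges[[1]])
  to <- as.character(edges[[2]])
  keep <- from != to # no self-loops
  from <- from[keep]
  to <- to[keep]
  # canonical unordered representation
  a <- pmin(from, to)
  b <- pmax(from, to)
  dup <- duplicated(paste(a, b, sep = "\r"))
  a <- a[!dup]
  b <- b[!dup]
  all_genes <- sort_genes(unique(c(a, b, as.character(genes))))
  p <- length(all_genes)
  ia <- match(a, all_genes)
  ib <- match(b, all_genes)
  adj <- Matrix::sparseMatrix(
    i = c(ia, ib), j = c(ib, ia), x = 1,
    dims = c(p, p), dimnames = list(all_genes, all_genes)
  )
  adj@x[] <- 1 # collapse any residual multiplicity
  deg <- setNames(as.integer(Matrix::rowSums(adj)), all_genes)
  structure(
    list(
      genes = all_genes,
      adjacency = adj,
      degree = deg,
      edges = tibble(from = a, to = b)[order(a, b, method = "radix"), ]
    ),
    class = "gene_network"
  )
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf(
    "<gene_network> %d genes, %d undirected edges (max degree %d)\n",
    length(x$genes), nrow(x$edges), if (length(x$degree)) max(x$degree) else 0L
  ))
  invisible(x)
}

#' Interaction types excluded by default when reading SIF networks
#'
#' Pathway Commons SIF exports mix gene-gene interactions with records that
#' involve small molecules; these interaction types are dropped by default so
#' the loaded network only connects genes.
#'
#' @return character vector of interaction-type strings.
#' @export
pc_excluded_types <- function() {
  c(
    "consumption-controlled-by", "controls-production-of",
    "controls-transport-of-chemical", "chemical-affects", "reacts-with",
    "used-to-produce", "SmallMoleculeReference",
    "ProteinReference;SmallMoleculeReference", "ProteinReference"
  )
}

#' Read an undirected gene network from a SIF or two-column edge list
#'
#' Accepts the common SIF dialects: three whitespace- or tab-separated fields
#' (`node  interaction-type  node`) or plain two-column edge lists; the two
#' row shapes may be mixed in one file. Lines starting with `#` and blank
#' lines are skipped. Edges whose interaction type is excluded are dropped;
#' duplicate edges and self-loops are collapsed/removed.
#'
#' @param path path to the file.
#' @param excluded_interaction_types character vector of interaction types to
#'   drop (default [pc_excluded_types()]).
#' @return a [gene_network()].
#' @export
read_sif <- function(path, excluded_interaction_types = pc_excluded_types()) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) abort(sprintf("no edge records in '%s'", path))
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf != 2L & nf != 3L)
  if (length(bad) > 0) {
    abort(sprintf(
      "malformed SIF row at line %d of '%s': expected 2 or 3 columns, found %d",
      idx[bad[1]], path, nf[bad[1]]
    ))
  }
  from <- vapply(fields, `[[`, character(1), 1L)
  to <- vapply(fields, function(f) f[[length(f)]], character(1))
  type <- vapply(fields, function(f) if (length(f) == 3L) f[[2L]] else NA_character_, character(1))
  drop <- !is.na(type) & type %in% excluded_interaction_types
  gene_network(tibble(from = from[!drop], to = to[!drop]))
}

#' Relabel network nodes by a random permutation
#'
#' Shuffles gene labels while keeping the edge structure fixed, the null
#' model used to test whether biological information in the network (and not
#' just its degree distribution) drives performance: the degree multiset is
#' preserved exactly, only the gene-to-position assignment changes.
#'
#' @param net a [gene_network()].
#' @param seed integer seed; the permutation is a deterministic function of it.
#' @return a new `gene_network` on the same gene set.
#' @export
randomize_labels <- function(net, seed) {
  stopifnot(inherits(net, "gene_network"))
  if (length(net$genes) == 0) abort("cannot randomize an empty network")
  perm <- with_seed(seed, sample(net$genes))
  relabel <- setNames(perm, net$genes)
  gene_network(
    tibble(from = unname(relabel[net$edges$from]), to = unname(relabel[net$edges$to])),
    genes = net$genes
  )
}

#' Count mutated network neighbours of every gene
#'
#' For one patient profile, the neighbourhood mutational burden (NMB) of a
#' gene is the number of its direct neighbours carrying a mutation; this is
#' the score NetNorM uses to pick proxy genes.
#'
#' @param net a [gene_network()].
#' @param profile binary 0/1 vector aligned to `net$genes`.
#' @return named integer vector of mutated-neighbour counts.
#' @export
mutated_neighbour_counts <- function(net, profile) {
  stopifnot(inherits(net, "gene_network"))
  if (length(profile) != length(net$genes)) {
    abort(sprintf(
      "profile length %d does not match the %d network genes",
      length(profile), length(net$genes)
    ))
  }
  setNames(as.integer(as.vector(net$adjacency %*% as.numeric(profile))), net$genes)
}

# patients x genes NMB matrix: row i = mutated-neighbour counts under row i of X
nmb_matrix <- function(X, net) {
  as.matrix(X %*% net$adjacency)
}
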