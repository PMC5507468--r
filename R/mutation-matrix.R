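#' Construct a binary patients-by-genes mutation matrix
#'
#' The raw representation used everywhere in the package: entry `(p, g)` is 1
#' when patient `p` carries at least one retained somatic mutation in gene
#' `g`. Row sums are the per-patient mutational burdens `T_i`.
#'
#' @param X numeric 0/1 matrix with patient row names and gene column names
#'   (or supply `patients` / `genes`).
#' @param patients,genes optional identifier vectors overriding the dimnames.
#' @return object of class `mutation_matrix` with elements `X` (binary base
#'   matrix), `patients`, `genes` and `totals` (named row sums).
#' @export
mutation_matrix <- function(X, patients = rownames(X), genes = colnames(X)) {
  assert_matrix_like(X, "X")
  X <- as.matrix(X)
  if (is.null(patients) || is.null(genes)) {
    abort("patient and gene identifiers are required (dimnames or arguments)")
  }
  patients <- as.character(patients)
  genes <- as.character(genes)
  if (anyDuplicated(patients)) abort("duplicate patient identifiers")
  if (anyDuplicated(genes)) abort("duplicate gene identifiers")
  if (!all(X %in% c(0, 1))) abort("mutation matrix entries must be 0 or 1")
  storage.mode(X) <- "double"
  dimnames(X) <- list(patients, genes)
  structure(
    list(
      X = X, patients = patients, genes = genes,
      totals = setNames(as.integer(rowSums(X)), patients)
    ),
    class = "mutation_matrix"
  )
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat(sprintf(
    "<mutation_matrix> %d patients x %d genes; burden median %s (range %s-%s)\n",
    length(x$patients), length(x$genes),
    median(x$totals), min(x$totals), max(x$totals)
  ))
  invisible(x)
}

#' Build a mutation matrix from a minimal MAF-like table
#'
#' Reads a tab-separated table with (at least) the columns `Hugo_Symbol`,
#' `Tumor_Sample_Barcode` and `Variant_Classification` and collapses it to a
#' binary patients-by-genes matrix. Records classified as silent are dropped
#' unless `keep_silent = TRUE`; the silent test is the literal string
#' `"Silent"`, case-insensitively — every other classification (missense,
#' nonsense, indels, splice, ...) counts as non-silent. Multiple records for
#' one patient-gene pair collapse to a single 1.
#'
#' @param path path to the tab-separated file.
#' @param keep_silent keep records classified as silent (default `FALSE`).
#' @return a [mutation_matrix()] with lexicographically ordered patients and
#'   genes.
#' @export
read_maf <- function(path, keep_silent = FALSE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "#")
  required <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    abort(sprintf("MAF file lacks required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(tab) == 0) abort(sprintf("no mutation records in '%s'", path))
  # every sample in the file stays a cohort member, even if all its records
  # are filtered out (it then carries a zero profile)
  patients <- sort_genes(unique(as.character(tab$Tumor_Sample_Barcode)))
  if (!keep_silent) {
    tab <- tab[tolower(tab$Variant_Classification) != "silent", , drop = FALSE]
  }
  if (nrow(tab) == 0) abort("no mutation records remain after the silent filter")
  genes <- sort_genes(unique(as.character(tab$Hugo_Symbol)))
  X <- matrix(0, length(patients), length(genes), dimnames = list(patients, genes))
  X[cbind(match(tab$Tumor_Sample_Barcode, patients), match(tab$Hugo_Symbol, genes))] <- 1
  mutation_matrix(X)
}

#' Read a binary mutation matrix from TSV
#'
#' Expects patients as rows, a header row of gene symbols and a first column
#' of patient identifiers (the layout written by [write_mutation_tsv()]).
#'
#' @param path path to the file.
#' @return a [mutation_matrix()].
#' @export
read_mutation_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  X <- as.matrix(tab[, -1, drop = FALSE])
  rownames(X) <- as.character(tab[[1]])
  mutation_matrix(X)
}

#' Write a mutation matrix to TSV
#'
#' @param m a [mutation_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mutation_tsv <- function(m, path) {
  stopifnot(inherits(m, "mutation_matrix"))
  df <- data.frame(patient = m$patients, m$X, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict a mutation matrix to the genes of a network
#'
#' Drops matrix columns absent from the network and appends all-zero columns
#' for network genes never mutated in the cohort, so the result is aligned
#' column-for-column with `net$genes` (the alignment every downstream
#' operation assumes). Patients left with zero mutations are retained.
#'
#' @param m a [mutation_matrix()].
#' @param net a [gene_network()].
#' @return a [mutation_matrix()] whose genes equal `net$genes`.
#' @export
restrict_to_network <- function(m, net) {
  stopifnot(inherits(m, "mutation_matrix"), inherits(net, "gene_network"))
  shared <- intersect(m$genes, net$genes)
  if (length(shared) == 0) {
    abort("no overlap between mutation-matrix genes and network genes")
  }
  X <- matrix(0, length(m$patients), length(net$genes),
              dimnames = list(m$patients, net$genes))
  X[, shared] <- m$X[, shared, drop = FALSE]
  mutation_matrix(X)
}
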