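# internal helpers shared across modules

# run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library calls never perturb user RNG
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# derive a reproducible sub-seed for a named stage from a master seed, kept
# below 2^31 so it is always a valid R integer
derive_seed <- function(seed, stage) {
  stopifnot(length(stage) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * (31L^(seq_along(utf8ToInt(as.character(stage))) %% 7L)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

assert_matrix_like <- function(x, arg = "x") {
  if (!is.matrix(x) && !inherits(x, "Matrix")) {
    abort(sprintf("`%s` must be a matrix", arg))
  }
  invisible(x)
}

# Frobenius norm of a dense matrix
frob <- function(x) sqrt(sum(x * x))

# scale a vector to unit variance without centring; zero-variance vectors
# become all zeros (with a warning) so downstream averaging ignores them
scale_unit_var <- function(x, warn_constant = TRUE) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    if (warn_constant) warn("zero-variance vector; returning zeros instead of scaling")
    return(rep(0, length(x)))
  }
  x / s
}

standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    warn("zero-variance score vector treated as all zeros")
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

# locale-independent deterministic ordering for gene symbols (C collation),
# so matrix column order is reproducible across systems
sort_genes <- function(x) sort(x, method = "radix")
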