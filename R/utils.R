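# Internal helpers shared across the package.

# Evaluate `expr` under a private RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Derive `n` independent sub-seeds from one master seed; all randomness in the
# package flows from a master seed through these named substreams.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}

upper_tri_mean <- function(m) {
  mean(m[upper.tri(m)])
}

row_sds <- function(x) {
  mu <- rowMeans(x)
  sqrt(rowSums((x - mu)^2) / (ncol(x) - 1L))
}

write_tsv_matrix <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_tsv_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  toks <- strsplit(first, "\t", fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(toks)))
  as.matrix(utils::read.table(path, sep = "\t", header = has_header))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
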