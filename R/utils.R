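# Internal helpers shared across modules.

# Named RNG substreams derived from one root seed, so any single stage can be
# re-run in isolation with the same draws.
.substream_offsets <- c(
  design = 101L, profiles = 211L, effects = 223L, bulk = 307L, sc = 401L,
  mixtures = 503L, permutations = 601L, clustering = 701L
)

substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  off <- .substream_offsets[[stream]]
  if (is.null(off)) abort(paste0("unknown RNG substream '", stream, "'"))
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483629)
}

with_substream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, stream))
  force(expr)
}

# Dirichlet draws via normalized gammas; rows sum to 1 exactly after division.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

is_count_matrix <- function(x) {
  is.matrix(x) && is.numeric(x) && all(x >= 0) && all(x == round(x))
}

check_count_matrix <- function(counts, what = "counts") {
  assert_that(is.matrix(counts) && is.numeric(counts),
              paste0(what, " must be a numeric matrix"))
  assert_that(!is.null(rownames(counts)) && !is.null(colnames(counts)),
              paste0(what, " must carry gene rownames and sample colnames"))
  assert_that(!anyDuplicated(rownames(counts)),
              paste0("duplicate gene IDs in ", what))
  assert_that(!anyDuplicated(colnames(counts)),
              paste0("duplicate sample IDs in ", what))
  assert_that(all(counts >= 0), paste0(what, " must be non-negative"))
  invisible(counts)
}

# Row-wise variance without apply() overhead.
row_vars <- function(x) {
  n <- ncol(x)
  (rowSums(x^2) - n * rowMeans(x)^2) / (n - 1)
}
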