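#' @useDynLib propnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm quantile sd setNames
#' @importFrom utils write.csv modifyList
NULL

# Run an expression under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL leaves the global RNG untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stream seed from a master seed and an index
#'
#' Training draws one fresh synthetic sample per iteration; deriving the
#' per-iteration seed from `(master, index)` makes the data stream independent
#' of restart points. The result always fits a 32-bit integer.
#'
#' @param seed master seed (integer).
#' @param index stream index (e.g. iteration number).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483629)
}

# 0-based voxel index grid as an N x 3 matrix (x fastest), matching the
# column-major layout of volume arrays.
grid_points <- function(dims) {
  d1 <- dims[1]; d2 <- dims[2]; d3 <- dims[3]
  cbind(
    rep.int(seq_len(d1) - 1, d2 * d3),
    rep.int(rep(seq_len(d2) - 1, each = d1), d3),
    rep(seq_len(d3) - 1, each = d1 * d2)
  )
}

stop_propnet <- function(msg, class) {
  stop(structure(class = c(class, "propnet_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
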