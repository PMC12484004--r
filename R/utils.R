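#' @keywords internal
#' @useDynLib amfn, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Numerical helpers shared across modules. Kept deliberately small: every
# model-specific computation lives in its own module file.

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Masked softmax over the columns of a matrix
#'
#' Rows are samples, columns are categories. Masked-out columns receive zero
#' probability; rows whose mask is entirely FALSE return all zeros.
#'
#' @param scores numeric matrix (n x K) of unnormalized scores.
#' @param mask logical or 0/1 matrix of the same shape; TRUE = keep.
#' @return matrix of the same shape with each masked row summing to 1.
#' @keywords internal
masked_softmax <- function(scores, mask) {
  stopifnot(all(dim(scores) == dim(mask)))
  s <- scores
  s[!mask] <- -Inf
  m <- s[, 1L]
  for (j in seq_len(ncol(s))[-1L]) m <- pmax(m, s[, j])
  m[!is.finite(m)] <- 0 # fully-masked row: avoid NaN, yields all zeros below
  e <- exp(s - m)
  e[!mask] <- 0
  z <- rowSums(e)
  out <- e / ifelse(z > 0, z, 1)
  out
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a child seed from a base seed and a stream index, staying within
# the 32-bit integer range R requires.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 9973) %% 2147483587L) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_amfn <- function(..., call. = FALSE) stop(..., call. = call.)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop_amfn(msg)
}
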