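#' @importFrom rlang abort warn %||% .data
#' @importFrom stats rnorm runif var sd cor predict
#' @importFrom utils head tail
#' @importFrom Rcpp evalCpp
#' @useDynLib dtakan, .registration = TRUE
NULL

# 32-bit FNV-1a hash of a string, reduced to a valid RNG seed. Used for
# per-entity seeding so that generated entities are independent of
# generation order and of each other.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(enc2utf8(s)))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), b)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  h
}

hash_seed <- function(...) {
  s <- paste(vapply(list(...), as.character, character(1)), collapse = "\r")
  as.integer(fnv1a32(s) %% 2147483647)
}

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

as_matrix2d <- function(x, what = "matrix") {
  if (is.null(dim(x))) {
    abort(sprintf("`%s` must be a 2-D matrix, got a vector of length %d.",
                  what, length(x)))
  }
  if (length(dim(x)) != 2L) {
    abort(sprintf("`%s` must be rank 2, got rank %d.", what, length(dim(x))))
  }
  as.matrix(x)
}
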