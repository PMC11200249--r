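# Internal helpers: seed management, hashing, small numerics.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so that
#' seeded internals never perturb the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Counter-based seed derivation: a master seed plus a stream of integer
# counters maps to a child seed < 2^31, reproducibly and independently of
# call order elsewhere.  Lehmer-style fold; collisions are harmless (the
# children only seed R's Mersenne twister).
derive_seed <- function(master, counters) {
  s <- as.double(master) %% 2147483647
  for (x in as.double(counters)) {
    s <- (s * 48271 + x + 1) %% 2147483647
  }
  as.integer(s)
}

# FNV-1a hash of a serialized R object, as hex.  Used for run-directory
# provenance and stage caching; not cryptographic.
object_hash <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(raw)) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (as.double(h) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
  x == round(x) && x > 0

# Row-stochasticity check used across the kinetics module.
assert_stochastic <- function(T, tol = 1e-8) {
  if (!is.matrix(T) || nrow(T) != ncol(T)) {
    stopf("transition matrix must be square")
  }
  if (any(!is.finite(T))) stopf("transition matrix has non-finite entries")
  if (any(T < -tol)) stopf("transition matrix has negative entries")
  rs <- rowSums(T)
  if (any(abs(rs - 1) > 1e-6)) {
    stopf("transition matrix rows must sum to 1 (max deviation %.3g)",
          max(abs(rs - 1)))
  }
  invisible(TRUE)
}
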