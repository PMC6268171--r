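#' @keywords internal
"_PACKAGE"

# 31-bit deterministic polynomial string hash (mod 2^31 - 1).
# Versioned contract: feature identifiers produced by this hash are stable
# across platforms and R versions; collisions are tolerated and documented.
zb_hash <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  h
}

# Run code with a temporarily-seeded RNG, restoring global state afterwards,
# so generators are pure functions of their seed argument.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed %% 2147483647L))
  force(code)
}

# Derive a sub-seed from a master seed and a stage label (kept < 2^31).
derive_seed <- function(seed, label) {
  (as.numeric(seed) * 7919 + zb_hash(label)) %% 2147483629
}

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v^2))

# Euclidean distances from one point to rows of a matrix
dist_to <- function(p, m) {
  if (is.null(dim(m))) m <- matrix(m, ncol = 3)
  sqrt(rowSums((m - matrix(p, nrow(m), 3, byrow = TRUE))^2))
}
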