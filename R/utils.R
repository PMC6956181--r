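# Internal helpers shared across modules.

# Full-scale value of 16-bit PCM; the "U" intensity unit is |sample * 32767|.
U_FULL_SCALE <- 32767

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a child RNG seed from a master seed and an index, kept below 2^31
# so it is always a valid R integer.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Lognormal draws parameterized by arithmetic mean and coefficient of
# variation (sd/mean), the parameterization used for per-recording
# minimum-intensity levels.
rlnorm_mean_cv <- function(n, mean, cv) {
  stopifnot(mean > 0, cv >= 0)
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

# Truncated-normal draw by clipping (mass outside the range moves to the
# bounds); used for durations and the discrete words-per-sentence counts.
rnorm_clipped <- function(n, mean, sd, range) {
  pmin(pmax(stats::rnorm(n, mean, sd), range[1]), range[2])
}

# FNV-1a 32-bit hash of a character scalar, reported as 8 hex digits.
# Used to stamp study outputs with a config fingerprint. Arithmetic is done
# in doubles (exact below 2^53); the xor only ever touches the low byte.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

# Round a duration in seconds to the 100 ms meter grid.
snap_grid <- function(x, grid = 0.1) round(x / grid) * grid

stop_invalid <- function(field, msg) {
  stop(sprintf("invalid spec: %s %s", field, msg), call. = FALSE)
}
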