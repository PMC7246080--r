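# Seed plumbing: every stochastic operation takes an explicit seed and
# leaves the caller's RNG state untouched.

with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
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

# Deterministic substream derivation, kept inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  ks <- c(...)
  x <- as.numeric(seed) %% 2147483562
  for (k in ks) {
    x <- (x * 40014 + as.numeric(k) * 12211 + 1) %% 2147483562
  }
  as.integer(x + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# FNV-1a over a deparsed object; used to stamp configs into outputs.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (as.numeric(h) * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
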