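# Run `code` with a temporarily seeded RNG, restoring the caller's RNG state.
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

# Tiny FNV-1a hash of an R object's serialization, as a hex string. Used to
# fingerprint configurations in training histories and checkpoints.
fnv1a_hash <- function(x) {
  bytes <- serialize(x, NULL, version = 2, xdr = TRUE)
  h <- 2166136261
  for (b in as.integer(bytes)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)   # xor touches the low byte only
    # h * 16777619 mod 2^32, split to stay inside exact double arithmetic
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

relu <- function(x) {
  if (is.matrix(x)) return(relu_cpp(x))
  x[x < 0] <- 0
  x
}

# Row-broadcast bias addition (faster than sweep for hot paths).
add_bias <- function(Z, b) {
  Z + rep(b, each = nrow(Z))
}
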