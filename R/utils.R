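# Internal numeric and plumbing helpers.

# Row-wise log(sum(exp(x))) without overflow; x is a matrix, returns a vector.
logsumexp_rows <- function(x) {
  m <- x[, 1L]
  for (k in seq_len(ncol(x))[-1L]) m <- pmax(m, x[, k])
  m + log(rowSums(exp(x - m)))
}

# Centered-free moving average over a window of n samples (n odd after
# rounding); pads by repeating edge values so the output has the input length.
moving_average <- function(x, n) {
  n <- max(1L, as.integer(n))
  if (n %% 2L == 0L) n <- n + 1L
  half <- (n - 1L) %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  cs <- cumsum(xp)
  (cs[(n):length(xp)] - c(0, cs[seq_len(length(xp) - n)])) / n
}

# Evaluate an expression under a fixed RNG seed, restoring the caller's RNG
# state afterwards so library code never clobbers user-level reproducibility.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# 32-bit FNV-1a hash of a character string, returned as 8 hex digits.
# Used to fingerprint configurations embedded in output artifacts.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    h <- mulmod32(h, 16777619)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# xor of two non-negative doubles holding 32-bit values
bitwXor_dbl <- function(a, b) {
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi <- bitwXor(floor(a / 65536) %% 65536, floor(b / 65536) %% 65536)
  hi * 65536 + lo
}

# (a * b) mod 2^32 for doubles holding 32-bit values, b < 2^25
mulmod32 <- function(a, b) {
  lo <- (a %% 65536) * b
  hi <- ((floor(a / 65536) %% 65536) * b) %% 65536
  (lo + hi * 65536) %% 4294967296
}

# Stable fingerprint of a (possibly nested) settings list. Functions are
# fingerprinted by their deparsed source so changing a map changes the hash.
settings_fingerprint <- function(x) {
  canon <- function(v) {
    if (is.function(v)) return(paste(deparse(v), collapse = " "))
    if (is.list(v)) {
      v <- v[order(names(v))]
      return(paste(names(v), vapply(v, canon, ""), sep = "=", collapse = ";"))
    }
    paste(format(v, digits = 12), collapse = ",")
  }
  fnv1a32(canon(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
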