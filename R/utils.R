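# internal helpers

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# 32-bit FNV-1a over a character vector; used to stamp output headers.
# The modular multiply by the FNV prime is done in 16-bit limbs so every
# intermediate product stays below 2^53 (exact in doubles).
fnv1a <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    lo <- bitwXor(h %% 65536, b)  # bytes only touch the low 16 bits
    hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

tool_version <- function() {
  as.character(utils::packageVersion("micmon"))
}

# mid-ranks (ties get the average of the ranks they span)
midrank <- function(x) {
  n <- length(x)
  o <- order(x)
  r <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && x[o[j + 1L]] == x[o[i]]) j <- j + 1L
    r[o[i:j]] <- (i + j) / 2
    i <- j + 1L
  }
  r
}

# all permutations of 1..n as an integer matrix (n! rows)
permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  p <- permutations(n - 1L)
  m <- nrow(p)
  out <- matrix(0L, m * n, n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * m + seq_len(m)
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[p], m)
  }
  out
}
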