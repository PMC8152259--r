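#' @importFrom stats median mad rnorm runif sd fft quantile
#' @import methods
NULL

# DFT sample frequencies (cycles/nm) in unshifted (fft) order.
fftFreq <- function(n, d) {
  k <- 0:(n - 1)
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  k / (n * d)
}

# Evaluate an expression under a fixed RNG seed without disturbing the
# caller's RNG stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# 32-bit FNV-1a over a character string; used to fingerprint run configs.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "")))
  h <- 0x811c9dc5
  p <- 16777619
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    # multiply by the FNV prime mod 2^32 in 16-bit halves (doubles stay exact)
    h0 <- h %% 65536
    h1 <- h %/% 65536
    h <- (h0 * p + ((h1 * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%08x", h)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
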