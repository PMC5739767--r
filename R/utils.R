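#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

mf_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "midflux_error", "error", "condition")))
}

mf_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "midflux_warning", "warning", "condition")))
}

# truncated polynomial convolution: coefficients of a*b kept for degrees
# 0..(len-1); mass above the window is dropped, not redistributed
conv_trunc <- function(a, b, len) {
  out <- numeric(len)
  na <- min(length(a), len)
  for (i in seq_len(na)) {
    if (a[i] == 0) next
    nb <- min(length(b), len - i + 1L)
    if (nb < 1L) break
    idx <- i:(i + nb - 1L)
    out[idx] <- out[idx] + a[i] * b[seq_len(nb)]
  }
  out
}

# FNV-1a 32-bit hash of a character scalar, as 8 hex digits; used to stamp
# outputs with a configuration fingerprint without external dependencies
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor32(h, b)
    h <- mulmod32(h, 16777619)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

bitwXor32 <- function(a, b) {
  # a may exceed .Machine$integer.max; split into two 16-bit halves
  ah <- a %/% 65536; al <- a %% 65536
  bh <- b %/% 65536; bl <- b %% 65536
  bitwXor(ah, bh) * 65536 + bitwXor(al, bl)
}

mulmod32 <- function(a, b) {
  # (a * b) mod 2^32 without losing precision past 2^53
  al <- a %% 65536
  ah <- a %/% 65536
  ((al * b) %% 4294967296 + ((ah * b) %% 65536) * 65536) %% 4294967296
}
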