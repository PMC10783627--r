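# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

# Deterministic 31-bit child seed from a parent seed and a stream label.
# Keeps derived seeds inside the signed 32-bit integer range.
derive_seed <- function(seed, ...) {
  s <- paste(c(seed, ...), collapse = "/")
  h <- fnv1a32(s)
  as.integer(h %% 2147483646) + 1L
}

# FNV-1a 32-bit hash, implemented with double arithmetic (exact below 2^53).
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor32(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

# xor of two non-negative doubles interpreted as 32-bit unsigned ints
bitwXor32 <- function(a, b) {
  hi_a <- a %/% 2147483648; lo_a <- a %% 2147483648
  hi_b <- b %/% 2147483648; lo_b <- b %% 2147483648
  lo <- bitwXor(as.integer(lo_a), as.integer(lo_b))
  hi <- bitwXor(as.integer(hi_a), as.integer(hi_b))
  hi * 2147483648 + as.numeric(lo)
}

#' Stable hash of a configuration
#'
#' 32-bit FNV-1a hash over a canonical `key=value` serialization (keys
#' sorted, numbers at full precision). Identical configurations always hash
#' identically, so every trial record can carry a compact fingerprint of the
#' resolved settings that produced it.
#'
#' @param cfg A named list (possibly nested) of configuration values.
#' @return An 8-character lowercase hex string.
#' @export
config_hash <- function(cfg) {
  flat <- flatten_config(cfg)
  flat <- flat[order(names(flat))]
  ser <- paste(names(flat), vapply(flat, canonical_value, character(1)),
               sep = "=", collapse = "\n")
  h <- fnv1a32(ser)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

flatten_config <- function(x, prefix = NULL) {
  if (!is.list(x)) {
    out <- list(x)
    names(out) <- paste(prefix, collapse = ".")
    return(out)
  }
  nm <- names(x)
  if (is.null(nm) || any(nm == "")) stop("configuration entries must be named")
  out <- list()
  for (i in seq_along(x)) {
    out <- c(out, flatten_config(x[[i]], c(prefix, nm[i])))
  }
  out
}

canonical_value <- function(v) {
  if (is.null(v)) return("null")
  if (is.numeric(v)) return(paste(sprintf("%.17g", v), collapse = ","))
  paste(as.character(v), collapse = ",")
}

# full-precision number formatting for delimited-text output (lossless
# round-trip of doubles)
format_full <- function(x) {
  out <- rep("NA", length(x))
  ok <- !is.na(x)
  out[ok] <- sprintf("%.17g", x[ok])
  short <- sprintf("%.15g", x[ok])
  keep <- is.finite(x[ok]) & as.numeric(short) == x[ok]
  out[ok][keep] <- short[keep]
  out
}
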