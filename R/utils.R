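# Internal helpers shared across modules.

#' Slice-level class tokens
#'
#' The five ordered slice-level classes. The ordinal encoding is fixed:
#' oap = 0, ap = 1, mid = 2, bs = 3, obs = 4 (apex to base).
#'
#' @return Character vector of the five class tokens in ordinal order.
#' @export
label_levels <- function() c("oap", "ap", "mid", "bs", "obs")

#' Convert between class tokens and ordinals
#'
#' @param x character vector of tokens (for `label_to_ordinal`) or integer
#'   ordinals in 0..4 (for `ordinal_to_label`).
#' @return Integer ordinals in 0..4, or character tokens.
#' @export
label_to_ordinal <- function(x) {
  ord <- match(x, label_levels()) - 1L
  if (anyNA(ord)) {
    bad <- unique(x[is.na(ord)])
    stop("unknown class token(s): ", paste(bad, collapse = ", "))
  }
  ord
}

#' @rdname label_to_ordinal
#' @export
ordinal_to_label <- function(x) {
  x <- as.integer(x)
  if (any(!is.na(x) & (x < 0L | x > 4L))) stop("ordinals must lie in 0..4")
  label_levels()[x + 1L]
}

# Derive a reproducible 31-bit sub-seed from a base seed and stream offsets.
derive_seed <- function(seed, ...) {
  parts <- c(as.numeric(seed), as.numeric(unlist(list(...))))
  s <- 0
  for (p in parts) s <- (s * 69069 + p + 1) %% 2147483647
  as.integer(s)
}

# FNV-1a hash of a character scalar, as hex; used for cache keys only.
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\x1f")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
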