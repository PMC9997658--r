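# internal numerical helpers

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row-wise log-sum-exp of a matrix
rowLogSumExp <- function(x) {
  m <- apply(x, 1L, max)
  out <- m + log(rowSums(exp(x - m)))
  out[!is.finite(m)] <- m[!is.finite(m)]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
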