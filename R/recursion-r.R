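# Pure-R reference implementation of the windowed forward recursion.
#
# Mirrors the compiled kernel exactly (same bucket codes, merge rule and
# update order) but runs one track at a time, vectorized over state-sequence
# buckets. It additionally can record, at every frame i, the merged Gaussian
# belief over the true position r_i given observations 1..i-1, grouped by the
# state at frame i -- the ingredient the position-refinement module combines
# in its forward and backward passes.

.rForward <- function(pos, d, sigma, logP, logF, m, u,
                      sigmaScale = NULL, fovLen = numeric(0), pK = 0,
                      useFov = FALSE, fovFinal = TRUE,
                      constrainFrame = 0L,
                      constrainState = 0L, record = FALSE) {
  n <- nrow(pos); na <- ncol(pos); N <- length(d)
  capA <- N^m
  if (N^(m + 1) > 4194304) stopf("N^(m+1) too large; reduce the window length")
  pairD2 <- outer(d^2, d^2, "+") / (2 * u)
  sig <- rep_len(sigma, na)
  scl <- if (is.null(sigmaScale)) rep(1, n) else sigmaScale
  logSurv <- if (useFov && pK < 1) log(1 - pK) else 0

  cur <- 0:(N - 1)                       # current state per bucket, 0-based
  acc <- numeric(N)                      # accumulated delta^2 this frame
  logw <- logF
  if (constrainFrame == 1L) logw[cur != constrainState] <- -Inf
  mu <- matrix(0, N, na)
  s2 <- matrix(0, N, na)

  if (record) {
    Wrec <- matrix(-Inf, n, N)
    muRec <- array(NA_real_, c(n, N, na))
    s2Rec <- array(NA_real_, c(n, N, na))
  }

  for (i in 1:(n - 1)) {
    for (k in 1:u) {
      # lazy merge: drop the oldest sub-state only when the next expansion
      # needs room, so sequences keep m+1 states through their last update
      if (length(cur) > capA) {
        KA <- length(cur) %/% N
        W <- matrix(logw, KA, N)       # row g: sources g + j*KA
        M <- do.call(pmax, c(as.data.frame(W), na.rm = FALSE))
        E <- exp(W - M)
        E[!is.finite(M), ] <- 1 / N    # all-dead group: weights arbitrary
        den <- rowSums(E)
        logwM <- M + log(den)
        logwM[!is.finite(M)] <- -Inf
        alpha <- E / den
        muM <- matrix(0, KA, na); s2M <- matrix(0, KA, na)
        for (a in seq_len(na)) {
          muM[, a] <- rowSums(alpha * matrix(mu[, a], KA, N))
          s2M[, a] <- rowSums(alpha * matrix(s2[, a], KA, N))
        }
        logw <- logwM; mu <- muM; s2 <- s2M
        acc <- acc[seq_len(KA)]
        cur <- cur[seq_len(KA)]
      }
      K <- length(cur)
      new0 <- 0:(K * N - 1)
      sNew <- new0 %% N
      oldI <- new0 %/% N + 1L
      logw <- logw[oldI] + logP[cbind(cur[oldI] + 1L, sNew + 1L)]
      acc <- acc[oldI] + pairD2[cbind(cur[oldI] + 1L, sNew + 1L)]
      mu <- mu[oldI, , drop = FALSE]
      s2 <- s2[oldI, , drop = FALSE]
      cur <- sNew

      if (k == u) {                      # arrived at frame i+1: use obs i
        if (constrainFrame == i + 1L) logw[cur != constrainState] <- -Inf
        delta2 <- acc
        acc <- numeric(length(acc))
        if (useFov) {
          plc <- .leaveCombined(sqrt(delta2), fovLen)
          logw <- logw + logSurv + log1p(-plc)
        }
        if (i == 1L) {
          for (a in seq_len(na)) {
            mu[, a] <- pos[1L, a]
            s2[, a] <- (sig[a] * scl[1L])^2 + delta2
          }
        } else {
          for (a in seq_len(na)) {
            sg2 <- (sig[a] * scl[i])^2
            v <- sg2 + s2[, a]
            dm <- pos[i, a] - mu[, a]
            logw <- logw - dm^2 / (2 * v) - 0.5 * log(2 * pi * v)
            mu[, a] <- (mu[, a] * sg2 + pos[i, a] * s2[, a]) / v
            s2[, a] <- (delta2 * sg2 + delta2 * s2[, a] + sg2 * s2[, a]) / v
          }
        }
      }
    }

    if (record) {                        # belief over r_{i+1} given obs <= i
      for (s in 0:(N - 1)) {
        sel <- cur == s & is.finite(logw)
        if (!any(sel)) next
        Wrec[i + 1L, s + 1L] <- logSumExp(logw[sel])
        al <- exp(logw[sel] - Wrec[i + 1L, s + 1L])
        for (a in seq_len(na)) {
          muRec[i + 1L, s + 1L, a] <- sum(al * mu[sel, a])
          s2Rec[i + 1L, s + 1L, a] <- sum(al * s2[sel, a])
        }
      }
    }
  }

  # final integration over r_n
  for (a in seq_len(na)) {
    sg2 <- (sig[a] * scl[n])^2
    v <- sg2 + s2[, a]
    dm <- pos[n, a] - mu[, a]
    logw <- logw - dm^2 / (2 * v) - 0.5 * log(2 * pi * v)
  }
  if (useFov && fovFinal) {
    plf <- .leaveCombined(d, fovLen)
    logw <- logw + log(pK + (1 - pK) * plf)[cur + 1L]
  }

  out <- list(logLik = logSumExp(logw))
  if (record) out <- c(out, list(W = Wrec, mu = muRec, s2 = s2Rec))
  out
}
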