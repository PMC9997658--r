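# shared fixtures and independent oracles, built in code at test time

# random N-state parameters in the regime of slow membrane proteins
randomParams <- function(N = 2, dt = 0.06) {
  k <- matrix(runif(N * N, 0.02, 0.3), N, N)
  diag(k) <- 0
  modelParams(d = sort(runif(N, 0, 0.15)), sigma = runif(1, 0.01, 0.05),
              k = k, dt = dt)
}

randomTrack <- function(n, na = 1, scale = 0.05, dt = 0.06) {
  Track(matrix(cumsum(rnorm(n * na, 0, scale)), n, na), dt = dt)
}

# exhaustive-enumeration likelihood: sums sequenceLogDensity over all N^nsub
# state sequences (independent of the windowed kernels)
enumLogLik <- function(track, params, u = 1) {
  n <- nFrames(track); N <- nStates(params)
  nsub <- (n - 1L) * u + 1L
  grid <- as.matrix(expand.grid(rep(list(seq_len(N)), nsub)))
  lls <- apply(grid, 1L, function(B)
    sequenceLogDensity(track, B, params, substeps = u))
  m <- max(lls)
  m + log(sum(exp(lls - m)))
}

# exhaustive posterior state probabilities at observation instants
enumPosterior <- function(track, params) {
  n <- nFrames(track); N <- nStates(params)
  grid <- as.matrix(expand.grid(rep(list(seq_len(N)), n)))
  lls <- apply(grid, 1L, function(B) sequenceLogDensity(track, B, params))
  w <- exp(lls - max(lls)); w <- w / sum(w)
  sapply(seq_len(N), function(s)
    sapply(seq_len(n), function(i) sum(w[grid[, i] == s])))
}

# multivariate-normal log density of the displacement vector for one state:
# Var(dc_i) = d^2 + 2 sigma^2, Cov(adjacent) = -sigma^2
mvnDisplacementLogLik <- function(track, d, sigma) {
  pos <- positions(track)
  n <- nrow(pos)
  S <- diag(rep(d^2 + 2 * sigma^2, n - 1))
  S[abs(row(S) - col(S)) == 1] <- -sigma^2
  ch <- chol(S)
  total <- 0
  for (a in seq_len(ncol(pos))) {
    dc <- diff(pos[, a])
    z <- backsolve(ch, dc, transpose = TRUE)
    total <- total - 0.5 * sum(z^2) - sum(log(diag(ch))) -
      (n - 1) / 2 * log(2 * pi)
  }
  total
}

# exact Gaussian-posterior oracle for single-state refinement: flat prior on
# the first position, random-walk increments, iid observation noise
gmrfPosterior <- function(y, d, sigma) {
  n <- length(y)
  D <- diff(diag(n))
  Q <- crossprod(D) / d^2 + diag(n) / sigma^2
  V <- solve(Q)
  list(mean = as.vector(V %*% (y / sigma^2)), sd = sqrt(diag(V)))
}

relErr <- function(est, truth) abs(est - truth) / abs(truth)
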