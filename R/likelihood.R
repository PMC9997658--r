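#' One step of the Gaussian belief recursion
#'
#' Integrating the hidden true positions out of the track density proceeds by
#' a conjugate-Gaussian recursion: given the belief about the next true
#' position (mean `mu`, variance `s2`, accumulated log-weight `logw`), one
#' observation `c` with localization error `sigma`, and the displacement SD
#' `delta` of the following step, the updated belief is
#' \deqn{s_i^2 = (\delta^2\sigma^2 + \delta^2 s_{i-1}^2 + \sigma^2
#'   s_{i-1}^2)/(\sigma^2 + s_{i-1}^2),\quad
#'   \mu_i = (\mu_{i-1}\sigma^2 + c_i s_{i-1}^2)/(\sigma^2 + s_{i-1}^2),}
#' and the log-weight gains the log of the Gaussian density of
#' `c - mu` with variance `sigma^2 + s2`. All quantities are per axis.
#'
#' @param belief list with numeric fields `mu`, `s2` (per axis) and scalar
#'   `logw`; use [initialBelief()] for the first step.
#' @param c observed position (one value per axis, um).
#' @param sigma localization error at this frame (um, scalar or per axis).
#' @param delta displacement SD of the step following this frame (um).
#' @return The updated belief list.
#' @export
recursionStep <- function(belief, c, sigma, delta) {
  if (!all(is.finite(c(belief$mu, belief$s2, belief$logw, c, sigma, delta))))
    stopf("non-finite inputs to recursionStep")
  sg2 <- rep_len(sigma, length(c))^2
  v <- sg2 + belief$s2
  dm <- c - belief$mu
  list(
    mu = (belief$mu * sg2 + c * belief$s2) / v,
    s2 = (delta^2 * sg2 + delta^2 * belief$s2 + sg2 * belief$s2) / v,
    logw = belief$logw + sum(-dm^2 / (2 * v) - 0.5 * log(2 * pi * v))
  )
}

#' @param c1 first observed position (per axis, um).
#' @param delta1 displacement SD of the first step (um).
#' @rdname recursionStep
#' @export
initialBelief <- function(c1, sigma, delta1) {
  sg2 <- rep_len(sigma, length(c1))^2
  list(mu = c1, s2 = sg2 + delta1^2, logw = 0)
}

# per-frame displacement SDs delta_i for a given (sub-)state sequence,
# together with the log prior of the sequence. states is 1-based, length n
# (u = 1) or (n-1)*u + 1.
.sequenceSteps <- function(states, n, u, d, logP, logF) {
  nsub <- (n - 1L) * u + 1L
  if (length(states) != nsub)
    stopf("state sequence must have %d entries for %d frames and %d substeps",
          nsub, n, u)
  pair <- cbind(states[-nsub], states[-1L])
  logBeta <- logF[states[1L]] + sum(logP[pair])
  d2sub <- (d[pair[, 1L]]^2 + d[pair[, 2L]]^2) / (2 * u)
  delta <- sqrt(colSums(matrix(d2sub, nrow = u)))
  list(delta = delta, logBeta = logBeta)
}

#' Exact log density of a track for one state sequence
#'
#' Evaluates the joint log density of the observed positions and one fixed
#' sequence of motion states: the log prior of the sequence (initial fraction
#' and transition probabilities) plus the Gaussian recursion over hidden
#' positions. Multi-axis tracks contribute one positional term per axis and a
#' single sequence-prior term. The uniform-prior constant over the first true
#' position is dropped, so only relative positions matter.
#'
#' @param track a [Track-class].
#' @param states integer states (1-based), length `nFrames(track)` for
#'   `substeps = 1`, else `(nFrames - 1) * substeps + 1` sub-states.
#' @param params a [ModelParams-class].
#' @param substeps sub-steps per frame.
#' @param transitionMode see [transitionMatrix()].
#' @return Scalar log density.
#' @export
sequenceLogDensity <- function(track, states, params, substeps = 1L,
                               transitionMode = c("perPair", "generator")) {
  stopifnot(is(track, "Track"), is(params, "ModelParams"))
  states <- as.integer(states)
  if (any(states < 1L | states > params@nStates))
    stopf("states must lie in 1..%d", params@nStates)
  pos <- track@positions
  n <- nrow(pos); na <- ncol(pos)
  P <- transitionMatrix(params@k, match.arg(transitionMode),
                        substeps = substeps)
  ss <- .sequenceSteps(states, n, substeps, params@d,
                       log(P), log(params@F))
  sig <- rep_len(params@sigma, na)
  scl <- if (length(track@peakErrorScale)) track@peakErrorScale else rep(1, n)
  total <- ss$logBeta
  for (a in seq_len(na)) {
    bel <- initialBelief(pos[1L, a], sig[a] * scl[1L], ss$delta[1L])
    if (n > 2L) {
      for (i in 2:(n - 1L))
        bel <- recursionStep(bel, pos[i, a], sig[a] * scl[i], ss$delta[i])
    }
    v <- (sig[a] * scl[n])^2 + bel$s2
    total <- total + bel$logw -
      (pos[n, a] - bel$mu)^2 / (2 * v) - 0.5 * log(2 * pi * v)
  }
  unname(total)
}

#' Probability that a diffusing molecule leaves the field of view in one frame
#'
#' For a molecule with per-frame displacement SD `delta` whose position is
#' uniform inside an observable 1D region of length `l`, the per-frame
#' probability of leaving is
#' \deqn{p_L(\delta) = 1 - \frac{1}{l}\int_0^l
#'   \left[\Phi\!\left(\frac{l-x}{\delta}\right) -
#'   \Phi\!\left(\frac{-x}{\delta}\right)\right] dx,}
#' evaluated in closed form via the integrated normal CDF
#' `G(t) = t * pnorm(t) + dnorm(t)`. The `1/l` normalization keeps
#' `p_L` in `[0, 1]` for the uniform position assumption. For several
#' finite axes the probabilities combine as `1 - prod(1 - pL_axis)`.
#'
#' @param delta per-frame displacement SD (um), vectorized.
#' @param l observable length (um); `Inf` gives 0.
#' @return Leave probability in `[0, 1]`.
#' @examples
#' leaveProbability(0, 0.5)      # immobile molecules never leave
#' leaveProbability(0.1, 0.5)
#' @export
leaveProbability <- function(delta, l) {
  if (any(l <= 0)) stopf("l must be positive")
  if (any(delta < 0)) stopf("delta must be non-negative")
  out <- numeric(length(delta))
  pos <- delta > 0 & is.finite(l)
  if (any(pos)) {
    h <- l / delta[pos]
    G0 <- dnorm(0)
    Gh <- h * pnorm(h) + dnorm(h)
    out[pos] <- pmin(1, pmax(0, 1 - (2 * (Gh - G0) - h) / h))
  }
  out
}

.leaveCombined <- function(delta, fovLen) {
  if (!length(fovLen)) return(rep(0, length(delta)))
  keep <- rep(1, length(delta))
  for (l in fovLen[is.finite(fovLen)]) keep <- keep * (1 - leaveProbability(delta, l))
  1 - keep
}

# log probability that a track reaches at least minLen positions under the
# track-termination model: a vector recursion over states with per-step
# survival (1 - pK) * (1 - pL(delta)); conditions the density on the
# min-length filter applied at input
.logSurvMinLen <- function(params, config, na) {
  minLen <- config@fovMinLen
  if (minLen <= 1L) return(0)
  N <- params@nStates
  fov <- if (length(params@fovLen)) rep_len(params@fovLen, na)
         else rep(Inf, na)
  P <- transitionMatrix(params@k, config@transitionMode)
  pl <- matrix(0, N, N)
  for (i in seq_len(N)) for (j in seq_len(N))
    pl[i, j] <- .leaveCombined(stepSD(params@d[i], params@d[j]), fov)
  M <- P * (1 - params@pK) * (1 - pl)    # survival-weighted transitions
  v <- params@F
  for (step in seq_len(minLen - 1L)) v <- as.vector(v %*% M)
  log(sum(v))
}

# shared argument preparation for the window kernels
.kernelArgs <- function(params, config, na) {
  P <- transitionMatrix(params@k, config@transitionMode,
                        substeps = config@substeps)
  list(logP = log(P), logF = log(params@F),
       sigma = rep_len(params@sigma, na),
       fovLen = if (length(params@fovLen)) rep_len(params@fovLen, na)
                else rep(Inf, na))
}

# windowed log-likelihood for a group of equal-length tracks given as an
# nt x n x na array; scales is nt x n or NULL
.windowLogLikGroup <- function(pos, scales, params, config,
                               constrainFrame = 0L, constrainState = 0L) {
  nt <- dim(pos)[1L]; n <- dim(pos)[2L]; na <- dim(pos)[3L]
  ka <- .kernelArgs(params, config, na)
  useFov <- config@fovCorrection
  if (useFov && !length(params@fovLen))
    stopf("fovCorrection requires fovLen in the model parameters")
  lsm <- if (useFov) .logSurvMinLen(params, config, na) else 0
  finalTerm <- is.na(config@fovMaxLen) || n < config@fovMaxLen
  if (config@engine == "R") {
    vapply(seq_len(nt), function(t) {
      .rForward(matrix(pos[t, , ], n, na), params@d, ka$sigma, ka$logP,
                ka$logF, config@window, config@substeps,
                sigmaScale = if (is.null(scales)) NULL else scales[t, ],
                fovLen = ka$fovLen, pK = params@pK, useFov = useFov,
                fovFinal = finalTerm,
                constrainFrame = constrainFrame,
                constrainState = constrainState - 1L)$logLik
    }, numeric(1)) - lsm
  } else {
    N <- params@nStates
    capB <- N^(config@window + 1)
    chunk <- max(64L, as.integer(6e7 / (capB * (1 + 2 * na) * 16)))
    out <- numeric(nt)
    for (start in seq(1L, nt, by = chunk)) {
      idx <- start:min(nt, start + chunk - 1L)
      out[idx] <- .cpp_window_loglik(
        as.numeric(pos[idx, , , drop = FALSE]),
        as.integer(c(length(idx), n, na)),
        params@d, ka$sigma, ka$logP, ka$logF,
        as.integer(config@window), as.integer(config@substeps),
        if (is.null(scales)) matrix(0, 0, 0)
        else scales[idx, , drop = FALSE],
        ka$fovLen, params@pK, useFov, finalTerm,
        as.integer(constrainFrame),
        as.integer(constrainState - 1L))
    }
    out - lsm
  }
}

# group tracks by (length, axes); returns list of list(idx, pos, scales)
.trackGroups <- function(tracks, perPeak = FALSE, maxLen = NA_integer_) {
  stopifnot(length(tracks) >= 1L)
  ns <- vapply(tracks, nFrames, integer(1))
  if (!is.na(maxLen)) ns <- pmin(ns, maxLen)
  na <- nAxes(tracks[[1L]])
  lapply(split(seq_along(tracks), ns), function(idx) {
    n <- ns[idx[1L]]
    pos <- array(NA_real_, c(length(idx), n, na))
    scales <- NULL
    if (perPeak) scales <- matrix(1, length(idx), n)
    for (j in seq_along(idx)) {
      tr <- tracks[[idx[j]]]
      pos[j, , ] <- tr@positions[seq_len(n), , drop = FALSE]
      if (perPeak && length(tr@peakErrorScale))
        scales[j, ] <- tr@peakErrorScale[seq_len(n)]
    }
    list(idx = idx, pos = pos, scales = scales)
  })
}

#' Log density of one track under a multi-state diffusion model
#'
#' Computes `log f(C | theta)`: the density of the observed positions given
#' the model, integrating over all hidden true positions exactly and summing
#' over hidden state sequences with the sliding-window approximation
#' (sequences sharing their last `window` sub-states are merged into one
#' belief with weights proportional to each branch's joint density). For
#' tracks shorter than the window the sum is exact. With
#' `fovCorrection = TRUE` the density includes the probability of observing a
#' track of exactly this length given termination by bleaching (`pK`) and by
#' diffusive exit from the observable region.
#'
#' @param track a [Track-class].
#' @param params a [ModelParams-class].
#' @param config a [LikelihoodConfig-class].
#' @return Scalar log density (uniform prior over the first true position
#'   dropped, so translations leave the value unchanged).
#' @examples
#' tr <- Track(cbind(c(0, 0.02, 0.11, 0.12)), dt = 0.06)
#' th <- modelParams(d = c(0, 0.1), sigma = 0.02, k = c(0.1, 0.1), dt = 0.06)
#' trackLogLik(tr, th, likelihoodConfig(window = 3))
#' @export
trackLogLik <- function(track, params, config = likelihoodConfig()) {
  stopifnot(is(track, "Track"))
  datasetLogLik(TrackSet(list(track)), params, config)
}

#' @param tracks a [TrackSet-class] or list of tracks.
#' @param maxTrackLen optional cap on positions used per track.
#' @rdname trackLogLik
#' @export
datasetLogLik <- function(tracks, params, config = likelihoodConfig(),
                          maxTrackLen = NA) {
  if (!is(tracks, "TrackSet")) tracks <- TrackSet(tracks)
  stopifnot(is(params, "ModelParams"), is(config, "LikelihoodConfig"))
  out <- numeric(length(tracks))
  groups <- .trackGroups(tracks, perPeak = config@perPeakSigma,
                         maxLen = as.integer(maxTrackLen))
  for (g in groups)
    out[g$idx] <- .windowLogLikGroup(g$pos, g$scales, params, config)
  if (any(!is.finite(out))) {
    bad <- vapply(tracks, trackId, character(1))[!is.finite(out)]
    warnf("non-finite log density for track(s): %s",
          paste(head(bad, 5), collapse = ", "))
  }
  sum(out)
}

# per-track version used by annotation / fitting internals
.perTrackLogLik <- function(tracks, params, config, maxTrackLen = NA,
                            constrainFrame = 0L, constrainState = 0L) {
  out <- numeric(length(tracks))
  groups <- .trackGroups(tracks, perPeak = config@perPeakSigma,
                         maxLen = as.integer(maxTrackLen))
  for (g in groups)
    out[g$idx] <- .windowLogLikGroup(g$pos, g$scales, params, config,
                                     constrainFrame, constrainState)
  out
}
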