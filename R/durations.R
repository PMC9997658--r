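# choose a window so the exact bucket count stays modest for reference
# likelihood evaluations inside the histogram module
.autoWindow <- function(N, n) {
  w <- max(1L, min(n - 1L, as.integer(floor(14 / log2(max(N, 2)))) - 1L))
  w
}

#' Most likely state sequences of a track
#'
#' Enumerates the state sequences with the highest joint density
#' `f(C, B | theta)` and their posterior weights `f(C, B) / f(C)`. When the
#' total number of sequences is small (`N^n <= 8 * bTop`) all sequences are
#' enumerated exactly; otherwise a beam search over the forward recursion
#' keeps the `bTop` highest-weight partial sequences at every frame (ties
#' broken deterministically by expansion order, i.e. by state index). The sum
#' of the returned weights is the retained fraction of the track density;
#' sequence-level merging is deliberately not windowed here because whole
#' sequences must be kept.
#'
#' @param track a [Track-class].
#' @param params a [ModelParams-class].
#' @param bTop number of sequences to retain.
#' @param transitionMode see [transitionMatrix()].
#' @return List: `states` (sequences x frames matrix, 1-based states),
#'   `weight` (posterior weights, sum = retained mass), `retained` (scalar),
#'   `logLik` (the reference `log f(C)`).
#' @export
topSequences <- function(track, params, bTop = 1000L,
                         transitionMode = c("perPair", "generator")) {
  stopifnot(is(track, "Track"), is(params, "ModelParams"), bTop >= 1L)
  transitionMode <- match.arg(transitionMode)
  pos <- track@positions
  n <- nrow(pos); na <- ncol(pos); N <- params@nStates
  logP <- log(transitionMatrix(params@k, transitionMode))
  logF <- log(params@F)
  sig <- rep_len(params@sigma, na)
  scl <- if (length(track@peakErrorScale)) track@peakErrorScale else rep(1, n)
  d <- params@d
  exact <- N^n <= 8 * bTop

  seqs <- matrix(seq_len(N), ncol = 1L)
  logw <- logF
  mu <- matrix(0, N, na); s2 <- matrix(0, N, na)
  for (i in 1:(n - 1L)) {
    K <- nrow(seqs)
    new0 <- 0:(K * N - 1L)
    sNew <- new0 %% N + 1L
    oldI <- new0 %/% N + 1L
    prev <- seqs[oldI, i]
    logw <- logw[oldI] + logP[cbind(prev, sNew)]
    delta2 <- (d[prev]^2 + d[sNew]^2) / 2
    seqs <- cbind(seqs[oldI, , drop = FALSE], sNew)
    if (i == 1L) {
      mu <- matrix(rep(pos[1L, ], each = length(sNew)), ncol = na)
      s2 <- matrix(rep((sig * scl[1L])^2, each = length(sNew)),
                   ncol = na) + delta2
    } else {
      mu <- mu[oldI, , drop = FALSE]
      s2 <- s2[oldI, , drop = FALSE]
      for (a in seq_len(na)) {
        sg2 <- (sig[a] * scl[i])^2
        v <- sg2 + s2[, a]
        dm <- pos[i, a] - mu[, a]
        logw <- logw - dm^2 / (2 * v) - 0.5 * log(2 * pi * v)
        mu[, a] <- (mu[, a] * sg2 + pos[i, a] * s2[, a]) / v
        s2[, a] <- (delta2 * sg2 + delta2 * s2[, a] + sg2 * s2[, a]) / v
      }
    }
    if (!exact && nrow(seqs) > bTop) {
      keep <- order(logw, decreasing = TRUE)[seq_len(bTop)]
      seqs <- seqs[keep, , drop = FALSE]
      logw <- logw[keep]
      mu <- mu[keep, , drop = FALSE]
      s2 <- s2[keep, , drop = FALSE]
    }
  }
  for (a in seq_len(na)) {
    v <- (sig[a] * scl[n])^2 + s2[, a]
    logw <- logw - (pos[n, a] - mu[, a])^2 / (2 * v) -
      0.5 * log(2 * pi * v)
  }
  logfC <- if (exact) logSumExp(logw) else
    trackLogLik(track, params,
                likelihoodConfig(window = .autoWindow(N, n),
                                 transitionMode = transitionMode))
  ord <- order(logw, decreasing = TRUE)
  if (!exact) ord <- ord[seq_len(min(bTop, length(ord)))]
  weight <- exp(logw[ord] - logfC)
  list(states = seqs[ord, , drop = FALSE], weight = weight,
       retained = sum(weight), logLik = logfC)
}

#' Probability-weighted state-duration histogram
#'
#' Accumulates, over tracks and over their most likely state sequences, the
#' number of runs of `i` consecutive time points in each state, weighted by
#' the posterior sequence probabilities. Under Markov switching the weights
#' decay exponentially with duration at the transition rate; deviations
#' (e.g. a two-exponential immobile-duration mixture) reveal hidden states or
#' non-Markovian kinetics. Runs touching a track end are right-censored and
#' tallied with `censored = TRUE` so they can be included or excluded
#' downstream.
#'
#' @param tracks a [TrackSet-class].
#' @param params a [ModelParams-class].
#' @param bTop sequences retained per track (see [topSequences()]).
#' @param minLen minimum track length used (durations from short tracks are
#'   dominated by censoring).
#' @return A [DurationHistogram-class].
#' @export
durationHistogram <- function(tracks, params, bTop = 1000L, minLen = 21L) {
  if (!is(tracks, "TrackSet")) tracks <- TrackSet(tracks)
  use <- which(vapply(tracks, nFrames, integer(1)) >= minLen)
  if (!length(use)) {
    warnf("no tracks of length >= %d; empty histogram", minLen)
    return(new("DurationHistogram",
               table = data.frame(state = integer(), duration = integer(),
                                  weight = numeric(), censored = logical(),
                                  exit_observed = logical()),
               nTracks = 0L, bTop = as.integer(bTop), retainedMass = NaN,
               dt = frameInterval(tracks)))
  }
  retained <- numeric(length(use))
  chunks <- vector("list", length(use))
  for (j in seq_along(use)) {
    top <- topSequences(tracks[[use[j]]], params, bTop = bTop)
    retained[j] <- top$retained
    runs <- lapply(seq_along(top$weight), function(b) {
      r <- rle(top$states[b, ])
      nr <- length(r$lengths)
      cens <- c(TRUE, rep(FALSE, max(nr - 2L, 0L)),
                if (nr > 1L) TRUE else NULL)
      exitObs <- c(rep(TRUE, nr - 1L), FALSE)   # last run: no exit seen
      cbind(r$values, r$lengths, cens, exitObs, top$weight[b])
    })
    m <- do.call(rbind, runs)
    key <- paste0(m[, 1L], ".", m[, 2L], ".", m[, 3L], ".", m[, 4L])
    w <- rowsum(m[, 5L], key)
    chunks[[j]] <- data.frame(key = rownames(w), weight = w[, 1L],
                              row.names = NULL)
  }
  all <- do.call(rbind, chunks)
  w <- rowsum(all$weight, all$key)
  parts <- do.call(rbind, strsplit(rownames(w), ".", fixed = TRUE))
  tab <- data.frame(state = as.integer(parts[, 1L]),
                    duration = as.integer(parts[, 2L]),
                    weight = w[, 1L],
                    censored = parts[, 3L] == "1",
                    exit_observed = parts[, 4L] == "1")
  tab <- tab[order(tab$state, tab$duration, tab$censored), , drop = FALSE]
  rownames(tab) <- NULL
  new("DurationHistogram", table = tab, nTracks = length(use),
      bTop = as.integer(bTop), retainedMass = mean(retained),
      dt = frameInterval(tracks))
}

#' @param object a [DurationHistogram-class].
#' @param path output CSV path; adds a `duration_s` column using `dt`.
#' @rdname durationHistogram
#' @export
writeDurationCSV <- function(object, path) {
  tab <- object@table
  tab$duration_s <- tab$duration * object@dt
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Exit rate from a duration histogram
#'
#' Weighted maximum-likelihood rate for exponentially distributed dwell
#' times observed at frame resolution: run lengths are geometric with
#' per-frame exit probability `p`, converted to a continuous rate
#' `k = -log(1 - p)` per frame. `p` is estimated as (weighted) observed
#' exits over Bernoulli exposure: a run of `j` frames contributes `j` trials
#' when its exit is observed and `j - 1` when it is right-censored at the
#' track end (runs starting at the track edge are left-truncated but, being
#' memoryless, still contribute their exit).
#'
#' @param histogram a [DurationHistogram-class].
#' @param state state index (1-based).
#' @param censored `"include"` (default; right-censored runs add exposure but
#'   no exit) or `"exclude"` (drop all track-edge runs entirely, biased low
#'   for long dwells).
#' @return Estimated exit rate per frame.
#' @export
fitExponentialRate <- function(histogram, state,
                               censored = c("include", "exclude")) {
  censored <- match.arg(censored)
  tab <- histogram@table
  tab <- tab[tab$state == state, , drop = FALSE]
  if (censored == "exclude") tab <- tab[!tab$censored, , drop = FALSE]
  if (!nrow(tab)) stopf("no durations for state %d", state)
  events <- sum(tab$weight[tab$exit_observed])
  trials <- sum(tab$weight * (tab$duration - !tab$exit_observed))
  p <- events / trials
  -log(1 - min(p, 1 - 1e-12))
}

#' Compare one- and two-exponential dwell models
#'
#' Fits the weighted durations of one state (right-censored runs enter
#' through their survival terms) with a single geometric dwell distribution
#' and with a two-component mixture, and reports the likelihood-ratio
#' statistic. A large statistic indicates two
#' dwell sub-populations (e.g. a hidden second bound state). The chi-square
#' p-value is a heuristic reference: mixture likelihood-ratio tests are not
#' regular, so treat it as descriptive.
#'
#' @param histogram a [DurationHistogram-class].
#' @param state state index.
#' @return List: `rate1` (single fit), `rates2`, `mix` (component weight),
#'   `logLik1`, `logLik2`, `stat` (LR statistic), `p.value`.
#' @export
exponentialMixtureTest <- function(histogram, state) {
  tab <- histogram@table
  tab <- tab[tab$state == state, , drop = FALSE]
  if (nrow(tab) < 3L) stopf("too few durations for state %d", state)
  x <- tab$duration; w <- tab$weight; ex <- tab$exit_observed
  # geometric dwell likelihood with right-censoring: an observed exit adds
  # log p, every continuation adds log(1 - p)
  llGeom <- function(p) sum(w * ((x - 1) * log1p(-p) + ex * log(p)))
  p1 <- sum(w * ex) / sum(w * (x - !ex))
  ll1 <- llGeom(p1)
  nll2 <- function(par) {
    pi1 <- plogis(par[1L])
    pa <- plogis(par[2L]); pb <- plogis(par[3L])
    dens <- pi1 * (1 - pa)^(x - 1) * ifelse(ex, pa, 1) +
      (1 - pi1) * (1 - pb)^(x - 1) * ifelse(ex, pb, 1)
    -sum(w * log(pmax(dens, 1e-300)))
  }
  start <- c(0, qlogis(min(p1 * 2, 0.9)), qlogis(p1 / 2))
  opt <- optim(start, nll2, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  ll2 <- -opt$value
  stat <- max(0, 2 * (ll2 - ll1))
  ps <- sort(plogis(opt$par[2:3]))
  list(rate1 = -log(1 - p1), rates2 = -log(1 - ps),
       mix = plogis(opt$par[1L]), logLik1 = ll1, logLik2 = ll2,
       stat = stat, p.value = pchisq(stat, df = 2, lower.tail = FALSE))
}
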