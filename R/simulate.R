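#' Scaled chi-square draws with a given mean and coefficient of variation
#'
#' Draws from a chi-square distribution with `nu = 2 / cv^2` degrees of
#' freedom, rescaled to the requested mean, as used for track-to-track
#' heterogeneity of localization error or diffusion coefficient. `cv = 0`
#' returns the mean exactly. When the implied `nu` falls below 1 a gamma
#' distribution with the same mean and CV is used instead (with a warning),
#' since fractional-df chi-square draws become degenerate near zero.
#'
#' @param n number of draws.
#' @param mean target mean (same units as the heterogeneous quantity).
#' @param cv coefficient of variation (SD / mean), non-negative.
#' @return Numeric vector of positive draws.
#' @examples
#' mean(chiSquareScaled(1e4, mean = 0.02, cv = 0.3))
#' @export
chiSquareScaled <- function(n, mean, cv) {
  if (cv < 0) stopf("cv must be non-negative")
  if (cv == 0) return(rep(mean, n))
  nu <- 2 / cv^2
  if (nu < 1) {
    warnf("cv = %g implies chi-square df < 1; using a gamma with matched mean and cv", cv)
    return(rgamma(n, shape = 1 / cv^2, scale = mean * cv^2))
  }
  rchisq(n, df = nu) * mean / nu
}

#' Describe a track simulation
#'
#' Bundles the ground-truth model with the simulation protocol: number of
#' particles and frames, fine time resolution (states switch and particles
#' move at `tau = dt / fineSubsteps`), observation geometry, and optional
#' track-to-track parameter heterogeneity. Defaults reproduce the reference
#' two-state protocol: 10,000 tracks of 10 positions in 2D, `sigma` = 0.02
#' um, `dt` = 0.06 s, an immobile state (`d1` = 0) and a diffusive state
#' (`d2` = 0.1 um), symmetric rates 0.1 per frame, steady-state initial
#' fractions, infinite field of view.
#'
#' @param params true [ModelParams-class] (default: the reference two-state
#'   model above).
#' @param nTracks,nFrames particles and frames per particle.
#' @param nAxes spatial dimensions (2 or 3).
#' @param fineSubsteps fine sub-steps per frame (default 50).
#' @param geometry list with `type` in `"infinite"`, `"fov1d"` (observable
#'   width `l` on axis 1, simulation box `3*l` periodic; a particle yields a
#'   new track each time it re-enters), `"fovz"` (observable depth `l` on the
#'   last axis, periodic period `3*l`), `"confined"` (reflecting box of side
#'   `size`); `minSegment` = minimum in-view segment length kept (default 3).
#' @param heterogeneity list with `target` (`"none"`, `"sigma"`, `"D"`) and
#'   `cv`; chi-square track-to-track variation rescaled to the model mean.
#' @param switching `"firstOrder"` (per-sub-step switch probability
#'   `k * tau`) or `"exact"` (exponential waiting times).
#' @return A [SimulationScenario-class].
#' @export
simulationScenario <- function(params = NULL, nTracks = 10000L,
                               nFrames = 10L, nAxes = 2L, fineSubsteps = 50L,
                               geometry = list(type = "infinite"),
                               heterogeneity = list(target = "none", cv = 0),
                               switching = c("firstOrder", "exact")) {
  if (is.null(params))
    params <- modelParams(d = c(0, 0.1), sigma = 0.02, k = c(0.1, 0.1),
                          dt = 0.06)
  geometry$type <- match.arg(geometry$type %||% "infinite",
                             c("infinite", "fov1d", "fovz", "confined"))
  geometry$minSegment <- geometry$minSegment %||% 3L
  heterogeneity$target <- match.arg(heterogeneity$target %||% "none",
                                    c("none", "sigma", "D"))
  heterogeneity$cv <- heterogeneity$cv %||% 0
  new("SimulationScenario", params = params, nTracks = as.integer(nTracks),
      nFrames = as.integer(nFrames), nAxes = as.integer(nAxes),
      fineSubsteps = as.integer(fineSubsteps), geometry = geometry,
      heterogeneity = heterogeneity, switching = match.arg(switching))
}

# fine-time Markov state paths, nTracks x (nFine+1), 1-based states
.simStates <- function(N, k, F, nTracks, nFine, fineSubsteps, switching) {
  states <- matrix(0L, nTracks, nFine + 1L)
  states[, 1L] <- sample.int(N, nTracks, replace = TRUE, prob = F)
  if (N == 1L) {
    states[] <- 1L
    return(states)
  }
  if (switching == "firstOrder") {
    Pt <- k / fineSubsteps             # per-sub-step switch probabilities
    if (any(rowSums(Pt) > 0.1))
      warnf("k * tau > 0.1: fine-time discretization of switching is coarse")
    cum <- t(apply(Pt, 1L, cumsum))    # N x N cumulative off-diag probs
    for (t in seq_len(nFine)) {
      s <- states[, t]
      udraw <- runif(nTracks)
      nxt <- s
      for (i in seq_len(N)) {
        sel <- s == i
        if (!any(sel)) next
        edges <- c(0, cum[i, ])
        bin <- findInterval(udraw[sel], edges, left.open = TRUE)
        tgt <- ifelse(bin >= 1 & bin <= N & udraw[sel] <= cum[i, N],
                      bin, i)
        nxt[sel] <- tgt
      }
      states[, t + 1L] <- nxt
    }
  } else {
    rates <- rowSums(k)
    for (tr in seq_len(nTracks)) {
      s <- states[tr, 1L]
      t0 <- 0
      while (t0 < nFine) {
        if (rates[s] <= 0) break
        wait <- rexp(1, rates[s] / fineSubsteps)   # in sub-steps
        t1 <- t0 + wait
        if (t1 >= nFine) break
        s2 <- sample.int(N, 1L, prob = k[s, ])
        idx <- (floor(t1) + 1L):nFine + 1L
        states[tr, idx] <- s2
        s <- s2
        t0 <- t1
      }
      # fill any untouched tail
      for (t in seq_len(nFine)) if (states[tr, t + 1L] == 0L)
        states[tr, t + 1L] <- states[tr, t]
    }
  }
  states
}

#' Simulate ground-truthed tracks
#'
#' Brownian-dynamics simulation of molecules switching between diffusive
#' states in continuous time (approximated at `tau = dt / fineSubsteps`),
#' with Gaussian per-sub-step displacements of SD `d[state] / sqrt(u)` per
#' axis and Gaussian localization noise of SD `sigma` added to the true
#' positions at observation instants. Supports per-frame termination
#' (`pK` in the parameters), track-to-track heterogeneity, reflecting
#' confinement, and finite-field-of-view geometries in which a particle's
#' path is split into separate observed tracks each time it leaves and
#' re-enters the observable region.
#'
#' @param scenario a [SimulationScenario-class].
#' @param seed RNG seed for reproducibility.
#' @return A [SimulatedTracks-class]: observed [TrackSet-class] plus a
#'   ground-truth table (`track_id`, `frame`, true positions, `true_state`
#'   at each observation instant).
#' @examples
#' sim <- simulateTracks(simulationScenario(nTracks = 50), seed = 1)
#' sim
#' @export
simulateTracks <- function(scenario, seed = NULL) {
  stopifnot(is(scenario, "SimulationScenario"))
  if (!is.null(seed)) set.seed(seed)
  th <- scenario@params
  N <- th@nStates
  nT <- scenario@nTracks; nF <- scenario@nFrames
  na <- scenario@nAxes; us <- scenario@fineSubsteps
  nFine <- (nF - 1L) * us
  geom <- scenario@geometry
  het <- scenario@heterogeneity

  d <- th@d
  sigEff <- rep(th@sigma[1L], nT)
  dScale <- rep(1, nT)
  if (het$target == "sigma" && het$cv > 0) {
    sigEff <- chiSquareScaled(nT, th@sigma[1L], het$cv)
  } else if (het$target == "D" && het$cv > 0) {
    # chi-square on D; d scales with sqrt(D)
    Dmean <- 1
    dScale <- sqrt(chiSquareScaled(nT, Dmean, het$cv))
  }

  states <- .simStates(N, th@k, th@F, nT, nFine, us, scenario@switching)

  # per-sub-step displacement SD mixes flanking sub-states (mid-sub-step
  # transition convention), scaled per track for D heterogeneity
  sdsub <- sqrt((d[states[, -(nFine + 1L), drop = FALSE]]^2 +
                 d[states[, -1L, drop = FALSE]]^2) / (2 * us))
  dim(sdsub) <- c(nT, nFine)
  sdsub <- sdsub * dScale

  lo <- hi <- NULL; periodicAxes <- integer(0); viewAxis <- 0L
  viewLo <- viewHi <- NA_real_
  if (geom$type == "confined") {
    size <- geom$size %||% stopf("confined geometry needs 'size'")
    lo <- rep(0, na); hi <- rep(size, na)
  } else if (geom$type == "fov1d") {
    l <- geom$l %||% stopf("fov1d geometry needs 'l'")
    viewAxis <- 1L; viewLo <- l; viewHi <- 2 * l
    periodicAxes <- 1L; lo <- rep(0, na); hi <- rep(3 * l, na)
  } else if (geom$type == "fovz") {
    l <- geom$l %||% stopf("fovz geometry needs 'l'")
    viewAxis <- na; viewLo <- l; viewHi <- 2 * l
    periodicAxes <- na; lo <- rep(0, na); hi <- rep(3 * l, na)
  }

  truePos <- array(0, c(nT, nFine + 1L, na))
  for (a in seq_len(na)) {
    if (geom$type == "infinite") {
      x0 <- 0
      steps <- matrix(rnorm(nT * nFine, 0, 1), nT, nFine) * sdsub
      truePos[, , a] <- cbind(x0, steps) |> apply(1L, cumsum) |> t()
    } else {
      span <- hi[a] - lo[a]
      x <- runif(nT, lo[a], hi[a])
      truePos[, 1L, a] <- x
      reflect <- geom$type == "confined"
      for (t in seq_len(nFine)) {
        x <- x + rnorm(nT, 0, 1) * sdsub[, t]
        if (reflect) {
          x <- lo[a] + abs((x - lo[a]) %% (2 * span))
          over <- x > hi[a]
          x[over] <- 2 * hi[a] - x[over]
        } else if (a %in% periodicAxes) {
          x <- lo[a] + (x - lo[a]) %% span
        }
        truePos[, t + 1L, a] <- x
      }
    }
  }

  obsIdx <- seq(1L, nFine + 1L, by = us)
  frameStates <- states[, obsIdx, drop = FALSE]
  framePos <- truePos[, obsIdx, , drop = FALSE]
  noise <- array(rnorm(nT * nF * na), c(nT, nF, na)) * sigEff
  obsPos <- framePos + noise

  # per-frame survival against state-independent termination
  lastFrame <- rep(nF, nT)
  if (th@pK > 0) {
    surv <- matrix(runif(nT * (nF - 1L)) >= th@pK, nT, nF - 1L)
    firstFail <- apply(surv, 1L, function(z) {
      w <- which(!z); if (length(w)) w[1L] else nF
    })
    lastFrame <- pmin(lastFrame, firstFail)
  }

  axNames <- c("x", "y", "z")[seq_len(na)]
  trackList <- list()
  truthList <- list()
  idw <- max(5L, nchar(nT))
  for (tr in seq_len(nT)) {
    nUse <- lastFrame[tr]
    if (nUse < 2L) next
    inView <- rep(TRUE, nUse)
    if (viewAxis > 0L) {
      z <- framePos[tr, seq_len(nUse), viewAxis]
      inView <- z >= viewLo & z <= viewHi
    }
    runs <- rle(inView)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    seg <- 0L
    for (r in seq_along(runs$values)) {
      if (!runs$values[r]) next
      len <- runs$lengths[r]
      if (len < max(2L, if (viewAxis > 0L) geom$minSegment else 2L)) next
      seg <- seg + 1L
      fr <- starts[r]:ends[r]
      id <- sprintf("sim%0*d%s", idw, tr,
                    if (viewAxis > 0L) paste0(".", seg) else "")
      pm <- matrix(obsPos[tr, fr, ], length(fr), na,
                   dimnames = list(NULL, axNames))
      pes <- if (het$target == "sigma" && het$cv > 0)
        rep(sigEff[tr] / th@sigma[1L], length(fr)) else NULL
      trackList[[length(trackList) + 1L]] <-
        Track(pm, dt = th@dt, frames = fr - 1L, trackId = id,
              peakErrorScale = pes)
      tp <- matrix(framePos[tr, fr, ], length(fr), na)
      colnames(tp) <- paste0("true_", axNames)
      truthList[[length(truthList) + 1L]] <-
        data.frame(track_id = id, frame = fr - 1L, tp,
                   true_state = frameStates[tr, fr],
                   het_draw = if (het$target == "sigma") sigEff[tr]
                              else dScale[tr]^2)
    }
  }
  truth <- if (length(truthList)) do.call(rbind, truthList)
           else data.frame()
  new("SimulatedTracks", tracks = TrackSet(trackList), truth = truth,
      scenario = scenario)
}

#' Reference six-state scenario with one bound and five diffusive states
#'
#' A packaged heterogeneous-diffusion scenario: one immobile state and five
#' diffusive states with diffusion lengths 0.04-0.12 um (d/sigma from 2 to 6
#' at sigma = 0.02 um) and a fixed, fully-connected 30-rate transition
#' matrix. Useful for testing coarse-grained fitting followed by state
#' aggregation, since the five diffusive states are practically
#' indistinguishable from displacement statistics alone.
#'
#' @param nTracks,nFrames protocol size (default 10,000 tracks of 10
#'   positions).
#' @return A [SimulationScenario-class].
#' @export
scenarioSixState <- function(nTracks = 10000L, nFrames = 10L) {
  k <- matrix(0, 6, 6)
  k[1, 2:6] <- c(0.03, 0.02, 0.06, 0.04, 0.05)
  k[2, c(1, 3:6)] <- c(0.04, 0.05, 0.10, 0.07, 0.04)
  k[3, c(1:2, 4:6)] <- c(0.19, 0.01, 0.04, 0.06, 0.10)
  k[4, c(1:3, 5:6)] <- c(0.02, 0.03, 0.05, 0.05, 0.10)
  k[5, c(1:4, 6)] <- c(0.10, 0.04, 0.04, 0.01, 0.05)
  k[6, 1:5] <- c(0.15, 0.05, 0.01, 0.02, 0.05)
  params <- modelParams(d = c(0, 0.04, 0.06, 0.08, 0.10, 0.12),
                        sigma = 0.02, k = k, dt = 0.02)
  simulationScenario(params, nTracks = nTracks, nFrames = nFrames)
}
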