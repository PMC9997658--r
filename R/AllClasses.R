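#' Track: one particle's observed positions over consecutive frames
#'
#' A `Track` stores the observed positions of a single molecule, one row per
#' frame and one column per spatial axis (micrometres), together with its
#' frame indices, the frame interval `dt` (seconds), and an optional per-frame
#' localization-error scale (a positive factor multiplying the global
#' localization error at that frame, e.g. from photon-count estimates).
#'
#' Frame indices must increase strictly by 1: frame gaps are resolved at
#' input time by splitting (see [readTrackCSV()]).
#'
#' @slot trackId character scalar identifier.
#' @slot positions numeric matrix, frames x axes, micrometres.
#' @slot frames integer vector of frame indices.
#' @slot dt numeric scalar, frame interval in seconds.
#' @slot peakErrorScale numeric vector of per-frame positive scales, or
#'   `numeric(0)` when absent.
#'
#' @examples
#' tr <- Track(cbind(x = c(0, 0.05, 0.1), y = c(0, 0, 0.02)), dt = 0.06)
#' nFrames(tr)
#' @export
setClass("Track", representation(
  trackId = "character",
  positions = "matrix",
  frames = "integer",
  dt = "numeric",
  peakErrorScale = "numeric"
))

setValidity("Track", function(object) {
  p <- object@positions
  msg <- character()
  if (!is.numeric(p) || nrow(p) < 2L)
    msg <- c(msg, "a track needs at least 2 frames of numeric positions")
  if (any(!is.finite(p)))
    msg <- c(msg, "positions must be finite")
  if (length(object@frames) != nrow(p))
    msg <- c(msg, "frames and positions disagree in length")
  if (length(object@frames) > 1L && any(diff(object@frames) != 1L))
    msg <- c(msg, "frame indices must increase strictly by 1 (split gaps at input)")
  if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
    msg <- c(msg, "dt must be a positive scalar")
  pes <- object@peakErrorScale
  if (length(pes) && (length(pes) != nrow(p) || any(!is.finite(pes)) || any(pes <= 0)))
    msg <- c(msg, "peakErrorScale must be strictly positive, one value per frame")
  if (length(msg)) msg else TRUE
})

#' Construct a Track
#'
#' @param positions numeric matrix (frames x axes, micrometres) or a numeric
#'   vector for a 1D track.
#' @param dt frame interval in seconds.
#' @param frames integer frame indices (default `0:(n-1)`).
#' @param trackId identifier.
#' @param peakErrorScale optional per-frame positive localization-error scale.
#' @return A [Track-class] object.
#' @export
Track <- function(positions, dt = 1, frames = NULL, trackId = "track1",
                  peakErrorScale = NULL) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 1L,
                                                   dimnames = list(NULL, "x"))
  positions <- as.matrix(positions)
  if (is.null(colnames(positions)))
    colnames(positions) <- c("x", "y", "z")[seq_len(ncol(positions))]
  if (is.null(frames)) frames <- seq_len(nrow(positions)) - 1L
  new("Track", trackId = as.character(trackId), positions = positions,
      frames = as.integer(frames), dt = dt,
      peakErrorScale = as.numeric(peakErrorScale %||% numeric(0)))
}

setMethod("show", "Track", function(object) {
  cat(sprintf("Track '%s': %d frames, %d axis(es), dt = %g s%s\n",
              object@trackId, nrow(object@positions), ncol(object@positions),
              object@dt,
              if (length(object@peakErrorScale)) ", per-peak error scales" else ""))
})

#' A collection of tracks
#'
#' `TrackSet` is a [S4Vectors::SimpleList] of [Track-class] objects sharing a
#' frame interval and axis count.
#' @export
setClass("TrackSet", contains = "SimpleList",
         prototype = prototype(elementType = "Track"))

setValidity("TrackSet", function(object) {
  if (!length(object)) return(TRUE)
  if (!all(vapply(object, is, logical(1), "Track")))
    return("all elements must be Track objects")
  dts <- vapply(object, function(t) t@dt, numeric(1))
  nax <- vapply(object, function(t) ncol(t@positions), integer(1))
  if (length(unique(dts)) > 1L) return("all tracks must share dt")
  if (length(unique(nax)) > 1L) return("all tracks must share the axis count")
  TRUE
})

#' @param tracks a list of [Track-class] objects (or a single Track).
#' @rdname TrackSet-class
#' @export
TrackSet <- function(tracks = list()) {
  if (is(tracks, "Track")) tracks <- list(tracks)
  new("TrackSet", SimpleList(as.list(tracks)))
}

setMethod("show", "TrackSet", function(object) {
  ns <- vapply(object, function(t) nrow(t@positions), integer(1))
  cat(sprintf("TrackSet: %d tracks, %d positions total (lengths %s)\n",
              length(object), sum(ns),
              if (length(ns)) paste0(min(ns), "-", max(ns)) else "-"))
})

#' Multi-state diffusion model parameters
#'
#' The global parameters of an N-state switching-diffusion model: per-state
#' diffusion lengths per frame `d` (micrometres, `d[i] = sqrt(2 * D[i] * dt)`),
#' the localization error `sigma` (micrometres, one value or one per axis),
#' initial state fractions `F`, the off-diagonal matrix of transition rates
#' `k` (per frame), an optional per-frame state-independent track-termination
#' probability `pK`, and optional per-axis observable lengths `fovLen`
#' (micrometres, `Inf` for unbounded axes) for finite-field-of-view
#' corrections.
#'
#' States are ordered by ascending diffusion length; state 1 is the slowest
#' (for a bound/diffusive model, the bound state). Rates are stored per frame;
#' conversion to per-second uses `dt` at input/output time only.
#'
#' @slot nStates integer.
#' @slot d numeric, per-state diffusion length per frame (um), ascending.
#' @slot sigma numeric, localization error (um), length 1 or one per axis.
#' @slot F numeric simplex of initial fractions.
#' @slot k numeric matrix of off-diagonal transition rates per frame (diagonal 0).
#' @slot pK numeric in [0, 1), per-frame termination probability.
#' @slot fovLen numeric, per-axis observable length, or `numeric(0)`.
#' @slot dt numeric, frame interval (s).
#' @export
setClass("ModelParams", representation(
  nStates = "integer",
  d = "numeric",
  sigma = "numeric",
  F = "numeric",
  k = "matrix",
  pK = "numeric",
  fovLen = "numeric",
  dt = "numeric"
))

setValidity("ModelParams", function(object) {
  N <- object@nStates
  msg <- character()
  if (length(object@d) != N || any(object@d < 0))
    msg <- c(msg, "d must have one non-negative entry per state")
  if (is.unsorted(object@d))
    msg <- c(msg, "states must be ordered by ascending diffusion length")
  if (!length(object@sigma) || any(object@sigma <= 0))
    msg <- c(msg, "sigma must be positive")
  if (length(object@F) != N || any(object@F < 0) ||
      abs(sum(object@F) - 1) > 1e-8)
    msg <- c(msg, "F must be a simplex of length nStates")
  if (!identical(dim(object@k), c(N, N)) || any(object@k < 0) ||
      any(diag(object@k) != 0))
    msg <- c(msg, "k must be an N x N non-negative matrix with zero diagonal")
  if (object@pK < 0 || object@pK >= 1)
    msg <- c(msg, "pK must lie in [0, 1)")
  if (object@dt <= 0)
    msg <- c(msg, "dt must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct model parameters
#'
#' @param d per-state diffusion lengths per frame (um). States are sorted
#'   ascending; `F` and `k` are permuted along.
#' @param sigma localization error (um), scalar or one per axis.
#' @param k off-diagonal transition rate matrix (per frame), or for a 2-state
#'   model a length-2 vector `c(k12, k21)`.
#' @param F initial state fractions; `NULL` (default) uses the steady-state
#'   fractions of `k`.
#' @param pK per-frame state-independent termination probability.
#' @param fovLen per-axis observable lengths (um, `Inf` = unbounded), or
#'   `numeric(0)` when no finite field of view is modelled.
#' @param dt frame interval (s).
#' @return A [ModelParams-class] object.
#' @examples
#' modelParams(d = c(0, 0.1), sigma = 0.02, k = c(0.1, 0.1), dt = 0.06)
#' @export
modelParams <- function(d, sigma, k, F = NULL, pK = 0, fovLen = numeric(0),
                        dt = 1) {
  N <- length(d)
  if (is.vector(k) && !is.matrix(k)) {
    if (N == 2L && length(k) == 2L) {
      k <- matrix(c(0, k[2], k[1], 0), 2, 2)
    } else if (length(k) == 1L) {
      k <- matrix(k, N, N); diag(k) <- 0
    } else stopf("k must be an N x N matrix (or c(k12, k21) for 2 states)")
  }
  k <- as.matrix(k); diag(k) <- 0
  if (is.null(F)) F <- steadyStateFractions(k)
  ord <- order(d)
  new("ModelParams", nStates = N, d = as.numeric(d[ord]),
      sigma = as.numeric(sigma), F = as.numeric(F[ord]),
      k = k[ord, ord, drop = FALSE], pK = pK,
      fovLen = as.numeric(fovLen), dt = dt)
}

setMethod("show", "ModelParams", function(object) {
  N <- object@nStates
  cat(sprintf("ModelParams: %d state(s), dt = %g s\n", N, object@dt))
  cat(sprintf("  sigma (um): %s\n", paste(signif(object@sigma, 4), collapse = ", ")))
  cat(sprintf("  d (um/frame): %s\n", paste(signif(object@d, 4), collapse = ", ")))
  cat(sprintf("  F: %s\n", paste(signif(object@F, 4), collapse = ", ")))
  if (N > 1L) {
    cat("  k (per frame):\n")
    km <- signif(object@k, 4); dimnames(km) <- list(paste0("from", seq_len(N)),
                                                    paste0("to", seq_len(N)))
    print(km)
  }
  if (object@pK > 0) cat(sprintf("  pK: %g\n", object@pK))
  if (length(object@fovLen))
    cat(sprintf("  field of view (um): %s\n",
                paste(signif(object@fovLen, 4), collapse = ", ")))
})

#' Likelihood evaluation settings
#'
#' @slot window integer, sliding-window length counted in sub-steps; state
#'   sequences sharing their last `window` sub-states are merged.
#' @slot substeps integer, sub-steps per frame interval (1 = transitions at
#'   mid-step only).
#' @slot fovCorrection logical, apply the finite-field-of-view track-length
#'   factor (requires `fovLen` in the parameters).
#' @slot perPeakSigma logical, use per-frame localization error scales stored
#'   in the tracks.
#' @slot transitionMode `"perPair"` (default, `p_ij = 1 - exp(-k_ij)`) or
#'   `"generator"` (matrix exponential of the rate generator).
#' @slot fovMinLen integer; with `fovCorrection`, condition each track's
#'   density on having survived to the minimum length kept at input
#'   (default 3). Without this factor the discarded short tracks bias fits
#'   toward immobile-rich parameters.
#' @slot fovMaxLen integer; with `fovCorrection`, tracks of this length are
#'   treated as censored by the end of the observation (movie end or
#'   analysis cap) and get no final termination factor (`NA` = never).
#' @slot engine `"cpp"` (default) or `"R"` (reference implementation).
#' @export
setClass("LikelihoodConfig", representation(
  window = "integer", substeps = "integer", fovCorrection = "logical",
  perPeakSigma = "logical", transitionMode = "character",
  fovMinLen = "integer", fovMaxLen = "integer", engine = "character"
))

setValidity("LikelihoodConfig", function(object) {
  msg <- character()
  if (object@window < 1L) msg <- c(msg, "window must be >= 1")
  if (object@substeps < 1L) msg <- c(msg, "substeps must be >= 1")
  if (!object@transitionMode %in% c("perPair", "generator"))
    msg <- c(msg, "transitionMode must be 'perPair' or 'generator'")
  if (!object@engine %in% c("cpp", "R"))
    msg <- c(msg, "engine must be 'cpp' or 'R'")
  if (length(msg)) msg else TRUE
})

#' @param window,substeps,fovCorrection,perPeakSigma,transitionMode,fovMinLen,fovMaxLen,engine
#'   see the class slots.
#' @rdname LikelihoodConfig-class
#' @export
likelihoodConfig <- function(window = 7, substeps = 1, fovCorrection = FALSE,
                             perPeakSigma = FALSE,
                             transitionMode = c("perPair", "generator"),
                             fovMinLen = 3, fovMaxLen = NA,
                             engine = c("cpp", "R")) {
  if (substeps > window)
    warnf("window (%d) shorter than substeps (%d); accuracy degrades when merged sub-states span a frame", window, substeps)
  new("LikelihoodConfig", window = as.integer(window),
      substeps = as.integer(substeps), fovCorrection = fovCorrection,
      perPeakSigma = perPeakSigma,
      transitionMode = match.arg(transitionMode),
      fovMinLen = as.integer(fovMinLen), fovMaxLen = as.integer(fovMaxLen),
      engine = match.arg(engine))
}

#' Fitting settings
#'
#' @slot nStates integer, number of model states.
#' @slot likelihood a [LikelihoodConfig-class].
#' @slot fixed named list of parameters held fixed during optimization
#'   (`sigma`, `d`, `k`, `F`, `pK`; vector/matrix entries may mix fixed values
#'   with `NA` = free).
#' @slot steadyStateF logical, tie initial fractions to the steady state of
#'   the rates (`NA` = default: free for 2 states, tied for 3+).
#' @slot optimizer `"powell"` or `"nelder-mead"`.
#' @slot ftol relative function tolerance.
#' @slot maxEval maximum objective evaluations (`NA` = 1000 per free
#'   parameter).
#' @slot init optional [ModelParams-class] starting point (`NULL` = data-driven
#'   heuristic).
#' @slot maxTrackLen optional cap on positions used per track.
#' @export
setClass("FitConfig", representation(
  nStates = "integer", likelihood = "LikelihoodConfig", fixed = "list",
  steadyStateF = "logical", optimizer = "character", ftol = "numeric",
  maxEval = "integer", init = "ANY", maxTrackLen = "integer"
))

#' @param nStates,fixed,steadyStateF,optimizer,ftol,maxEval,init,maxTrackLen
#'   see the class slots.
#' @param window,substeps,fovCorrection,perPeakSigma,transitionMode,fovMinLen,fovMaxLen,engine
#'   forwarded to [likelihoodConfig()]; the default window follows the number
#'   of states (7 for 2 states, 5 for 3, 4 for more).
#' @rdname FitConfig-class
#' @export
fitConfig <- function(nStates = 2, window = NULL, substeps = 1,
                      fovCorrection = FALSE, perPeakSigma = FALSE,
                      transitionMode = c("perPair", "generator"),
                      fovMinLen = 3, fovMaxLen = NA,
                      engine = c("cpp", "R"),
                      fixed = list(), steadyStateF = NA,
                      optimizer = c("powell", "nelder-mead"), ftol = 1e-6,
                      maxEval = NA, init = NULL, maxTrackLen = NA) {
  if (is.null(window))
    window <- if (nStates <= 2) 7L else if (nStates == 3) 5L else 4L
  lik <- likelihoodConfig(window = window, substeps = substeps,
                          fovCorrection = fovCorrection,
                          perPeakSigma = perPeakSigma,
                          transitionMode = match.arg(transitionMode),
                          fovMinLen = fovMinLen, fovMaxLen = fovMaxLen,
                          engine = match.arg(engine))
  new("FitConfig", nStates = as.integer(nStates), likelihood = lik,
      fixed = fixed, steadyStateF = as.logical(steadyStateF),
      optimizer = match.arg(optimizer), ftol = ftol,
      maxEval = as.integer(maxEval), init = init,
      maxTrackLen = as.integer(maxTrackLen))
}

#' Result of a maximum-likelihood fit
#'
#' @slot params fitted [ModelParams-class], states sorted by ascending d.
#' @slot logLik maximized total log density of the track set.
#' @slot nIter optimizer direction-set iterations.
#' @slot nEval objective evaluations.
#' @slot converged logical.
#' @slot config the [FitConfig-class] used.
#' @export
setClass("FitResult", representation(
  params = "ModelParams", logLik = "numeric", nIter = "integer",
  nEval = "integer", converged = "logical", config = "FitConfig"
))

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: logLik = %.4f after %d iterations (%d evaluations)%s\n",
              object@logLik, object@nIter, object@nEval,
              if (object@converged) "" else " [NOT converged]"))
  show(object@params)
})

#' Per-time-point posterior state probabilities for one track
#'
#' @slot trackId character.
#' @slot probs frames x states matrix of posterior probabilities
#'   `P(state at frame i = s | whole track, parameters)`; rows sum to 1.
#' @slot labels integer argmax state per frame (ties to the lower index).
#' @export
setClass("AnnotationResult", representation(
  trackId = "character", probs = "matrix", labels = "integer"
))

setValidity("AnnotationResult", function(object) {
  p <- object@probs
  if (any(p < -1e-9 | p > 1 + 1e-9)) return("probabilities out of [0,1]")
  if (any(abs(rowSums(p) - 1) > 1e-6)) return("rows must sum to 1")
  TRUE
})

setMethod("show", "AnnotationResult", function(object) {
  cat(sprintf("AnnotationResult '%s': %d frames x %d states\n",
              object@trackId, nrow(object@probs), ncol(object@probs)))
})

#' Posterior summaries of refined molecule positions
#'
#' @slot trackId character.
#' @slot mean frames x axes matrix, posterior expected true positions (um).
#' @slot sd frames x axes matrix, posterior SDs (um).
#' @export
setClass("RefinedTrack", representation(
  trackId = "character", mean = "matrix", sd = "matrix"
))

setMethod("show", "RefinedTrack", function(object) {
  cat(sprintf("RefinedTrack '%s': %d frames, mean posterior SD %.4g um\n",
              object@trackId, nrow(object@mean), mean(object@sd)))
})

#' Probability-weighted histogram of state durations
#'
#' @slot table data.frame with columns `state`, `duration` (frames), `weight`,
#'   `censored` (TRUE when the run touches a track end and is right-censored).
#' @slot nTracks number of tracks used.
#' @slot bTop retained sequences per track.
#' @slot retainedMass mean per-track fraction of the track density carried by
#'   the retained sequences.
#' @slot dt frame interval (s).
#' @export
setClass("DurationHistogram", representation(
  table = "data.frame", nTracks = "integer", bTop = "integer",
  retainedMass = "numeric", dt = "numeric"
))

setMethod("show", "DurationHistogram", function(object) {
  cat(sprintf("DurationHistogram: %d tracks, top %d sequences, retained mass %.3f\n",
              object@nTracks, object@bTop, object@retainedMass))
})

#' Simulation scenario for ground-truthed synthetic tracks
#'
#' @slot params true [ModelParams-class].
#' @slot nTracks,nFrames integers.
#' @slot nAxes spatial dimensions.
#' @slot fineSubsteps fine sub-steps per frame for the continuous-time
#'   switching approximation (default 50).
#' @slot geometry list: `type` one of `"infinite"`, `"fov1d"` (finite width
#'   `l` on the first axis, simulation box of width `3*l`, periodic), `"fovz"`
#'   (finite depth `l` on the last axis, periodic period `3*l`), `"confined"`
#'   (reflecting square box of side `size`); plus `minSegment` for the
#'   field-of-view types (minimum in-view segment length kept).
#' @slot heterogeneity list: `target` (`"none"`, `"sigma"` or `"D"`) and `cv`
#'   (track-to-track chi-square coefficient of variation).
#' @slot switching `"firstOrder"` (per-sub-step probability `k*tau`) or
#'   `"exact"` (exponential waiting times).
#' @export
setClass("SimulationScenario", representation(
  params = "ModelParams", nTracks = "integer", nFrames = "integer",
  nAxes = "integer", fineSubsteps = "integer", geometry = "list",
  heterogeneity = "list", switching = "character"
))

#' Simulated tracks with ground truth
#'
#' @slot tracks observed [TrackSet-class].
#' @slot truth data.frame: `track_id`, `frame`, true positions (`true_x`,
#'   ...) and the true motion state at each observation instant
#'   (`true_state`, 1-based).
#' @slot scenario the generating [SimulationScenario-class].
#' @export
setClass("SimulatedTracks", representation(
  tracks = "TrackSet", truth = "data.frame", scenario = "SimulationScenario"
))

setMethod("show", "SimulatedTracks", function(object) {
  cat(sprintf("SimulatedTracks: %d observed tracks from %d simulated particles\n",
              length(object@tracks), object@scenario@nTracks))
})
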