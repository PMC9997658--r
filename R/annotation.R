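#' Posterior state probabilities at every time point
#'
#' Computes, for each frame `i` and state `s`, the posterior probability that
#' the molecule occupied state `s` at that observation instant given the
#' whole track and the global parameters,
#' `P(b_i = s | C, theta) = f(C, b_i = s | theta) / f(C | theta)`.
#' Each constrained density runs the same windowed forward recursion as the
#' likelihood with the state at frame `i` clamped to `s`, so rows sum to one
#' by construction. A larger window than for fitting costs little here (one
#' pass per frame and state instead of thousands of optimizer iterations) and
#' the default is therefore `window = 10`.
#'
#' @param track a [Track-class].
#' @param params a [ModelParams-class] (fitted or user-supplied).
#' @param config a [LikelihoodConfig-class]; defaults to `window = 10`.
#' @return An [AnnotationResult-class] with the frames x states probability
#'   matrix and argmax labels (ties resolved toward the lower, slower state).
#' @examples
#' sim <- simulateTracks(simulationScenario(nTracks = 3), seed = 2)
#' th <- simulationScenario()@params
#' annotateTrack(getTracks(sim)[[1]], th)
#' @export
annotateTrack <- function(track, params, config = likelihoodConfig(window = 10)) {
  annotateTracks(TrackSet(list(track)), params, config)[[1L]]
}

#' @param tracks a [TrackSet-class]; all tracks are annotated in one
#'   vectorized pass per (frame, state).
#' @rdname annotateTrack
#' @export
annotateTracks <- function(tracks, params,
                           config = likelihoodConfig(window = 10)) {
  if (!is(tracks, "TrackSet")) tracks <- TrackSet(tracks)
  stopifnot(is(params, "ModelParams"))
  if (nAxes(tracks[[1L]]) != length(rep_len(params@sigma, nAxes(tracks[[1L]]))))
    stopf("axis mismatch between tracks and parameters")
  N <- params@nStates
  groups <- .trackGroups(tracks, perPeak = config@perPeakSigma)
  out <- vector("list", length(tracks))
  for (g in groups) {
    nt <- dim(g$pos)[1L]; n <- dim(g$pos)[2L]
    full <- .windowLogLikGroup(g$pos, g$scales, params, config)
    probs <- array(NA_real_, c(nt, n, N))
    for (i in seq_len(n)) {
      for (s in seq_len(N)) {
        lc <- .windowLogLikGroup(g$pos, g$scales, params, config,
                                 constrainFrame = i, constrainState = s)
        probs[, i, s] <- exp(lc - full)
      }
    }
    # renormalize away residual floating-point error
    tot <- apply(probs, c(1L, 2L), sum)
    probs <- probs / as.vector(tot)
    for (j in seq_len(nt)) {
      pm <- matrix(probs[j, , ], n, N,
                   dimnames = list(NULL, paste0("state", seq_len(N))))
      out[[g$idx[j]]] <- new("AnnotationResult",
                             trackId = trackId(tracks[[g$idx[j]]]),
                             probs = pm,
                             labels = max.col(pm, ties.method = "first"))
    }
  }
  out
}

#' Tabulate annotations
#'
#' Flattens annotation results (and the matching tracks) into one data.frame
#' per the package CSV dialect: `track_id`, `frame`, per-axis positions,
#' per-state probability columns, and the argmax `label`.
#'
#' @param annotations list of [AnnotationResult-class].
#' @param tracks the matching [TrackSet-class].
#' @return A data.frame.
#' @export
annotationTable <- function(annotations, tracks) {
  if (!is(tracks, "TrackSet")) tracks <- TrackSet(tracks)
  stopifnot(length(annotations) == length(tracks))
  do.call(rbind, lapply(seq_along(annotations), function(j) {
    an <- annotations[[j]]; tr <- tracks[[j]]
    pos <- positions(tr)
    colnames(pos) <- paste0(colnames(pos), "_um")
    data.frame(track_id = trackId(tr), frame = tr@frames, pos,
               stateProbabilities(an), label = stateLabels(an),
               row.names = NULL)
  }))
}

#' @param path output CSV path.
#' @rdname annotationTable
#' @export
writeAnnotationsCSV <- function(annotations, tracks, path) {
  write.csv(annotationTable(annotations, tracks), path, row.names = FALSE)
  invisible(path)
}

# flatten per-frame true states aligned with annotation results
.alignTruth <- function(annotations, truths) {
  if (is.data.frame(truths)) {
    ids <- unlist(lapply(annotations, function(a)
      rep(a@trackId, nrow(a@probs))))
    key <- split(truths$true_state, truths$track_id)
    tv <- unlist(lapply(annotations, function(a) key[[a@trackId]]))
    if (length(tv) != length(ids))
      stopf("ground truth does not align with annotations")
    tv
  } else {
    unlist(truths)
  }
}

#' Calibration of annotated state probabilities
#'
#' On simulated data with known states, bins time points by their predicted
#' probability of occupying a reference state and reports the empirical
#' fraction truly in that state per bin. For a well-calibrated annotator the
#' curve lies on the diagonal: among all time points predicted diffusive with
#' probability p, a fraction p is actually diffusive.
#'
#' @param annotations list of [AnnotationResult-class].
#' @param truths ground truth: either the data.frame from [groundTruth()] or
#'   a list of per-track integer state vectors (1-based).
#' @param state reference state column (default 2, the faster state of a
#'   bound/diffusive model).
#' @param binWidth probability bin width (default 0.01).
#' @return data.frame: `bin` (midpoint), `n`, `predicted` (mean predicted
#'   probability), `empirical` (fraction truly in the state).
#' @export
calibrationCurve <- function(annotations, truths, state = 2L,
                             binWidth = 0.01) {
  p <- unlist(lapply(annotations, function(a) a@probs[, state]))
  tv <- .alignTruth(annotations, truths) == state
  bin <- pmin(floor(p / binWidth), floor(1 / binWidth) - 1L)
  keep <- !is.na(bin)
  agg <- split(data.frame(p = p[keep], t = tv[keep]), bin[keep])
  out <- do.call(rbind, lapply(names(agg), function(b) {
    d <- agg[[b]]
    data.frame(bin = (as.numeric(b) + 0.5) * binWidth, n = nrow(d),
               predicted = mean(d$p), empirical = mean(d$t))
  }))
  out[order(out$bin), , drop = FALSE]
}

#' Fraction of mislabeled time points
#'
#' Compares categorical labels (argmax state per time point, ties toward the
#' lower state index) against ground-truth states.
#'
#' @inheritParams calibrationCurve
#' @return Fraction in `[0, 1]`.
#' @export
mislabelRate <- function(annotations, truths) {
  lab <- unlist(lapply(annotations, stateLabels))
  tv <- .alignTruth(annotations, truths)
  if (length(lab) != length(tv)) stopf("length mismatch")
  mean(lab != tv)
}
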