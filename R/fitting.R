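# parameter vector packing ---------------------------------------------------
#
# The optimizer works on transformed coordinates: log(sigma), sqrt(d) (so
# d = x^2 can reach 0 smoothly), log(k), additive log-ratios for free F, and
# logit(pK). Fixed parameters are excluded from the search vector.

.paramNames <- function(N) {
  kn <- outer(seq_len(N), seq_len(N), function(i, j) paste0("k", i, j))
  c("sigma", paste0("d", seq_len(N)), kn[row(kn) != col(kn)],
    paste0("F", seq_len(N)), "pK")
}

.packSpec <- function(init, fixed, steadyStateF, fitPK) {
  N <- init@nStates
  off <- which(row(init@k) != col(init@k))
  fx <- function(name, default) {
    v <- fixed[[name]]
    if (is.null(v)) default else v
  }
  sigmaFix <- fx("sigma", NA_real_)[1L]
  dFix <- rep_len(fx("d", rep(NA_real_, N)), N)
  kFixM <- fx("k", matrix(NA_real_, N, N))
  if (is.vector(kFixM) && N == 2L && length(kFixM) == 2L)
    kFixM <- matrix(c(0, kFixM[2], kFixM[1], 0), 2, 2)
  kFix <- as.matrix(kFixM)[off]
  FFix <- fx("F", rep(NA_real_, N))
  pKFix <- if (fitPK) fx("pK", NA_real_)[1L] else fx("pK", 0)[1L]
  list(N = N, off = off, sigmaFix = sigmaFix, dFix = dFix, kFix = kFix,
       FFix = FFix, pKFix = pKFix, steadyStateF = steadyStateF,
       freeF = !steadyStateF && anyNA(FFix) && N > 1L)
}

.pack <- function(theta, spec) {
  x <- numeric(0)
  if (is.na(spec$sigmaFix)) x <- c(x, log(theta@sigma[1L]))
  x <- c(x, sqrt(theta@d[is.na(spec$dFix)]))
  kOff <- theta@k[spec$off]
  x <- c(x, log(pmax(kOff[is.na(spec$kFix)], 1e-6)))
  if (spec$freeF) {
    Fv <- pmax(theta@F, 1e-8)
    x <- c(x, log(Fv[-spec$N] / Fv[spec$N]))
  }
  if (is.na(spec$pKFix))
    x <- c(x, qlogis(min(max(theta@pK, 1e-4), 0.9)))
  x
}

.unpack <- function(x, spec, template) {
  i <- 0L
  take <- function(n) { out <- x[i + seq_len(n)]; i <<- i + n; out }
  sigma <- if (is.na(spec$sigmaFix)) exp(take(1L)) else spec$sigmaFix
  d <- spec$dFix
  d[is.na(spec$dFix)] <- take(sum(is.na(spec$dFix)))^2
  kOff <- spec$kFix
  kOff[is.na(spec$kFix)] <- exp(take(sum(is.na(spec$kFix))))
  k <- matrix(0, spec$N, spec$N)
  k[spec$off] <- kOff
  if (spec$freeF) {
    z <- c(take(spec$N - 1L), 0)
    Fv <- exp(z - max(z)); Fv <- Fv / sum(Fv)
  } else if (spec$steadyStateF) {
    Fv <- NULL
  } else {
    Fv <- spec$FFix
    if (anyNA(Fv)) Fv <- NULL
  }
  pK <- if (is.na(spec$pKFix)) plogis(take(1L)) else spec$pKFix
  modelParams(d = d, sigma = sigma, k = k, F = Fv, pK = pK,
              fovLen = template@fovLen, dt = template@dt)
}

# data-driven starting point: localization error from the small-displacement
# quantile (immobile molecules dominate there, E[dc^2] = 2 sigma^2), diffusion
# lengths from quantiles of per-track mean squared one-frame displacements
.defaultInit <- function(tracks, N, dt, fovLen = numeric(0),
                         maxTrackLen = NA) {
  perTrack <- vapply(tracks, function(tr) {
    p <- tr@positions
    if (!is.na(maxTrackLen)) p <- p[seq_len(min(nrow(p), maxTrackLen)), ,
                                    drop = FALSE]
    mean(diff(p)^2)
  }, numeric(1))
  allSq <- unlist(lapply(tracks, function(tr) as.vector(diff(tr@positions)^2)))
  sigma0 <- sqrt(max(quantile(allSq, 0.25) / 2, 1e-8))
  q <- quantile(perTrack, (seq_len(N) - 0.5) / N)
  d0 <- sqrt(pmax(q - 2 * sigma0^2, 0)) + (seq_len(N) - 1L) * 1e-3
  k0 <- matrix(0.05, N, N); diag(k0) <- 0
  modelParams(d = d0, sigma = sigma0, k = k0, F = rep(1 / N, N), pK = 0.05,
              fovLen = fovLen, dt = dt)
}

#' Fit a multi-state diffusion model by maximum likelihood
#'
#' Maximizes the summed log density of all tracks over the global parameters
#' (localization error, per-state diffusion lengths, transition rates,
#' initial fractions, and, with the field-of-view correction, the
#' termination probability) using Powell's derivative-free direction-set
#' method on transformed coordinates. Individual parameters can be held
#' fixed, and initial fractions can be tied to the steady state of the rates.
#' Fitted states are reported sorted by ascending diffusion length, which
#' resolves label switching across replicates.
#'
#' @param tracks a [TrackSet-class] (or list of [Track-class]).
#' @param config a [FitConfig-class]; see [fitConfig()].
#' @param fovLen per-axis observable lengths (um) when fitting with the
#'   field-of-view correction; overrides any value in the init.
#' @return A [FitResult-class].
#' @examples
#' sim <- simulateTracks(simulationScenario(nTracks = 200), seed = 7)
#' fit <- fitTracks(getTracks(sim), fitConfig(nStates = 2, window = 4,
#'                                            maxEval = 300))
#' fittedParams(fit)
#' @export
fitTracks <- function(tracks, config = fitConfig(), fovLen = numeric(0)) {
  if (!is(tracks, "TrackSet")) tracks <- TrackSet(tracks)
  stopifnot(is(config, "FitConfig"), length(tracks) >= 1L)
  N <- config@nStates
  lik <- config@likelihood
  dt <- frameInterval(tracks)
  maxLen <- config@maxTrackLen
  if (lik@fovCorrection && !length(fovLen) && !is.null(config@init))
    fovLen <- config@init@fovLen
  if (lik@fovCorrection && !length(fovLen))
    stopf("fovCorrection requires fovLen")
  steadyF <- if (is.na(config@steadyStateF)) N >= 3L else config@steadyStateF

  init <- config@init %||% .defaultInit(tracks, N, dt, fovLen, maxLen)
  if (init@nStates != N) stopf("init has %d states, expected %d",
                               init@nStates, N)
  spec <- .packSpec(init, config@fixed, steadyF, fitPK = lik@fovCorrection)
  x0 <- .pack(init, spec)
  if (!length(x0)) stopf("no free parameters to fit")

  groups <- .trackGroups(tracks, perPeak = lik@perPeakSigma, maxLen = maxLen)
  objective <- function(x) {
    th <- tryCatch(.unpack(x, spec, init), error = function(e) NULL)
    if (is.null(th)) return(1e10)
    ll <- tryCatch({
      tot <- 0
      for (g in groups)
        tot <- tot + sum(.windowLogLikGroup(g$pos, g$scales, th, lik))
      tot
    }, error = function(e) NA_real_)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  if (config@optimizer == "powell") {
    opt <- .powell(objective, x0, ftol = config@ftol,
                   maxEval = config@maxEval)
    res <- list(par = opt$par, value = opt$value, iter = opt$iter,
                evals = opt$evals, converged = opt$converged)
  } else {
    maxEval <- if (is.na(config@maxEval)) 1000L * length(x0)
               else config@maxEval
    opt <- optim(x0, objective, method = "Nelder-Mead",
                 control = list(reltol = config@ftol, maxit = maxEval))
    res <- list(par = opt$par, value = opt$value,
                iter = as.integer(opt$counts[1L]),
                evals = as.integer(opt$counts[1L]),
                converged = opt$convergence == 0L)
  }

  theta <- .unpack(res$par, spec, init)   # modelParams() re-sorts by d
  dd <- abs(outer(theta@d, theta@d, "-")); diag(dd) <- Inf
  if (N > 1L && any(dd < 1e-4 & (theta@k + t(theta@k)) > 5))
    warnf("degenerate fit: two states collapsed (near-equal d with diverging rates)")
  if (!res$converged)
    warnf("optimizer stopped before convergence (%d evaluations)", res$evals)
  new("FitResult", params = theta, logLik = -res$value,
      nIter = as.integer(res$iter), nEval = as.integer(res$evals),
      converged = res$converged, config = config)
}

#' Log-likelihood profile along one parameter
#'
#' Evaluates the summed track log density along a grid for one component of
#' the parameters, holding all others fixed. Useful to diagnose flat or
#' multi-modal likelihoods (weakly identified parameters).
#'
#' @param tracks tracks to evaluate on.
#' @param params the reference [ModelParams-class].
#' @param param component name: `"sigma"`, `"d1"`..., `"k12"`..., `"F1"`...,
#'   or `"pK"`.
#' @param grid numeric grid of values.
#' @param config a [LikelihoodConfig-class].
#' @return data.frame with columns `value` and `logLik`.
#' @export
profileObjective <- function(tracks, params, param, grid,
                             config = likelihoodConfig()) {
  if (!is(tracks, "TrackSet")) tracks <- TrackSet(tracks)
  vapply(grid, function(v) {
    th <- .setParam(params, param, v)
    datasetLogLik(tracks, th, config)
  }, numeric(1)) -> ll
  data.frame(value = grid, logLik = ll)
}

.setParam <- function(params, name, value) {
  d <- params@d; k <- params@k; sigma <- params@sigma
  Fv <- params@F; pK <- params@pK
  if (name == "sigma") sigma <- value
  else if (grepl("^d[0-9]+$", name)) d[as.integer(sub("d", "", name))] <- value
  else if (grepl("^k[0-9][0-9]$", name)) {
    ij <- as.integer(strsplit(sub("k", "", name), "")[[1L]])
    k[ij[1L], ij[2L]] <- value
  } else if (grepl("^F[0-9]+$", name)) {
    i <- as.integer(sub("F", "", name))
    rest <- setdiff(seq_along(Fv), i)
    Fv[rest] <- Fv[rest] * (1 - value) / sum(Fv[rest])
    Fv[i] <- value
  } else if (name == "pK") pK <- value
  else stopf("unknown parameter '%s'", name)
  modelParams(d = d, sigma = sigma, k = k, F = Fv, pK = pK,
              fovLen = params@fovLen, dt = params@dt)
}

#' Aggregate model states into coarse groups
#'
#' Collapses an N-state model into fewer effective states, for example to
#' report a single diffusive fraction when several diffusive states were fit.
#' Group occupancies are summed steady-state fractions; the coarse rate from
#' group A to group B is the occupancy-weighted mean outflow
#' `sum_{i in A} F_i * sum_{j in B} k_ij / sum_{i in A} F_i`; the coarse
#' diffusion length is the occupancy-weighted root mean square of the member
#' diffusion lengths. These definitions preserve total flux between groups at
#' steady state.
#'
#' @param params a [ModelParams-class].
#' @param groups list of integer vectors partitioning `1..nStates`.
#' @return A coarse [ModelParams-class] with one state per group.
#' @export
aggregateStates <- function(params, groups) {
  N <- params@nStates
  all <- sort(unlist(groups))
  if (!identical(all, seq_len(N))) stopf("groups must partition 1..%d", N)
  if (any(!lengths(groups))) stopf("empty group")
  Fs <- steadyStateFractions(params@k)
  G <- length(groups)
  Fg <- vapply(groups, function(g) sum(Fs[g]), numeric(1))
  dg <- vapply(groups, function(g)
    sqrt(sum(Fs[g] * params@d[g]^2) / max(sum(Fs[g]), 1e-300)), numeric(1))
  kg <- matrix(0, G, G)
  for (a in seq_len(G)) for (b in seq_len(G)) {
    if (a == b) next
    wa <- Fs[groups[[a]]]
    out <- vapply(groups[[a]], function(i) sum(params@k[i, groups[[b]]]),
                  numeric(1))
    kg[a, b] <- if (sum(wa) > 0) sum(wa * out) / sum(wa) else mean(out)
  }
  modelParams(d = dg, sigma = params@sigma, k = kg, F = Fg, pK = params@pK,
              fovLen = params@fovLen, dt = params@dt)
}

#' Split tracks into replicate subsets
#'
#' Random, equal-sized partition of a track set, for replicate-based
#' dispersion estimates of fitted parameters (the package reports no
#' Hessian-based standard errors).
#'
#' @param tracks a [TrackSet-class].
#' @param n number of replicates.
#' @param seed optional RNG seed.
#' @return List of `n` [TrackSet-class] objects.
#' @export
splitReplicates <- function(tracks, n, seed = NULL) {
  if (!is(tracks, "TrackSet")) tracks <- TrackSet(tracks)
  if (!is.null(seed)) set.seed(seed)
  grp <- sample(rep_len(seq_len(n), length(tracks)))
  lapply(seq_len(n), function(i) TrackSet(as.list(tracks)[grp == i]))
}

#' Fit each replicate and tabulate parameters
#'
#' @param replicates list of track sets (see [splitReplicates()]).
#' @param config a [FitConfig-class].
#' @param fovLen forwarded to [fitTracks()].
#' @return data.frame with columns `replicate`, `parameter`, `value`
#'   (rates per frame).
#' @export
fitReplicates <- function(replicates, config = fitConfig(),
                          fovLen = numeric(0)) {
  out <- lapply(seq_along(replicates), function(r) {
    fit <- fitTracks(replicates[[r]], config, fovLen = fovLen)
    th <- fit@params
    vals <- c(th@sigma[1L], th@d, th@k[row(th@k) != col(th@k)], th@F, th@pK)
    data.frame(replicate = r, parameter = .paramNames(th@nStates),
               value = vals, row.names = NULL)
  })
  do.call(rbind, out)
}
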