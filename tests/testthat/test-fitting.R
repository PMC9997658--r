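test_that("the Powell minimizer solves smooth test problems", {
  # quadratic bowl with correlated coordinates
  A <- matrix(c(3, 1, 1, 2), 2, 2)
  f <- function(x) drop(t(x - c(1, -2)) %*% A %*% (x - c(1, -2)))
  opt <- TrackStates:::.powell(f, c(5, 5), ftol = 1e-10)
  expect_true(opt$converged)
  expect_equal(opt$par, c(1, -2), tolerance = 1e-4)
  # agrees with Nelder-Mead on the Rosenbrock valley
  rb <- function(x) (1 - x[1])^2 + 100 * (x[2] - x[1]^2)^2
  op <- TrackStates:::.powell(rb, c(-1.2, 1), ftol = 1e-12, maxIter = 500)
  expect_lt(op$value, 1e-6)
  expect_equal(op$par, c(1, 1), tolerance = 1e-2)
})

test_that("single-state fits recover sigma and d from the displacement law", {
  # oracle: for N = 1 the MLE is identified by the displacement covariance
  # (Var = d^2 + 2 sigma^2, adjacent Cov = -sigma^2); simulated at known truth
  d <- 0.08; sg <- 0.025
  th <- modelParams(d = d, sigma = sg, k = matrix(0, 1, 1), dt = 0.06)
  sim <- simulateTracks(simulationScenario(th, nTracks = 800, nFrames = 10),
                        seed = 51)
  fit <- fitTracks(getTracks(sim), fitConfig(nStates = 1, window = 2))
  expect_true(fit@converged)
  expect_equal(diffusionLengths(fittedParams(fit)), d, tolerance = 0.03)
  expect_equal(localizationError(fittedParams(fit)), sg, tolerance = 0.03)
  # MLE dominance: fitted objective at least as good as the truth
  expect_gte(logLik(fit) + 1e-6,
             datasetLogLik(getTracks(sim), th, likelihoodConfig(window = 2)))
})

test_that("two-state fits recover all parameters within a few percent", {
  # d/sigma = 5 regime, 10 replicates of 2,000 tracks x 10 frames
  truth <- modelParams(d = c(0, 0.1), sigma = 0.02, k = c(0.1, 0.1),
                       dt = 0.06)
  sc <- simulationScenario(truth, nTracks = 2000, nFrames = 10)
  cfg <- fitConfig(nStates = 2, window = 3)
  rel <- matrix(NA_real_, 10, 4,
                dimnames = list(NULL, c("d2", "F1", "k12", "k21")))
  fits <- vector("list", 10)
  for (r in 1:10) {
    sim <- simulateTracks(sc, seed = 600 + r)
    fit <- fitTracks(getTracks(sim), cfg)
    th <- fittedParams(fit)
    fits[[r]] <- fit
    rel[r, ] <- abs(c(diffusionLengths(th)[2] - 0.1,
                      initialFractions(th)[1] - 0.5,
                      rateMatrix(th)[1, 2] - 0.1,
                      rateMatrix(th)[2, 1] - 0.1)) / c(0.1, 0.5, 0.1, 0.1)
  }
  expect_true(all(colMeans(rel) < 0.10))
  # objective improved over the starting point for every replicate
  expect_true(all(vapply(fits, function(f) f@converged, logical(1))))
})

test_that("fixed parameters are excluded from the search and tolerated off-truth", {
  truth <- modelParams(d = c(0, 0.1), sigma = 0.02, k = c(0.1, 0.1),
                       dt = 0.06)
  sim <- simulateTracks(simulationScenario(truth, nTracks = 2000,
                                           nFrames = 10), seed = 61)
  # sigma fixed 20% high: rates must stay within 25% of truth
  fit <- fitTracks(getTracks(sim),
                   fitConfig(nStates = 2, window = 3,
                             fixed = list(sigma = 0.024)))
  th <- fittedParams(fit)
  expect_identical(localizationError(th), 0.024)
  expect_lt(abs(rateMatrix(th)[1, 2] - 0.1) / 0.1, 0.25)
  expect_lt(abs(rateMatrix(th)[2, 1] - 0.1) / 0.1, 0.25)
  # fixing d1 = 0 keeps it at exactly zero
  fit0 <- fitTracks(getTracks(sim),
                    fitConfig(nStates = 2, window = 3,
                              fixed = list(d = c(0, NA)), maxEval = 400))
  expect_identical(diffusionLengths(fittedParams(fit0))[1], 0)
})

test_that("fits are invariant to translation, track order, and init d*", {
  truth <- modelParams(d = c(0, 0.1), sigma = 0.02, k = c(0.1, 0.1),
                       dt = 0.06)
  sim <- simulateTracks(simulationScenario(truth, nTracks = 400,
                                           nFrames = 10), seed = 62)
  tracks <- getTracks(sim)
  cfg <- fitConfig(nStates = 2, window = 3)
  f1 <- fitTracks(tracks, cfg)
  shifted <- TrackSet(lapply(as.list(tracks), function(t)
    Track(positions(t) + 5, dt = frameInterval(t), trackId = trackId(t))))
  f2 <- fitTracks(shifted, cfg)
  expect_equal(logLik(f1), logLik(f2), tolerance = 1e-6)
  permuted <- TrackSet(as.list(tracks)[rev(seq_along(tracks))])
  f3 <- fitTracks(permuted, cfg)
  expect_equal(logLik(f1), logLik(f3), tolerance = 1e-6)
  # widely different starting d* reach the same optimum
  for (dstar in c(0.3, 10)) {
    init <- modelParams(d = c(0, dstar * 0.02), sigma = 0.02,
                        k = c(0.05, 0.05), F = c(0.5, 0.5), dt = 0.06)
    fi <- fitTracks(tracks, fitConfig(nStates = 2, window = 3, init = init))
    expect_equal(diffusionLengths(fittedParams(fi))[2],
                 diffusionLengths(fittedParams(f1))[2], tolerance = 0.02)
  }
})

test_that("profile objective peaks at the fitted value and declines away", {
  truth <- modelParams(d = c(0, 0.1), sigma = 0.02, k = c(0.1, 0.1),
                       dt = 0.06)
  sim <- simulateTracks(simulationScenario(truth, nTracks = 500,
                                           nFrames = 10), seed = 63)
  fit <- fitTracks(getTracks(sim), fitConfig(nStates = 2, window = 3))
  th <- fittedParams(fit)
  s0 <- localizationError(th)
  grid <- s0 * c(0.6, 0.8, 0.95, 1, 1.05, 1.25, 1.6)
  prof <- profileObjective(getTracks(sim), th, "sigma", grid,
                           likelihoodConfig(window = 3))
  expect_equal(which.max(prof$logLik), 4L)
  expect_true(all(diff(prof$logLik[4:7]) < 0))
  expect_true(all(diff(prof$logLik[1:4]) > 0))
})

test_that("state aggregation preserves occupancy and steady-state flux", {
  th <- scenarioSixState()@params
  # trivial partition: identity
  same <- aggregateStates(th, as.list(1:6))
  expect_equal(diffusionLengths(same), diffusionLengths(th))
  expect_equal(rateMatrix(same), rateMatrix(th))
  # everything in one group: fraction 1, no rates
  one <- aggregateStates(th, list(1:6))
  expect_equal(initialFractions(one), 1)
  expect_equal(rateMatrix(one), matrix(0, 1, 1))
  expect_error(aggregateStates(th, list(1:3)), "partition")
  expect_error(aggregateStates(th, list(1:6, integer(0))), "empty group")
  # bound vs diffusive grouping: occupancies sum, fluxes balance at steady
  # state (occupancy-weighted outflow oracle computed directly)
  agg <- aggregateStates(th, list(1L, 2:6))
  Fs <- steadyStateFractions(rateMatrix(th))
  expect_equal(initialFractions(agg), c(Fs[1], sum(Fs[2:6])))
  k <- rateMatrix(th)
  kOn <- sum(Fs[2:6] * rowSums(k[2:6, 1, drop = FALSE])) / sum(Fs[2:6])
  expect_equal(rateMatrix(agg)[2, 1], kOn)
  expect_equal(rateMatrix(agg)[1, 2], sum(k[1, 2:6]))
  # flux balance: F_bound * k_off = F_diff * k_on
  expect_equal(initialFractions(agg)[1] * rateMatrix(agg)[1, 2],
               initialFractions(agg)[2] * rateMatrix(agg)[2, 1],
               tolerance = 1e-10)
})

test_that("replicate splitting partitions tracks evenly and fits tabulate", {
  sim <- simulateTracks(simulationScenario(nTracks = 90, nFrames = 8),
                        seed = 64)
  reps <- splitReplicates(getTracks(sim), 3, seed = 1)
  expect_length(reps, 3)
  expect_equal(sort(unlist(lapply(reps, function(r)
    vapply(r, trackId, character(1))))),
    sort(vapply(getTracks(sim), trackId, character(1))))
  tab <- fitReplicates(reps, fitConfig(nStates = 1, window = 2))
  expect_setequal(unique(tab$parameter), c("sigma", "d1", "F1", "pK"))
  expect_equal(nrow(tab), 3 * 4)
})
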