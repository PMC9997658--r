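test_that("posterior state probabilities match exhaustive enumeration", {
  set.seed(71)
  for (i in 1:6) {
    n <- sample(4:6, 1); N <- sample(2:3, 1); na <- sample(1:2, 1)
    th <- randomParams(N)
    tr <- randomTrack(n, na)
    an <- annotateTrack(tr, th, likelihoodConfig(window = n + 1))
    expect_equal(unname(stateProbabilities(an)), enumPosterior(tr, th),
                 tolerance = 1e-8)
    expect_lt(max(abs(rowSums(stateProbabilities(an)) - 1)), 1e-9)
  }
})

test_that("degenerate models give trivial or symmetric annotations", {
  tr <- randomTrack(8, 1)
  th1 <- modelParams(d = 0.05, sigma = 0.02, k = matrix(0, 1, 1), dt = 0.06)
  an1 <- annotateTrack(tr, th1)
  expect_true(all(stateProbabilities(an1) == 1))
  # fully symmetric two-state model: every probability is 1/2
  thS <- modelParams(d = c(0.05, 0.05), sigma = 0.02, k = c(0.2, 0.2),
                     F = c(0.5, 0.5), dt = 0.06)
  anS <- annotateTrack(tr, thS)
  expect_equal(unname(stateProbabilities(anS)),
               matrix(0.5, 8, 2), tolerance = 1e-9)
})

test_that("time reversal mirrors annotations under a symmetric model", {
  # stationary symmetric two-state chain: detailed balance makes the
  # posterior of the reversed track the reverse of the posterior
  th <- modelParams(d = c(0, 0.1), sigma = 0.02, k = c(0.1, 0.1),
                    F = c(0.5, 0.5), dt = 0.06)
  set.seed(72)
  sim <- simulateTracks(simulationScenario(th, nTracks = 5, nFrames = 9),
                        seed = 72)
  for (tr in as.list(getTracks(sim))) {
    fw <- annotateTrack(tr, th, likelihoodConfig(window = 10))
    rv <- annotateTrack(Track(positions(tr)[nFrames(tr):1, , drop = FALSE],
                              dt = frameInterval(tr)),
                        th, likelihoodConfig(window = 10))
    expect_equal(stateProbabilities(fw),
                 stateProbabilities(rv)[nFrames(tr):1, , drop = FALSE],
                 tolerance = 1e-7)
  }
})

test_that("annotation probabilities are calibrated on matched simulations", {
  truth <- modelParams(d = c(0, 0.1), sigma = 0.02, k = c(0.1, 0.1),
                       dt = 0.06)
  sim <- simulateTracks(simulationScenario(truth, nTracks = 800,
                                           nFrames = 10), seed = 73)
  # sub-steps sharpen the discrete approximation of continuous switching
  ann <- annotateTracks(getTracks(sim), truth,
                        likelihoodConfig(window = 10, substeps = 2))
  cal <- calibrationCurve(ann, groundTruth(sim), state = 2, binWidth = 0.05)
  busy <- cal[cal$n >= 100, ]
  expect_gt(nrow(busy), 5)
  outside <- 0
  for (j in seq_len(nrow(busy))) {
    ci <- binom.test(round(busy$empirical[j] * busy$n[j]),
                     busy$n[j])$conf.int
    if (busy$predicted[j] < ci[1] || busy$predicted[j] > ci[2])
      outside <- outside + 1
  }
  # a calibrated annotator misses a 95% CI in ~5% of bins by construction
  expect_lte(outside, qbinom(0.999, nrow(busy), 0.05))
  expect_lt(mean(abs(busy$empirical - busy$predicted)), 0.03)
  # shuffled truths flatten the curve to the global diffusive fraction
  tru <- groundTruth(sim)
  set.seed(1)
  tru$true_state <- sample(tru$true_state)
  calS <- calibrationCurve(ann, tru, state = 2, binWidth = 0.25)
  busyS <- calS[calS$n >= 200, ]
  expect_lt(max(abs(busyS$empirical - mean(tru$true_state == 2))), 0.05)
})

test_that("mislabel rate is 0/1 at the extremes and falls with d*", {
  probs <- matrix(c(0.9, 0.2, 0.6, 0.1, 0.8, 0.4), 3, 2)
  probs <- probs / rowSums(probs)
  an <- new("AnnotationResult", trackId = "t", probs = probs,
            labels = max.col(probs, ties.method = "first"))
  expect_equal(mislabelRate(list(an), list(an@labels)), 0)
  expect_equal(mislabelRate(list(an), list(3L - an@labels)), 1)
  expect_error(mislabelRate(list(an), list(1L)), "mismatch")
  # larger diffusion length to noise ratio -> easier state calls
  rates <- vapply(c(0.5, 2), function(dstar) {
    truth <- modelParams(d = c(0, dstar * 0.02), sigma = 0.02,
                         k = c(0.1, 0.1), dt = 0.06)
    sim <- simulateTracks(simulationScenario(truth, nTracks = 400,
                                             nFrames = 10), seed = 74)
    ann <- annotateTracks(getTracks(sim), truth,
                          likelihoodConfig(window = 7))
    mislabelRate(ann, groundTruth(sim))
  }, numeric(1))
  expect_gt(rates[1], rates[2])
})

test_that("mislabel rate degrades slowly under 30% parameter error", {
  truth <- modelParams(d = c(0, 0.1), sigma = 0.02, k = c(0.1, 0.1),
                       dt = 0.06)
  sim <- simulateTracks(simulationScenario(truth, nTracks = 400,
                                           nFrames = 10), seed = 75)
  cfg <- likelihoodConfig(window = 7)
  base <- mislabelRate(annotateTracks(getTracks(sim), truth, cfg),
                       groundTruth(sim))
  for (wrong in list(c("d2", 0.13), c("sigma", 0.026), c("k12", 0.13))) {
    thW <- TrackStates:::.setParam(truth, wrong[[1]],
                                   as.numeric(wrong[[2]]))
    rW <- mislabelRate(annotateTracks(getTracks(sim), thW, cfg),
                       groundTruth(sim))
    expect_lt(rW, 1.5 * base)
  }
})

test_that("annotation tables and CSV export carry all columns", {
  truth <- modelParams(d = c(0, 0.1), sigma = 0.02, k = c(0.1, 0.1),
                       dt = 0.06)
  sim <- simulateTracks(simulationScenario(truth, nTracks = 4,
                                           nFrames = 6), seed = 76)
  ann <- annotateTracks(getTracks(sim), truth)
  tab <- annotationTable(ann, getTracks(sim))
  expect_named(tab, c("track_id", "frame", "x_um", "y_um",
                      "state1", "state2", "label"))
  path <- tempfile(fileext = ".csv")
  writeAnnotationsCSV(ann, getTracks(sim), path)
  back <- read.csv(path)
  expect_equal(nrow(back), sum(vapply(getTracks(sim), nFrames, integer(1))))
})
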