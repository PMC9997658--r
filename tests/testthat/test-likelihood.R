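test_that("recursion step matches conjugate updates and quadrature", {
  # sigma -> 0 limit: belief collapses onto the observation
  b <- initialBelief(0.3, 1e-9, 0.05)
  b2 <- recursionStep(b, 0.31, 1e-9, 0.05)
  expect_equal(b2$mu, 0.31, tolerance = 1e-12)
  expect_equal(sqrt(b2$s2), 0.05, tolerance = 1e-6)
  # immobile state: conjugate-Gaussian posterior for a static mean
  sg <- 0.02; obs <- c(0.11, 0.09, 0.10)
  b <- initialBelief(obs[1], sg, 0)
  b <- recursionStep(b, obs[2], sg, 0)
  b <- recursionStep(b, obs[3], sg, 0)
  expect_equal(b$mu, mean(obs), tolerance = 1e-12)
  expect_equal(b$s2, sg^2 / 3, tolerance = 1e-12)
  # random inputs against 1D adaptive quadrature of the defining integral
  set.seed(2)
  for (i in 1:10) {
    mu0 <- rnorm(1); s0 <- runif(1, 0.01, 0.2); cv <- mu0 + rnorm(1, 0, s0)
    sg <- runif(1, 0.005, 0.1); dl <- runif(1, 0, 0.2)
    b <- recursionStep(list(mu = mu0, s2 = s0^2, logw = 0), cv, sg, dl)
    f <- function(r2) {
      vapply(r2, function(z) integrate(function(r)
        dnorm(z - r, 0, max(dl, 1e-12)) * dnorm(r - cv, 0, sg) *
          dnorm(r - mu0, 0, s0), -Inf, Inf, rel.tol = 1e-10)$value,
        numeric(1))
    }
    grid <- b$mu + c(-1, -0.3, 0, 0.4, 1.2) * sqrt(b$s2)
    expect_equal(exp(b$logw) * dnorm(grid, b$mu, sqrt(b$s2)), f(grid),
                 tolerance = 1e-8)
  }
})

test_that("single-sequence density matches closed forms", {
  th1 <- modelParams(d = 0.08, sigma = 0.02, k = matrix(0, 1, 1), dt = 0.06)
  tr2 <- Track(cbind(c(0.1, 0.17)), dt = 0.06)
  # n = 2: convolution closed form per axis
  expect_equal(sequenceLogDensity(tr2, c(1, 1), th1),
               dnorm(0.07, 0, sqrt(0.08^2 + 2 * 0.02^2), log = TRUE),
               tolerance = 1e-12)
  th0 <- modelParams(d = 0, sigma = 0.02, k = matrix(0, 1, 1), dt = 0.06)
  expect_equal(sequenceLogDensity(tr2, c(1, 1), th0),
               dnorm(0.07, 0, sqrt(2) * 0.02, log = TRUE), tolerance = 1e-12)
  # n <= 6, single state: multivariate normal of displacements
  set.seed(3)
  for (i in 1:10) {
    n <- sample(3:6, 1); na <- sample(1:2, 1)
    d <- runif(1, 0.01, 0.2); sg <- runif(1, 0.005, 0.08)
    th <- modelParams(d = d, sigma = sg, k = matrix(0, 1, 1), dt = 0.06)
    tr <- randomTrack(n, na)
    expect_equal(sequenceLogDensity(tr, rep(1, n), th),
                 mvnDisplacementLogLik(tr, d, sg), tolerance = 1e-10)
  }
  expect_error(sequenceLogDensity(tr2, c(1, 3), th1), "states")
})

test_that("windowed likelihood reproduces exhaustive enumeration when m >= n-1", {
  set.seed(11)
  for (i in 1:40) {
    n <- sample(3:6, 1); na <- sample(1:2, 1)
    u <- sample(1:2, 1)
    # enumeration over N^((n-1)u+1) sequences: cap the state count at u = 2
    N <- if (u == 2) sample(1:2, 1) else sample(1:3, 1)
    th <- randomParams(N)
    tr <- randomTrack(n, na)
    ref <- enumLogLik(tr, th, u)
    cfg <- likelihoodConfig(window = (n - 1) * u + 1, substeps = u)
    expect_equal(trackLogLik(tr, th, cfg), ref,
                 tolerance = 1e-10)
    # pure-R engine agrees with the compiled kernel
    cfgR <- likelihoodConfig(window = (n - 1) * u + 1, substeps = u,
                             engine = "R")
    expect_equal(trackLogLik(tr, th, cfgR), ref, tolerance = 1e-10)
  }
})

test_that("window approximation error shrinks with the window length", {
  # two-state tracks drawn from the model with d/sigma >= 2: the merged
  # recursion approaches exact enumeration as the window grows and is exact
  # once the window covers the track
  set.seed(13)
  errs <- matrix(NA_real_, 30, 3)   # columns: m = 3, 5, 7
  row <- 0
  for (i in 1:5) {
    sg <- runif(1, 0.01, 0.03)
    th <- modelParams(d = c(0, runif(1, 2, 6) * sg), sigma = sg,
                      k = c(runif(1, 0.05, 0.3), runif(1, 0.05, 0.3)),
                      dt = 0.06)
    sim <- simulateTracks(simulationScenario(th, nTracks = 6, nFrames = 9,
                                             nAxes = 1, fineSubsteps = 20),
                          seed = 100 + i)
    for (tr in as.list(getTracks(sim))) {
      ref <- enumLogLik(tr, th)
      expect_equal(trackLogLik(tr, th, likelihoodConfig(window = 8)), ref,
                   tolerance = 1e-10)
      row <- row + 1
      errs[row, ] <- vapply(c(3, 5, 7), function(m)
        abs(trackLogLik(tr, th, likelihoodConfig(window = m)) - ref),
        numeric(1))
    }
  }
  errs <- errs[seq_len(row), , drop = FALSE]
  expect_gt(mean(errs[, 1]), mean(errs[, 2]))
  expect_gt(mean(errs[, 2]), mean(errs[, 3]))
  expect_lt(mean(errs[, 2]), 0.02)   # window 5: small on average
  expect_lt(mean(errs[, 3]), 2e-3)   # window 7: nearly exact for n = 9
})

test_that("likelihood is translation invariant and additive over tracks", {
  set.seed(17)
  th <- randomParams(2)
  tr <- randomTrack(8, 2)
  cfg <- likelihoodConfig(window = 4)
  shifted <- Track(positions(tr) + rep(c(3.7, -1.2), each = nFrames(tr)),
                   dt = frameInterval(tr))
  expect_equal(trackLogLik(tr, th, cfg), trackLogLik(shifted, th, cfg),
               tolerance = 1e-9)
  tr2 <- randomTrack(5, 2)
  ts <- TrackSet(list(tr, tr2))
  expect_equal(datasetLogLik(ts, th, cfg),
               trackLogLik(tr, th, cfg) + trackLogLik(tr2, th, cfg),
               tolerance = 1e-10)
  # duplicated set doubles, order is irrelevant
  expect_equal(datasetLogLik(TrackSet(list(tr2, tr)), th, cfg),
               datasetLogLik(ts, th, cfg), tolerance = 1e-10)
  expect_equal(datasetLogLik(TrackSet(list(tr, tr2, tr, tr2)), th, cfg),
               2 * datasetLogLik(ts, th, cfg), tolerance = 1e-10)
})

test_that("the n = 2 track density is normalized", {
  # integrating exp(log f) over the second position gives 1 for a fixed
  # first position (trapezoid over +-8 SD of the widest component)
  set.seed(19)
  th <- randomParams(2)
  cfg <- likelihoodConfig(window = 2)
  halfwidth <- 8 * sqrt(max(diffusionLengths(th))^2 +
                        2 * localizationError(th)^2)
  c2 <- seq(-halfwidth, halfwidth, length.out = 2001)
  ll <- vapply(c2, function(z)
    trackLogLik(Track(cbind(c(0, z)), dt = 0.06), th, cfg), numeric(1))
  est <- sum(exp(ll)) * diff(c2[1:2])
  expect_equal(est, 1, tolerance = 1e-4)
})

test_that("axis factorization holds for a fixed state sequence", {
  set.seed(23)
  th <- randomParams(2)
  tr <- randomTrack(6, 2)
  B <- sample(1:2, 6, replace = TRUE)
  pos <- positions(tr)
  trx <- Track(pos[, 1, drop = FALSE], dt = 0.06)
  try_ <- Track(pos[, 2, drop = FALSE], dt = 0.06)
  logBeta <- log(initialFractions(th))[B[1]] +
    sum(log(transitionMatrix(rateMatrix(th)))[cbind(B[-6], B[-1])])
  expect_equal(sequenceLogDensity(tr, B, th),
               sequenceLogDensity(trx, B, th) +
                 sequenceLogDensity(try_, B, th) - logBeta,
               tolerance = 1e-10)
})

test_that("leave probability matches quadrature and is monotone", {
  expect_equal(leaveProbability(0, 0.5), 0)
  expect_lt(leaveProbability(0.01, 1e6), 1e-7)
  # quadrature oracle for the printed integrand, including delta = l
  for (case in list(c(0.2, 0.2), c(0.05, 0.3), c(0.4, 0.25))) {
    delta <- case[1]; l <- case[2]
    num <- 1 - integrate(function(x)
      pnorm((l - x) / delta) - pnorm(-x / delta), 0, l,
      rel.tol = 1e-12)$value / l
    expect_equal(leaveProbability(delta, l), num, tolerance = 1e-9)
  }
  # monotone: increasing in delta, decreasing in l
  dgrid <- seq(0.01, 0.5, by = 0.01)
  expect_true(all(diff(leaveProbability(dgrid, 0.3)) > 0))
  lgrid <- seq(0.1, 2, by = 0.05)
  pl <- vapply(lgrid, function(l) leaveProbability(0.1, l), numeric(1))
  expect_true(all(diff(pl) < 0))
  # compiled kernel and R implementation agree
  for (delta in c(0.02, 0.1, 0.37))
    expect_equal(TrackStates:::.cpp_leave_prob(delta, 0.4),
                 leaveProbability(delta, 0.4), tolerance = 1e-12)
})

test_that("per-peak error scales enter the likelihood as stated", {
  set.seed(29)
  th <- modelParams(d = c(0, 0.1), sigma = 0.02, k = c(0.1, 0.1), dt = 0.06)
  pos <- cbind(cumsum(rnorm(5, 0, 0.05)))
  scl <- c(1.5, 0.7, 1.2, 1, 2)
  trS <- Track(pos, dt = 0.06, peakErrorScale = scl)
  cfgS <- likelihoodConfig(window = 6, perPeakSigma = TRUE)
  # oracle: enumeration with sigma scaled per frame via sequenceLogDensity,
  # which reads the same scales
  ref <- enumLogLik(trS, th)
  expect_equal(trackLogLik(trS, th, cfgS), ref, tolerance = 1e-10)
  # scales change the density unless all equal 1
  trU <- Track(pos, dt = 0.06)
  expect_gt(abs(trackLogLik(trU, th, likelihoodConfig(window = 6)) - ref),
            1e-6)
})

test_that("field-of-view factor multiplies the per-sequence densities", {
  set.seed(31)
  sg <- 0.02
  th <- modelParams(d = c(0, 0.1), sigma = sg, k = c(0.1, 0.1), pK = 0.04,
                    fovLen = c(0.5, Inf), dt = 0.06)
  tr <- randomTrack(5, 2)
  cfg <- likelihoodConfig(window = 6, fovCorrection = TRUE, fovMinLen = 1)
  # oracle: enumerate sequences, adding the termination factor by hand
  n <- 5; N <- 2
  grid <- as.matrix(expand.grid(rep(list(1:N), n)))
  d <- diffusionLengths(th)
  lls <- apply(grid, 1, function(B) {
    base <- sequenceLogDensity(tr, B, th)
    deltas <- stepSD(d[B[-n]], d[B[-1]])
    pl <- vapply(deltas, function(dd) leaveProbability(dd, 0.5), numeric(1))
    plN <- leaveProbability(d[B[n]], 0.5)
    base + sum(log(1 - pl)) + (n - 1) * log(1 - 0.04) +
      log(0.04 + (1 - 0.04) * plN)
  })
  ref <- logSumExp <- max(lls) + log(sum(exp(lls - max(lls))))
  expect_equal(trackLogLik(tr, th, cfg), ref, tolerance = 1e-10)
  # conditioning on the input min-length filter subtracts the closed-form
  # survival probability of the first two steps (enumeration oracle)
  cfg3 <- likelihoodConfig(window = 6, fovCorrection = TRUE, fovMinLen = 3)
  surv <- 0
  for (b1 in 1:2) for (b2 in 1:2) for (b3 in 1:2) {
    P <- transitionMatrix(rateMatrix(th))
    dd <- diffusionLengths(th)
    s12 <- (1 - 0.04) * (1 - leaveProbability(stepSD(dd[b1], dd[b2]), 0.5))
    s23 <- (1 - 0.04) * (1 - leaveProbability(stepSD(dd[b2], dd[b3]), 0.5))
    surv <- surv + initialFractions(th)[b1] * P[b1, b2] * P[b2, b3] *
      s12 * s23
  }
  expect_equal(trackLogLik(tr, th, cfg3), ref - log(surv),
               tolerance = 1e-10)
})
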