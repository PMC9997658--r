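#' Convert between diffusion coefficient and diffusion length
#'
#' The diffusion length is the typical per-frame physical displacement of a
#' molecule in one axis, `d = sqrt(2 * D * dt)`. The dimensionless ratio
#' `d / sigma` acts as a signal-to-noise ratio: states with `d` comparable to
#' the localization error produce displacement distributions that overlap
#' heavily with those of immobile molecules.
#'
#' @param D diffusion coefficient (um^2/s), non-negative.
#' @param dt frame interval (s), positive.
#' @param d diffusion length per frame (um).
#' @return `diffusionLength` returns `d` in um; `diffusionCoefficient` is the
#'   inverse, returning `D` in um^2/s.
#' @examples
#' diffusionLength(0.04, 0.02)   # 0.04 um, i.e. d/sigma = 2 at sigma = 20 nm
#' diffusionCoefficient(0.1, 0.02)
#' @export
diffusionLength <- function(D, dt) {
  if (any(D < 0)) stopf("D must be non-negative")
  if (any(dt <= 0)) stopf("dt must be positive")
  sqrt(2 * D * dt)
}

#' @rdname diffusionLength
#' @export
diffusionCoefficient <- function(d, dt) {
  if (any(d < 0)) stopf("d must be non-negative")
  if (any(dt <= 0)) stopf("dt must be positive")
  d^2 / (2 * dt)
}

#' Displacement SD of a step spanning two states
#'
#' Transitions are taken to occur at the middle of a frame interval, so the
#' displacement SD of a step starting in a state with diffusion length
#' `dFrom` and ending in one with `dTo` mixes both:
#' `delta = sqrt((dFrom^2 + dTo^2) / 2)`. Assigning the whole step to the
#' current state instead biases fits toward diffusive motion when transitions
#' are frequent.
#'
#' @param dFrom,dTo diffusion lengths (um) of the flanking states.
#' @return The step SD `delta` in um.
#' @examples
#' stepSD(0, 0.1)   # 0.1 / sqrt(2)
#' @export
stepSD <- function(dFrom, dTo) {
  if (any(dFrom < 0) || any(dTo < 0)) stopf("diffusion lengths must be >= 0")
  sqrt((dFrom^2 + dTo^2) / 2)
}

#' Per-frame displacement SD from sub-step SDs
#'
#' With `u` sub-steps per frame the physical displacement over a frame is the
#' sum of independent Gaussian sub-displacements, so the per-frame SD is
#' `sqrt(sum(deltaSub^2) / u)` where each `deltaSub` is a mid-sub-step SD on
#' the frame scale.
#'
#' @param deltaSub numeric vector of `u` sub-step SDs (um).
#' @param u sub-step count; must equal `length(deltaSub)`.
#' @return The per-frame SD in um. For `u = 1` this is `deltaSub` itself.
#' @export
substepSD <- function(deltaSub, u = length(deltaSub)) {
  if (length(deltaSub) != u) stopf("deltaSub must have u = %d entries", u)
  if (u < 1) stopf("u must be >= 1")
  sqrt(sum(deltaSub^2) / u)
}

#' Per-frame transition probability matrix from rates
#'
#' Converts the off-diagonal rate matrix `k` (per frame) into a row-stochastic
#' matrix of per-frame transition probabilities. Two conventions are
#' available:
#' \describe{
#'   \item{`perPair` (default)}{`p_ij = 1 - exp(-k_ij)` for `i != j`,
#'     diagonal as the remainder. This slightly damped form compensates the
#'     rate overestimation introduced by the mid-step discretization of the
#'     continuous-time process and performs better for 2- and 3-state
#'     models.}
#'   \item{`generator`}{the exact matrix exponential `expm(G)` of the
#'     generator `G` with `G_ij = k_ij`, `G_ii = -sum_j k_ij`, which permits
#'     multiple transitions per step.}
#' }
#' Both agree to first order for small `k`.
#'
#' @param k off-diagonal rate matrix (per frame) or `c(k12, k21)` for 2
#'   states.
#' @param mode `"perPair"` or `"generator"`.
#' @param substeps evaluate the matrix for a sub-interval `1/substeps` of a
#'   frame (rates are divided accordingly).
#' @return An N x N row-stochastic matrix.
#' @examples
#' transitionMatrix(c(0.1, 0.1))
#' @export
transitionMatrix <- function(k, mode = c("perPair", "generator"),
                             substeps = 1L) {
  mode <- match.arg(mode)
  if (is.vector(k) && length(k) == 2L)
    k <- matrix(c(0, k[2], k[1], 0), 2, 2)
  k <- as.matrix(k)
  if (any(k < 0)) stopf("rates must be non-negative")
  k <- k / substeps
  N <- nrow(k)
  if (mode == "generator") {
    G <- k
    diag(G) <- 0
    diag(G) <- -rowSums(G)
    P <- as.matrix(Matrix::expm(G))
  } else {
    P <- 1 - exp(-k)
    diag(P) <- 0
    off <- rowSums(P)
    if (any(off >= 1))
      stopf("invalid rates: per-pair probabilities sum to >= 1 in a row (diagonal would be negative); reduce rates or use more substeps")
    diag(P) <- 1 - off
  }
  err <- abs(rowSums(P) - 1)
  if (any(err >= 1e-12)) {
    if (any(err > 1e-8)) stopf("transition matrix rows deviate from 1")
    P <- P / rowSums(P)
  }
  P
}

#' Steady-state fractions of a Markov switching model
#'
#' The stationary distribution of the continuous-time chain with off-diagonal
#' rates `k`: the normalized left null vector of the generator. For a 2-state
#' model this is `(k21, k12) / (k12 + k21)`.
#'
#' @param k off-diagonal rate matrix (per frame) or `c(k12, k21)`.
#' @return Numeric simplex of length N.
#' @examples
#' steadyStateFractions(c(0.1, 0.1))   # c(0.5, 0.5)
#' @export
steadyStateFractions <- function(k) {
  if (is.vector(k) && length(k) == 2L)
    k <- matrix(c(0, k[2], k[1], 0), 2, 2)
  k <- as.matrix(k)
  N <- nrow(k)
  if (N == 1L) return(1)
  if (any(k < 0)) stopf("rates must be non-negative")
  G <- k
  diag(G) <- 0
  diag(G) <- -rowSums(G)
  dec <- svd(t(G))
  small <- dec$d < max(dec$d, 1) * 1e-10
  if (sum(small) == 0L) small[N] <- TRUE
  if (sum(small) > 1L)
    warnf("reducible rate matrix: stationary distribution is not unique; returning one with zero-fraction states")
  v <- dec$v[, which(small)[1L]]
  v <- abs(v)
  v[v < 1e-14] <- 0
  v / sum(v)
}

#' Write or read model parameters as JSON
#'
#' Parameters are stored flat with units in the key names (`sigma_um`,
#' `d_um`, `F`, `k_per_frame` row-major, `p_k`, `fov_len_um`, `dt_s`, plus
#' the derived `k_per_s` for convenience).
#'
#' @param params a [ModelParams-class].
#' @param path file path.
#' @return `readModelParams` returns a [ModelParams-class];
#'   `writeModelParams` returns `path` invisibly.
#' @export
writeModelParams <- function(params, path) {
  stopifnot(is(params, "ModelParams"))
  doc <- list(
    n_states = params@nStates,
    sigma_um = params@sigma,
    d_um = params@d,
    F = params@F,
    k_per_frame = as.vector(t(params@k)),
    k_per_s = as.vector(t(params@k)) / params@dt,
    p_k = params@pK,
    fov_len_um = params@fovLen,
    dt_s = params@dt
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeModelParams
#' @export
readModelParams <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  N <- as.integer(doc$n_states)
  k <- matrix(as.numeric(doc$k_per_frame), N, N, byrow = TRUE)
  modelParams(d = as.numeric(doc$d_um), sigma = as.numeric(doc$sigma_um),
              k = k, F = as.numeric(doc$F), pK = as.numeric(doc$p_k %||% 0),
              fovLen = as.numeric(doc$fov_len_um %||% numeric(0)),
              dt = as.numeric(doc$dt_s))
}
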