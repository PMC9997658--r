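# Powell's direction-set minimizer (derivative-free), with Brent line
# minimization via stats::optimize and the standard direction-replacement
# test. Used because the likelihood surface is smooth but gradients of the
# windowed recursion are not available analytically.

.lineMin <- function(fn, p, u, f0, tol = 1e-3, span = 1, maxExpand = 6) {
  g <- function(a) fn(p + a * u)
  lo <- -span; hi <- span
  for (e in seq_len(maxExpand)) {
    opt <- optimize(g, c(lo, hi), tol = tol)
    inner <- (hi - lo) * 0.05
    if (opt$minimum > lo + inner && opt$minimum < hi - inner) break
    lo <- lo * 3; hi <- hi * 3
  }
  if (opt$objective >= f0) return(list(p = p, f = f0, moved = FALSE))
  list(p = p + opt$minimum * u, f = opt$objective, moved = TRUE)
}

.powell <- function(fn, par, ftol = 1e-6, maxIter = 200, maxEval = NA,
                    lineTol = 1e-3) {
  np <- length(par)
  evals <- 0L
  wrapped <- function(x) { evals <<- evals + 1L; fn(x) }
  dirs <- diag(np)
  p <- par
  fval <- wrapped(p)
  iter <- 0L
  converged <- FALSE
  if (is.na(maxEval)) maxEval <- 1000L * np
  repeat {
    iter <- iter + 1L
    f0 <- fval; p0 <- p
    del <- 0; ibig <- 1L
    for (i in seq_len(np)) {
      ls <- .lineMin(wrapped, p, dirs[, i], fval, tol = lineTol)
      dec <- fval - ls$f
      if (dec > del) { del <- dec; ibig <- i }
      p <- ls$p; fval <- ls$f
      if (evals >= maxEval) break
    }
    if (2 * (f0 - fval) <= ftol * (abs(f0) + abs(fval)) + 1e-12) {
      converged <- TRUE
      break
    }
    if (iter >= maxIter || evals >= maxEval) break
    # try the extrapolated point; replace the direction of largest decrease
    pe <- 2 * p - p0
    fe <- wrapped(pe)
    if (fe < f0) {
      tcrit <- 2 * (f0 - 2 * fval + fe) * (f0 - fval - del)^2 -
        del * (f0 - fe)^2
      if (tcrit < 0) {
        u <- p - p0
        nu <- sqrt(sum(u^2))
        if (nu > 0) {
          ls <- .lineMin(wrapped, p, u / nu, fval, tol = lineTol)
          p <- ls$p; fval <- ls$f
          dirs[, ibig] <- dirs[, np]
          dirs[, np] <- u / nu
        }
      }
    }
  }
  list(par = p, value = fval, iter = iter, evals = evals,
       converged = converged)
}
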