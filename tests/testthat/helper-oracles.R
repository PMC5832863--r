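# Independent oracles used across the suite.  Each reimplements the
# quantity it checks by a different route than the package code.

# Horn's quaternion method for optimal superposition RMSD
quaternionRmsd <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  S <- t(Pc) %*% Qc
  key <- matrix(0, 4, 4)
  key[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  key[1, 2] <- key[2, 1] <- S[2, 3] - S[3, 2]
  key[1, 3] <- key[3, 1] <- S[3, 1] - S[1, 3]
  key[1, 4] <- key[4, 1] <- S[1, 2] - S[2, 1]
  key[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  key[2, 3] <- key[3, 2] <- S[1, 2] + S[2, 1]
  key[2, 4] <- key[4, 2] <- S[3, 1] + S[1, 3]
  key[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  key[3, 4] <- key[4, 3] <- S[2, 3] + S[3, 2]
  key[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lmax <- max(eigen(key, symmetric = TRUE)$values)
  msd <- (sum(Pc^2) + sum(Qc^2) - 2 * lmax) / nrow(P)
  sqrt(max(msd, 0))
}

# grid-search least-squares rate oracle: for each candidate rate the
# amplitude is profiled out analytically; coarse pass then local refine
# at the stated resolution
gridSearchRate <- function(t, y, lo = 0.01, hi = 20, res = 1e-4) {
  sse <- function(r) {
    e <- exp(-r * t)
    i0 <- sum(y * e) / sum(e * e)
    sum((y - i0 * e)^2)
  }
  coarse <- seq(lo, hi, by = 0.01)
  s <- vapply(coarse, sse, numeric(1))
  best <- coarse[which.min(s)]
  fine <- seq(max(lo, best - 0.02), min(hi, best + 0.02), by = res)
  fine[which.min(vapply(fine, sse, numeric(1)))]
}

# sequential mass-balance ITC oracle: same displacement-volume dilution
# bookkeeping, but free/bound species found by numerical root finding of
# the mass-balance equation at every injection (no closed form)
itcOracleHeats <- function(n, kd, dh, sched) {
  v0 <- sched@cellVolume * 1e-6
  vi <- sched@injectionVolume * 1e-6
  ninj <- sched@nInjections
  dV <- cumsum(rep(vi, ninj))
  mt <- sched@cellConc * 1e-6 * (1 - dV / (2 * v0)) / (1 + dV / (2 * v0))
  xt <- sched@syringeConc * 1e-6 * (dV / v0) * (1 - dV / (2 * v0))
  C <- vapply(seq_len(ninj), function(i) {
    f <- function(xf) xf + n * mt[i] * xf / (kd + xf) - xt[i]
    if (xt[i] == 0) return(0)
    xf <- uniroot(f, c(0, xt[i]), tol = 1e-18)$root
    n * mt[i] * xf / (kd + xf)
  }, numeric(1))
  Q <- C * v0 * dh * 1000
  Qprev <- c(0, Q[-ninj])
  dQ <- Q - Qprev + (vi / v0) * (Q + Qprev) / 2
  list(heats = dQ * 1e6, complexM = C, v0 = v0, vi = vi)
}

# ensemble precision without iteration: superpose every model onto the
# first, average, report per-model RMSD to that explicit mean
bruteForcePrecision <- function(ens, sel = NULL) {
  nm <- nModels(ens)
  idx <- if (!is.null(sel)) {
    which(solnmr:::selectionIndex(atomTable(ens), sel))
  } else seq_len(nrow(atomTable(ens)))
  ref <- modelCoords(ens, 1)
  aligned <- lapply(seq_len(nm), function(m) {
    x <- modelCoords(ens, m)
    f <- kabschSuperpose(ref[idx, , drop = FALSE],
                         x[idx, , drop = FALSE])
    f$transform(x)
  })
  meanC <- Reduce(`+`, aligned) / nm
  per <- vapply(aligned, function(x)
    sqrt(mean(rowSums((x[idx, , drop = FALSE] -
                       meanC[idx, , drop = FALSE])^2))), numeric(1))
  list(meanRmsd = mean(per), perModel = per)
}

# exact linear solve for the 5 tensor components (normal equations)
directTensorSolve <- function(vectors, d) {
  v <- vectors@vectors
  M <- cbind(v[, 1]^2 - v[, 3]^2, v[, 2]^2 - v[, 3]^2,
             2 * v[, 1] * v[, 2], 2 * v[, 1] * v[, 3],
             2 * v[, 2] * v[, 3])
  s <- solve(t(M) %*% M, t(M) %*% d)
  matrix(c(s[1], s[3], s[4],
           s[3], s[2], s[5],
           s[4], s[5], -s[1] - s[2]), 3, 3, byrow = TRUE)
}

# random rotation matrix from a QR decomposition
randomRotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

r1DelaySet <- c(10, 50, 100, 400, 800, 1200, 1500) / 1000
r1rhoDelaySet <- c(0, 4, 12, 24, 40, 60, 80, 96) / 1000
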