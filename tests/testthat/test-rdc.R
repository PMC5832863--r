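test_that("bond vectors are extracted, normalized and counted", {
  atoms <- data.frame(residueId = c(1L, 1L, 2L, 2L, 3L),
                      residueName = "ALA",
                      atomName = c("N", "H", "N", "H", "N"))
  coords <- array(0, dim = c(5, 3, 1))
  coords[1, , 1] <- c(0, 0, 0); coords[2, , 1] <- c(0, 0, 1.02)
  coords[3, , 1] <- c(5, 0, 0); coords[4, , 1] <- c(5, 1.02, 0)
  coords[5, , 1] <- c(9, 9, 9)  # residue 3 has no H
  ens <- StructureEnsemble(atoms, coords)
  bv <- extractVectors(ens)
  expect_equal(length(bv), 2)
  expect_equal(bv@vectors[1, ], c(0, 0, 1))
  expect_equal(bv@vectors[2, ], c(0, 1, 0))
  expect_equal(attr(bv, "skipped"), 3L)

  ens2 <- simulateEnsemble(2, 12, 0.1, seed = 5)
  expect_equal(length(extractVectors(ens2)), 12)
})

test_that("extracted vectors co-rotate with the structure", {
  ens <- simulateEnsemble(2, 10, 0, seed = 6)
  R <- randomRotation(8)
  rot <- ens
  rot@coords[, , 1] <- ens@coords[, , 1] %*% t(R)
  v0 <- extractVectors(ens)@vectors
  v1 <- extractVectors(rot, model = 1)@vectors
  expect_equal(v1, v0 %*% t(R), tolerance = 1e-12)
})

test_that("SVD fit matches the exact linear solve and is optimal", {
  tens <- AlignmentTensor(6.4, 0.3, euler = c(25, 60, -15))
  bv5 <- randomBondVectors(5, seed = 13)
  d <- backCalculate(tens, bv5)
  fit <- svdFit(bv5, d, nBoot = 0)
  expect_equal(saupeMatrix(fit), directTensorSolve(bv5, d),
               tolerance = 1e-9)
  expect_equal(saupeMatrix(fit), saupeMatrix(tens), tolerance = 1e-9)
  expect_lt(max(abs(attr(fit, "dCalc") - d)), 1e-9)

  # least-squares optimality against perturbed tensors
  bv <- randomBondVectors(30, seed = 14)
  dn <- backCalculate(tens, bv) + rnorm(30, sd = 0.5)
  fitn <- svdFit(bv, dn, nBoot = 0)
  ssrFit <- sum((dn - backCalculate(fitn, bv))^2)
  set.seed(15)
  for (k in 1:20) {
    pert <- saupeMatrix(fitn) + {
      m <- matrix(rnorm(9, sd = 0.05), 3); m <- (m + t(m)) / 2
      m - diag(rep(sum(diag(m)) / 3, 3))
    }
    pt <- new("AlignmentTensor", tensor = pert, daSd = NA_real_,
              rhombicitySd = NA_real_)
    expect_gte(sum((dn - backCalculate(pt, bv))^2), ssrFit - 1e-10)
  }
})

test_that("zero couplings give the zero tensor and degenerate geometry
           is rejected", {
  bv <- randomBondVectors(10, seed = 16)
  fit <- svdFit(bv, rep(0, 10), nBoot = 0)
  expect_equal(Da(fit), 0, tolerance = 1e-12)
  expect_equal(max(abs(saupeMatrix(fit))), 0, tolerance = 1e-12)

  same <- BondVectorSet(1:6, matrix(rep(c(0, 0, 1), 6), ncol = 3,
                                    byrow = TRUE))
  expect_error(svdFit(same, rep(1, 6), nBoot = 0), "rank-deficient")
})

test_that("Da and rhombicity are rotation invariants of the fit", {
  tens <- AlignmentTensor(7.3, 0.35, euler = c(10, 40, 110))
  bv <- randomBondVectors(25, seed = 17)
  d <- backCalculate(tens, bv)
  for (seed in 1:5) {
    R <- randomRotation(seed + 100)
    bvR <- BondVectorSet(bv@residueId, bv@vectors %*% t(R))
    fit <- svdFit(bvR, d, nBoot = 0)
    expect_equal(Da(fit), 7.3, tolerance = 1e-8)
    expect_equal(rhombicity(fit), 0.35, tolerance = 1e-8)
  }
})

test_that("back-calculation agrees with the principal-frame closed form", {
  # axis-aligned closed forms
  tens <- AlignmentTensor(7.3, 0)
  expect_equal(backCalculate(tens, BondVectorSet(1L, matrix(c(0, 0, 1),
                                                            1))), 14.6)
  expect_equal(backCalculate(tens, BondVectorSet(1L, matrix(c(1, 0, 0),
                                                            1))), -7.3)

  # general case: molecular-frame quadratic form vs principal-frame
  # angular formula evaluated through an independent eigen-decomposition
  tgen <- AlignmentTensor(5.7, 0.41, euler = c(33, 64, -121))
  bv <- randomBondVectors(40, seed = 18)
  dq <- backCalculate(tgen, bv)
  e <- eigen(saupeMatrix(tgen), symmetric = TRUE)
  ord <- order(abs(e$values))
  axes <- e$vectors[, ord]   # x, y, z principal axes
  da <- e$values[ord][3] / 2
  rr <- (e$values[ord][1] - e$values[ord][2]) / (3 * da)
  if (rr < 0) { axes <- axes[, c(2, 1, 3)]; rr <- -rr }
  vp <- bv@vectors %*% axes  # components in the principal frame
  ct <- vp[, 3]
  phi <- atan2(vp[, 2], vp[, 1])
  dang <- da * ((3 * ct^2 - 1) + 1.5 * rr * (1 - ct^2) * cos(2 * phi))
  expect_equal(dq, dang, tolerance = 1e-10)
})

test_that("R-factor closed forms and monotonicity in noise", {
  d <- c(5, -3, 8, 2, -6)
  expect_equal(rdcRfactor(d, d), 0)
  expect_equal(rdcRfactor(d, rep(0, 5)), 100 * sqrt(1 / 2))
  expect_error(rdcRfactor(rep(0, 5), rep(0, 5)), "zero")

  tens <- AlignmentTensor(7.3, 0.35, euler = c(20, 30, 40))
  bv <- randomBondVectors(40, seed = 19)
  rf <- vapply(c(0, 0.2, 0.8, 2), function(sig) {
    tab <- simulateRdc(tens, bv, noiseSd = sig, seed = 99)
    rdcRfactor(svdFit(bv, tab, nBoot = 0))
  }, numeric(1))
  expect_lt(rf[1], 1e-6)
  expect_true(all(diff(rf) > 0))
})

test_that("bootstrap errors are reported and deterministic under seed", {
  tens <- AlignmentTensor(7.3, 0.35)
  bv <- randomBondVectors(30, seed = 20)
  tab <- simulateRdc(tens, bv, noiseSd = 0.5, seed = 1)
  f1 <- svdFit(bv, tab, nBoot = 200, seed = 5)
  f2 <- svdFit(bv, tab, nBoot = 200, seed = 5)
  expect_gt(f1@daSd, 0)
  expect_identical(f1@daSd, f2@daSd)
})
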