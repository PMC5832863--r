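test_that("superposition handles identity, rigid motions and rejects
           degenerate selections", {
  set.seed(41)
  ref <- matrix(rnorm(45), ncol = 3)
  f <- kabschSuperpose(ref, ref)
  expect_equal(f$rmsd, 0, tolerance = 1e-10)
  expect_equal(f$rotation, diag(3), tolerance = 1e-8)

  R <- randomRotation(42)
  moved <- ref %*% t(R) + matrix(c(3, -2, 7), nrow(ref), 3, byrow = TRUE)
  f2 <- kabschSuperpose(ref, moved)
  expect_equal(f2$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(f2$rotation), 1, tolerance = 1e-10)

  line <- cbind(1:5, 1:5, 1:5)
  expect_error(kabschSuperpose(line, line + 1), "collinear")
})

test_that("superposition RMSD equals the quaternion oracle and is
           invariant under rigid motions of either input", {
  for (seed in 1:10) {
    set.seed(seed)
    P <- matrix(rnorm(60), ncol = 3)
    Q <- matrix(rnorm(60), ncol = 3)
    base <- kabschSuperpose(Q, P)
    expect_equal(base$rmsd, quaternionRmsd(P, Q), tolerance = 1e-8)
    expect_equal(det(base$rotation), 1, tolerance = 1e-10)

    R <- randomRotation(seed + 50)
    shift <- matrix(rnorm(3, sd = 5), nrow(P), 3, byrow = TRUE)
    expect_equal(kabschSuperpose(Q, P %*% t(R) + shift)$rmsd, base$rmsd,
                 tolerance = 1e-8)
    expect_equal(kabschSuperpose(Q %*% t(R) + shift, P)$rmsd, base$rmsd,
                 tolerance = 1e-8)
  }
})

test_that("ensemble precision: trivial, oracle and invariance checks", {
  ens0 <- simulateEnsemble(5, 10, scatterProfile = 0, seed = 1)
  p0 <- ensemblePrecision(ens0)
  expect_equal(p0$meanRmsd, 0, tolerance = 1e-10)
  expect_equal(p0$sdRmsd, 0, tolerance = 1e-10)

  ens <- simulateEnsemble(15, 25, scatterProfile = 0.5, seed = 2)
  sel <- Selection("1-25:N,CA,C")
  p <- ensemblePrecision(ens, sel)
  o <- bruteForcePrecision(ens, sel)
  expect_equal(p$meanRmsd, o$meanRmsd, tolerance = 0.05)

  # invariance under a global rigid motion of the whole ensemble
  R <- randomRotation(77)
  moved <- ens
  for (m in seq_len(nModels(ens)))
    moved@coords[, , m] <- ens@coords[, , m] %*% t(R) +
      matrix(c(10, -4, 2), nrow(atomTable(ens)), 3, byrow = TRUE)
  pm <- ensemblePrecision(moved, sel)
  expect_equal(pm$meanRmsd, p$meanRmsd, tolerance = 1e-8)

  expect_error(ensemblePrecision(simulateEnsemble(2, 5, 0, seed = 1),
                                 Selection("1-1:N")), "fewer than 3")
})

test_that("heavy-atom precision exceeds backbone precision when
           side chains scatter more", {
  ens <- simulateEnsemble(15, 20, scatterProfile = 0.4, seed = 3,
                          sidechainScale = 3)
  bb <- ensemblePrecision(ens, Selection("1-20:N,CA,C"))
  heavy <- ensemblePrecision(ens, Selection("1-20:N,CA,C,O,CB"))
  expect_gt(heavy$meanRmsd, bb$meanRmsd)
})

test_that("pairwise precision convention is available and positive", {
  ens <- simulateEnsemble(6, 10, 0.4, seed = 4)
  pw <- ensemblePrecision(ens, method = "pairwise")
  expect_gt(pw$meanRmsd, 0)
  expect_equal(length(pw$perModel), choose(6, 2))
})

test_that("per-residue RMSD profile localizes and ranks scatter", {
  ens0 <- simulateEnsemble(5, 12, scatterProfile = 0, seed = 5)
  expect_equal(perResidueRmsd(ens0)$rmsd, rep(0, 12), tolerance = 1e-10)

  prof2 <- perResidueRmsd(simulateEnsemble(
    20, 30, scatterProfile = c(rep(0.2, 10), rep(1.3, 5), rep(0.2, 15)),
    seed = 6))
  expect_true(which.max(prof2$rmsd) %in% 11:15)

  # scatter ranking preserved (Spearman = 1 over distinct levels)
  levels <- c(0.1, 0.4, 0.8, 1.6)
  ens3 <- simulateEnsemble(25, 20, scatterProfile = rep(levels, each = 5),
                           seed = 7)
  prof3 <- perResidueRmsd(ens3)
  seg <- vapply(1:4, function(k) mean(prof3$rmsd[(k - 1) * 5 + 1:5]),
                numeric(1))
  expect_equal(cor(seg, levels, method = "spearman"), 1)
})

test_that("restraint tallies are additive and match printed-style
           accounting", {
  t <- RestraintTable(1504, c(phi = 71, psi = 71, chi = 19), 38, 79, 87)
  out <- tallyRestraints(t)
  expect_equal(unname(out["total"]), 1782)
  expect_equal(unname(out["per_residue"]), 20.5)
  expect_equal(sum(t@dihedralCounts), 161)

  empty <- RestraintTable()
  expect_equal(unname(tallyRestraints(empty)["total"]), 0)
  expect_equal(unname(tallyRestraints(empty)["per_residue"]), 0)

  # additivity and order independence
  a <- tallyRestraints(RestraintTable(10, c(phi = 1, psi = 2, chi = 3),
                                      4, 5, 10))
  b <- tallyRestraints(RestraintTable(5, c(phi = 3, psi = 2, chi = 1),
                                      4, 10, 10))
  expect_equal(unname(a["total"]), 10 + 1 + 2 + 3 + 4 + 5)
  expect_equal(unname(a["total"]), unname(b["total"]))
  expect_error(RestraintTable(-1), "counts")
})
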