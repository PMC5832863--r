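test_that("isotherm heats agree with the sequential mass-balance oracle
           to 0.1%", {
  sched <- InjectionSchedule()
  cases <- list(c(1, 4.8e-6, -11.5), c(0.8, 1e-6, -8),
                c(1.2, 2e-5, 5), c(1, 1e-7, -12))
  for (p in cases) {
    q <- wisemanIsotherm(p[1], p[2], p[3], sched)
    oracle <- itcOracleHeats(p[1], p[2], p[3], sched)
    expect_lt(max(abs(q - oracle$heats) / max(abs(oracle$heats))), 1e-3)
  }
})

test_that("isotherm limits: zero enthalpy, stoichiometric first
           injection, saturation decay", {
  sched <- InjectionSchedule()
  expect_equal(wisemanIsotherm(1, 4.8e-6, 0, sched), rep(0, 20))

  # kd -> 0: first 2 uL of 500 uM titrant binds completely;
  # heat = dh x 1e-9 mol = -11.5 ucal
  q <- wisemanIsotherm(1, 1e-15, -11.5, sched)
  expect_equal(q[1], -11.5, tolerance = 1e-3)

  # past the equivalence point heats decay monotonically toward zero
  qn <- wisemanIsotherm(1, 4.8e-6, -11.5, sched)
  tail <- abs(qn[12:20])
  expect_true(all(diff(tail) < 0))
})

test_that("total heat balances the enthalpy of all complex formed", {
  sched <- InjectionSchedule()
  for (p in list(c(1, 4.8e-6, -11.5), c(1, 5e-7, -9))) {
    q <- wisemanIsotherm(p[1], p[2], p[3], sched)
    o <- itcOracleHeats(p[1], p[2], p[3], sched)
    # complex formed = final in-cell moles + complex lost in overflow
    C <- o$complexM
    Cprev <- c(0, C[-length(C)])
    molesFormed <- C[length(C)] * o$v0 +
      sum((o$vi / o$v0) * (C + Cprev) / 2 * o$v0)
    expect_equal(sum(q), p[3] * 1000 * molesFormed * 1e6,
                 tolerance = 5e-3)
  }
})

test_that("dilution subtraction is elementwise and validated", {
  sched <- InjectionSchedule()
  q <- wisemanIsotherm(1, 4.8e-6, -11.5, sched)

  zeroBlank <- ItcExperiment(sched, q, rep(0, 20))
  expect_equal(heats(subtractDilution(zeroBlank)), q)

  selfBlank <- ItcExperiment(sched, q, q)
  expect_equal(heats(subtractDilution(selfBlank)), rep(0, 20))

  set.seed(31)
  blank <- rnorm(20, sd = 0.2)
  exp <- ItcExperiment(sched, q, blank)
  expect_equal(heats(subtractDilution(exp)), q - blank)

  expect_error(ItcExperiment(sched, q, blank[1:5]), "length")
  noBlank <- ItcExperiment(sched, q)
  expect_warning(out <- subtractDilution(noBlank), "blank")
  expect_equal(heats(out), q)
})

test_that("noise-free one-site fits are exact across the c range", {
  sched <- InjectionSchedule()
  cell <- sched@cellConc * 1e-6
  for (cval in c(5, 50, 500)) {
    kd <- cell / cval
    fit <- fitOneSite(simulateItc(1, kd, -11.5, sched))
    expect_equal(kdFit(fit), kd, tolerance = 1e-4)
    expect_equal(stoichiometry(fit), 1, tolerance = 1e-4)
    expect_equal(fit@dh, -11.5, tolerance = 1e-4)
  }
  expect_error(fitOneSite(ItcExperiment(sched, rep(0, 20))), "signal")
})

test_that("kd is recovered within 10% from 1%-noise thermograms", {
  sched <- InjectionSchedule()
  q0 <- wisemanIsotherm(1, 4.8e-6, -11.5, sched)
  noiseSd <- 0.01 * max(abs(q0))
  for (seed in 1:50) {
    exp <- simulateItc(1, 4.8e-6, -11.5, sched, noiseSd = noiseSd,
                       seed = seed)
    fit <- fitOneSite(exp)
    expect_equal(kdFit(fit), 4.8e-6, tolerance = 0.1)
  }
})

test_that("ill-conditioned c-values are flagged, not suppressed", {
  sched <- InjectionSchedule()
  tight <- fitOneSite(simulateItc(1, 1e-10, -10.3, sched))
  expect_true(any(grepl("c-value", tight@flags)))
  weak <- fitOneSite(simulateItc(1, 1e-3, -11.5, sched))
  expect_true(any(grepl("c-value", weak@flags)))
})

test_that("thermodynamic decomposition reproduces the identities", {
  td <- thermodynamics(4800e-9, -11.5)
  expect_equal(round(td[["dg"]], 1), -7.3)
  expect_equal(round(td[["tdsNeg"]], 1), 4.2)

  td2 <- thermodynamics(0.6e-9, -10.3)
  expect_equal(round(td2[["dg"]], 1), -12.6)
  expect_equal(round(td2[["tdsNeg"]], 1), -2.3)

  expect_equal(thermodynamics(1, -5)[["dg"]], 0)
  expect_error(thermodynamics(-1, 0), "positive")
})

test_that("BindingFit enforces the dg and -TdS identities", {
  fit <- BindingFit(1, 4.8e-6, -11.5)
  R <- nmrConstants()$gas_constant_kcal
  expect_equal(fit@dg, R * 298.15 * log(4.8e-6), tolerance = 1e-9)
  expect_equal(fit@tdsNeg, fit@dg - fit@dh, tolerance = 1e-9)
  # direct slot tampering is caught by the validity method
  broken <- fit
  broken@dg <- -5
  expect_error(validObject(broken), "dg")
})

test_that("affinity enhancement is the kd ratio", {
  expect_equal(enhancementFactor(4800e-9, 0.6e-9), 8000)
  expect_equal(enhancementFactor(2e-6, 2e-6), 1)
  expect_equal(enhancementFactor(17e-9, 1e-9), 17)
  expect_error(enhancementFactor(-1, 1), "positive")
})
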