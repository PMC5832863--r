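test_that("exponential fit is exact on noise-free data", {
  s <- simulateDecay(1.2, 100, r1DelaySet, noiseSd = 0)
  f <- fitExponential(s, nBoot = 0)
  expect_equal(f$rate, 1.2, tolerance = 1e-8)
  expect_equal(f$i0, 100, tolerance = 1e-8)

  flat <- RelaxationSeries(1L, r1DelaySet,
                           rep(80, length(r1DelaySet)))
  expect_equal(fitExponential(flat, nBoot = 0)$rate, 0)

  expect_error(fitExponential(RelaxationSeries(1L, c(0, 0.1),
                                               c(10, 5))), "3")
  expect_error(fitExponential(RelaxationSeries(1L, r1DelaySet,
    rep(0, length(r1DelaySet)))), "zero")
})

test_that("noisy fits agree with the grid-search oracle", {
  for (seed in 1:5) {
    s <- simulateDecay(2.4, 100, r1DelaySet, noiseSd = 2, seed = seed)
    f <- fitExponential(s, nBoot = 0)
    oracle <- gridSearchRate(s@delays, s@intensities)
    expect_equal(f$rate, oracle, tolerance = 5e-4)
  }
})

test_that("Monte Carlo rate errors scale with the noise level", {
  s1 <- simulateDecay(1.5, 100, r1DelaySet, noiseSd = 1, seed = 3)
  s2 <- simulateDecay(1.5, 100, r1DelaySet, noiseSd = 4, seed = 3)
  f1 <- fitExponential(s1, nBoot = 100, seed = 11)
  f2 <- fitExponential(s2, nBoot = 100, seed = 11)
  expect_gt(f1$rateSd, 0)
  expect_gt(f2$rateSd, f1$rateSd)
})

test_that("R1rho offset correction matches its closed forms", {
  # zero offset: identity for any inputs
  for (seed in 1:20) {
    set.seed(seed)
    rr <- runif(1, 5, 20); r1 <- runif(1, 0.5, 3)
    expect_equal(r2FromR1rho(rr, r1, offset = 0, spinlock = 1500)$r2, rr)
  }
  # theta = 45 degrees
  expect_equal(r2FromR1rho(10, 2, offset = 1500, spinlock = 1500)$r2, 18)
  # theta = 30 degrees: (8 - 1.6 * 0.25) / 0.75
  off30 <- 1500 * tan(pi / 6)
  expect_equal(r2FromR1rho(8, 1.6, offset = off30, spinlock = 1500)$r2,
               (8 - 1.6 * 0.25) / 0.75)
  # uncertainty propagation in quadrature at theta = 45
  out <- r2FromR1rho(10, 2, offset = 1500, spinlock = 1500,
                     r1rhoSd = 0.3, r1Sd = 0.1)
  expect_equal(out$r2Sd, sqrt(0.3^2 + (0.5 * 0.1)^2) / 0.5)
  # offset too close to 90 degrees is rejected
  expect_error(r2FromR1rho(10, 2, offset = 1e6, spinlock = 10), "offset")
  expect_error(r2FromR1rho(10, 2, spinlock = -5), "spinlock")
})

test_that("heteronuclear NOE is the intensity ratio with quadrature error", {
  expect_equal(hetNoe(0.8, 0.8)$noe, 1)
  expect_equal(hetNoe(0.6, 0.8)$noe, 0.75)
  out <- hetNoe(0.6, 0.8, noiseSd = 0.02)
  expect_equal(out$noeSd, (0.02 / 0.8) * sqrt(1 + 0.75^2))
  # reference within noise of zero is flagged undefined
  weak <- hetNoe(0.05, 0.01, noiseSd = 0.02)
  expect_true(weak$undefined)
  expect_true(is.na(weak$noe))
  expect_error(hetNoe(0.5, 0), "non-zero")
})

test_that("a rigid tumbler shows the large-NOE rigidity signature", {
  r <- modelfreeRates(SpinParams(0.87, 6.2, 50, 0, 800))
  i_ref <- 100
  i_sat <- r$noe * i_ref
  expect_gt(hetNoe(i_sat, i_ref)$noe, 0.8)
})

test_that("tauc estimator inverts the forward model and trims outliers", {
  r <- modelfreeRates(SpinParams(1, 3.0, 0, 0, 800))
  rates <- data.frame(residue_id = 1:8, r1 = r$r1, r2 = r$r2,
                      noe = r$noe)
  expect_equal(tauC(estimateTauc(rates, 800)), 3.0, tolerance = 1e-6)

  # an exchange-broadened residue is trimmed away
  rex <- modelfreeRates(SpinParams(1, 3.0, 0, 10, 800))
  rates2 <- rbind(rates, data.frame(residue_id = 9L, r1 = rex$r1,
                                    r2 = rex$r2, noe = rex$noe))
  est2 <- estimateTauc(rates2, 800)
  expect_equal(tauC(est2), 3.0, tolerance = 1e-6)
  expect_true(9L %in% est2@trimmedIds)

  expect_error(estimateTauc(rates[1:4, ], 800), "fewer than 5")
})

test_that("tauc estimate is monotone in the R2/R1 ratio", {
  mk <- function(tc) {
    r <- modelfreeRates(SpinParams(1, tc, 0, 0, 800))
    data.frame(residue_id = 1:6, r1 = r$r1, r2 = r$r2, noe = r$noe)
  }
  est <- vapply(c(3, 5, 8, 12), function(tc)
    tauC(estimateTauc(mk(tc), 800)), numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("closed-form tauc approximation tracks the inversion", {
  r <- modelfreeRates(SpinParams(1, 6.2, 0, 0, 800))
  rates <- data.frame(residue_id = 1:6, r1 = r$r1, r2 = r$r2,
                      noe = r$noe)
  inv <- tauC(estimateTauc(rates, 800, method = "invert"))
  cf <- tauC(estimateTauc(rates, 800, method = "closed"))
  expect_equal(cf, inv, tolerance = 0.05)
})

test_that("dynamics classification follows the NOE/R2 criteria and
           partitions residues exactly once", {
  base <- data.frame(residue_id = 1:10,
                     r2 = c(rep(10, 7), 10, 10, NA),
                     noe = c(rep(0.85, 7), 0.6, 0.85, NA))
  base$r2[9] <- 18  # well above mean + 3 sd of the trimmed pool
  labs <- classifyDynamics(base)
  expect_equal(as.character(labs$label[8]), "fast")
  expect_equal(as.character(labs$label[9]), "exchange")
  expect_equal(as.character(labs$label[10]), "broadened/missing")
  expect_equal(as.character(labs$label[1]), "rigid")
  # both criteria met
  both <- base; both$noe[9] <- 0.5
  expect_equal(as.character(classifyDynamics(both)$label[9]), "both")
  # exactly one label per residue, all residues covered
  expect_equal(labs$residue_id, base$residue_id)
  expect_false(any(is.na(labs$label)))
})

test_that("intensity ratios equal elementwise division", {
  free <- data.frame(residue_id = 1:5, intensity = c(1, 2, 4, 5, 8))
  expect_equal(intensityRatio(free, free)$ratio, rep(1, 5))

  bound <- free; bound$intensity <- 0.3 * free$intensity
  expect_equal(intensityRatio(bound, free)$ratio, rep(0.3, 5))

  set.seed(21)
  b2 <- data.frame(residue_id = 1:5, intensity = runif(5))
  f2 <- data.frame(residue_id = 1:5, intensity = runif(5))
  expect_equal(intensityRatio(b2, f2)$ratio, b2$intensity / f2$intensity)

  # missing in bound reported as 0; zero free flagged undefined
  b3 <- data.frame(residue_id = c(1, 3), intensity = c(1, 1))
  f3 <- data.frame(residue_id = 1:3, intensity = c(2, 2, 0))
  out <- intensityRatio(b3, f3)
  expect_equal(out$ratio[2], 0)
  expect_true(out$undefined[3] && is.na(out$ratio[3]))
})

test_that("rates are recovered within 3% median error at 2% noise", {
  set.seed(7)
  n <- 100
  r1True <- runif(n, 1.0, 2.0)
  rrTrue <- runif(n, 8, 14)
  relErr <- function(rates, delays, seeds) {
    vapply(seq_len(n), function(i) {
      s <- simulateDecay(rates[i], 100, delays, noiseSd = 2,
                         seed = seeds[i])
      abs(fitExponential(s, nBoot = 0)$rate - rates[i]) / rates[i]
    }, numeric(1))
  }
  expect_lt(median(relErr(r1True, r1DelaySet, 1:n)), 0.03)
  expect_lt(median(relErr(rrTrue, r1rhoDelaySet, n + 1:n)), 0.03)
})

test_that("analyzeRelaxation assembles per-residue rates end to end", {
  ids <- 1:8
  p <- SpinParams(1, 6.2, 0, 0, 800)
  tr <- modelfreeRates(p)
  r1s <- lapply(ids, function(i)
    simulateDecay(tr$r1, 100, r1DelaySet, noiseSd = 0, residueId = i))
  rrs <- lapply(ids, function(i)
    simulateDecay(tr$r2, 100, r1rhoDelaySet, noiseSd = 0,
                  residueId = i))
  noeTab <- data.frame(residue_id = ids, i_sat = tr$noe * 100,
                       i_ref = 100, noise_sd = 0)
  cfg <- SpectrometerConfig(800, 1500)
  expect_warning(out <- analyzeRelaxation(r1s, rrs, noeTab, cfg,
                                          nBoot = 0), "offsets")
  expect_equal(nrow(out), length(ids))
  expect_equal(out$r1, rep(tr$r1, length(ids)), tolerance = 1e-6)
  expect_equal(out$r2, rep(tr$r2, length(ids)), tolerance = 1e-6)
  expect_equal(out$noe, rep(tr$noe, length(ids)), tolerance = 1e-10)
})
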