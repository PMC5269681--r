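test_that("double-well preset reproduces its declared geometry", {
  for (B in c(2, 3.5, 6, 10)) {
    m <- modelSystem("double-well", barrier = B, deltaF = -2, D0 = 1e-3)
    x <- seq(-180, 180, by = 0.05)
    Fx <- modelPMF(m, x)
    dF <- diff(sign(diff(Fx)))
    mins <- x[which(dF == 2) + 1]
    expect_equal(sort(mins), c(-135, 30), tolerance = 0.5)
    expect_equal(modelPMF(m, -135) - modelPMF(m, 30), -2,
                 tolerance = 0.05)
    path <- seq(30, 225, by = 0.05)
    expect_equal(max(modelPMF(m, path)) - modelPMF(m, 30), B,
                 tolerance = 0.05)
  }
  # diffusivity fluctuation spans one order of magnitude when requested
  mr <- modelSystem("double-well", dLogAmp = log(10) / 2)
  Dx <- modelDiffusivity(mr, seq(-180, 180, by = 1))
  expect_equal(max(Dx) / min(Dx), 10, tolerance = 0.01)
})

test_that("trajectories are deterministic given the seed", {
  m <- modelSystem("double-well", D0 = 1e-3)
  s1 <- langevinTrajectory(m, simulationSpec(0.01, 1e4, 10), seed = 5,
                           biasCenter = 30, biasK = 400)
  s2 <- langevinTrajectory(m, simulationSpec(0.01, 1e4, 10), seed = 5,
                           biasCenter = 30, biasK = 400)
  s3 <- langevinTrajectory(m, simulationSpec(0.01, 1e4, 10), seed = 6,
                           biasCenter = 30, biasK = 400)
  expect_identical(angleValues(s1), angleValues(s2))
  expect_false(identical(angleValues(s1), angleValues(s3)))
})

test_that("free diffusion and biased stationary statistics are exact", {
  m <- modelSystem("flat", D0 = 1e-3)
  # per-step increment variance 2 D dt
  s <- langevinTrajectory(m, simulationSpec(0.01, 1e6, 1), seed = 3)
  dv <- diff(.deg2radTest(angleValues(s)))
  expect_rel(var(dv), 2 * 1e-3 * 0.01, 0.01)
  # harmonic bias: stationary variance kT/k_U within 2%
  sb <- langevinTrajectory(m, simulationSpec(0.01, 1e6, 10), seed = 4,
                           biasCenter = 0, biasK = 400)
  expect_rel(var(.deg2radTest(angleValues(sb))),
             thermalEnergy(300) / 400, 0.02)
})

test_that("the drift-stability check rejects oversized timesteps", {
  m <- modelSystem("double-well", barrier = 10, D0 = 0.5)
  expect_error(
    langevinTrajectory(m, simulationSpec(dt = 5, steps = 1000, stride = 1),
                       seed = 1, biasCenter = 30, biasK = 400),
    "dt")
})

test_that("unbiased long runs sample the Boltzmann distribution", {
  # mixing-friendly test system: low barrier, fast diffusion
  m <- modelSystem("double-well", barrier = 1.2, deltaF = -0.5, D0 = 0.02)
  s <- langevinTrajectory(m, simulationSpec(0.05, 1e6, 20), seed = 8)
  v <- wrapAngle(angleValues(s))
  # thin to roughly independent samples
  v <- v[seq(1, length(v), by = 40)]
  breaks <- seq(-180, 180, by = 30)
  counts <- table(cut(v, breaks))
  mid <- breaks[-1] - 15
  pExp <- exp(-modelPMF(m, mid) / thermalEnergy(300))
  pExp <- pExp / sum(pExp)
  chi <- suppressWarnings(stats::chisq.test(counts, p = pExp))
  expect_gt(chi$p.value, 0.01)
})

test_that("replica exchange preserves window marginals (KS)", {
  m <- modelSystem("double-well", D0 = 1e-3)
  ctrs <- seq(-60, -22, by = 2)                 # spans the minor saddle
  spec <- simulationSpec(0.01, 4e4, 10)
  wsX <- runUmbrellaCampaign(m, ctrs, spec = spec, exchangeEvery = 2,
                             seed = 31)
  ws0 <- runUmbrellaCampaign(m, ctrs, spec = spec, exchangeEvery = 0,
                             seed = 77)
  acc <- windowMetadata(wsX)$acceptance
  expect_gt(acc, 0.1)
  expect_lt(acc, 0.9)
  pvals <- vapply(seq_along(ctrs), function(i) {
    thin <- function(w) angleValues(w)[seq(1, 4000, by = 40)]
    suppressWarnings(ks.test(thin(windows(wsX)[[i]]),
                             thin(windows(ws0)[[i]]))$p.value)
  }, numeric(1))
  # Holm-adjusted: no window rejected at alpha = 0.01
  expect_true(all(p.adjust(pvals, "holm") > 0.01))
})

test_that("widely separated windows essentially never exchange", {
  m <- modelSystem("flat", D0 = 1e-3)
  ws <- runUmbrellaCampaign(m, c(-90, 0, 90), kU = 400,
                            spec = simulationSpec(0.01, 2e4, 10),
                            exchangeEvery = 2, seed = 2)
  expect_lt(windowMetadata(ws)$acceptance, 1e-3)
})

test_that("first-passage oracle matches the free-diffusion closed form", {
  m <- modelSystem("flat", D0 = 1e-3)
  o <- firstPassageOracle(m, 0, 90, nWalkers = 2000, dt = 0.1, seed = 5)
  L <- pi / 2
  expect_lt(abs(o$mean - L^2 / (2 * 1e-3)), 3 * o$se)
  expect_equal(o$censored, 0)
  # starting on the absorbing boundary gives zero
  o0 <- firstPassageOracle(m, 0, 90, nWalkers = 50, dt = 0.1, seed = 5,
                           x0 = 90)
  expect_equal(o0$mean, 0)
  expect_equal(o0$se, 0)
})

test_that("oracle sample means increase with barrier height", {
  means <- vapply(c(1, 2, 3), function(B) {
    m <- modelSystem("double-well", barrier = B, deltaF = -1, D0 = 5e-3)
    firstPassageOracle(m, 30, 225, nWalkers = 400, dt = 0.5,
                       seed = 9)$mean
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("oracle equivalence: double integral within 3 SE across landscapes", {
  cases <- list(
    modelSystem("flat", D0 = 2e-3),
    modelSystem("single-well", barrier = 2, intraMin = 0, D0 = 2e-3),
    modelSystem("double-well", barrier = 2, deltaF = -1, D0 = 2e-3))
  bounds <- list(c(0, 120), c(0, 150), c(30, 225))
  for (i in seq_along(cases)) {
    m <- cases[[i]]
    p <- modelProfile(m, nBins = 1440, gridOrigin = bounds[[i]][1] - 180)
    ctr <- seq(bounds[[i]][1], bounds[[i]][2], length.out = 91)
    dp <- new("DiffusivityProfile", centers = ctr,
              values = modelDiffusivity(m, ctr))
    tau <- mfptForward(p, dp, bounds[[i]][1], bounds[[i]][2], nGrid = 2000)
    o <- firstPassageOracle(m, bounds[[i]][1], bounds[[i]][2],
                            nWalkers = 1500, dt = 0.1, seed = 40 + i)
    expect_lt(abs(tau - o$mean), 3 * o$se + 0.03 * o$mean)
  }
})

test_that("perturbation-series generator hits its analytic limits", {
  # restraint never active -> all dU identically zero
  wide <- restraintSpec(0, 100, 5)
  ps <- makePerturbationSeries(wide, kRef = 3, d0 = 50, D = 0.1,
                               spec = simulationSpec(0.01, 1e4, 10),
                               seed = 2)
  expect_true(all(ps@deltaU == 0))
  # widening the flat bottom sends dF to zero
  sp1 <- restraintSpec(3.5, 4.5, 20)
  sp2 <- restraintSpec(1.0, 7.0, 20)
  d1 <- abs(analyticRestraintDeltaF(sp1, kRef = 2, d0 = 4))
  d2 <- abs(analyticRestraintDeltaF(sp2, kRef = 2, d0 = 4))
  expect_lt(d2, d1)
  expect_lt(d2, 1e-3)
})
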