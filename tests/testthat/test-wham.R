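test_that("one window on a flat landscape unbiases to a flat profile", {
  w <- boltzmannWindow(0, n = 5e4, seed = 2)
  p <- suppressWarnings(wham(windowSet(list(w)), binWidth = 2))
  occ <- occupancy(p) >= 50            # bins with enough mass to compare
  Fv <- profileValues(p)[occ]
  # pointwise standard error of -kT log(n_b) is kT/sqrt(n_b)
  kT <- thermalEnergy(300)
  se <- kT / sqrt(occupancy(p)[occ])
  dev <- Fv - mean(Fv)
  expect_true(all(abs(dev) < 3 * (se + kT * 0.05)))
})

test_that("duplicating every window leaves the profile unchanged", {
  ws <- windowSet(lapply(c(-10, -5, 0, 5), boltzmannWindow, n = 2000))
  p1 <- suppressWarnings(wham(ws, binWidth = 2))
  wsDup <- windowSet(c(windows(ws), lapply(windows(ws), function(w)
    umbrellaWindow(windowCenter(w) + 1e-9, windowSeries(w),
                   forceConstant(w), temperature(w)))),
    period = 360)
  p2 <- suppressWarnings(wham(wsDup, binWidth = 2, gridOrigin = binCenters(p1)[1] - 1))
  expect_equal(profileValues(p2), profileValues(p1), tolerance = 1e-6)
})

test_that("per-window bias offsets are a gauge freedom", {
  ws <- windowSet(lapply(c(-6, -2, 2, 6), boltzmannWindow, n = 3000))
  p1 <- suppressWarnings(wham(ws, tol = 1e-12))
  p2 <- suppressWarnings(wham(ws, tol = 1e-12, biasOffset = c(5, -3, 0.7, 100)))
  occ <- occupancy(p1) > 0
  expect_equal(profileValues(p2)[occ], profileValues(p1)[occ],
               tolerance = 1e-8)
})

test_that("rotating the grid by whole bins cyclically shifts the profile", {
  ws <- windowSet(lapply(seq(-20, 20, by = 4), boltzmannWindow, n = 2000))
  p1 <- suppressWarnings(wham(ws, binWidth = 2))
  p2 <- suppressWarnings(wham(ws, binWidth = 2, gridOrigin = binCenters(p1)[1] - 1 - 5 * 2))
  shift <- 5
  v1 <- profileValues(p1)
  v2 <- profileValues(p2)
  n <- length(v1)
  expect_equal(v2[(seq_len(n) + shift - 1) %% n + 1], v1, tolerance = 1e-9)
})

test_that("a single weak window reduces to direct Boltzmann inversion", {
  set.seed(8)
  # samples from an arbitrary distribution; k_U -> 0 makes the bias inert
  v <- c(rnorm(4000, -20, 12), rnorm(2000, 25, 8))
  w <- umbrellaWindow(0, angleSeries(v, 0.1), forceConstant = 1e-8)
  p <- suppressWarnings(wham(windowSet(list(w)), binWidth = 4))
  kT <- thermalEnergy(300)
  h <- hist(((v - (binCenters(p)[1] - 2)) %% 360) + binCenters(p)[1] - 2,
            breaks = seq(binCenters(p)[1] - 2, binCenters(p)[1] - 2 + 360,
                         by = 4), plot = FALSE)
  direct <- -kT * log(h$counts)
  direct <- direct - min(direct[is.finite(direct)])
  occ <- occupancy(p) > 0
  expect_equal(profileValues(p)[occ], direct[occ], tolerance = 1e-6)
})

test_that("WHAM recovers a known double-well landscape", {
  m <- modelSystem("double-well", D0 = 1e-3)
  ws <- runUmbrellaCampaign(m, spec = simulationSpec(0.01, 5e4, 10),
                            exchangeEvery = 0, seed = 12)
  p <- wham(ws)
  gt <- modelPMF(m, binCenters(p))
  dev <- profileValues(p) - gt
  dev <- dev - mean(dev)
  expect_lt(sqrt(mean(dev^2)), 0.3)
})

test_that("non-convergence raises an error carrying the residual", {
  ws <- windowSet(lapply(c(-10, 0, 10), boltzmannWindow, n = 1000))
  expect_error(wham(ws, maxIter = 2), "did not converge")
})

test_that("state free-energy differences follow the Boltzmann integrals", {
  # symmetric double well, symmetric regions -> 0
  bc <- seq(-179, 179, by = 2)
  vals <- 2 * (1 + cos(2 * bc * pi / 180)) / 2
  sym <- new("FreeEnergyProfile", binCenters = bc, values = vals - min(vals),
             occupancy = rep(1, 180), period = 360, temperature = 300)
  expect_equal(stateDeltaF(sym, c(45, 135), c(-135, -45)), 0,
               tolerance = 1e-12)
  # constant profiles: F = 0 on A, c on B -> exactly c
  step <- ifelse(bc > 0, 1.5, 0)
  pr <- new("FreeEnergyProfile", binCenters = bc, values = step,
            occupancy = rep(1, 180), period = 360, temperature = 300)
  expect_equal(stateDeltaF(pr, c(-170, -10), c(10, 170)), 1.5,
               tolerance = 1e-12)
  # antisymmetry is exact
  expect_equal(stateDeltaF(pr, c(-170, -10), c(10, 170)),
               -stateDeltaF(pr, c(10, 170), c(-170, -10)))
})

test_that("state dF matches adaptive quadrature on a smooth landscape", {
  m <- modelSystem("double-well", D0 = 1e-3)
  p <- modelProfile(m, nBins = 3600)
  kT <- thermalEnergy(300)
  Ffun <- function(x) modelPMF(m, x) - min(profileValues(p))
  bolt <- function(lo, hi) integrate(function(x) exp(-Ffun(x) / kT), lo, hi,
                                     rel.tol = 1e-10)$value
  # intra basin (-42, 121), extra basin (121, 318) on an unwrapped branch
  ref <- -kT * log(bolt(121, 318) / bolt(-42, 121))
  est <- stateDeltaF(p, c(-42, 121), c(121, -42))
  expect_equal(est, ref, tolerance = 1e-3)
})

test_that("extrema location handles cosine, flat and double-well profiles", {
  bc <- seq(-179, 179, by = 2)
  mk <- function(v) new("FreeEnergyProfile", binCenters = bc,
                        values = v - min(v), occupancy = rep(1, 180),
                        period = 360, temperature = 300)
  # single-well cosine: one minimum at 40 within one bin
  single <- mk(2 * (1 - cos((bc - 40) * pi / 180)))
  ex <- locateExtrema(single)
  expect_equal(sum(ex$kind == "min"), 1)
  expect_lt(abs(ex$position[ex$kind == "min"] - 40), 2)

  # flat: no extrema
  expect_equal(nrow(locateExtrema(mk(rep(1, 180)))), 0)

  # calibrated double well: two minima within one bin of ground truth
  m <- modelSystem("double-well", D0 = 1e-3)
  p <- modelProfile(m, nBins = 180, gridOrigin = -321)
  ex2 <- locateExtrema(p)
  mins <- sort(wrapAngle(ex2$position[ex2$kind == "min"]))
  expect_equal(length(mins), 2)
  expect_lt(abs(mins[1] + 135), 2)
  expect_lt(abs(mins[2] - 30), 2)
  b <- barrierHeight(p, 30, -135)
  expect_lt(abs(b$height - (3.5 + 2)), 0.1)   # from the lower (extra) minimum
  expect_error(locateExtrema(mk(rep(1, 180)), smoothingWindow = 2), "odd")
})

test_that("segment RMSD is gauge-invariant and zero for identical input", {
  bc <- seq(-179, 179, by = 2)
  v <- abs(sin(bc * pi / 120))
  mk <- function(vals) new("FreeEnergyProfile", binCenters = bc,
                           values = vals - min(vals),
                           occupancy = rep(1, 180), period = 360,
                           temperature = 300)
  p <- mk(v)
  expect_equal(convergenceRMSD(list(p, p))[1, 2], 0)
  # profiles differing by a constant also give 0 after re-referencing
  expect_equal(convergenceRMSD(list(p, mk(v + 2)))[1, 2], 0,
               tolerance = 1e-12)
  # two half-data WHAM runs agree closely at default synthetic sampling
  m <- modelSystem("double-well", D0 = 1e-3)
  ws <- runUmbrellaCampaign(m, spec = simulationSpec(0.01, 4e4, 10),
                            exchangeEvery = 0, seed = 4)
  halves <- splitSegments(ws, 2)
  g0 <- min(centers(ws)) - 1
  ps <- lapply(halves, wham, gridOrigin = g0)
  expect_lt(convergenceRMSD(ps)[1, 2], 0.5)
})
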