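test_that("autocorrelation is the biased normalized autocovariance", {
  set.seed(9)
  x <- rnorm(1e5)
  C <- autocorrelation(x, 20)
  expect_equal(C[1], 1)
  expect_true(all(abs(C[-1]) < 3 / sqrt(1e5)))

  # AR(1): C(t) ~ phi^t
  phi <- 0.8
  ar <- as.numeric(stats::arima.sim(list(ar = phi), n = 2e5))
  Car <- autocorrelation(ar, 10)
  expect_equal(Car, phi^(0:10), tolerance = 0.03)

  # sinusoid plus constant: cosine decay
  t <- seq_len(5e4)
  s <- 3 + sin(2 * pi * t / 50)
  Cs <- autocorrelation(s, 100)
  expect_equal(Cs, cos(2 * pi * (0:100) / 50), tolerance = 0.01)

  expect_error(autocorrelation(rep(1, 100), 10), "zero variance")
})

test_that("correlation-time fits recover single and double exponentials", {
  C1 <- exp(-(0:100) * 0.1 / 5)
  est1 <- fitCorrelationTime(C1, 0.1)
  expect_equal(tauInt(est1), 5, tolerance = 1e-6)

  C2 <- 0.5 * exp(-(0:300) * 0.1 / 2) + 0.5 * exp(-(0:300) * 0.1 / 20)
  est2 <- fitCorrelationTime(C2, 0.1)
  expect_equal(tauInt(est2), 11, tolerance = 1e-4)
  expect_true(est2@fitted)

  # block-averaging diagnostic attaches when the series is supplied
  set.seed(2)
  ar <- as.numeric(stats::arima.sim(list(ar = 0.9), n = 2e4))
  est3 <- fitCorrelationTime(autocorrelation(ar, 200), 1, series = ar)
  expect_gt(nrow(est3@blockSE), 3)
  # plateau of the block SE agrees with sqrt(2 tau_int / T) * sd within 30%
  plateau <- tail(est3@blockSE$se, 2)[1]
  pred <- sd(ar) * sqrt(2 * tauInt(est3) / 2e4)
  expect_lt(abs(plateau / pred - 1), 0.3)
})

test_that("window diffusivity recovers an OU process within 10%", {
  m <- modelSystem("flat", D0 = 1e-3)
  s <- langevinTrajectory(m, simulationSpec(0.01, 1e6, 10), seed = 3,
                          biasCenter = 0, biasK = 400)
  w <- umbrellaWindow(0, s)
  ld <- localDiffusivity(w, maxLag = 400)
  expect_rel(ld$D, 1e-3, 0.1)
  # tau_int agrees with the analytic OU relaxation time var/D
  expect_rel(ld$tauInt, ld$variance / 1e-3, 0.1)

  # doubling the sampling interval leaves D unchanged within tolerance
  v <- angleValues(s)
  w2 <- umbrellaWindow(0, angleSeries(v[seq(1, length(v), by = 2)],
                                      samplingInterval(s) * 2))
  expect_rel(localDiffusivity(w2, maxLag = 200)$D, ld$D, 0.1)

  # scaling angles by c scales D by c^2 (units covariance)
  w3 <- umbrellaWindow(0, angleSeries(3 * v, samplingInterval(s)))
  expect_rel(localDiffusivity(w3, maxLag = 400)$D, 9 * ld$D, 1e-6)
})

test_that("flat-potential MFPT reproduces L^2/(2D) to quadrature accuracy", {
  bc <- seq(-179, 179, by = 2)
  flat <- new("FreeEnergyProfile", binCenters = bc, values = rep(0, 180),
              occupancy = rep(1, 180), period = 360, temperature = 300)
  D <- 2e-3
  L <- 120 * pi / 180
  tau <- mfptForward(flat, D, 0, 120, nGrid = 1000)
  expect_rel(tau, L^2 / (2 * D), 1e-3)
  # backward with exchanged roles gives the same on a symmetric landscape
  expect_equal(mfptBackward(flat, D, absorbAt = 0, reflectAt = 120), tau)
})

test_that("MFPT is exactly linear in 1/D and monotone in barrier height", {
  m <- modelSystem("double-well", D0 = 1e-3)
  p <- modelProfile(m, nBins = 720)
  dp <- new("DiffusivityProfile", centers = seq(-340, 20, by = 20),
            values = exp(rnorm(19, log(1e-3), 0.5)))
  t1 <- mfptForward(p, dp, 30, 225)
  dp2 <- new("DiffusivityProfile", centers = centers(dp),
             values = 2 * diffusivities(dp))
  expect_equal(mfptForward(p, dp2, 30, 225), t1 / 2, tolerance = 1e-12)

  taus <- vapply(c(2, 3, 4, 5, 6), function(B) {
    mB <- modelSystem("double-well", barrier = B, D0 = 1e-3)
    mfptForward(modelProfile(mB, nBins = 720), 1e-3, 30, 225)
  }, numeric(1))
  expect_true(all(diff(taus) > 0))
})

test_that("undefined bins and non-positive D are rejected", {
  bc <- seq(-179, 179, by = 2)
  v <- rep(0, 180); v[90] <- NA
  p <- new("FreeEnergyProfile", binCenters = bc, values = v,
           occupancy = c(rep(1, 89), 0, rep(1, 90)), period = 360,
           temperature = 300)
  expect_error(mfptForward(p, 1e-3, -50, 50), "undefined")
  flat <- new("FreeEnergyProfile", binCenters = bc, values = rep(0, 180),
              occupancy = rep(1, 180), period = 360, temperature = 300)
  expect_error(mfptForward(flat, -1, 0, 90), "non-positive")
})

test_that("equilibrium constants: kinetic matches thermodynamic", {
  # symmetric system: both are exactly 1
  bc <- seq(-179.5, 179.5, by = 1)
  vals <- 3 * (1 + cos(2 * bc * pi / 180)) / 2
  sym <- new("FreeEnergyProfile", binCenters = bc, values = vals - min(vals),
             occupancy = rep(1, 360), period = 360, temperature = 300)
  tf <- mfptForward(sym, 1e-3, -90, 90)
  tb <- mfptBackward(sym, 1e-3, absorbAt = -90, reflectAt = 90)
  eq <- equilibriumCheck(tf, tb, sym, c(-180, 0), c(0, 180))
  expect_equal(eq$Kkin, 1, tolerance = 1e-10)
  expect_equal(eq$Kthermo, 1, tolerance = 1e-10)

  # equally deep two-state system with asymmetric D: the equilibrium
  # constant stays ~1 because D drops out of the ratio in the deep-well limit
  m0 <- modelSystem("double-well", barrier = 6, deltaF = 0, D0 = 1e-3)
  p0 <- modelProfile(m0, nBins = 1440)
  dp <- new("DiffusivityProfile", centers = seq(-340, 20, by = 20),
            values = exp(seq(log(1e-4), log(1e-3), length.out = 19)))
  tf2 <- mfptForward(p0, dp, 30, 225)
  tb2 <- mfptBackward(p0, dp, absorbAt = 30, reflectAt = 225)
  expect_lt(abs(log(tb2 / tf2)), 0.1)
})

test_that("constant-D variant reports the roughness slowdown", {
  bc <- seq(-179.5, 179.5, by = 1)
  flat <- new("FreeEnergyProfile", binCenters = bc, values = rep(0, 360),
              occupancy = rep(1, 360), period = 360, temperature = 300)
  # already-constant D: ratio exactly 1
  dpc <- new("DiffusivityProfile", centers = seq(-170, 170, by = 20),
             values = rep(1e-3, 18))
  cv <- constantDiffusivityVariant(flat, dpc, 0, 120)
  expect_equal(cv$ratioForward, 1, tolerance = 1e-12)

  # alternating d, 2d: local-D passage slower than with the arithmetic mean
  dpa <- new("DiffusivityProfile", centers = seq(-175, 175, by = 10),
             values = rep(c(1e-3, 2e-3), 18))
  cva <- constantDiffusivityVariant(flat, dpa, 0, 120)
  expect_gt(cva$ratioForward, 1)

  # at one-order-of-magnitude D roughness the smooth-D speedup stays below 5
  m <- modelSystem("double-well", dLogAmp = log(10) / 2)
  p <- modelProfile(m, nBins = 1440)
  ctr <- seq(-320, 38, by = 2)
  dp <- new("DiffusivityProfile", centers = ctr,
            values = modelDiffusivity(m, ctr))
  cvr <- constantDiffusivityVariant(p, dp, 30, 225)
  expect_gt(cvr$ratioForward, 1)
  expect_lt(cvr$ratioForward, 5)
})

test_that("kinetics reports are written and read back", {
  m <- modelSystem("double-well", D0 = 1e-3)
  p <- modelProfile(m, nBins = 360)
  rep1 <- kineticsReport(p, 1e-3, 30, 225, c(-42, 121), c(121, -42),
                         label = "double-well")
  expect_s4_class(rep1, "KineticsReport")
  expect_gt(rep1@Keq, 1)           # extra state lower -> tau- > tau+
  f <- withr::local_tempfile(fileext = ".txt")
  writeKineticsReport(rep1, f)
  lines <- readLines(f)
  expect_true(any(grepl("tau_forward_s", lines)))
  expect_equal(as.numeric(sub(".* ", "", lines[grepl("tau_forward_s", lines)])),
               rep1@tauForward, tolerance = 1e-9)
})

test_that("published MFPT tables read back in seconds and microseconds", {
  tab <- readMFPTTable(system.file("extdata", "mfpt_table.txt",
                                   package = "flipkinetics"))
  expect_equal(nrow(tab), 6)
  expect_equal(tab$tauForwardUs[tab$system == "CPD_prot"], 120)
  expect_equal(tab$tauForwardUs[tab$system == "TT_prot"], 3900)
})
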