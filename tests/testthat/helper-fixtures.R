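# shared fixtures, all generated in code

# one fixed-width ATOM record (PDB columns)
pdbLine <- function(serial, name, resname, chain, resno, x, y, z,
                    element = "") {
  sprintf("ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name, resname, chain, resno, x, y, z, element)
}

# a two-residue DNA-like fragment with hydrogens
tinyPDB <- function() {
  c(pdbLine(1, "P",   "DT", "A", 1, 0.0, 0.0, 0.0, "P"),
    pdbLine(2, "C1'", "DT", "A", 1, 1.0, 2.0, 3.0, "C"),
    pdbLine(3, "O5'", "DT", "A", 1, 1.0, 0.0, 0.0, "O"),
    pdbLine(4, "H5'", "DT", "A", 1, 1.5, 0.5, 0.0, "H"),
    pdbLine(5, "N1",  "DA", "A", 2, 2.0, 2.0, 2.0, "N"),
    pdbLine(6, "C2",  "DA", "A", 2, 3.0, 2.0, 2.0),
    pdbLine(7, "H2",  "DA", "A", 2, 3.5, 2.5, 2.0, "H"))
}

# random rigid transform (rotation + translation) applied to 3-vectors
rigidTransform <- function(points, seed) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  tr <- rnorm(3, sd = 10)
  lapply(points, function(p) as.numeric(R %*% p + tr))
}

# an umbrella window with i.i.d. samples from the exact bias Boltzmann
# distribution (flat underlying landscape)
boltzmannWindow <- function(center, kU = 400, temperature = 300, n = 2e4,
                            dt = 0.1, seed = 1) {
  set.seed(seed)
  sdDeg <- sqrt(thermalEnergy(temperature) / kU) * 180 / pi
  umbrellaWindow(center, angleSeries(rnorm(n, center, sdDeg), dt),
                 forceConstant = kU, temperature = temperature)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}

.deg2radTest <- function(x) x * pi / 180
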