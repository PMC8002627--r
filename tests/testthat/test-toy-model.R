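# Toy torsional model: energies, embedding, oracle, frequencies, crossing.

test_that("torsional potential terms evaluate as specified", {
  m <- toy_torsion_model(1, data.frame(amplitude = 1, multiplicity = 2,
                                       phase = 0))
  expect_equal(toy_energy(m, 0), 0)
  expect_equal(toy_energy(m, pi / 2), 2)
  expect_equal(toy_energy(m, pi), 0, tolerance = 1e-12)
  expect_error(toy_energy(m, c(0, 0)), "expected 1")
})

test_that("the ellipsoid wall is zero inside and at the boundary", {
  host <- list(semiaxes = c(4, 4, 4), wall_k = 10, wall_exp = 2)
  m <- toy_torsion_model(1, data.frame(amplitude = 1, multiplicity = 2,
                                       phase = 0), host = host)
  e0 <- toy_energy(m, 0)                                # centroid near origin
  m_free <- toy_torsion_model(1, data.frame(amplitude = 1, multiplicity = 2,
                                            phase = 0))
  expect_equal(e0, toy_energy(m_free, 0))               # inside: no wall term
  # push the centroid onto the surface: still zero (boundary), beyond: grows
  cen <- colMeans(embed_torsions(m_free, 0)$coords)
  to_surface <- c(4 - cen[1], -cen[2], -cen[3])         # q = 1 exactly
  expect_equal(toy_energy(m, 0, position = to_surface),
               toy_energy(m_free, 0), tolerance = 1e-10)
  expect_gt(toy_energy(m, 0, position = to_surface + c(2, 0, 0)),
            toy_energy(m_free, 0) + 1)
})

test_that("nearest-neighbor coupling penalizes unequal torsions", {
  m <- toy_torsion_model(2, data.frame(amplitude = 0.0001, multiplicity = 3,
                                       phase = 0), coupling = 2)
  expect_lt(toy_energy(m, c(1, 1)), toy_energy(m, c(1, 1 + pi)))
  expect_equal(toy_energy(m, c(0.7, 0.7)) - toy_energy(m, c(0, 0)),
               0, tolerance = 1e-3)
})

test_that("embedding and dihedral measurement are mutually inverse", {
  withr::local_seed(71)
  m <- toy_torsion_model(4)
  for (i in 1:10) {
    phi <- stats::runif(4, -pi, pi)
    s <- embed_torsions(m, phi)
    expect_equal(measure_torsions(s), phi, tolerance = 1e-8)
  }
  # canonical placement: first atom at the origin
  expect_equal(embed_torsions(m, rep(0, 4))$coords[1, ], c(0, 0, 0))
})

test_that("all-trans chain maximizes the end-to-end distance", {
  m <- toy_torsion_model(5)
  e2e <- function(phi) {
    X <- embed_torsions(m, phi)$coords
    sqrt(sum((X[nrow(X), ] - X[1, ])^2))
  }
  d_trans <- e2e(rep(pi, 5))
  withr::local_seed(72)
  for (i in 1:20) expect_lte(e2e(stats::runif(5, -pi, pi)), d_trans + 1e-9)
})

test_that("brute-force oracle finds symmetric double-well minima", {
  m <- toy_torsion_model(1, data.frame(amplitude = 1, multiplicity = 2,
                                       phase = 0))
  o <- brute_force_reference(m, 72)
  expect_equal(nrow(o$minima), 2L)
  expect_equal(sort(o$minima[, 1]), c(0, pi), tolerance = 2 * pi / 72)
  expect_equal(o$populations, c(0.5, 0.5), tolerance = 1e-12)
  expect_error(brute_force_reference(m, 12), "at least 36")
})

test_that("asymmetric wells reproduce the two-state Boltzmann ratio", {
  # V = (1 - cos 2phi) + 0.3 (1 - cos phi): minima near 0 and pi, the
  # pi well deeper is FALSE -- the 0 well is deeper here
  terms <- rbind(data.frame(amplitude = 1, multiplicity = 2, phase = 0),
                 data.frame(amplitude = 0.3, multiplicity = 1, phase = 0))
  m <- toy_torsion_model(1, terms)
  o <- brute_force_reference(m, 360, T = 298.15)
  expect_equal(nrow(o$minima), 2L)
  # grid-basin populations vs direct numerical integration of the
  # Boltzmann density split at the barrier tops (independent quadrature)
  RT <- phys_constants()$R_kcal * 298.15
  dens <- function(p) exp(-toy_energy(m, p) / RT)
  # barrier tops where V'(phi) = 0 between the wells
  z1 <- stats::integrate(Vectorize(dens), -pi / 2, pi / 2)$value
  z2 <- stats::integrate(Vectorize(dens), pi / 2, 3 * pi / 2)$value
  expect_equal(o$populations[1], z1 / (z1 + z2), tolerance = 0.01)
})

test_that("grid refinement changes oracle populations by under 1%", {
  terms <- rbind(data.frame(amplitude = 1, multiplicity = 2, phase = 0),
                 data.frame(amplitude = 0.3, multiplicity = 1, phase = 0))
  m <- toy_torsion_model(1, terms)
  p36 <- brute_force_reference(m, 36)$populations
  p360 <- brute_force_reference(m, 360)$populations
  expect_equal(p36, p360, tolerance = 0.01)
})

test_that("numerical frequencies match the harmonic closed form", {
  # V = A (1 - cos phi) has curvature A at the minimum: omega = sqrt(A/I)
  A <- 4
  m <- toy_torsion_model(1, data.frame(amplitude = A, multiplicity = 1,
                                       phase = 0))
  nu <- numerical_frequencies(m, 0)
  I <- torsion_inertia(m, 0)
  k <- phys_constants()
  conv <- k$cal_J * 1e3 / (k$amu_kg * k$NA_SI * 1e-20)
  nu_ref <- sqrt(A / I * conv) / (2 * pi * k$c_cm)
  expect_equal(nu, nu_ref, tolerance = 1e-3)
  # step halving: converged to well under 0.1%
  nu2 <- numerical_frequencies(m, 0, step = 5e-4)
  expect_equal(nu, nu2, tolerance = 1e-3)
})

test_that("frequencies at a maximum are flagged as imaginary", {
  m <- toy_torsion_model(1, data.frame(amplitude = 2, multiplicity = 2,
                                       phase = 0))
  expect_error(numerical_frequencies(m, pi / 2), "imaginary")
  expect_error(numerical_frequencies(m, 0.3), "not a stationary point")
})

test_that("torsion inertia matches the axis-distance closed form", {
  # I_j = sum over rotated atoms of m_a * (distance to the torsion axis)^2
  m <- toy_torsion_model(1)
  phi <- 0.9
  X <- embed_torsions(m, phi)$coords
  axis_a <- X[2, ]; axis_b <- X[3, ]
  u <- (axis_b - axis_a) / sqrt(sum((axis_b - axis_a)^2))
  v <- X[4, ] - axis_a
  d2 <- sum(v^2) - sum(v * u)^2
  expect_equal(torsion_inertia(m, phi), m$masses[4] * d2, tolerance = 1e-6)
})

test_that("genetic crossing enumerates proper torsion exchanges", {
  ch <- genetic_cross(c(0, 0), c(pi, pi))
  expect_equal(nrow(ch), 2L)
  expect_true(any(apply(ch, 1, function(x) all(x == c(0, pi)))))
  expect_true(any(apply(ch, 1, function(x) all(x == c(pi, 0)))))
  # identical parents produce no new children
  expect_equal(nrow(genetic_cross(c(1, 2, 3), c(1, 2, 3))), 0L)
  # child count bound 2^n - 2
  ch3 <- genetic_cross(c(0, 0, 0), c(1, 2, 3))
  expect_lte(nrow(ch3), 2^3 - 2)
  expect_equal(nrow(ch3), 6L)
  expect_error(genetic_cross(c(0, 0), c(1, 2, 3)), "differ")
})
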