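# Metadynamics bias, Monte-Carlo sampling, determinism, equilibrium checks.

double_well_model <- function(barrier = 2.4, asym = 0) {
  terms <- data.frame(amplitude = barrier / 2, multiplicity = 2, phase = 0)
  if (asym != 0)
    terms <- rbind(terms,
                   data.frame(amplitude = asym, multiplicity = 1, phase = 0))
  toy_torsion_model(2, torsion_terms = terms, seed = 1)
}

test_that("mtd_bias evaluates the Gaussian hill sum", {
  m <- double_well_model()
  s0 <- embed_torsions(m, c(0, 0))
  expect_equal(mtd_bias(s0, list(s0), k_push = 1, alpha = 1), 1)
  expect_equal(mtd_bias(s0, list(), k_push = 1, alpha = 1), 0)
  expect_equal(mtd_bias(s0, list(s0, s0), k_push = 0.5, alpha = 1), 1)
  far <- embed_torsions(m, c(pi, pi))
  expect_lt(mtd_bias(s0, list(far), k_push = 1, alpha = 5),
            mtd_bias(s0, list(s0), k_push = 1, alpha = 5))
  # decays towards zero with distance
  expect_lt(mtd_bias(s0, list(far), k_push = 1, alpha = 50), 1e-6)
})

test_that("mtd parameter units convert as documented", {
  p <- mtd_params(k_push = 1, k_unit = "mEh", alpha = 1,
                  alpha_unit = "bohr")
  expect_equal(p$k_push, 0.6275095, tolerance = 1e-7)
  expect_equal(p$alpha, 1 / 0.529177210903^2, tolerance = 1e-9)
  q <- mtd_params(k_push = 2, k_unit = "kcal/mol", alpha = 3,
                  alpha_unit = "ang")
  expect_equal(q$k_push, 2)
  expect_equal(q$alpha, 3)
  expect_error(mtd_params(k_push = -1), ">= 0")
  expect_error(mtd_params(steps = 0), "zero steps")
})

test_that("sampling is seed-deterministic and leaves the caller's RNG alone", {
  m <- double_well_model()
  set.seed(999)
  before <- stats::runif(1)
  set.seed(999)
  e1 <- run_mtd(m, mtd_params(steps = 300, seed = 5))
  after <- stats::runif(1)
  expect_equal(before, after)        # engine did not consume caller's stream
  e2 <- run_mtd(m, mtd_params(steps = 300, seed = 5))
  expect_identical(attr(e1, "torsions"), attr(e2, "torsions"))
  expect_equal(ensemble_energies(e1), ensemble_energies(e2))
})

test_that("zero pushing strength reduces exactly to unbiased sampling", {
  m <- double_well_model()
  eb <- run_mtd(m, mtd_params(k_push = 0, k_unit = "kcal/mol", steps = 400,
                              seed = 9))
  eu <- run_unbiased(m, T = 300, steps = 400, seed = 9)
  expect_identical(attr(eb, "torsions"), attr(eu, "torsions"))
  expect_equal(ensemble_energies(eb), ensemble_energies(eu))
})

test_that("recorded snapshot energies never include the bias", {
  m <- double_well_model()
  ens <- run_mtd(m, mtd_params(steps = 400, seed = 13, deposit_every = 20))
  tor <- attr(ens, "torsions")
  for (i in seq_len(nrow(tor)))
    expect_equal(ens$structures[[i]]$energy, toy_energy(m, tor[i, ]),
                 tolerance = 1e-12)
})

test_that("long unbiased runs reproduce the Boltzmann torsion density", {
  m1 <- toy_torsion_model(1, data.frame(amplitude = 2, multiplicity = 1,
                                        phase = pi))
  ens <- run_unbiased(m1, T = 300, steps = 20000, seed = 3,
                      proposal_sd = 0.8, record_every = 3)
  tor <- attr(ens, "torsions")[, 1]
  breaks <- seq(-pi, pi, length.out = 25)
  h <- hist(tor, breaks = breaks, plot = FALSE)
  RT <- phys_constants()$R_kcal * 300
  dens <- vapply(h$mids, function(p) exp(-toy_energy(m1, p) / RT),
                 numeric(1))
  expect_equal(h$counts / sum(h$counts), dens / sum(dens), tolerance = 0.05)
})

test_that("quenching sends every snapshot to a basin minimum", {
  m <- double_well_model()
  o <- brute_force_reference(m, 36, T = 300)
  ens <- run_unbiased(m, T = 300, steps = 600, seed = 17)
  q <- quench_ensemble(m, ens)
  tor <- attr(q, "torsions")
  for (i in seq_len(nrow(tor))) {
    d <- apply(o$minima, 1, function(mm)
      sqrt(sum((atan2(sin(tor[i, ] - mm), cos(tor[i, ] - mm)))^2)))
    expect_lt(min(d), 0.2)           # lands on an oracle minimum
  }
  # quenched energies at (or below) the sampled ones
  expect_true(all(ensemble_energies(q) <= ensemble_energies(ens) + 1e-9))
})

test_that("host-confined sampling keeps the centroid near the ellipsoid", {
  host <- list(semiaxes = c(3, 3, 3), wall_k = 25, wall_exp = 4)
  m <- toy_torsion_model(2, host = host, seed = 2)
  ens <- run_mtd(m, mtd_params(steps = 500, seed = 4))
  cen <- t(vapply(ens$structures, function(s) colMeans(s$coords),
                  numeric(3)))
  q <- rowSums(sweep(cen, 2, host$semiaxes, `/`)^2)
  expect_lt(stats::quantile(q, 0.95), 2.5)  # wall keeps excursions bounded
})

test_that("crossing children beyond the window are pruned by the CRE", {
  # genetic children of two low conformers can land in high-energy basins;
  # the standard window machinery removes them
  m <- double_well_model(barrier = 2, asym = 4)
  parents <- list(c(0, 0), c(pi, pi))
  kids <- genetic_cross(parents[[1]], parents[[2]])
  structs <- lapply(c(parents, split(kids, seq_len(nrow(kids)))),
                    function(phi) embed_torsions(m, as.numeric(phi)))
  ens <- conformer_ensemble(structs)
  win <- 6
  cre <- assemble_cre(ens, cre_thresholds(window = win))
  emin <- min(ensemble_energies(ens))
  expect_true(all(cre_energies(cre) <= emin + win))
  expect_true(any(ensemble_energies(ens) > emin + win))  # something to prune
})
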