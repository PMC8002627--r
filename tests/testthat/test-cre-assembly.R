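# Duplicate/rotamer/conformer classification and CRE assembly.

# scalene 4-atom arrangement whose atom-permuted copy is the classic
# rotamer case: identical point set (same energy, same rotational
# constants) but large index-wise RMSD
scalene <- function(energy = 0) {
  xyz_structure(rep("C", 4),
                rbind(c(0, 0, 0), c(3, 0, 0), c(0.5, 2, 0), c(-1, -1, 1)),
                energy)
}
scalene_permuted <- function(energy = 0) {
  s <- scalene(energy)
  xyz_structure(s$symbols, s$coords[c(2, 1, 3, 4), ], energy)
}

test_that("classify_pair implements the CRE criteria", {
  th <- cre_thresholds()
  a <- scalene()
  expect_identical(classify_pair(a, a, th), "duplicate")
  expect_identical(classify_pair(a, rigid_move(a), th), "duplicate")
  # same energy + same rotational constants + large RMSD -> rotamer
  b <- scalene_permuted()
  expect_gt(kabsch_rmsd(a, b), th$rmsd_thresh)
  expect_identical(classify_pair(a, b, th), "rotamer")
  # energy criterion alone forces conformer
  expect_identical(classify_pair(a, scalene(energy = 1.0), th), "conformer")
  # different shape at similar energy -> conformer
  cc <- xyz_structure(rep("C", 4),
                      rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0.2, 0),
                            c(4.5, 0, 0.2)), 0.01)
  expect_identical(classify_pair(a, cc, th), "conformer")
  expect_error(classify_pair(a, random_structure(5), th), "differ")
})

test_that("assemble_cre groups duplicates, rotamers, and conformers", {
  s <- scalene()
  # three copies of one structure collapse to one group, one member
  cre <- assemble_cre(conformer_ensemble(list(s, rigid_move(s),
                                              rigid_move(s))))
  expect_length(cre$groups, 1L)
  expect_length(cre$groups[[1]]$rotamers, 0L)
  expect_equal(cre$groups[[1]]$occupancy, 3L)
  expect_equal(nrow(cre$drop_log), 2L)

  # constructed 4-frame ensemble: {A, A rotamer image +0.01, B at +2, A dup}
  b <- xyz_structure(rep("C", 4),
                     rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0.2, 0),
                           c(4.5, 0, 0.2)), 2)
  ens <- conformer_ensemble(list(s, scalene_permuted(0.01), b,
                                 rigid_move(scalene(0.001))))
  cre <- assemble_cre(ens)
  expect_length(cre$groups, 2L)
  expect_length(cre$groups[[1]]$rotamers, 1L)
  expect_equal(cre_energies(cre), c(0, 2))
})

test_that("global minimum is always group 1's representative", {
  withr::local_seed(31)
  for (i in 1:5) {
    ens <- random_ensemble(n_frames = 8)
    cre <- assemble_cre(ens, cre_thresholds(window = Inf))
    expect_equal(cre$groups[[1]]$representative$energy,
                 min(ensemble_energies(ens)))
    expect_equal(cre_energies(cre), sort(cre_energies(cre)))
  }
})

test_that("prune_window keeps groups inside the window", {
  structs <- lapply(c(0, 3, 7), function(e) random_structure(5,
    symbols = c("C", "C", "N", "O", "O"), energy = e, spread = 3 + e))
  cre <- assemble_cre(conformer_ensemble(structs), apply_window = FALSE)
  expect_length(prune_window(cre, 6)$groups, 2L)
  expect_length(prune_window(cre, Inf)$groups, 3L)
  expect_length(prune_window(cre, 100)$groups, 3L)
})

test_that("count conservation: retained + dropped equals input size", {
  withr::local_seed(32)
  for (i in 1:5) {
    ens <- random_ensemble(n_frames = 10)
    cre <- assemble_cre(ens, cre_thresholds(window = 2))
    retained <- length(cre$groups) +
      sum(vapply(cre$groups, function(g) length(g$rotamers), integer(1)))
    expect_equal(retained + nrow(cre$drop_log), length(ens))
  }
})

test_that("assembly is idempotent and order-robust", {
  withr::local_seed(33)
  for (i in 1:4) {
    ens <- random_ensemble(n_frames = 9)
    cre1 <- assemble_cre(ens)
    cre2 <- assemble_cre(cre_flatten(cre1))
    expect_equal(cre_energies(cre2), cre_energies(cre1), tolerance = 1e-12)
    shuffled <- conformer_ensemble(sample(ens$structures))
    cre3 <- assemble_cre(shuffled)
    expect_equal(sort(cre_energies(cre3)), sort(cre_energies(cre1)),
                 tolerance = 0.1)  # representatives may swap within e_thresh
  }
})

test_that("shrinking the window never increases retained structures", {
  withr::local_seed(34)
  ens <- random_ensemble(n_frames = 12)
  count <- function(w) {
    cre <- assemble_cre(ens, cre_thresholds(window = w))
    length(cre$groups) +
      sum(vapply(cre$groups, function(g) length(g$rotamers), integer(1)))
  }
  counts <- vapply(c(Inf, 6, 3, 1.5, 0.5), count, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("staged refinement applies successively tighter windows", {
  structs <- lapply(c(0, 4, 8, 12, 20), function(e) random_structure(
    5, symbols = rep("C", 5), energy = e, spread = 2 + e))
  ens <- conformer_ensemble(structs)
  res <- staged_refine(ens, windows = c(15, 10, 6))
  expect_equal(res$stage_counts, c(4, 3, 2))
  expect_error(staged_refine(ens, windows = c(6, 10)), "decreasing")
  # single structure always survives every stage
  one <- conformer_ensemble(structs[1])
  expect_equal(staged_refine(one)$stage_counts, c(1, 1, 1))
  # final stage equals direct assembly at the last window
  direct <- assemble_cre(ens, cre_thresholds(window = 6))
  expect_equal(cre_energies(res$cre), cre_energies(direct))
})

test_that("staged refinement equals single-pass assembly on random input", {
  withr::local_seed(35)
  for (i in 1:4) {
    ens <- random_ensemble(n_frames = 10)
    res <- staged_refine(ens, windows = c(4, 2, 1))
    direct <- assemble_cre(ens, cre_thresholds(window = 1))
    expect_equal(cre_energies(res$cre), cre_energies(direct),
                 tolerance = 1e-12)
  }
})

test_that("thresholds validate and empty ensembles are rejected", {
  expect_error(cre_thresholds(e_thresh = -1), "positive")
  expect_error(assemble_cre(list()), "conformer_ensemble")
})
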