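## RMSD-biased metadynamics and unbiased Monte-Carlo sampling on the toy
## torsional surface. Sampling is Metropolis MC in torsion space: the
## Gaussian RMSD bias needs only energies, and validation targets are
## distributional, not dynamical.

#' Metadynamics sampling parameters
#'
#' Parameters of the history-dependent RMSD bias
#' `V_bias = sum_i k_i exp(-alpha * Delta_i^2)` (with `Delta_i` the
#' Kabsch RMSD to reference structure `i`) and of the Metropolis walk.
#' Pushing strengths may be given in the millihartree convention of
#' tight-binding metadynamics (`k_unit = "mEh"`) or directly in kcal/mol;
#' `alpha` may be given per Angstrom^2 or in the Bohr-based convention
#' (`alpha_unit = "bohr"`, converted as a per-length-squared quantity).
#'
#' @param k_push Pushing strength per deposited reference (>= 0).
#' @param alpha Bias width parameter (> 0).
#' @param k_unit `"kcal/mol"` or `"mEh"`.
#' @param alpha_unit `"ang"` (per Angstrom^2) or `"bohr"`.
#' @param deposit_every Steps between bias depositions.
#' @param max_refs Maximum number of reference structures kept.
#' @param steps Number of MC steps (> 0).
#' @param T Sampling temperature, K.
#' @param proposal_sd Torsion proposal standard deviation, rad.
#' @param record_every Steps between recorded snapshots.
#' @param seed Integer seed; the full trajectory is reproducible from it.
#' @return A list of class `mtd_params` with `k_push`/`alpha` converted to
#'   kcal/mol and per-Angstrom^2.
#' @export
mtd_params <- function(k_push = 1.5, alpha = 0.8,
                       k_unit = c("mEh", "kcal/mol"),
                       alpha_unit = c("bohr", "ang"),
                       deposit_every = 50, max_refs = 50,
                       steps = 5000, T = 300, proposal_sd = 0.4,
                       record_every = 10, seed = 1L) {
  k_unit <- match.arg(k_unit)
  alpha_unit <- match.arg(alpha_unit)
  if (k_push < 0) stop("k_push must be >= 0")
  if (alpha <= 0) stop("alpha must be > 0")
  if (steps < 1) stop("zero steps")
  k_kcal <- if (k_unit == "mEh") k_push * 1e-3 * .const$hartree_kcal
            else k_push
  a_ang <- if (alpha_unit == "bohr") alpha / .const$bohr_angstrom^2
           else alpha
  structure(list(k_push = k_kcal, alpha = a_ang,
                 deposit_every = as.integer(deposit_every),
                 max_refs = as.integer(max_refs), steps = as.integer(steps),
                 T = T, proposal_sd = proposal_sd,
                 record_every = as.integer(record_every),
                 seed = as.integer(seed)),
            class = "mtd_params")
}

#' RMSD-Gaussian metadynamics bias energy
#'
#' `V_bias = sum_i k_i exp(-alpha * Delta_i^2)` with `Delta_i` the minimal
#' superposition RMSD to reference structure `i`. An empty reference list
#' gives zero.
#'
#' @param structure An [xyz_structure].
#' @param reference_structures List of reference `xyz_structure`s sharing
#'   the composition.
#' @param k_push Pushing strength, kcal/mol (scalar, or one per reference).
#' @param alpha Bias width, per Angstrom^2.
#' @return Bias energy, kcal/mol.
#' @export
mtd_bias <- function(structure, reference_structures, k_push, alpha) {
  if (length(reference_structures) == 0L) return(0)
  k <- rep_len(k_push, length(reference_structures))
  d <- vapply(reference_structures, function(r) kabsch_rmsd(structure, r),
              numeric(1))
  sum(k * exp(-alpha * d^2))
}

.mc_engine <- function(model, params, use_bias) {
  ## Metropolis walk on toy_energy (+ optional history bias). RNG state is
  ## localized so the caller's stream is untouched.
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(params$seed)
  n <- model$n_torsions
  RT <- .const$R_kcal * params$T
  sample_pos <- !is.null(model$host)
  phi <- rep(0, n)
  pos <- c(0, 0, 0)
  e_phys <- toy_energy(model, phi, pos)
  cur_struct <- embed_torsions(model, phi, energy = e_phys, position = pos)
  e_bias <- 0
  refs <- list()
  rec_phi <- list(); rec_pos <- list(); rec_e <- numeric(0)
  n_acc <- 0L
  for (step in seq_len(params$steps)) {
    phi_new <- .wrap_angle(phi + stats::rnorm(n, 0, params$proposal_sd))
    pos_new <- if (sample_pos)
      pos + stats::rnorm(3, 0, 0.5 * params$proposal_sd) else pos
    e_phys_new <- toy_energy(model, phi_new, pos_new)
    if (use_bias) {
      s_new <- embed_torsions(model, phi_new, energy = e_phys_new,
                              position = pos_new)
      e_bias_new <- mtd_bias(s_new, refs, params$k_push, params$alpha)
    } else {
      s_new <- NULL
      e_bias_new <- 0
    }
    dE <- (e_phys_new + e_bias_new) - (e_phys + e_bias)
    if (dE <= 0 || stats::runif(1) < exp(-dE / RT)) {
      phi <- phi_new; pos <- pos_new
      e_phys <- e_phys_new; e_bias <- e_bias_new
      if (use_bias) cur_struct <- s_new
      n_acc <- n_acc + 1L
    }
    if (use_bias && step %% params$deposit_every == 0L) {
      if (is.null(cur_struct) || !identical(attr(cur_struct, "torsions"), phi))
        cur_struct <- embed_torsions(model, phi, energy = e_phys,
                                     position = pos)
      refs <- c(refs, list(cur_struct))
      if (length(refs) > params$max_refs)
        refs <- refs[seq.int(length(refs) - params$max_refs + 1L,
                             length(refs))]
      # bias changed under our feet: re-evaluate at the current state
      e_bias <- mtd_bias(cur_struct, refs, params$k_push, params$alpha)
    }
    if (step %% params$record_every == 0L) {
      rec_phi <- c(rec_phi, list(phi))
      rec_pos <- c(rec_pos, list(pos))
      rec_e <- c(rec_e, e_phys)        # bias excluded from recorded energies
    }
  }
  if (!length(rec_e)) stop("no snapshots recorded; increase steps")
  structs <- lapply(seq_along(rec_e), function(i)
    embed_torsions(model, rec_phi[[i]], energy = rec_e[i],
                   position = rec_pos[[i]]))
  ens <- conformer_ensemble(structs, temperature = params$T,
                            provenance = sprintf(
                              "%s seed=%d steps=%d accept=%.2f",
                              if (use_bias) "run_mtd" else "run_unbiased",
                              params$seed, params$steps,
                              n_acc / params$steps))
  attr(ens, "torsions") <- do.call(rbind, rec_phi)
  attr(ens, "acceptance") <- n_acc / params$steps
  ens
}

#' RMSD-biased metadynamics sampling of a toy model
#'
#' Metropolis Monte-Carlo walk in torsion space on
#' `toy_energy + mtd_bias`; the current structure is deposited as a new
#' bias reference every `deposit_every` steps, pushing the walker out of
#' visited minima. Recorded snapshot energies exclude the bias. With
#' `k_push = 0` the trajectory is identical to [run_unbiased()] at the same
#' seed. When the model has a host, the centroid position is sampled too
#' (confined by the ellipsoid wall).
#'
#' @param model A [toy_torsion_model].
#' @param params An [mtd_params] object.
#' @return A [conformer_ensemble] with `torsions` and `acceptance`
#'   attributes.
#' @export
run_mtd <- function(model, params = mtd_params()) {
  stopifnot(inherits(model, "toy_torsion_model"),
            inherits(params, "mtd_params"))
  .mc_engine(model, params, use_bias = params$k_push > 0)
}

#' Unbiased Monte-Carlo sampling of a toy model
#'
#' The same Metropolis walk as [run_mtd()] with no bias; used for the
#' high-temperature refinement stage and as the equilibrium sampler whose
#' long-run torsion distribution is Boltzmann.
#'
#' @param model A [toy_torsion_model].
#' @param T Temperature, K.
#' @param steps Number of MC steps.
#' @param seed Integer seed.
#' @param proposal_sd Torsion proposal standard deviation, rad.
#' @param record_every Steps between recorded snapshots.
#' @return A [conformer_ensemble] with `torsions` attribute.
#' @export
run_unbiased <- function(model, T = 300, steps = 5000, seed = 1L,
                         proposal_sd = 0.4, record_every = 10) {
  params <- mtd_params(k_push = 0, k_unit = "kcal/mol", steps = steps,
                       T = T, proposal_sd = proposal_sd,
                       record_every = record_every, seed = seed)
  .mc_engine(model, params, use_bias = FALSE)
}

#' Genetic torsion crossing
#'
#' Children formed by exchanging torsion subsets between two parent torsion
#' vectors: all `2^n` component mixtures for `n <= 10` (a deterministic
#' enumeration), a seeded random sample of masks otherwise. The parents
#' themselves, and children coinciding with a parent, are excluded.
#'
#' @param torsions_a,torsions_b Parent torsion vectors of equal length.
#' @param n_sample Number of random masks when `n > 10`.
#' @param seed Seed for the random-mask branch.
#' @return Matrix with one child torsion vector per row (possibly 0 rows).
#' @examples
#' genetic_cross(c(0, 0), c(pi, pi))  # rows (0,pi) and (pi,0)
#' @export
genetic_cross <- function(torsions_a, torsions_b, n_sample = 256,
                          seed = 1L) {
  n <- length(torsions_a)
  if (length(torsions_b) != n) stop("parent torsion lengths differ")
  if (n <= 10) {
    masks <- as.matrix(do.call(expand.grid, rep(list(c(FALSE, TRUE)), n)))
  } else {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                     envir = globalenv())
    })
    set.seed(seed)
    masks <- matrix(stats::runif(n_sample * n) < 0.5, n_sample, n)
  }
  children <- t(apply(masks, 1, function(m)
    ifelse(m, torsions_b, torsions_a)))
  same <- function(x, y) all(abs(.wrap_angle(x - y)) < 1e-12)
  keep <- !apply(children, 1, function(ch)
    same(ch, torsions_a) || same(ch, torsions_b))
  children <- children[keep, , drop = FALSE]
  unique(children)
}
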