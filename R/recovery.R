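## Bridging sampling output and the brute-force oracle: basin populations
## estimated from quenched snapshots routed through CRE assembly, and
## distinct-minima counting for sampling-enhancement comparisons.

.nearest_minimum <- function(torsions, minima) {
  d2 <- apply(minima, 1, function(m)
    sum(.wrap_angle(torsions - m)^2))
  which.min(d2)
}

#' Estimate conformer populations from a sampled ensemble
#'
#' Quenches every snapshot of a sampled ensemble to its basin minimum,
#' assembles the quenched structures into a CRE (duplicates are absorbed
#' into their group's occupancy count), maps each conformer group to the
#' nearest oracle minimum, and returns the occupancy fractions aligned with
#' the oracle's minima. For an equilibrium sampler the fractions estimate
#' the basin Boltzmann populations.
#'
#' @param model A [toy_torsion_model].
#' @param ensemble Sampled [conformer_ensemble] with a `torsions`
#'   attribute (from [run_mtd()] / [run_unbiased()]).
#' @param oracle A [brute_force_reference()] result for the same model.
#' @param thresholds [cre_thresholds] for the CRE assembly of the quenched
#'   snapshots.
#' Two population estimates are returned, aligned with the oracle's minima
#' order: `populations` are Boltzmann weights of the discovered conformer
#' energies (the estimate appropriate for biased sampling, where snapshot
#' frequencies are distorted but the set of discovered minima and their
#' quenched energies are not), and `occupancy` are raw snapshot basin
#' fractions (the equilibrium estimate for unbiased sampling), with
#' batch-means Monte-Carlo standard errors.
#'
#' @return A list with `populations` (Boltzmann weights of discovered
#'   conformers, summed per oracle minimum), `occupancy` (snapshot basin
#'   fractions), `se_occupancy` (batch-means MC standard errors of
#'   `occupancy`, floored at the binomial standard error), `counts`, `n`,
#'   and `cre` (the assembled CRE of quenched snapshots).
#' @export
recover_populations <- function(model, ensemble, oracle,
                                thresholds = cre_thresholds(window = Inf)) {
  quenched <- quench_ensemble(model, ensemble)
  k <- nrow(oracle$minima)
  labels <- apply(attr(quenched, "torsions"), 1, .nearest_minimum,
                  minima = oracle$minima)
  n <- length(labels)
  counts <- vapply(seq_len(k), function(i) sum(labels == i), numeric(1))
  occupancy <- counts / n
  # batch-means standard error (accounts for MC autocorrelation)
  B <- min(20L, n)
  batch <- cut(seq_len(n), B, labels = FALSE)
  bf <- vapply(seq_len(k), function(i)
    stats::sd(tapply(labels == i, batch, mean)) / sqrt(B), numeric(1))
  se_binom <- sqrt(occupancy * (1 - occupancy) / n)
  se <- pmax(bf, se_binom, 1 / n)
  # conformer-energy Boltzmann weights, aggregated per oracle minimum
  cre <- assemble_cre(quenched, thresholds)
  w <- boltzmann_weights(cre_energies(cre), T = ensemble$temperature)
  pops <- numeric(k)
  for (g in seq_along(cre$groups)) {
    lab <- .nearest_minimum(attr(cre$groups[[g]]$representative, "torsions"),
                            oracle$minima)
    pops[lab] <- pops[lab] + w[g]
  }
  list(populations = pops, occupancy = occupancy, se_occupancy = se,
       counts = counts, n = n, cre = cre)
}

#' Count distinct potential minima visited by a sampled ensemble
#'
#' Assigns each recorded snapshot to its nearest oracle minimum in the
#' periodic torsion metric and counts how many distinct minima appear; the
#' standard measure for comparing the exploration power of biased vs
#' unbiased sampling.
#'
#' @param ensemble Sampled [conformer_ensemble] with a `torsions` attribute.
#' @param oracle A [brute_force_reference()] result.
#' @return Integer count of distinct minima visited.
#' @export
distinct_minima_visited <- function(ensemble, oracle) {
  tor <- attr(ensemble, "torsions")
  if (is.null(tor)) stop("ensemble carries no torsions attribute")
  labs <- apply(as.matrix(tor), 1, .nearest_minimum,
                minima = oracle$minima)
  length(unique(labs))
}
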