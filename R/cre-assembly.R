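## CRE assembly: energy-sorted greedy grouping of an ensemble into conformer
## groups (representative + rotamers) using energy, RMSD and
## rotational-constant thresholds, followed by energy-window pruning.

#' CRE classification thresholds
#'
#' Threshold set for duplicate/rotamer/conformer discrimination and
#' energy-window pruning. Defaults follow the published defaults of the
#' CREST sampler: 0.1 kcal/mol energy, 0.125 Angstrom RMSD, 1% relative
#' rotational-constant difference, 6 kcal/mol window above the global
#' minimum.
#'
#' @param e_thresh Energy threshold, kcal/mol (> 0).
#' @param rmsd_thresh RMSD threshold, Angstrom (> 0).
#' @param be_thresh Relative rotational-constant threshold (> 0).
#' @param window Energy window above the global minimum, kcal/mol (> 0; may
#'   be `Inf`).
#' @param heavy_only Passed to [kabsch_rmsd()].
#' @return A list of class `cre_thresholds`.
#' @export
cre_thresholds <- function(e_thresh = 0.1, rmsd_thresh = 0.125,
                           be_thresh = 0.01, window = 6.0,
                           heavy_only = FALSE) {
  vals <- c(e_thresh = e_thresh, rmsd_thresh = rmsd_thresh,
            be_thresh = be_thresh, window = window)
  if (any(vals <= 0)) stop("all thresholds must be strictly positive")
  structure(list(e_thresh = e_thresh, rmsd_thresh = rmsd_thresh,
                 be_thresh = be_thresh, window = window,
                 heavy_only = isTRUE(heavy_only)),
            class = "cre_thresholds")
}

#' Classify a structure pair as duplicate, rotamer, or conformer
#'
#' Applies the combined energetic and structural criteria used to
#' deduplicate sampling output: two structures are *duplicates* when their
#' energies agree within `e_thresh` and their superposition RMSD is below
#' `rmsd_thresh`; *rotamers* when energies and rotational constants agree
#' (within `e_thresh` and `be_thresh`) but the RMSD is at or above the
#' threshold, i.e. the same conformer reached through an internal rotation
#' or a symmetry-equivalent atom ordering; *conformers* otherwise.
#'
#' @param a,b `xyz_structure` objects with the same atom sequence.
#' @param thresholds A [cre_thresholds] object.
#' @return One of `"duplicate"`, `"rotamer"`, `"conformer"`.
#' @examples
#' s <- xyz_structure(c("C", "C", "O"),
#'                    rbind(c(0, 0, 0), c(1.5, 0, 0), c(2, 1.2, 0)), -5)
#' classify_pair(s, s)  # "duplicate"
#' @export
classify_pair <- function(a, b, thresholds = cre_thresholds()) {
  stopifnot(inherits(thresholds, "cre_thresholds"))
  if (!identical(a$symbols, b$symbols))
    stop("atom symbol sequences differ; cannot classify pair")
  if (abs(a$energy - b$energy) >= thresholds$e_thresh) return("conformer")
  r <- kabsch_rmsd(a, b, heavy_only = thresholds$heavy_only)
  if (r < thresholds$rmsd_thresh) return("duplicate")
  if (length(a$symbols) >= 2L) {
    bd <- rotconst_rel_diff(rotational_constants(a), rotational_constants(b))
    if (bd < thresholds$be_thresh) return("rotamer")
  }
  "conformer"
}

.new_cre <- function(groups, thresholds, drop_log) {
  structure(list(groups = groups, thresholds = thresholds,
                 drop_log = drop_log),
            class = "cre")
}

#' Assemble a conformer-rotamer ensemble
#'
#' Processes the structures of an ensemble sorted ascending by energy and
#' greedily groups them: each structure is compared against the existing
#' group representatives; a *duplicate* is dropped (but counted towards that
#' group's occupancy), a *rotamer* joins that group, and a structure that is
#' a *conformer* with respect to every representative opens a new group.
#' The energy window is applied at the end via [prune_window()]. The
#' procedure is deterministic for a given input; the global minimum is
#' always retained as the representative of the first group.
#'
#' @param ensemble A [conformer_ensemble].
#' @param thresholds A [cre_thresholds] object.
#' @param apply_window If `FALSE`, skip the final window pruning.
#' @return An object of class `cre`: a list with `groups` (each a list with
#'   `representative`, `rotamers`, `occupancy`), `thresholds`, and
#'   `drop_log` (a data.frame of dropped frame indices and reasons).
#' @examples
#' s <- xyz_structure(c("C", "C"), rbind(c(0, 0, 0), c(1.5, 0, 0)), 0)
#' assemble_cre(conformer_ensemble(list(s, s, s)))  # 1 group, 1 member
#' @export
assemble_cre <- function(ensemble, thresholds = cre_thresholds(),
                         apply_window = TRUE) {
  stopifnot(inherits(ensemble, "conformer_ensemble"),
            inherits(thresholds, "cre_thresholds"))
  energies <- ensemble_energies(ensemble)
  ord <- order(energies)
  groups <- list()
  drop_idx <- integer(0); drop_reason <- character(0)
  for (i in ord) {
    s <- ensemble$structures[[i]]
    placed <- FALSE
    for (g in seq_along(groups)) {
      cls <- classify_pair(s, groups[[g]]$representative, thresholds)
      if (cls == "duplicate") {
        groups[[g]]$occupancy <- groups[[g]]$occupancy + 1L
        drop_idx <- c(drop_idx, i)
        drop_reason <- c(drop_reason, sprintf("duplicate_of_group_%d", g))
        placed <- TRUE
        break
      }
      if (cls == "rotamer") {
        groups[[g]]$rotamers <- c(groups[[g]]$rotamers, list(s))
        groups[[g]]$occupancy <- groups[[g]]$occupancy + 1L
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      groups[[length(groups) + 1L]] <-
        list(representative = s, rotamers = list(), occupancy = 1L)
    }
  }
  # groups were created in ascending-energy order of representatives already
  drop_log <- data.frame(frame = drop_idx, reason = drop_reason,
                         stringsAsFactors = FALSE)
  cre <- .new_cre(groups, thresholds, drop_log)
  if (apply_window) cre <- prune_window(cre, thresholds$window)
  cre
}

#' @export
print.cre <- function(x, ...) {
  nrot <- vapply(x$groups, function(g) length(g$rotamers), integer(1))
  cat(sprintf(
    "<cre> %d conformer groups (%d structures incl. rotamers, %d dropped)\n",
    length(x$groups), length(x$groups) + sum(nrot), nrow(x$drop_log)))
  e0 <- x$groups[[1]]$representative$energy
  for (g in utils::head(seq_along(x$groups), 10)) {
    cat(sprintf("  group %d: dE = %.3f kcal/mol, %d rotamer(s), occupancy %d\n",
                g, x$groups[[g]]$representative$energy - e0, nrot[g],
                x$groups[[g]]$occupancy))
  }
  if (length(x$groups) > 10) cat("  ...\n")
  invisible(x)
}

#' Representative energies of a CRE
#' @param cre A `cre` object.
#' @return Numeric vector, ascending, kcal/mol.
#' @export
cre_energies <- function(cre) {
  vapply(cre$groups, function(g) g$representative$energy, numeric(1))
}

#' Flatten a CRE back into an ensemble
#'
#' Representatives first within each group, groups in energy order.
#'
#' @param cre A `cre` object.
#' @param temperature Temperature for the resulting ensemble, K.
#' @return A [conformer_ensemble].
#' @export
cre_flatten <- function(cre, temperature = 298.15) {
  structs <- list()
  for (g in cre$groups)
    structs <- c(structs, list(g$representative), g$rotamers)
  conformer_ensemble(structs, temperature = temperature,
                     provenance = "cre_flatten")
}

#' Prune a CRE by energy window
#'
#' Removes conformer groups whose representative lies more than `window`
#' kcal/mol above the global minimum, and rotamers above the window from
#' surviving groups. The global minimum group always survives.
#'
#' @param cre A `cre` object.
#' @param window Energy window, kcal/mol (`Inf` = no pruning).
#' @return A pruned `cre`.
#' @export
prune_window <- function(cre, window = 6.0) {
  stopifnot(inherits(cre, "cre"), window > 0)
  e0 <- min(cre_energies(cre))
  keep <- cre_energies(cre) <= e0 + window
  dropped <- which(!keep)
  log2 <- cre$drop_log
  add_log <- function(reason, times = 1L) {
    if (times > 0L)
      log2 <<- rbind(log2, data.frame(
        frame = rep(NA_integer_, times), reason = rep(reason, times),
        stringsAsFactors = FALSE))
  }
  for (g in dropped)   # one log row per removed structure
    add_log(sprintf("window_pruned_group_%d", g),
            1L + length(cre$groups[[g]]$rotamers))
  groups <- cre$groups[keep]
  for (g in seq_along(groups)) {
    rot_e <- vapply(groups[[g]]$rotamers, `[[`, numeric(1), "energy")
    if (length(rot_e)) {
      rkeep <- rot_e <= e0 + window
      groups[[g]]$rotamers <- groups[[g]]$rotamers[rkeep]
      groups[[g]]$occupancy <- groups[[g]]$occupancy - sum(!rkeep)
      add_log(sprintf("window_pruned_rotamer_group_%d", g), sum(!rkeep))
    }
  }
  .new_cre(groups, cre$thresholds, log2)
}

#' Staged energy-window refinement
#'
#' Emulates the staged refinement of iterative conformer searches: the
#' ensemble is assembled into a CRE and pruned with successively tighter
#' energy windows (e.g. 15, 10, 6 kcal/mol), optionally with a schedule of
#' tighter classification thresholds per stage. The survivor count after
#' each stage is recorded.
#'
#' @param ensemble A [conformer_ensemble].
#' @param windows Strictly decreasing numeric vector of windows, kcal/mol.
#' @param threshold_schedule Optional list of [cre_thresholds], one per
#'   stage; defaults to `thresholds` at every stage.
#' @param thresholds Base thresholds (window field ignored; stage windows
#'   come from `windows`).
#' @return A list with `cre` (the final-stage CRE) and `stage_counts`
#'   (retained structures after each stage, including rotamers).
#' @examples
#' # energies 0,4,8,12,20 under windows 15,10,6 survive as 4,3,2
#' @export
staged_refine <- function(ensemble, windows = c(15, 10, 6),
                          threshold_schedule = NULL,
                          thresholds = cre_thresholds()) {
  if (length(windows) < 1L || any(diff(windows) >= 0))
    stop("windows must be strictly decreasing")
  if (is.null(threshold_schedule))
    threshold_schedule <- rep(list(thresholds), length(windows))
  if (length(threshold_schedule) != length(windows))
    stop("threshold_schedule length must match windows")
  counts <- integer(length(windows))
  current <- ensemble
  cre <- NULL
  for (k in seq_along(windows)) {
    th <- threshold_schedule[[k]]
    th$window <- windows[k]
    cre <- assemble_cre(current, th)
    counts[k] <- length(cre$groups) +
      sum(vapply(cre$groups, function(g) length(g$rotamers), integer(1)))
    current <- cre_flatten(cre, temperature = ensemble$temperature)
  }
  list(cre = cre, stage_counts = counts)
}
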