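## Deviation bookkeeping against experiment and cross-method comparison of
## association energies.

#' Signed deviations from experiment
#'
#' `d_i = exp_dg - calc_dg` per ligand; a positive deviation means the
#' calculation *overbinds* (calculated binding free energy more negative
#' than experiment).
#'
#' @param reference_rows Data frame from [read_reference_table()] with
#'   `ligand_id`, `exp_dg`, and the requested calculated flavor column.
#' @param flavor Which calculated column to use: `"top"` (column `dg_top`)
#'   or `"ensemble"` (column `dg_ens`), or the name of any other numeric
#'   column present.
#' @return A data.frame of class `deviation_set` with `ligand_id`,
#'   `deviation` (kcal/mol), and a `flavor` attribute.
#' @examples
#' tab <- read_reference_table(
#'   system.file("extdata", "table2_reference.csv", package = "crebind"))
#' deviations(tab, "top")  # G0: -14.67 - (-18.25) = +3.58 (overbinding)
#' @export
deviations <- function(reference_rows, flavor = c("top", "ensemble")) {
  col <- if (length(flavor) == 1L && !flavor[1] %in% c("top", "ensemble")) {
    flavor[1]
  } else {
    switch(match.arg(flavor), top = "dg_top", ensemble = "dg_ens")
  }
  if (!col %in% names(reference_rows))
    stop("missing calculated-flavor column: ", col)
  if (!all(c("ligand_id", "exp_dg") %in% names(reference_rows)))
    stop("reference rows need ligand_id and exp_dg columns")
  out <- data.frame(ligand_id = reference_rows$ligand_id,
                    deviation = reference_rows$exp_dg - reference_rows[[col]],
                    stringsAsFactors = FALSE)
  attr(out, "flavor") <- col
  class(out) <- c("deviation_set", class(out))
  out
}

#' Summary error statistics of a deviation set
#'
#' MAE (mean absolute deviation), RMSE (root-mean-square deviation), and SD
#' (population standard deviation of the absolute deviations, so that
#' `sd^2 = rmse^2 - mae^2`).
#'
#' @param deviation_set A [deviations()] result, or any data frame with a
#'   `deviation` column.
#' @return A list of class `error_summary` with `mae`, `rmse`, `sd`
#'   (kcal/mol) and `n`.
#' @export
error_summary <- function(deviation_set) {
  d <- deviation_set$deviation
  if (is.null(d) || length(d) == 0L) stop("empty deviation set")
  mae <- mean(abs(d))
  rmse <- sqrt(mean(d^2))
  out <- list(mae = mae, rmse = rmse,
              sd = sqrt(max(0, mean(d^2) - mae^2)), n = length(d))
  class(out) <- "error_summary"
  out
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("<error_summary> n=%d: MAE=%.2f RMSE=%.2f SD=%.2f kcal/mol\n",
              x$n, x$mae, x$rmse, x$sd))
  invisible(x)
}

#' Count of overbinding ligands
#'
#' Number of ligands with positive deviation (calculated binding free
#' energy more negative than experiment).
#'
#' @param deviation_set A [deviations()] result.
#' @return Integer count.
#' @export
overbinding_count <- function(deviation_set) {
  sum(deviation_set$deviation > 0)
}

#' Mean pairwise difference between two methods' association energies
#'
#' `mean over ligands of (E_a[method_a] - E_a[method_b])` on a
#' method-comparison table (one column per method).
#'
#' @param table_rows Data frame with `ligand_id` and one numeric column per
#'   method.
#' @param method_a,method_b Column names.
#' @return Mean difference, kcal/mol.
#' @export
method_mean_difference <- function(table_rows, method_a, method_b) {
  for (m in c(method_a, method_b))
    if (!m %in% names(table_rows)) stop("missing method column: ", m)
  a <- table_rows[[method_a]]; b <- table_rows[[method_b]]
  if (anyNA(a) || anyNA(b))
    stop("both methods must be present for all ligands")
  mean(a - b)
}

#' Ratio of calculated to experimental binding free energy
#'
#' `calc_dg / exp_dg`; both negative gives a positive ratio, so values above
#' one flag calculations stronger than experiment (e.g. a wrongly assigned
#' protonation state overbinding by more than a factor of two).
#'
#' @param calc_dg,exp_dg Binding free energies, kcal/mol; `exp_dg` nonzero.
#' @return Unitless ratio.
#' @examples
#' ratio_to_experiment(-35.93, -14.67)  # 2.449: doubly-protonated overshoot
#' @export
ratio_to_experiment <- function(calc_dg, exp_dg) {
  if (any(exp_dg == 0)) stop("experimental value must be nonzero")
  calc_dg / exp_dg
}
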