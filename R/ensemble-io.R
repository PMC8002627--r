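## Multi-frame XYZ I/O in the CREST/xtb dialect: frame = atom count line,
## comment line whose first float token is the total energy, then atom lines.
## Internal canonical unit is kcal/mol; the file-side unit is explicit.

.energy_to_kcal <- function(x, unit) {
  switch(match.arg(unit, c("hartree", "kcal/mol")),
         "hartree"  = x * .const$hartree_kcal,
         "kcal/mol" = x)
}

.energy_from_kcal <- function(x, unit) {
  switch(match.arg(unit, c("hartree", "kcal/mol")),
         "hartree"  = x / .const$hartree_kcal,
         "kcal/mol" = x)
}

#' Read a multi-frame XYZ ensemble
#'
#' Parses the multi-structure XYZ convention used by conformer samplers
#' (e.g. `crest_conformers.xyz`): each frame is an atom-count line, a comment
#' line whose first whitespace token parseable as a float is the frame's
#' total energy (remaining tokens are kept as the structure tag), and one
#' `symbol x y z` line per atom. Energies are converted to kcal/mol on read;
#' the file-side unit is an explicit argument, never guessed (the xtb
#' convention is Hartree).
#'
#' @param path Path to the XYZ file.
#' @param energy_unit Unit of the comment-line energies: `"hartree"`
#'   (default) or `"kcal/mol"`.
#' @param temperature Temperature attached to the returned ensemble, K.
#' @return A [conformer_ensemble].
#' @seealso [write_multixyz()]
#' @examples
#' f <- tempfile(fileext = ".xyz")
#' writeLines(c("1", "-0.5 frame1", "Ar 0.0 0.0 0.0"), f)
#' read_multixyz(f)  # energy -313.75475 kcal/mol
#' @export
read_multixyz <- function(path, energy_unit = "hartree",
                          temperature = 298.15) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # drop trailing blank lines only
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (!length(lines)) stop("empty XYZ file: ", path)
  structures <- list()
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    frame <- frame + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L)
      stop("frame ", frame, ": invalid atom count line: '", lines[i], "'")
    if (i + 1L + nat > length(lines))
      stop("frame ", frame, ": truncated (expected ", nat, " atom lines)")
    comment <- trimws(lines[i + 1L])
    toks <- strsplit(comment, "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    ei <- which(is.finite(vals))[1]
    if (is.na(ei))
      stop("frame ", frame, ": no parseable energy in comment line: '",
           comment, "'")
    energy <- .energy_to_kcal(vals[ei], energy_unit)
    tag <- paste(toks[-ei], collapse = " ")
    atom_lines <- lines[(i + 2L):(i + 1L + nat)]
    fields <- strsplit(trimws(atom_lines), "\\s+")
    nf <- lengths(fields)
    if (any(nf < 4L))
      stop("frame ", frame, ": malformed atom line(s): ",
           paste(which(nf < 4L), collapse = ", "))
    symbols <- vapply(fields, `[[`, character(1), 1L)
    coords <- t(vapply(fields, function(f)
      suppressWarnings(as.numeric(f[2:4])), numeric(3)))
    if (anyNA(coords))
      stop("frame ", frame, ": non-numeric coordinates")
    structures[[frame]] <- xyz_structure(symbols, coords, energy, tag = tag)
    i <- i + 2L + nat
  }
  conformer_ensemble(structures, temperature = temperature,
                     provenance = paste0("read_multixyz:", path))
}

#' Write a multi-frame XYZ ensemble
#'
#' Inverse of [read_multixyz()]: frames in ensemble order, comment line
#' carrying the total energy in the requested unit followed by the tag.
#'
#' @param ensemble A [conformer_ensemble].
#' @param path Output path.
#' @param energy_unit `"hartree"` (default) or `"kcal/mol"`.
#' @return `path`, invisibly.
#' @export
write_multixyz <- function(ensemble, path, energy_unit = "hartree") {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  con <- file(path, "w")
  on.exit(close(con))
  for (s in ensemble$structures) {
    e <- .energy_from_kcal(s$energy, energy_unit)
    writeLines(as.character(length(s$symbols)), con)
    writeLines(trimws(sprintf("%.12f %s", e, s$tag)), con)
    writeLines(sprintf("%-3s %18.10f %18.10f %18.10f",
                       s$symbols, s$coords[, 1], s$coords[, 2],
                       s$coords[, 3]), con)
  }
  invisible(path)
}

#' Read an experimental/calculated reference table
#'
#' Reads a delimited reference table of per-ligand binding free energies:
#' required columns `ligand_id`, `exp_dg`, `exp_unc` (kcal/mol) and,
#' depending on the table, the calculated flavors `dg_top` / `dg_ens` or
#' per-method association-energy columns. Numeric columns are validated;
#' `exp_unc` must be non-negative.
#'
#' @param path CSV path.
#' @param required Character vector of column names that must be present
#'   beyond `ligand_id` (default `c("exp_dg", "exp_unc")`; pass
#'   `character(0)` for method-comparison tables without experiment).
#' @return A data.frame, one row per ligand.
#' @examples
#' tab <- read_reference_table(
#'   system.file("extdata", "table2_reference.csv", package = "crebind"))
#' tab[tab$ligand_id == "G2", ]
#' @export
read_reference_table <- function(path, required = c("exp_dg", "exp_unc")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE),
    error = function(e) stop("cannot parse reference table: ",
                             conditionMessage(e)))
  if (nrow(df) == 0L || !"ligand_id" %in% names(df))
    stop("reference table schema error: need a ligand_id column and >= 1 row")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("reference table schema error: missing column(s): ",
         paste(missing, collapse = ", "))
  num_cols <- setdiff(names(df), "ligand_id")
  for (cn in num_cols) {
    df[[cn]] <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(df[[cn]]))
      stop("reference table schema error: non-numeric values in column ", cn)
  }
  if ("exp_unc" %in% names(df) && any(df$exp_unc < 0))
    stop("reference table schema error: negative experimental uncertainty")
  df
}
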