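#' @title Reference compound table
#' @name reference_table
#' @description
#' The dereplicated compound table for the *C. crambe* extract (observed
#' m/z, retention time, charge state, experimental molecular weight,
#' proposed formula, ppm error, major MS/MS fragments and identification)
#' ships with the package as a plain-text table. It serves two purposes:
#' it is the arithmetic ground truth that the formula engine must
#' reproduce, and it parameterises the "paper-like" synthetic manifest.
NULL

#' Load the reference compound table
#'
#' @return data.frame with one row per reported feature (53 compounds plus
#'   the two internal standards). The `fragments` column is a list column
#'   of data.frames with `mz` and `z`. Rows whose feature cells are NA
#'   share a consensus feature with the preceding isobaric row.
#' @export
reference_compounds <- function() {
  path <- system.file("extdata", "crambe_reference_table.tsv",
                      package = "CrambeDerep", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  tab$fragments <- lapply(tab$fragments, function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(data.frame(mz = numeric(0), z = integer(0)))
    }
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "/", fixed = TRUE)
    data.frame(mz = as.numeric(vapply(parts, `[`, "", 1L)),
               z = as.integer(vapply(parts, `[`, "", 2L)))
  })
  tab
}

#' Recompute the reference table's mass arithmetic
#'
#' From each printed (m/z, z, formula) the experimental molecular weight
#' and ppm error are recomputed with the reporting mass table and compared
#' with the printed values. Residual ppm disagreements of up to ~0.2-0.3
#' ppm are expected for some rows because the printed m/z values are
#' rounded to 4 decimals.
#'
#' @param table element mass table.
#' @return data.frame with recomputed `mw_exp_calc`, `delta_ppm_calc`
#'   (2 d.p., half-away-from-zero) and the differences to the printed
#'   values.
#' @export
recompute_reference_arithmetic <- function(table = mass_table("paper")) {
  tab <- reference_compounds()
  tab <- tab[!is.na(tab$mz), , drop = FALSE]
  mw_calc <- neutral_mass_from_mz(tab$mz, tab$z, table)
  mw_theor <- vapply(tab$formula, function(f) monoisotopic_mass(f, table),
                     numeric(1), USE.NAMES = FALSE)
  dppm <- delta_ppm_neutral(mw_calc, mw_theor)
  data.frame(
    row = tab$row, mz = tab$mz, z = tab$z, formula = tab$formula,
    mw_exp_printed = tab$mw_exp,
    mw_exp_calc = round_half_up(mw_calc, 4),
    delta_ppm_printed = tab$delta_ppm,
    delta_ppm_calc = round_half_up(dppm, 2),
    mw_diff = round_half_up(mw_calc, 4) - tab$mw_exp,
    ppm_diff = round_half_up(dppm, 2) - tab$delta_ppm,
    stringsAsFactors = FALSE)
}
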