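#' @title Parametric crambescin series and crambescidin entries
#' @name scaffold_library
#' @description
#' The crambescin sub-families share two alkyl side chains: a lower
#' guanidinoalkyl chain with (m + 2) methylene units and an upper chain
#' with (n + 2) methylene units (fixed and unsaturated for the "3"-type
#' sub-families, which are therefore parameterised by m alone). This
#' module generates molecular formulas, compound names, side-chain-type
#' labels and diagnostic fragment ions for any in-range (sub-family, m, n),
#' plus a closed list of crambescidin and small-guanidine entries.
NULL

.FIXED_UPPER <- c("A3", "B3", "C3")

# 13C-12C spacing used for isotope envelopes / charge inference only;
# the reporting mass table has no carbon-13 entry.
.ISOTOPE_SPACING <- 1.0033

# memo caches: instantiated fragment rules (keyed on every input) and the
# default configuration file
.frag_cache <- new.env(parent = emptyenv())
.cfg_cache <- new.env(parent = emptyenv())

.library_config_path <- function() {
  system.file("extdata", "crambe_library.yaml", package = "CrambeDerep",
              mustWork = TRUE)
}

#' Load the scaffold library configuration
#'
#' The library is configured from a human-editable YAML file holding the
#' series coefficients, enumeration ranges and the closed crambescidin /
#' small-guanidine / internal-standard lists, so new scaffolds can be
#' added without code changes.
#'
#' @param path YAML file; defaults to the configuration shipped with the
#'   package.
#' @return A list with elements `series`, `ranges`, `crambescidins`,
#'   `small_guanidines`, `standards`.
#' @export
library_config <- function(path = .library_config_path()) {
  hit <- .cfg_cache[[path]]
  if (!is.null(hit)) return(hit)
  cfg <- yaml::read_yaml(path)
  stopifnot(all(c("series", "ranges", "crambescidins") %in% names(cfg)))
  .cfg_cache[[path]] <- cfg
  cfg
}

.check_params <- function(subfamily, m, n, config = library_config(),
                          ranges = NULL) {
  sc <- config$series[[subfamily]]
  if (is.null(sc)) {
    stop("unknown sub-family: ", subfamily)
  }
  fixed <- identical(sc$chains, "lower")
  if (m < 2 || m != round(m)) stop("lower-chain parameter m must be an integer >= 2")
  if (!fixed) {
    if (is.null(n) || is.na(n)) stop("sub-family ", subfamily, " requires an upper-chain parameter n")
    if (n < 2 || n != round(n)) stop("upper-chain parameter n must be an integer >= 2")
  }
  if (!is.null(ranges)) {
    if (m > ranges$m[2] || m < ranges$m[1]) stop("m out of configured range")
    if (!fixed && (n > ranges$n[2] || n < ranges$n[1])) stop("n out of configured range")
  }
  invisible(TRUE)
}

#' Molecular formula of a crambescin series member
#'
#' For chain-parameterised families (A, didehydro-A, B, C) the carbon
#' count is k = 14 + m + n; for the fixed-upper-chain families (A3, B3,
#' C3) it is k = 26 + m. Hydrogen counts follow the family's empirical
#' formula type (e.g. CkH2k-4N6O2 for A, CkH2k-12N6O2 for A3,
#' CkH2k-2N6O3 for B/C).
#'
#' @param subfamily one of `"A"`, `"didehydroA"`, `"B"`, `"C"`, `"A3"`,
#'   `"B3"`, `"C3"`.
#' @param m lower-chain parameter (integer >= 2).
#' @param n upper-chain parameter (integer >= 2; ignored for the "3"-type
#'   families).
#' @param config library configuration, see [library_config()].
#' @return A [chem_formula()].
#' @export
#' @examples
#' formula_string(series_formula("A", m = 2, n = 8))   # "C24H44N6O2"
#' formula_string(series_formula("A3", m = 4))         # "C30H48N6O2"
series_formula <- function(subfamily, m, n = NULL, config = library_config()) {
  .check_params(subfamily, m, n, config)
  sc <- config$series[[subfamily]]
  k <- if (identical(sc$chains, "lower")) sc$k_base + m else sc$k_base + m + n
  h <- 2 * k + sc$h_offset
  if (h <= 0) stop("out-of-range parameters for sub-family ", subfamily)
  chem_formula(c(C = k, H = h, N = sc$n_atoms, O = sc$o_atoms))
}

#' Side-chain type label
#'
#' The reported compounds cluster by side-chain type rather than by core:
#' `"3"` for the fixed-unsaturated-upper-chain families; `"1"` for n = 6
#' with m in 4..6; `"2"` for m = 2; `"homologue"` otherwise (newly
#' reported chain-length combinations).
#'
#' @inheritParams series_formula
#' @return character label.
#' @export
sidechain_type <- function(subfamily, m, n = NULL,
                           config = library_config()) {
  .check_params(subfamily, m, n, config)
  if (identical(config$series[[subfamily]]$chains, "lower")) return("3")
  if (n == 6 && m %in% 4:6) return("1")
  if (m == 2) return("2")
  "homologue"
}

#' Conventional compound name
#'
#' Sub-family type followed by the nominal molecular weight, e.g.
#' `"crambescin A2 448"`; homologues outside the named 1/2/3 types are
#' rendered as `"crambescin A 448 homologue (m = 6, n = 4)"`.
#'
#' @inheritParams series_formula
#' @param table mass table used for the nominal mass.
#' @return character name.
#' @export
compound_name <- function(subfamily, m, n = NULL, config = library_config(),
                          table = mass_table("paper")) {
  f <- series_formula(subfamily, m, n, config)
  nominal <- round(monoisotopic_mass(f, table))
  type <- sidechain_type(subfamily, m, n, config)
  stem <- if (startsWith(subfamily, "didehydro")) "didehydrocrambescin"
          else "crambescin"
  letter <- sub("^didehydro", "", subfamily)
  if (identical(config$series[[subfamily]]$chains, "lower")) {
    return(sprintf("%s %s %d", stem, letter, nominal))
  }
  if (type == "homologue") {
    sprintf("%s %s %d homologue (m = %d, n = %d)", stem, letter, nominal, m, n)
  } else {
    sprintf("%s %s%s %d", stem, letter, type, nominal)
  }
}

#' Diagnostic fragment ions of a series member
#'
#' Returns the sub-family's fragmentation rules instantiated at (m, n) as
#' concrete cations. A-type families fragment by methylenediamine (CH2N2)
#' loss from the doubly protonated precursor followed by loss of the upper
#' alkyl chain (which determines n), and release the lower guanidinoalkyl
#' chain as `[C(m+3)H(2m+10)N3O]+` (which determines m) together with its
#' dehydrated form. B-type cores split by retro-Diels-Alder into an upper
#' `[C(n+5)H(2n+12)N3]+` / lower `[C(m+9)H(2m+16)N3O3]+` pair plus the
#' constant spiroaminal ion `[C6H7O2]+`; C-type cores instead show the
#' doubly charged `[C(m+10)H(2m+17)N3O3]2+` diagnostic. Each rule carries
#' a diagnostic weight used by the annotation scorer.
#'
#' @inheritParams series_formula
#' @param table mass table for theoretical m/z.
#' @return data.frame with columns `role`, `cation`, `z`, `weight`, `mz`.
#' @export
diagnostic_fragments <- function(subfamily, m, n = NULL,
                                 config = library_config(),
                                 table = mass_table("paper")) {
  .check_params(subfamily, m, n, config)
  sc0 <- config$series[[subfamily]]
  key <- paste(subfamily, m, if (is.null(n)) "-" else n,
               paste(unlist(sc0), collapse = ","),
               paste(names(table), table, collapse = ","), sep = "|")
  hit <- .frag_cache[[key]]
  if (!is.null(hit)) return(hit)
  M <- series_formula(subfamily, m, n, config)
  H2 <- chem_formula(c(H = 2))
  H1 <- chem_formula(c(H = 1))
  ch2n2 <- parse_formula("CH2N2")
  rule <- function(role, cation, z, weight) {
    data.frame(role = role, cation = formula_string(cation), z = as.integer(z),
               weight = weight, stringsAsFactors = FALSE)
  }
  guan <- chem_formula(c(C = m + 3, H = 2 * m + 10, N = 3, O = 1))
  guan_dehyd <- chem_formula(c(C = m + 3, H = 2 * m + 8, N = 3))
  rules <- switch(subfamily,
    A = {
      prec2 <- formula_add(M, H2)
      loss1 <- formula_subtract(prec2, ch2n2)
      alkyl <- chem_formula(c(C = n + 3, H = 2 * n + 6))
      rbind(
        rule("ch2n2_loss", loss1, 2, 0.8),
        rule("alkyl_chain_loss", formula_subtract(loss1, alkyl), 2, 1.0),
        rule("guanidinoalkyl", guan, 1, 1.0),
        rule("guanidinoalkyl_dehydrated", guan_dehyd, 1, 0.5),
        rule("core_ester_cleavage",
             chem_formula(c(C = n + 10, H = 2 * n + 14, N = 1, O = 1)), 1, 0.25),
        rule("ch2n2_loss_1plus", formula_subtract(formula_add(M, H1), ch2n2), 1, 0.3))
    },
    didehydroA = {
      prec2 <- formula_add(M, H2)
      loss1 <- formula_subtract(prec2, ch2n2)
      # the extra unsaturation leaves with the neutral chain
      alkyl <- chem_formula(c(C = n + 3, H = 2 * n + 4))
      rbind(
        rule("ch2n2_loss", loss1, 2, 0.8),
        rule("alkyl_chain_loss", formula_subtract(loss1, alkyl), 2, 1.0),
        rule("guanidinoalkyl", guan, 1, 1.0),
        rule("guanidinoalkyl_dehydrated", guan_dehyd, 1, 0.5),
        rule("ch2n2_loss_1plus", formula_subtract(formula_add(M, H1), ch2n2), 1, 0.3))
    },
    A3 = {
      prec2 <- formula_add(M, H2)
      loss1 <- formula_subtract(prec2, ch2n2)
      rbind(
        rule("ch2n2_loss", loss1, 2, 0.8),
        rule("alkyl_chain_loss",
             formula_subtract(loss1, parse_formula("C15H22")), 2, 1.0),
        rule("guanidinoalkyl", guan, 1, 1.0),
        rule("guanidinoalkyl_dehydrated", guan_dehyd, 1, 0.5),
        rule("a3_core", parse_formula("C23H34N3O2"), 1, 0.4),
        rule("ch2n2_loss_1plus", formula_subtract(formula_add(M, H1), ch2n2), 1, 0.3))
    },
    B = {
      upper <- chem_formula(c(C = n + 5, H = 2 * n + 12, N = 3))
      rbind(
        rule("rda_upper", upper, 1, 1.0),
        rule("rda_lower",
             chem_formula(c(C = m + 9, H = 2 * m + 16, N = 3, O = 3)), 1, 1.0),
        rule("rda_upper_ch2n2",
             chem_formula(c(C = n + 4, H = 2 * n + 10, N = 1)), 1, 0.8),
        rule("spiroaminal", parse_formula("C6H7O2"), 1, 0.5),
        rule("guanidinoalkyl", guan, 1, 1.0),
        rule("guanidinoalkyl_dehydrated", guan_dehyd, 1, 0.5))
    },
    B3 = {
      rbind(
        rule("rda_upper", parse_formula("C17H28N3"), 1, 1.0),
        rule("rda_lower",
             chem_formula(c(C = m + 9, H = 2 * m + 16, N = 3, O = 3)), 1, 1.0),
        rule("rda_upper_ch2n2", parse_formula("C16H26N"), 1, 0.8),
        rule("spiroaminal", parse_formula("C6H7O2"), 1, 0.5),
        rule("guanidinoalkyl", guan, 1, 1.0),
        rule("guanidinoalkyl_dehydrated", guan_dehyd, 1, 0.5))
    },
    C = ,
    C3 = {
      rbind(
        rule("c_diagnostic",
             chem_formula(c(C = m + 10, H = 2 * m + 17, N = 3, O = 3)), 2, 1.0),
        rule("guanidinoalkyl", guan, 1, 1.0),
        rule("guanidinoalkyl_dehydrated", guan_dehyd, 1, 0.5))
    },
    stop("no diagnostic fragment rules for sub-family ", subfamily))
  rules$mz <- vapply(seq_len(nrow(rules)), function(i) {
    theoretical_mz(rules$cation[i], rules$z[i], table)
  }, numeric(1))
  .frag_cache[[key]] <- rules
  rules
}

#' Build the candidate library
#'
#' Enumerates every series member over the configured (m, n) ranges plus
#' the closed crambescidin, small-guanidine and internal-standard entries,
#' as one table of (kind, subfamily, m, n, formula, neutral mass, name).
#' Isobaric B/C (and B3/C3) members are deliberately kept as separate
#' entries; disambiguation is the dereplication stage's job.
#'
#' @param config library configuration, see [library_config()].
#' @param m_range,n_range optional overrides of the configured ranges.
#' @param table mass table.
#' @return A data.frame of class `crambe_library`.
#' @export
build_library <- function(config = library_config(),
                          m_range = NULL, n_range = NULL,
                          table = mass_table("paper")) {
  ranges <- config$ranges
  if (!is.null(m_range)) ranges$m <- m_range
  if (!is.null(n_range)) ranges$n <- n_range
  rows <- list()
  for (sf in names(config$series)) {
    fixed <- identical(config$series[[sf]]$chains, "lower")
    for (m in ranges$m[1]:ranges$m[2]) {
      ns <- if (fixed) NA_integer_ else ranges$n[1]:ranges$n[2]
      for (n in ns) {
        f <- series_formula(sf, m, if (fixed) NULL else n, config)
        rows[[length(rows) + 1L]] <- data.frame(
          kind = "series", subfamily = sf, m = m, n = n,
          formula = formula_string(f),
          mass = monoisotopic_mass(f, table),
          name = compound_name(sf, m, if (fixed) NULL else n, config, table),
          known = NA, stringsAsFactors = FALSE)
      }
    }
  }
  closed <- function(entries, kind) {
    lapply(entries, function(e) data.frame(
      kind = kind, subfamily = NA_character_, m = NA_integer_, n = NA_integer_,
      formula = formula_string(e$formula),
      mass = monoisotopic_mass(e$formula, table),
      name = e$name, known = isTRUE(e$known), stringsAsFactors = FALSE))
  }
  rows <- c(rows,
            closed(config$crambescidins, "crambescidin"),
            closed(config$small_guanidines, "guanidine"),
            closed(config$standards, "standard"))
  lib <- do.call(rbind, rows)
  lib <- lib[order(lib$mass, lib$name, method = "radix"), , drop = FALSE]
  rownames(lib) <- NULL
  attr(lib, "config") <- config
  attr(lib, "ranges") <- ranges
  class(lib) <- c("crambe_library", class(lib))
  lib
}

#' Candidate formulas for a neutral mass
#'
#' All library entries whose neutral mass lies within `tol_ppm` of
#' `neutral_mass`, ordered by absolute ppm error (ties broken by name for
#' determinism). Isobaric B/C pairs are both returned.
#'
#' @param neutral_mass neutral mass (Da).
#' @param tol_ppm mass tolerance in ppm (default 5, the annotation window).
#' @param library a [build_library()] table.
#' @return data.frame of candidates with a `delta_ppm` column.
#' @export
enumerate_candidates <- function(neutral_mass, tol_ppm = 5,
                                 library = build_library()) {
  stopifnot(tol_ppm > 0)
  dppm <- delta_ppm_neutral(neutral_mass, library$mass)
  keep <- abs(dppm) <= tol_ppm
  out <- library[keep, , drop = FALSE]
  out$delta_ppm <- dppm[keep]
  out <- out[order(abs(out$delta_ppm), out$name, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
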