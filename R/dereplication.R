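#' @title Feature annotation and reporting
#' @name dereplication
#' @description
#' Matches MS1 features to library candidates at +/- 5 ppm on the neutral
#' mass, scores sub-family diagnostic fragments in the attached MS2
#' spectrum, resolves isobaric crambescin B/C pairs by the intensity of
#' the doubly charged C diagnostic relative to the retro-Diels-Alder pair,
#' applies the crambescidin marker-ion logic, labels A3 cis/trans isomer
#' pairs by elution order, and emits the conventional report table.
NULL

.CRAMBESCIDIN_MARKERS <- data.frame(
  role = c("guanidine_core", "guanidine_core_dehydrated", "hydroxyspermidine"),
  cation = c("C14H22N3O2", "C14H20N3O", "C4H8N"),
  z = c(1L, 1L, 1L),
  weight = c(1, 1, 1),
  stringsAsFactors = FALSE)

.marker_ions <- function(table = mass_table("paper")) {
  mk <- .CRAMBESCIDIN_MARKERS
  mk$mz <- vapply(seq_len(nrow(mk)),
                  function(i) theoretical_mz(mk$cation[i], mk$z[i], table),
                  numeric(1))
  mk
}

#' Match spectrum peaks against rule ions
#'
#' A peak matches a rule when the absolute m/z difference is within
#' `tol_ppm` of the theoretical m/z, or within `abs_floor` Da for ions
#' below `floor_below` (several reported fragments deviate by ~4-6 ppm at
#' low m/z where the ppm window is narrower than the centroid accuracy).
#'
#' @param mz,intensity spectrum peak vectors.
#' @param rules data.frame from [diagnostic_fragments()] (needs `mz`,
#'   `z`, `role`, `weight`).
#' @param tol_ppm fragment tolerance in ppm.
#' @param abs_floor absolute tolerance floor in Da.
#' @param floor_below apply the floor below this m/z.
#' @return `rules` with `matched`, `mz_obs`, `intensity_obs` and the
#'   fragment ppm error (full-cation-mass convention).
#' @export
match_fragments <- function(mz, intensity, rules, tol_ppm = 5,
                            abs_floor = 0.002, floor_below = 400) {
  nr <- nrow(rules)
  rules$matched <- rep(FALSE, nr)
  rules$mz_obs <- rep(NA_real_, nr)
  rules$intensity_obs <- rep(0, nr)
  rules$ppm <- rep(NA_real_, nr)
  if (!length(mz) || !nr) return(rules)
  for (i in seq_len(nrow(rules))) {
    tol <- tol_ppm * 1e-6 * rules$mz[i]
    if (rules$mz[i] < floor_below) tol <- max(tol, abs_floor)
    d <- abs(mz - rules$mz[i])
    hit <- which(d <= tol)
    if (length(hit)) {
      hit <- hit[which.max(intensity[hit])]
      rules$matched[i] <- TRUE
      rules$mz_obs[i] <- mz[hit]
      rules$intensity_obs[i] <- intensity[hit]
      rules$ppm[i] <- 1e6 * (mz[hit] - rules$mz[i]) / (rules$z[i] * rules$mz[i])
    }
  }
  rules
}

#' Discriminate isobaric crambescin B and C candidates
#'
#' B and C members with the same (m, n) share one molecular formula; the
#' difference lies in the intensity of the doubly charged C diagnostic ion
#' versus the retro-Diels-Alder pair, which the C core (two conjugated
#' double bonds) produces much less readily. With `I_C` the intensity of
#' the C diagnostic and `I_B` the summed RDA-pair intensity, the call is C
#' when `I_C / (I_C + I_B) >= theta`, B otherwise; when neither diagnostic
#' is present the pair is reported undetermined ("B or C").
#'
#' @param spectrum an [ms2_spectrum()].
#' @param m,n chain parameters shared by the candidate pair.
#' @param theta decision threshold on the intensity ratio.
#' @param three_type TRUE for the fixed-upper-chain (B3/C3) pair.
#' @param tol_ppm,abs_floor fragment matching tolerances.
#' @param config,table library configuration and mass table.
#' @return list with `call` (`"B"`, `"C"` or `"undetermined"`), `ratio`,
#'   `i_c`, `i_b`.
#' @export
discriminate_b_vs_c <- function(spectrum, m, n = NULL, theta = 0.5,
                                three_type = FALSE,
                                tol_ppm = 5, abs_floor = 0.002,
                                config = library_config(),
                                table = mass_table("paper")) {
  b_sf <- if (three_type) "B3" else "B"
  c_sf <- if (three_type) "C3" else "C"
  b_rules <- diagnostic_fragments(b_sf, m, n, config, table)
  c_rules <- diagnostic_fragments(c_sf, m, n, config, table)
  bm <- match_fragments(spectrum$mz, spectrum$intensity, b_rules,
                        tol_ppm, abs_floor)
  cm <- match_fragments(spectrum$mz, spectrum$intensity, c_rules,
                        tol_ppm, abs_floor)
  i_b <- sum(bm$intensity_obs[bm$role %in% c("rda_upper", "rda_lower")])
  i_c <- sum(cm$intensity_obs[cm$role == "c_diagnostic"])
  if (i_b + i_c <= 0) {
    return(list(call = "undetermined", ratio = NA_real_, i_c = 0, i_b = 0))
  }
  ratio <- i_c / (i_c + i_b)
  list(call = if (ratio >= theta) "C" else "B", ratio = ratio,
       i_c = i_c, i_b = i_b)
}

.annotation_row <- function(feature, cand, mw_exp, matched, score, flag,
                            bc_ratio = NA_real_) {
  mf <- matched[matched$matched, , drop = FALSE]
  frag_str <- if (nrow(mf)) {
    mf <- mf[order(-mf$intensity_obs, method = "radix"), , drop = FALSE]
    paste(sprintf("%.4f (%d)", mf$mz_obs, mf$z), collapse = "; ")
  } else ""
  data.frame(
    feature_id = feature$feature_id, mz = feature$mz, rt = feature$rt,
    z = feature$z, mw_exp = mw_exp,
    kind = cand$kind, subfamily = cand$subfamily, m = cand$m, n = cand$n,
    formula = cand$formula, name = cand$name,
    delta_ppm = cand$delta_ppm,
    n_matched = sum(matched$matched), n_rules = nrow(matched),
    score = score, flag = flag, bc_ratio = bc_ratio,
    fragments = frag_str, stringsAsFactors = FALSE)
}

#' Annotate one feature
#'
#' Candidates are drawn from the library within `precursor_tol` ppm of the
#' neutral mass recovered from (m/z, z); each is scored by the
#' diagnostic-weighted count of matched fragment ions, with ties broken by
#' absolute precursor ppm error and then by the number of unmatched
#' rules. Candidates with no matched fragment are retained but flagged
#' `"formula-only"`. Isobaric B/C (B3/C3) pairs are resolved by
#' [discriminate_b_vs_c()]; an unresolvable pair is reported as a single
#' `"B or C"` annotation. Crambescidin entries require at least
#' `min_markers` of the three marker ions for a named annotation. When a
#' feature's MS2 was triggered on a different protonation state, set
#' `try_charges` to annotate against several charge interpretations; the
#' best-supported interpretation wins.
#'
#' @param feature one-row data.frame (or list) with `feature_id`, `mz`,
#'   `rt`, `z`, `intensity`.
#' @param spectrum the linked [ms2_spectrum()] or NULL.
#' @param library a [build_library()] table.
#' @param precursor_tol precursor tolerance (ppm).
#' @param fragment_tol fragment tolerance (ppm).
#' @param abs_floor absolute fragment tolerance floor (Da) below m/z 400.
#' @param theta B/C discrimination threshold.
#' @param min_markers crambescidin marker ions required.
#' @param try_charges charge interpretations to attempt (default: the
#'   feature's own charge).
#' @param table mass table.
#' @return data.frame of ranked annotations (possibly empty), best first.
#' @export
annotate_feature <- function(feature, spectrum = NULL,
                             library = build_library(),
                             precursor_tol = 5, fragment_tol = 5,
                             abs_floor = 0.002, theta = 0.5,
                             min_markers = 2L, try_charges = NULL,
                             table = mass_table("paper")) {
  config <- attr(library, "config")
  if (is.null(config)) config <- library_config()
  if (is.null(try_charges)) try_charges <- feature$z
  try_charges <- try_charges[!is.na(try_charges)]
  if (!length(try_charges)) try_charges <- 1L
  out <- list()
  for (z in unique(try_charges)) {
    mw_exp <- neutral_mass_from_mz(feature$mz, z, table)
    cands <- enumerate_candidates(mw_exp, precursor_tol, library)
    if (!nrow(cands)) next
    for (i in seq_len(nrow(cands))) {
      cand <- cands[i, ]
      if (cand$kind == "series") {
        rules <- diagnostic_fragments(cand$subfamily, cand$m,
                                      if (is.na(cand$n)) NULL else cand$n,
                                      config, table)
      } else if (cand$kind == "crambescidin" &&
                 !identical(cand$name, "crambescidin acid")) {
        rules <- .marker_ions(table)
      } else {
        rules <- data.frame(role = character(0), cation = character(0),
                            z = integer(0), weight = numeric(0),
                            mz = numeric(0))
      }
      matched <- match_fragments(
        if (is.null(spectrum)) numeric(0) else spectrum$mz,
        if (is.null(spectrum)) numeric(0) else spectrum$intensity,
        rules, fragment_tol, abs_floor)
      score <- sum(matched$weight[matched$matched])
      flag <- "ok"
      if (cand$kind == "crambescidin" &&
          !identical(cand$name, "crambescidin acid")) {
        if (sum(matched$matched) < min_markers) flag <- "formula-only"
      } else if (nrow(matched) > 0 && !any(matched$matched)) {
        flag <- "formula-only"
      } else if (nrow(matched) == 0) {
        flag <- "formula-only"
      }
      out[[length(out) + 1L]] <- .annotation_row(feature, cand, mw_exp,
                                                 matched, score, flag)
    }
  }
  if (!length(out)) {
    return(.empty_annotations())
  }
  ann <- do.call(rbind, out)

  # resolve isobaric B/C and B3/C3 pairs sharing a formula
  if (!is.null(spectrum)) {
    for (fstr in unique(ann$formula[ann$kind == "series"])) {
      idx <- which(ann$formula == fstr & ann$kind == "series")
      sfs <- ann$subfamily[idx]
      for (pair in list(c("B", "C"), c("B3", "C3"))) {
        bi <- idx[sfs == pair[1] & !is.na(ann$m[idx])]
        ci <- idx[sfs == pair[2] & !is.na(ann$m[idx])]
        # discriminate members with identical (m, n) only
        key <- function(i) paste(ann$m[i], ann$n[i])
        for (b in bi) {
          cc <- ci[key(ci) == key(b)]
          if (!length(cc)) next
          d <- discriminate_b_vs_c(
            spectrum, ann$m[b], if (is.na(ann$n[b])) NULL else ann$n[b],
            theta = theta, three_type = pair[1] == "B3",
            tol_ppm = fragment_tol, abs_floor = abs_floor,
            config = config, table = table)
          ann$bc_ratio[c(b, cc)] <- d$ratio
          if (d$call == "undetermined") {
            ann$flag[c(b, cc)] <- "B-or-C"
            nominal <- round(monoisotopic_mass(ann$formula[b], table))
            ann$name[c(b, cc)] <- sprintf("crambescin %s or %s %d",
                                          pair[1], pair[2], nominal)
          } else if (d$call == "C") {
            ann$score[b] <- -1   # demote the rejected B candidate
            ann$flag[b] <- "bc-rejected"
          } else {
            ann$score[cc] <- -1
            ann$flag[cc] <- "bc-rejected"
          }
        }
      }
    }
  }
  ann <- ann[order(-ann$score, abs(ann$delta_ppm),
                   ann$n_rules - ann$n_matched, ann$name,
                   method = "radix"), , drop = FALSE]
  ann$rank <- seq_len(nrow(ann))
  rownames(ann) <- NULL
  ann
}

.empty_annotations <- function() {
  data.frame(feature_id = integer(0), mz = numeric(0), rt = numeric(0),
             z = integer(0), mw_exp = numeric(0), kind = character(0),
             subfamily = character(0), m = integer(0), n = integer(0),
             formula = character(0), name = character(0),
             delta_ppm = numeric(0), n_matched = integer(0),
             n_rules = integer(0), score = numeric(0), flag = character(0),
             bc_ratio = numeric(0), fragments = character(0),
             rank = integer(0), stringsAsFactors = FALSE)
}

#' Label cis/trans isomer pairs by elution order
#'
#' A3-type members detected as exactly two features sharing one molecular
#' formula are labelled by expected relative polarity: the earlier-eluting
#' feature cis, the later trans. Groups of any other size are left
#' unlabelled (with a warning for > 2).
#'
#' @param annotations best-per-feature annotation table.
#' @return `annotations` with an `isomer` column and labels appended to
#'   the A3 pair names.
#' @export
label_isomer_pairs <- function(annotations) {
  annotations$isomer <- NA_character_
  a3 <- which(!is.na(annotations$subfamily) & annotations$subfamily == "A3")
  for (fstr in unique(annotations$formula[a3])) {
    grp <- a3[annotations$formula[a3] == fstr]
    if (length(grp) == 2) {
      grp <- grp[order(annotations$rt[grp])]
      annotations$isomer[grp] <- c("cis", "trans")
      annotations$name[grp] <- paste0(annotations$name[grp],
                                      c(" (cis)", " (trans)"))
    } else if (length(grp) > 2) {
      warning(sprintf("%d co-formula A3 features (%s); isomer labels omitted",
                      length(grp), fstr))
    }
  }
  annotations
}

#' Annotate a whole run
#'
#' Runs [annotate_feature()] over a feature table with linked MS2 spectra,
#' keeps the top-ranked annotation per feature (all ranked alternatives
#' are attached as the `"alternatives"` attribute), and labels A3 isomer
#' pairs. Features without any candidate are reported unidentified.
#'
#' @param features feature table with an `ms2` list column (see
#'   [link_ms2()]); a plain table works when no spectra are available.
#' @param library a [build_library()] table.
#' @param ... passed to [annotate_feature()].
#' @return annotation table, one row per feature, RT-ordered.
#' @export
annotate_run <- function(features, library = build_library(), ...) {
  has_ms2 <- !is.null(features$ms2)
  best <- list(); alts <- list()
  for (i in seq_len(nrow(features))) {
    f <- features[i, , drop = FALSE]
    sp <- if (has_ms2) features$ms2[[i]] else NULL
    ann <- annotate_feature(f[, setdiff(names(f), "ms2"), drop = FALSE],
                            sp, library, ...)
    if (nrow(ann) == 0) {
      ann <- .empty_annotations()[0, ]
    } else {
      alts[[length(alts) + 1L]] <- ann
      # an undetermined B/C pair stays a single reported row
      ann <- ann[1, , drop = FALSE]
    }
    best[[length(best) + 1L]] <- ann
  }
  out <- do.call(rbind, best)
  if (nrow(out)) {
    out <- out[order(out$rt, out$mz, out$name, method = "radix"), , drop = FALSE]
    rownames(out) <- NULL
    out <- label_isomer_pairs(out)
  }
  attr(out, "alternatives") <- if (length(alts)) do.call(rbind, alts) else NULL
  out
}

#' Build the conventional report table
#'
#' One row per annotated feature in the layout of the reference table:
#' index, m/z (4 d.p.), Rt, charge state, experimental molecular weight
#' (4 d.p.), proposed formula, ppm error (2 d.p.), up to `max_fragments`
#' major MS/MS fragments with charge states, proposed identification.
#' Rounding is half-away-from-zero throughout.
#'
#' @param annotations output of [annotate_run()].
#' @param max_fragments fragments reported per row.
#' @return character-formatted data.frame, deterministic for identical
#'   inputs.
#' @export
build_report <- function(annotations, max_fragments = 4L) {
  hdr <- data.frame(index = integer(0), mz = character(0), rt = character(0),
                    z = integer(0), mw_exp = character(0),
                    formula = character(0), delta_ppm = character(0),
                    fragments = character(0), identification = character(0),
                    stringsAsFactors = FALSE)
  if (is.null(annotations) || nrow(annotations) == 0) return(hdr)
  trim_frags <- vapply(strsplit(annotations$fragments, "; ", fixed = TRUE),
                       function(p) paste(utils::head(p, max_fragments),
                                         collapse = "; "), "")
  data.frame(
    index = seq_len(nrow(annotations)),
    mz = sprintf("%.4f", round_half_up(annotations$mz, 4)),
    rt = sprintf("%.2f", round_half_up(annotations$rt, 2)),
    z = annotations$z,
    mw_exp = sprintf("%.4f", round_half_up(annotations$mw_exp, 4)),
    formula = annotations$formula,
    delta_ppm = sprintf("%.2f", round_half_up(annotations$delta_ppm, 2)),
    fragments = trim_frags,
    identification = annotations$name,
    stringsAsFactors = FALSE)
}

#' Write a report as TSV
#' @param report a [build_report()] table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
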