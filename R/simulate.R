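#' @title Seeded synthetic LC-MS/MS run generator
#' @name synthetic_data
#' @description
#' Forward model of the sub-family fragmentation rules: for every planted
#' compound it emits an MS1 feature (multiply charged precursor with an
#' isotope envelope at 1/z spacing), an HCD-style MS2 spectrum holding
#' the family's diagnostic ions under a family intensity profile, decoy
#' noise peaks, and optionally the spiked internal standards — together
#' with a ground-truth manifest, so every pipeline stage can be scored
#' without any raw-data download.
NULL

#' Generator configuration
#'
#' @param seed integer seed fixing all randomness.
#' @param mass_jitter_ppm Gaussian mass jitter, truncated at this bound
#'   (ppm) so that recomputed ppm errors never exceed it; 0 disables.
#' @param decoys_per_spectrum uniform decoy peaks added per MS2 spectrum
#'   over m/z 60 to the precursor.
#' @param isotope_peaks isotope envelope length for MS1 features.
#' @param include_standards plant yohimbine/reserpine at their reference
#'   retention times.
#' @param adversarial_decoys when TRUE, decoys are placed *inside* the
#'   +/- 5 ppm windows of other library compounds' diagnostic ions to
#'   measure false-annotation rates; by default decoys avoid the planted
#'   compound's own windows so the ground truth stays well defined.
#' @param intensity_sd log-scale standard deviation of fragment intensity
#'   multipliers.
#' @param residual_precursor relative intensity of the residual precursor
#'   ion (and its co-isolated first isotope peak) in MS2; multiply
#'   charged precursors retain both through a ~1 Da isolation window.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, mass_jitter_ppm = 3,
                             decoys_per_spectrum = 10L, isotope_peaks = 3L,
                             include_standards = TRUE,
                             adversarial_decoys = FALSE,
                             intensity_sd = 0.15,
                             residual_precursor = 0.2) {
  stopifnot(mass_jitter_ppm >= 0, decoys_per_spectrum >= 0, isotope_peaks >= 1)
  structure(list(seed = as.integer(seed), mass_jitter_ppm = mass_jitter_ppm,
                 decoys_per_spectrum = as.integer(decoys_per_spectrum),
                 isotope_peaks = as.integer(isotope_peaks),
                 include_standards = include_standards,
                 adversarial_decoys = adversarial_decoys,
                 intensity_sd = intensity_sd,
                 residual_precursor = residual_precursor),
            class = "generator_config")
}

# family intensity profiles (fraction of the MS2 base peak) encoding the
# qualitative reporting: the C diagnostic is intense while the RDA-type
# ions appear in C spectra only at much lower intensity, and vice versa.
.INTENSITY_PROFILES <- list(
  A = c(ch2n2_loss = 0.9, alkyl_chain_loss = 0.7, guanidinoalkyl = 1.0,
        guanidinoalkyl_dehydrated = 0.35, core_ester_cleavage = 0.25,
        ch2n2_loss_1plus = 0.05),
  didehydroA = c(ch2n2_loss = 0.9, alkyl_chain_loss = 0.7,
                 guanidinoalkyl = 1.0, guanidinoalkyl_dehydrated = 0.4,
                 ch2n2_loss_1plus = 0.05),
  A3 = c(ch2n2_loss = 0.9, alkyl_chain_loss = 0.7, guanidinoalkyl = 1.0,
         guanidinoalkyl_dehydrated = 0.5, a3_core = 0.4,
         ch2n2_loss_1plus = 0.05),
  B = c(rda_upper = 1.0, rda_lower = 0.8, rda_upper_ch2n2 = 0.5,
        spiroaminal = 0.6, guanidinoalkyl = 0.7,
        guanidinoalkyl_dehydrated = 0.3),
  B3 = c(rda_upper = 1.0, rda_lower = 0.8, rda_upper_ch2n2 = 0.5,
         spiroaminal = 0.6, guanidinoalkyl = 0.7,
         guanidinoalkyl_dehydrated = 0.3),
  C = c(c_diagnostic = 1.0, guanidinoalkyl = 0.8,
        guanidinoalkyl_dehydrated = 0.3),
  C3 = c(c_diagnostic = 1.0, guanidinoalkyl = 0.8,
         guanidinoalkyl_dehydrated = 0.3))

# B-type shadow ions present in C-family spectra at low intensity
.C_SHADOW_LEVEL <- 0.08

.jitter_mz <- function(mz, jitter_ppm) {
  if (jitter_ppm <= 0) return(mz)
  dev <- stats::rnorm(length(mz), 0, jitter_ppm / 2)
  dev <- pmin(pmax(dev, -jitter_ppm), jitter_ppm)
  mz * (1 + dev * 1e-6)
}

.planted_rules <- function(compound, config, table) {
  extra <- NULL
  if (compound$kind == "series") {
    rules <- diagnostic_fragments(compound$subfamily, compound$m,
                                  if (is.na(compound$n)) NULL else compound$n,
                                  config, table)
    prof <- .INTENSITY_PROFILES[[compound$subfamily]]
    rules$rel <- unname(prof[rules$role])
    if (compound$subfamily %in% c("C", "C3")) {
      shadow <- diagnostic_fragments(
        if (compound$subfamily == "C") "B" else "B3",
        compound$m, if (is.na(compound$n)) NULL else compound$n,
        config, table)
      shadow$rel <- .C_SHADOW_LEVEL
      shadow <- shadow[!shadow$role %in% rules$role, , drop = FALSE]
      extra <- shadow
    }
  } else if (compound$kind == "crambescidin" &&
             !identical(compound$name, "crambescidin acid")) {
    rules <- .marker_ions(table)
    rules$rel <- c(1.0, 0.6, 0.8)
  } else {
    rules <- data.frame(role = character(0), cation = character(0),
                        z = integer(0), weight = numeric(0), mz = numeric(0),
                        rel = numeric(0))
  }
  rbind(rules, extra)
}

#' Simulate one compound's feature and MS2 spectrum
#'
#' The precursor appears at its theoretical m/z (for the compound's
#' charge state) with truncated-Gaussian ppm jitter; MS2 peaks are placed
#' at each diagnostic fragment's theoretical m/z with the family
#' intensity profile (C-family spectra carry the B-type ions at low
#' intensity); `extra_mz` peaks (e.g. literature fragments of closed-list
#' entries) are added verbatim; decoy peaks are drawn uniformly over m/z
#' 60 to the precursor, avoiding (or, in adversarial mode, targeting)
#' diagnostic windows.
#'
#' @param compound one manifest row (see [paperlike_manifest()]): needs
#'   `kind`, `subfamily`, `m`, `n`, `formula`, `name`, `rt`, `z`,
#'   `intensity`, optionally `extra_mz`.
#' @param cfg a [generator_config()]. Randomness is drawn from the
#'   current RNG state; seed at the run level.
#' @param config,table library configuration and mass table.
#' @return list with `feature` (one-row data.frame) and `spectrum`
#'   ([ms2_spectrum()]).
#' @export
generate_spectrum <- function(compound, cfg = generator_config(),
                              config = library_config(),
                              table = mass_table("paper")) {
  proton_mass <- table[["H"]]
  z <- compound$z
  mass <- monoisotopic_mass(compound$formula, table)
  prec_theor <- (mass + z * proton_mass) / z
  prec_mz <- .jitter_mz(prec_theor, cfg$mass_jitter_ppm)
  base_int <- compound$intensity * stats::rlnorm(1, 0, cfg$intensity_sd)

  rules <- .planted_rules(compound, config, table)
  rel <- if (nrow(rules)) {
    rules$rel * stats::rlnorm(nrow(rules), 0, cfg$intensity_sd)
  } else numeric(0)
  frag_mz <- .jitter_mz(rules$mz, cfg$mass_jitter_ppm)
  frag_int <- rel * base_int

  extra_mz <- compound$extra_mz[[1]]
  if (!is.null(extra_mz) && length(extra_mz)) {
    keep <- !vapply(extra_mz, function(x) any(abs(x - rules$mz) < 0.01),
                    logical(1))
    extra_mz <- extra_mz[keep]
    frag_mz <- c(frag_mz, .jitter_mz(extra_mz, cfg$mass_jitter_ppm))
    frag_int <- c(frag_int,
                  0.4 * base_int * stats::rlnorm(length(extra_mz), 0,
                                                 cfg$intensity_sd))
  }

  # residual precursor and its co-isolated first isotope
  if (cfg$residual_precursor > 0) {
    frag_mz <- c(frag_mz, prec_mz, prec_mz + .ISOTOPE_SPACING / z)
    frag_int <- c(frag_int, cfg$residual_precursor * base_int,
                  0.4 * cfg$residual_precursor * base_int)
  }

  if (cfg$decoys_per_spectrum > 0) {
    protected <- c(rules$mz, prec_theor, prec_theor + .ISOTOPE_SPACING / z)
    decoys <- numeric(0)
    guard <- 0L
    while (length(decoys) < cfg$decoys_per_spectrum && guard < 1000L) {
      guard <- guard + 1L
      cand <- stats::runif(1, 60, max(100, prec_mz))
      inside <- any(abs(cand - protected) <=
                      pmax(5e-6 * protected, 0.002) + 0.008)
      if (cfg$adversarial_decoys) {
        # place the decoy inside a diagnostic window to stress matching
        tgt <- protected[1 + (guard %% length(protected))]
        cand <- tgt * (1 + stats::runif(1, -4e-6, 4e-6))
        inside <- FALSE
      }
      if (!inside) decoys <- c(decoys, cand)
    }
    frag_mz <- c(frag_mz, decoys)
    frag_int <- c(frag_int,
                  stats::runif(length(decoys), 0.02, 0.15) * base_int)
  }

  feature <- data.frame(feature_id = NA_integer_, mz = prec_mz,
                        rt = compound$rt, z = z, intensity = base_int,
                        stringsAsFactors = FALSE)
  spectrum <- ms2_spectrum(prec_mz, mz = frag_mz, intensity = frag_int,
                           precursor_z = z, rt = compound$rt,
                           id = compound$name)
  list(feature = feature, spectrum = spectrum)
}

#' The paper-like manifest
#'
#' The 53 reported compounds (39 crambescins, 8 crambescidins, 4 small
#' guanidine compounds plus the crambescidin acid and the two minor
#' crambescins) with their reference retention times and charge states;
#' the two internal standards are appended by [generate_run()] when
#' enabled. Literature fragment m/z values of closed-list entries are
#' carried as `extra_mz` so their spectra are distinguishable. Rows that
#' shared a consensus feature in the reference table are planted at a
#' small RT offset as their own features (co-eluting isobar stress case).
#'
#' @return data.frame manifest, one row per planted compound.
#' @export
paperlike_manifest <- function() {
  tab <- reference_compounds()
  cmp <- tab[tab$kind != "standard", , drop = FALSE]
  rt <- cmp$rt
  z <- cmp$z
  for (i in which(is.na(rt))) {
    rt[i] <- rt[i - 1] + 0.03
    z[i] <- z[i - 1]
  }
  data.frame(
    id = cmp$row, kind = cmp$kind, subfamily = cmp$subfamily,
    m = cmp$m, n = cmp$n, formula = cmp$formula,
    name = cmp$identification, rt = rt, z = z,
    intensity = 1e6,
    extra_mz = I(lapply(seq_len(nrow(cmp)), function(i) {
      if (cmp$kind[i] == "series") numeric(0) else cmp$fragments[[i]]$mz
    })),
    stringsAsFactors = FALSE)
}

#' Manifest covering the full crambescin grid
#'
#' One entry per (sub-family, m, n) over the library ranges; used for the
#' forward-inverse consistency tests and the networking stage.
#'
#' @param config library configuration.
#' @param subfamilies which sub-families to include.
#' @param table mass table.
#' @return manifest data.frame with a `sidechain_type` column.
#' @export
grid_manifest <- function(config = library_config(),
                          subfamilies = names(config$series),
                          table = mass_table("paper")) {
  lib <- build_library(config, table = table)
  lib <- lib[lib$kind == "series" & lib$subfamily %in% subfamilies, ,
             drop = FALSE]
  rt <- seq(8, 14, length.out = nrow(lib))
  data.frame(
    id = sprintf("grid_%03d", seq_len(nrow(lib))),
    kind = "series", subfamily = lib$subfamily, m = lib$m, n = lib$n,
    formula = lib$formula, name = lib$name, rt = rt, z = 2L,
    intensity = 1e6,
    sidechain_type = mapply(function(sf, m, n) {
      sidechain_type(sf, m, if (is.na(n)) NULL else n)
    }, lib$subfamily, lib$m, lib$n, USE.NAMES = FALSE),
    extra_mz = I(replicate(nrow(lib), numeric(0), simplify = FALSE)),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic run
#'
#' Seeds the RNG from the configuration, simulates every manifest
#' compound (plus internal standards when enabled), and returns the
#' feature table with linked spectra and the ground-truth manifest.
#' Co-eluting compounds (RT within 0.02 min at the same m/z) are allowed
#' and warned about. With `out_dir` set, the run is also written to disk
#' as MGF, feature TSV and manifest TSV (and mzML when `write_mzml` is
#' TRUE and \pkg{mzR} is available).
#'
#' @param manifest data.frame as [paperlike_manifest()] or
#'   [grid_manifest()].
#' @param cfg a [generator_config()].
#' @param out_dir optional output directory.
#' @param write_mzml also write an mzML file with synthetic MS1 scans.
#' @param config,table library configuration and mass table.
#' @return list of class `synthetic_run` with `features` (including an
#'   `ms2` list column), `spectra`, `manifest`, `cfg`.
#' @export
generate_run <- function(manifest, cfg = generator_config(), out_dir = NULL,
                         write_mzml = FALSE, config = library_config(),
                         table = mass_table("paper")) {
  stopifnot(nrow(manifest) > 0)
  set.seed(cfg$seed)
  manifest <- manifest[order(manifest$rt, manifest$name, method = "radix"), ,
                       drop = FALSE]
  if (cfg$include_standards) {
    st <- do.call(rbind, lapply(config$standards, function(s) data.frame(
      id = s$name, kind = "standard", subfamily = NA_character_,
      m = NA_integer_, n = NA_integer_,
      formula = formula_string(s$formula), name = s$name, rt = s$rt, z = 1L,
      intensity = 5e6, extra_mz = I(list(numeric(0))),
      stringsAsFactors = FALSE)))
    keep <- intersect(names(manifest), names(st))
    manifest <- rbind(manifest[, keep, drop = FALSE], st[, keep, drop = FALSE])
    manifest <- manifest[order(manifest$rt, manifest$name, method = "radix"), ,
                         drop = FALSE]
  }
  sims <- lapply(seq_len(nrow(manifest)), function(i) {
    generate_spectrum(manifest[i, , drop = FALSE], cfg, config, table)
  })
  features <- do.call(rbind, lapply(sims, `[[`, "feature"))
  features$feature_id <- seq_len(nrow(features))
  spectra <- lapply(sims, `[[`, "spectrum")
  dup <- which(duplicated(round(features$mz, 2)) &
                 duplicated(round(features$rt / 0.02)))
  if (length(dup)) {
    warning(sprintf("%d co-eluting compound(s) share a feature window",
                    length(dup)))
  }
  features$ms2 <- spectra
  run <- structure(list(features = features, spectra = spectra,
                        manifest = manifest, cfg = cfg),
                   class = "synthetic_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_mgf(spectra, file.path(out_dir, "run.mgf"))
    utils::write.table(features[, setdiff(names(features), "ms2")],
                       file.path(out_dir, "features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    man_out <- manifest[, setdiff(names(manifest), "extra_mz")]
    man_out$seed <- cfg$seed
    utils::write.table(man_out, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (write_mzml) {
      ms1 <- build_ms1_scans(run, table = table)
      write_mzml(ms1, spectra, file.path(out_dir, "run.mzML"))
    }
  }
  run
}

#' Score annotations against a run's ground truth
#'
#' For every planted crambescin series member, checks whether the
#' top-ranked annotation of its feature recovers the true
#' (sub-family, m, n); B/C-type members are additionally scored for
#' correct sub-family discrimination.
#'
#' @param run a [generate_run()] result (manifest order matches feature
#'   ids).
#' @param annotations output of [annotate_run()] on `run$features`.
#' @return list with `n_series`, `n_correct`, `recovery`, `n_bc`,
#'   `n_bc_correct`, `bc_accuracy`, and a per-compound `detail` table.
#' @export
score_annotations <- function(run, annotations) {
  man <- run$manifest
  detail <- list()
  for (i in seq_len(nrow(man))) {
    if (man$kind[i] != "series") next
    ai <- annotations[annotations$feature_id == run$features$feature_id[i], ,
                      drop = FALSE]
    got <- nrow(ai) == 1 && !is.na(ai$subfamily)
    correct <- got && ai$subfamily == man$subfamily[i] &&
      ai$m == man$m[i] &&
      (is.na(man$n[i]) || (!is.na(ai$n) && ai$n == man$n[i]))
    detail[[length(detail) + 1L]] <- data.frame(
      id = man$id[i], subfamily = man$subfamily[i], m = man$m[i],
      n = man$n[i],
      annotated = if (got) ai$name else NA_character_,
      correct = correct,
      bc_member = man$subfamily[i] %in% c("B", "C", "B3", "C3"),
      bc_correct = got && ai$subfamily == man$subfamily[i],
      stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, detail)
  list(n_series = nrow(d), n_correct = sum(d$correct),
       recovery = mean(d$correct),
       n_bc = sum(d$bc_member),
       n_bc_correct = sum(d$bc_correct[d$bc_member]),
       bc_accuracy = mean(d$bc_correct[d$bc_member]),
       detail = d)
}

#' Synthesise MS1 scans for a run
#'
#' Renders each feature as an isotope envelope (1/z spacing, geometric
#' intensity decay) over a few consecutive scans around its apex with a
#' triangular elution profile — enough chromatographic structure for the
#' feature-assembly stage to be exercised end to end.
#'
#' @param run a [generate_run()] result.
#' @param scan_interval MS1 scan spacing in minutes.
#' @param envelope_scans scans across the elution profile.
#' @param table mass table.
#' @return list of MS1 scan data.frames with `rt` attributes (minutes).
#' @export
build_ms1_scans <- function(run, scan_interval = 0.05, envelope_scans = 5L,
                            table = mass_table("paper")) {
  feats <- run$features
  rts <- seq(min(feats$rt) - 0.2, max(feats$rt) + 0.2, by = scan_interval)
  half <- (envelope_scans - 1) / 2
  scans <- lapply(rts, function(rt) {
    mz <- numeric(0); int <- numeric(0)
    for (i in seq_len(nrow(feats))) {
      d <- abs(rt - feats$rt[i]) / scan_interval
      if (d > half) next
      scale <- 1 - d / (half + 1)
      iso <- 0:(run$cfg$isotope_peaks - 1)
      mz <- c(mz, feats$mz[i] + iso * .ISOTOPE_SPACING / feats$z[i])
      int <- c(int, feats$intensity[i] * scale * 0.55^iso)
    }
    ord <- order(mz)
    d <- data.frame(mz = mz[ord], intensity = int[ord])
    attr(d, "rt") <- rt
    d
  })
  scans[vapply(scans, nrow, integer(1)) > 0]
}
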