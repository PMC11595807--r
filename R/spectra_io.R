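#' @title Spectral I/O, feature assembly and QC
#' @name spectra_io
#' @description
#' Readers/writers for centroided spectra (MGF natively, mzML through
#' \pkg{mzR}), simplified MS1 feature assembly (5 ppm m/z grouping with
#' contiguous retention time, apex = maximum intensity), charge inference
#' from isotope spacing, MS2-to-feature linking, and a QC check against
#' the spiked internal standards.
NULL

#' Construct an MS2 spectrum
#'
#' @param precursor_mz precursor m/z (Th), positive.
#' @param mz,intensity fragment peak vectors (same length); stored sorted
#'   by m/z.
#' @param precursor_z optional precursor charge.
#' @param rt retention time in minutes.
#' @param id optional identifier.
#' @return list of class `ms2_spectrum`.
#' @export
ms2_spectrum <- function(precursor_mz, mz = numeric(0), intensity = numeric(0),
                         precursor_z = NA_integer_, rt = NA_real_, id = NULL) {
  stopifnot(precursor_mz > 0, length(mz) == length(intensity))
  if (any(mz <= 0)) stop("fragment m/z must be positive")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  ord <- order(mz)
  structure(list(precursor_mz = precursor_mz,
                 precursor_z = as.integer(precursor_z),
                 rt = rt, mz = mz[ord], intensity = intensity[ord],
                 id = id),
            class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("<ms2_spectrum> precursor %.4f (%s+) rt %.2f min, %d peaks\n",
              x$precursor_mz,
              if (is.na(x$precursor_z)) "?" else x$precursor_z,
              x$rt, length(x$mz)))
  invisible(x)
}

# ---- MGF ------------------------------------------------------------------

#' Read an MGF file
#'
#' One spectrum per BEGIN IONS/END IONS block with PEPMASS, optional
#' CHARGE (`2+` style) and RTINSECONDS.
#'
#' @param path MGF file path.
#' @return list of [ms2_spectrum()] objects.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("BEGIN IONS", lines, fixed = TRUE))) {
    stop("no spectra found in MGF file: ", path)
  }
  starts <- grep("^BEGIN IONS", lines)
  ends <- grep("^END IONS", lines)
  if (length(starts) != length(ends)) stop("unbalanced BEGIN/END IONS blocks")
  lapply(seq_along(starts), function(k) {
    block <- lines[(starts[k] + 1L):(ends[k] - 1L)]
    kv <- grepl("=", block, fixed = TRUE)
    meta <- strsplit(block[kv], "=", fixed = TRUE)
    keys <- toupper(vapply(meta, `[`, "", 1L))
    vals <- vapply(meta, function(p) paste(p[-1L], collapse = "="), "")
    peaks <- block[!kv & nzchar(trimws(block))]
    pm <- do.call(rbind, strsplit(trimws(peaks), "[[:space:]]+"))
    pepmass <- as.numeric(strsplit(vals[keys == "PEPMASS"][1], "[[:space:]]+")[[1]][1])
    zc <- vals[keys == "CHARGE"]
    z <- if (length(zc)) as.integer(sub("\\+$", "", zc[1])) else NA_integer_
    rts <- vals[keys == "RTINSECONDS"]
    rt <- if (length(rts)) as.numeric(rts[1]) / 60 else NA_real_
    idv <- vals[keys == "TITLE"]
    ms2_spectrum(pepmass,
                 mz = if (length(peaks)) as.numeric(pm[, 1]) else numeric(0),
                 intensity = if (length(peaks)) as.numeric(pm[, 2]) else numeric(0),
                 precursor_z = z, rt = rt,
                 id = if (length(idv)) idv[1] else NULL)
  })
}

#' Write spectra to an MGF file
#'
#' @param spectra list of [ms2_spectrum()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    if (!is.null(s$id)) writeLines(paste0("TITLE=", s$id), con)
    writeLines(sprintf("PEPMASS=%.4f", s$precursor_mz), con)
    if (!is.na(s$precursor_z)) writeLines(sprintf("CHARGE=%d+", s$precursor_z), con)
    if (!is.na(s$rt)) writeLines(sprintf("RTINSECONDS=%.2f", s$rt * 60), con)
    if (length(s$mz)) {
      writeLines(sprintf("%.4f %.6g", s$mz, s$intensity), con)
    }
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

# ---- mzML (via mzR) -------------------------------------------------------

.require_mzr <- function() {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("mzML support requires the 'mzR' package")
  }
}

#' Read a centroided mzML file
#'
#' @param path mzML file.
#' @return list with `ms1` (list of data.frames `mz`, `intensity`, plus an
#'   `rt` attribute in minutes) and `ms2` (list of [ms2_spectrum()]).
#'   Profile-mode scans are rejected.
#' @export
read_mzml <- function(path) {
  .require_mzr()
  if (!file.exists(path)) stop("file not found: ", path)
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h))
  hdr <- mzR::header(h)
  if (nrow(hdr) == 0) stop("no spectra found in mzML file: ", path)
  if (any(!is.na(hdr$centroided) & !hdr$centroided)) {
    stop("profile-mode data are not supported; centroid before import")
  }
  pk <- mzR::peaks(h)
  if (is.matrix(pk)) pk <- list(pk)
  ms1 <- list(); ms2 <- list()
  for (i in seq_len(nrow(hdr))) {
    m <- pk[[i]]
    if (hdr$msLevel[i] == 1L) {
      d <- data.frame(mz = m[, 1], intensity = m[, 2])
      attr(d, "rt") <- hdr$retentionTime[i] / 60
      ms1[[length(ms1) + 1L]] <- d
    } else {
      z <- hdr$precursorCharge[i]
      ms2[[length(ms2) + 1L]] <- ms2_spectrum(
        hdr$precursorMZ[i], mz = m[, 1], intensity = m[, 2],
        precursor_z = if (is.na(z) || z == 0) NA_integer_ else z,
        rt = hdr$retentionTime[i] / 60,
        id = as.character(hdr$spectrumId[i]))
    }
  }
  list(ms1 = ms1, ms2 = ms2)
}

#' Write MS1 scans and MS2 spectra to mzML
#'
#' @param ms1 list of MS1 scan data.frames (`mz`, `intensity`) each with
#'   an `rt` attribute in minutes; may be empty.
#' @param ms2 list of [ms2_spectrum()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(ms1, ms2, path) {
  .require_mzr()
  scans <- list(); rows <- list()
  add <- function(mat, level, rt, prec_mz = NA_real_, prec_z = NA_integer_,
                  prec_int = NA_real_) {
    i <- length(scans) + 1L
    scans[[i]] <<- mat
    bp <- if (nrow(mat)) which.max(mat[, 2]) else NA_integer_
    rows[[i]] <<- data.frame(
      seqNum = i, acquisitionNum = i, msLevel = level, polarity = 1L,
      peaksCount = nrow(mat), totIonCurrent = sum(mat[, 2]),
      retentionTime = rt * 60,
      basePeakMZ = if (is.na(bp)) 0 else mat[bp, 1],
      basePeakIntensity = if (is.na(bp)) 0 else mat[bp, 2],
      collisionEnergy = if (level == 2L) 35 else NA_real_,
      ionisationEnergy = 0,
      lowMZ = if (nrow(mat)) min(mat[, 1]) else 0,
      highMZ = if (nrow(mat)) max(mat[, 1]) else 0,
      precursorScanNum = NA_integer_, precursorMZ = prec_mz,
      precursorCharge = prec_z, precursorIntensity = prec_int,
      mergedScan = NA_integer_, mergedResultScanNum = NA_integer_,
      mergedResultStartScanNum = NA_integer_, mergedResultEndScanNum = NA_integer_,
      injectionTime = 0, filterString = NA_character_,
      spectrumId = paste0("scan=", i), centroided = TRUE,
      ionMobilityDriftTime = NA_real_,
      isolationWindowTargetMZ = prec_mz,
      isolationWindowLowerOffset = if (is.na(prec_mz)) NA_real_ else 1,
      isolationWindowUpperOffset = if (is.na(prec_mz)) NA_real_ else 1,
      scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_)
  }
  for (d in ms1) {
    add(cbind(mz = d$mz, intensity = d$intensity), 1L, attr(d, "rt"))
  }
  for (s in ms2) {
    add(cbind(mz = s$mz, intensity = s$intensity), 2L, s$rt,
        prec_mz = s$precursor_mz,
        prec_z = if (is.na(s$precursor_z)) NA_integer_ else s$precursor_z,
        prec_int = 0)
  }
  if (!length(scans)) stop("nothing to write")
  hdr <- do.call(rbind, rows)
  # mzML scans must be RT-ordered
  ord <- order(hdr$retentionTime, hdr$msLevel, method = "radix")
  hdr <- hdr[ord, , drop = FALSE]
  hdr$seqNum <- seq_len(nrow(hdr))
  hdr$acquisitionNum <- seq_len(nrow(hdr))
  hdr$spectrumId <- paste0("scan=", hdr$seqNum)
  mzR::writeMSData(scans[ord], file = path, header = hdr)
  invisible(path)
}

#' Read spectra from MGF or mzML
#'
#' @param path input file; format inferred from the extension unless given.
#' @param format `"auto"`, `"mgf"` or `"mzml"`.
#' @return As [read_mzml()]; for MGF input `ms1` is an empty list.
#' @export
read_spectra <- function(path, format = c("auto", "mgf", "mzml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mgf$", path, ignore.case = TRUE)) "mgf" else "mzml"
  }
  if (format == "mgf") {
    list(ms1 = list(), ms2 = read_mgf(path))
  } else {
    read_mzml(path)
  }
}

# ---- charge inference and feature assembly --------------------------------

#' Infer charge state from an isotope envelope
#'
#' The median spacing of consecutive isotope peaks is compared with 1/z
#' for z = 1..`max_z`; ties are broken toward the lower charge. Returns
#' `NA` when fewer than two peaks are supplied or no spacing is consistent
#' within `tol` (the feature is kept but flagged undetermined).
#'
#' @param mz isotope peak m/z values (>= 2 peaks for a determined charge).
#' @param tol spacing tolerance in Da (default 0.01, suitable for
#'   70,000-resolution centroids).
#' @param max_z maximum charge considered.
#' @return integer charge or `NA`.
#' @export
infer_charge <- function(mz, tol = 0.01, max_z = 3L) {
  mz <- sort(mz)
  if (length(mz) < 2) return(NA_integer_)
  spacing <- stats::median(diff(mz))
  for (z in seq_len(max_z)) {   # ascending: ties resolve to lower z
    if (abs(spacing - .ISOTOPE_SPACING / z) <= tol) return(as.integer(z))
  }
  NA_integer_
}

#' Assemble MS1 features from centroided scans
#'
#' Simplified feature finding: centroids are grouped into mass traces
#' within `ppm_tol`, traces are split at retention-time gaps larger than
#' `rt_gap`, and each monoisotopic trace is reported with its apex
#' (maximum-intensity) RT and intensity. Traces separated by the isotope
#' spacing at the same apex are collapsed into one feature whose charge is
#' taken from the spacing via [infer_charge()].
#'
#' @param ms1 list of MS1 scans as returned by [read_mzml()].
#' @param ppm_tol m/z grouping tolerance (ppm).
#' @param rt_gap maximum RT gap within a trace (minutes).
#' @param min_points minimum scans per trace.
#' @param iso_tol isotope-spacing tolerance (Da).
#' @return data.frame with `feature_id`, `mz`, `rt`, `z` (NA when
#'   undetermined), `intensity`, `n_isotopes`.
#' @export
assemble_features <- function(ms1, ppm_tol = 5, rt_gap = 0.2, min_points = 1L,
                              iso_tol = 0.01) {
  pts <- do.call(rbind, lapply(ms1, function(d) {
    data.frame(rt = attr(d, "rt"), mz = d$mz, intensity = d$intensity)
  }))
  empty <- data.frame(feature_id = integer(0), mz = numeric(0), rt = numeric(0),
                      z = integer(0), intensity = numeric(0),
                      n_isotopes = integer(0))
  if (is.null(pts) || nrow(pts) == 0) return(empty)
  pts <- pts[order(pts$mz, method = "radix"), , drop = FALSE]
  gap <- c(FALSE, diff(pts$mz) > pmax(ppm_tol * 1e-6 * pts$mz[-nrow(pts)], 1e-4))
  grp <- cumsum(gap)
  traces <- lapply(split(pts, grp), function(d) {
    d <- d[order(d$rt, method = "radix"), , drop = FALSE]
    sub <- cumsum(c(FALSE, diff(d$rt) > rt_gap))
    lapply(split(d, sub), identity)
  })
  traces <- unlist(traces, recursive = FALSE)
  traces <- Filter(function(d) nrow(d) >= min_points, traces)
  if (!length(traces)) return(empty)
  tr <- do.call(rbind, lapply(traces, function(d) {
    apex <- which.max(d$intensity)
    data.frame(mz = sum(d$mz * d$intensity) / sum(d$intensity),
               rt = d$rt[apex], intensity = max(d$intensity))
  }))
  tr <- tr[order(tr$mz, method = "radix"), , drop = FALSE]
  used <- rep(FALSE, nrow(tr))
  feats <- list()
  for (i in seq_len(nrow(tr))) {
    if (used[i]) next
    env <- i
    # greedily extend the envelope upward at 1, 1/2 or 1/3 Da spacing
    for (z_try in c(3L, 2L, 1L)) {
      step <- .ISOTOPE_SPACING / z_try
      cur <- tr$mz[i]; envz <- i
      repeat {
        nxt <- which(!used & abs(tr$mz - (cur + step)) <= iso_tol &
                       abs(tr$rt - tr$rt[i]) <= 0.1)
        if (!length(nxt)) break
        nxt <- nxt[which.max(tr$intensity[nxt])]
        envz <- c(envz, nxt); cur <- tr$mz[nxt]
      }
      if (length(envz) > length(env)) env <- envz
    }
    used[env] <- TRUE
    feats[[length(feats) + 1L]] <- data.frame(
      mz = tr$mz[i], rt = tr$rt[i],
      z = infer_charge(tr$mz[env], tol = iso_tol),
      intensity = tr$intensity[i], n_isotopes = length(env))
  }
  out <- do.call(rbind, feats)
  out <- out[order(out$rt, out$mz, method = "radix"), , drop = FALSE]
  out <- cbind(feature_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Link MS2 spectra to features
#'
#' Each MS2 scan is attached to the nearest feature whose m/z lies within
#' `mz_tol` (the precursor tolerance) and RT within `rt_tol`.
#'
#' @param features feature table from [assemble_features()].
#' @param spectra list of [ms2_spectrum()].
#' @param mz_tol precursor m/z tolerance (Da).
#' @param rt_tol retention-time tolerance (minutes).
#' @return `features` with a `ms2` list column (NULL where unlinked).
#' @export
link_ms2 <- function(features, spectra, mz_tol = 0.02, rt_tol = 0.2) {
  slots <- vector("list", nrow(features))
  for (s in spectra) {
    dmz <- abs(features$mz - s$precursor_mz)
    drt <- abs(features$rt - s$rt)
    ok <- which(dmz <= mz_tol & (is.na(drt) | drt <= rt_tol))
    if (!length(ok)) next
    best <- ok[which.min(dmz[ok])]
    if (is.null(slots[[best]]) ||
        max(s$intensity, 0) > max(slots[[best]]$intensity, 0)) {
      slots[[best]] <- s
    }
  }
  features$ms2 <- slots
  features
}

#' QC against the spiked internal standards
#'
#' Checks that the [M+H]+ ions of yohimbine and reserpine are present
#' within `tol_ppm` of their theoretical m/z. Absence is reported, not
#' raised.
#'
#' @param features feature table (needs `mz`, and optionally `rt`).
#' @param tol_ppm mass tolerance (ppm).
#' @param config library configuration (provides the standards).
#' @param table mass table.
#' @return data.frame with one row per standard: expected and observed
#'   m/z, observed ppm error, RT, and `pass`.
#' @export
qc_internal_standards <- function(features, tol_ppm = 5,
                                  config = library_config(),
                                  table = mass_table("paper")) {
  proton <- chem_formula(c(H = 1))
  out <- lapply(config$standards, function(st) {
    mz_theor <- theoretical_mz(formula_add(st$formula, proton), 1L, table)
    dppm <- 1e6 * (features$mz - mz_theor) / mz_theor
    hit <- which(abs(dppm) <= tol_ppm)
    if (length(hit)) {
      hit <- hit[which.max(features$intensity[hit])]
      data.frame(standard = st$name, mz_expected = round_half_up(mz_theor, 4),
                 mz_observed = features$mz[hit],
                 ppm = round_half_up(dppm[hit], 2),
                 rt = features$rt[hit], pass = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      near <- if (nrow(features)) which.min(abs(dppm)) else integer(0)
      data.frame(standard = st$name, mz_expected = round_half_up(mz_theor, 4),
                 mz_observed = if (length(near)) features$mz[near] else NA_real_,
                 ppm = if (length(near)) round_half_up(dppm[near], 2) else NA_real_,
                 rt = if (length(near)) features$rt[near] else NA_real_,
                 pass = FALSE, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}
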