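#!/usr/bin/env Rscript
# Step 4 — desk validation against the published reference table.
#
# Recomputes the experimental molecular weights and ppm errors of every
# reported feature from its printed (m/z, z, formula), regenerates each
# crambescin formula from its (sub-family, m, n), and measures fragment
# coverage of the diagnostic rule set; writes the comparison tables.

suppressMessages(library(CrambeDerep))
dir.create("results", showWarnings = FALSE)

arith <- recompute_reference_arithmetic()
utils::write.table(arith, "results/reference_arithmetic.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sprintf("mass arithmetic: %d rows, max |ppm dev| = %.2f, max |Mw dev| = %.4f Da",
                nrow(arith), max(abs(arith$ppm_diff)),
                max(abs(arith$mw_diff))))

ref <- reference_compounds()
ser <- ref[ref$kind == "series", ]
ok <- vapply(seq_len(nrow(ser)), function(i) {
  formula_string(series_formula(ser$subfamily[i], ser$m[i],
                                if (is.na(ser$n[i])) NULL else ser$n[i])) ==
    ser$formula[i]
}, logical(1))
message(sprintf("series formulas regenerated: %d/%d", sum(ok), nrow(ser)))

cfgL <- library_config()
rows <- list()
for (i in seq_len(nrow(ser))) {
  ions <- do.call(rbind, lapply(names(cfgL$series), function(sf) {
    fixed <- sf %in% c("A3", "B3", "C3")
    tryCatch(diagnostic_fragments(sf, ser$m[i],
                                  if (fixed) NULL else ser$n[i]),
             error = function(e) NULL)
  }))
  fr <- ser$fragments[[i]]
  for (j in seq_len(nrow(fr))) {
    tol <- pmax(5e-6 * ions$mz, ifelse(ions$mz < 400, 0.002, 0))
    hit <- which(abs(fr$mz[j] - ions$mz) <= tol)
    best <- if (length(hit)) hit[which.min(abs(fr$mz[j] - ions$mz[hit]))] else NA
    rows[[length(rows) + 1L]] <- data.frame(
      row = ser$row[i], mz_printed = fr$mz[j],
      matched = length(hit) > 0,
      role = if (length(hit)) ions$role[best] else NA_character_,
      cation = if (length(hit)) ions$cation[best] else NA_character_,
      mz_theor = if (length(hit)) round_half_up(ions$mz[best], 4) else NA_real_)
  }
}
cov <- do.call(rbind, rows)
utils::write.table(cov, "results/fragment_coverage.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sprintf("fragment coverage: %d/%d printed fragments matched (%.1f%%)",
                sum(cov$matched), nrow(cov), 100 * mean(cov$matched)))
if (any(!cov$matched)) {
  message("unmatched: ",
          paste(sprintf("row %s %.4f", cov$row[!cov$matched],
                        cov$mz_printed[!cov$matched]), collapse = "; "))
}
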