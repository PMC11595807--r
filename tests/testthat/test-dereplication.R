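lib <- build_library()

test_that("reported crambescin A spectra annotate to their published identities", {
  # the most abundant metabolite: doubly charged ion at 225.1835
  rf <- reference_feature(225.1835, 2L, 11.70,
                         c(127.0863, 204.1721, 132.1130, 276.2321))
  ann <- annotate_feature(rf$feature, rf$spectrum, lib)
  expect_equal(ann$name[1], "crambescin A2 448")
  expect_equal(c(ann$m[1], ann$n[1]), c(2L, 8L))
  expect_lte(abs(ann$delta_ppm[1]), 5)

  # the new homologue with m = 5, n = 4
  rf8 <- reference_feature(218.1757, 2L, 10.87,
                          c(197.1646, 174.1600, 148.1095, 220.1689))
  ann8 <- annotate_feature(rf8$feature, rf8$spectrum, lib)
  expect_equal(ann8$name[1], "crambescin A 434 homologue (m = 5, n = 4)")
})

test_that("features without a library match return no annotation", {
  f <- data.frame(feature_id = 1L, mz = 999.9, rt = 5, z = 1L,
                  intensity = 1)
  ann <- annotate_feature(f, NULL, lib)
  expect_equal(nrow(ann), 0)
})

test_that("formula-only candidates are retained but flagged", {
  f <- data.frame(feature_id = 1L, mz = 225.1835, rt = 11.7, z = 2L,
                  intensity = 1)
  ann <- annotate_feature(f, NULL, lib)
  expect_gt(nrow(ann), 0)
  expect_true(all(ann$flag == "formula-only"))
})

test_that("B/C isobars are discriminated by diagnostic intensity, never merged", {
  f <- data.frame(feature_id = 1L, mz = 241.1961, rt = 11.24, z = 2L,
                  intensity = 1)
  # dominant doubly charged C diagnostic at 148.6021
  spC <- ms2_spectrum(241.1961, mz = c(174.1600, 148.6021, 198.1965, 284.1957),
                      intensity = c(80, 100, 8, 6), precursor_z = 2L)
  annC <- annotate_feature(f, spC, lib)
  expect_equal(annC$name[1], "crambescin C1 480")
  expect_gte(annC$bc_ratio[1], 0.5)

  # dominant RDA pair
  spB <- ms2_spectrum(241.1961, mz = c(156.1749, 111.0443, 174.1600,
                                       284.1957, 198.1965),
                      intensity = c(40, 50, 60, 80, 100), precursor_z = 2L)
  annB <- annotate_feature(f, spB, lib)
  expect_equal(annB$name[1], "crambescin B1 480")

  # neither diagnostic: undetermined, reported as one of B/C/"B or C"
  spU <- ms2_spectrum(241.1961, mz = c(174.1600, 111.0443),
                      intensity = c(100, 40), precursor_z = 2L)
  annU <- annotate_feature(f, spU, lib)
  expect_match(annU$name[1], "^crambescin (B or C|B1|C1|B |C )")
  top_bc <- annU[annU$subfamily %in% c("B", "C") & annU$m == 5, ]
  expect_true(all(top_bc$flag %in% c("B-or-C", "formula-only", "ok")))
  expect_true(any(grepl("B or C", annU$name)))
})

test_that("direct discrimination reports the intensity ratio and evidence", {
  spC <- ms2_spectrum(241.1961, mz = c(148.6021, 198.1965, 284.1957),
                      intensity = c(100, 5, 5), precursor_z = 2L)
  d <- discriminate_b_vs_c(spC, 5, 6)
  expect_equal(d$call, "C")
  expect_gt(d$ratio, 0.9)
  d2 <- discriminate_b_vs_c(ms2_spectrum(241.1961, mz = 174.16,
                                         intensity = 1, precursor_z = 2L),
                            5, 6)
  expect_equal(d2$call, "undetermined")
})

test_that("crambescidins need two of three marker ions for a named call", {
  rf <- reference_feature(273.2094, 3L, 11.84,
                         c(264.1707, 246.1587, 139.0751, 70.0657))
  ann <- annotate_feature(rf$feature, rf$spectrum, lib)
  expect_equal(ann$name[1], "crambescidin 816")
  expect_equal(ann$flag[1], "ok")
  expect_gte(ann$n_matched[1], 2)

  # formula match but no markers: formula-only flag
  rf2 <- reference_feature(273.2094, 3L, 11.84, c(500.1, 600.2))
  ann2 <- annotate_feature(rf2$feature, rf2$spectrum, lib)
  expect_equal(ann2$flag[ann2$name == "crambescidin 816"], "formula-only")

  # small guanidine compounds annotate by formula
  rf3 <- reference_feature(282.1806, 1L, 8.16, c(246.1587, 60.0562))
  ann3 <- annotate_feature(rf3$feature, rf3$spectrum, lib)
  expect_equal(ann3$name[1], "guanidine-related compound (C14H23N3O3)")
})

test_that("A3 isomer pairs are labelled cis before trans by elution", {
  ann <- data.frame(
    feature_id = 1:3, mz = c(263.1990, 263.1990, 225.1835),
    rt = c(12.03, 11.79, 11.7), z = 2L, mw_exp = 0,
    kind = "series", subfamily = c("A3", "A3", "A"),
    m = c(4L, 4L, 2L), n = c(NA, NA, 8L),
    formula = c("C30H48N6O2", "C30H48N6O2", "C24H44N6O2"),
    name = c("crambescin A3 524", "crambescin A3 524", "crambescin A2 448"),
    delta_ppm = 0, n_matched = 3L, n_rules = 5L, score = 3, flag = "ok",
    bc_ratio = NA_real_, fragments = "", rank = 1L,
    stringsAsFactors = FALSE)
  lab <- label_isomer_pairs(ann)
  expect_equal(lab$isomer[lab$rt == 11.79], "cis")
  expect_equal(lab$isomer[lab$rt == 12.03], "trans")
  expect_match(lab$name[lab$rt == 11.79], "\\(cis\\)$")
  expect_true(is.na(lab$isomer[3]))

  # singletons stay unlabelled; triples warn
  single <- ann[1, ]
  expect_true(is.na(label_isomer_pairs(single)$isomer))
  triple <- ann[c(1, 1, 2), ]
  triple$feature_id <- 1:3
  expect_warning(label_isomer_pairs(triple), "isomer labels omitted")
})

test_that("reports carry the published arithmetic and layout", {
  rf <- reference_feature(225.1835, 2L, 11.16,
                         c(204.1722, 188.1756, 155.1178, 220.1689))
  ann <- annotate_feature(rf$feature, rf$spectrum, lib)
  rep <- build_report(ann[1, ])
  expect_equal(rep$mw_exp, "448.3514")
  expect_equal(rep$delta_ppm, "-0.45")
  expect_equal(rep$z, 2L)
  expect_named(rep, c("index", "mz", "rt", "z", "mw_exp", "formula",
                      "delta_ppm", "fragments", "identification"))
  # at most four fragments are printed
  expect_lte(length(strsplit(rep$fragments, "; ")[[1]]), 4)
  # empty annotation set gives a header-only table
  expect_equal(nrow(build_report(ann[0, ])), 0)
})

test_that("identical inputs give byte-identical reports", {
  render <- function() {
    run <- suppressWarnings(
      generate_run(paperlike_manifest(), generator_config(seed = 21)))
    ann <- annotate_run(run$features, lib)
    path <- tempfile(fileext = ".tsv")
    write_report(build_report(ann), path)
    readBin(path, "raw", file.size(path))
  }
  expect_identical(render(), render())
})

test_that("noise-free spectra from the full grid annotate to their true identity", {
  man <- grid_manifest()
  cfg <- generator_config(seed = 3, mass_jitter_ppm = 0,
                          decoys_per_spectrum = 0, include_standards = FALSE)
  run <- suppressWarnings(generate_run(man, cfg))
  ann <- annotate_run(run$features, lib)
  sc <- score_annotations(run, ann)
  expect_equal(sc$n_series, nrow(man))
  expect_equal(sc$recovery, 1)
  expect_equal(sc$bc_accuracy, 1)
})
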