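#!/usr/bin/env Rscript
# Step 1 — simulate a paper-like LC-MS/MS run of the C. crambe extract.
#
# Plants the 53 reported compounds (plus the yohimbine/reserpine internal
# standards) with 3 ppm mass jitter and 10 decoy peaks per MS2 spectrum,
# and writes the run (MGF + feature table + ground-truth manifest + mzML
# with synthetic MS1 scans) under results/run/.

suppressMessages(library(CrambeDerep))

out_dir <- "results/run"
cfg <- generator_config(seed = 20260920L, mass_jitter_ppm = 3,
                        decoys_per_spectrum = 10L)
run <- suppressWarnings(
  generate_run(paperlike_manifest(), cfg, out_dir = out_dir,
               write_mzml = requireNamespace("mzR", quietly = TRUE)))

message(sprintf("planted %d compounds (%d crambescins, %d crambescidins, %d other)",
                nrow(run$manifest),
                sum(run$manifest$kind == "series"),
                sum(run$manifest$kind == "crambescidin"),
                sum(run$manifest$kind %in% c("guanidine", "standard"))))
message("run written to ", out_dir)
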