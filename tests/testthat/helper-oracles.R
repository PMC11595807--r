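# Independent oracles and small fixture builders used across tests.

# exhaustive-assignment modified cosine for small spectra: enumerates all
# one-to-one match sets (direct or precursor-shifted peaks), independent
# of the package's matching-based implementation
brute_force_cosine <- function(a, b, frag_tol = 0.02) {
  na <- sqrt(a$intensity); na <- na / sqrt(sum(na^2))
  nb <- sqrt(b$intensity); nb <- nb / sqrt(sum(nb^2))
  shift <- b$precursor_mz - a$precursor_mz
  ok <- function(i, j) {
    abs(a$mz[i] - b$mz[j]) <= frag_tol ||
      abs(a$mz[i] + shift - b$mz[j]) <= frag_tol
  }
  best <- 0; best_n <- 0L
  rec <- function(i, used, s, n) {
    if (i > length(a$mz)) {
      if (s > best) { best <<- s; best_n <<- n }
      return()
    }
    rec(i + 1L, used, s, n)
    for (j in seq_along(b$mz)) {
      if (!used[j] && ok(i, j)) {
        u <- used; u[j] <- TRUE
        rec(i + 1L, u, s + na[i] * nb[j], n + 1L)
      }
    }
  }
  rec(1L, rep(FALSE, length(b$mz)), 0, 0L)
  list(score = best, matched = best_n)
}

random_spectrum <- function(n_peaks, precursor = NULL) {
  ms2_spectrum(if (is.null(precursor)) runif(1, 200, 600) else precursor,
               mz = sort(runif(n_peaks, 60, 550)),
               intensity = runif(n_peaks, 1, 100))
}

# deterministic feature + spectrum pair built from printed fragment lists
reference_feature <- function(mz, z, rt, frag_mz, frag_int = NULL,
                              feature_id = 1L) {
  if (is.null(frag_int)) frag_int <- rev(seq_along(frag_mz)) * 10
  list(feature = data.frame(feature_id = feature_id, mz = mz, rt = rt,
                            z = z, intensity = 1e6),
       spectrum = ms2_spectrum(mz, mz = frag_mz, intensity = frag_int,
                               precursor_z = z, rt = rt))
}

run_recovery_trials <- function(n_runs, base_seed, lib,
                                cfg_args = list()) {
  totals <- c(ok = 0, tot = 0, bc_ok = 0, bc_tot = 0)
  for (k in seq_len(n_runs)) {
    cfg <- do.call(generator_config,
                   c(list(seed = base_seed + k), cfg_args))
    run <- suppressWarnings(generate_run(paperlike_manifest(), cfg))
    ann <- annotate_run(run$features, lib)
    sc <- score_annotations(run, ann)
    totals <- totals + c(sc$n_correct, sc$n_series,
                         sc$n_bc_correct, sc$n_bc)
  }
  totals
}
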