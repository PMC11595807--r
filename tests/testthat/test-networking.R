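test_that("modified cosine handles the degenerate cases", {
  a <- ms2_spectrum(300, mz = c(100, 150, 200), intensity = c(10, 20, 30))
  expect_equal(modified_cosine(a, a)$score, 1, tolerance = 1e-12)
  expect_equal(modified_cosine(a, a)$matched, 3L)
  b <- ms2_spectrum(300, mz = c(120, 170), intensity = c(5, 5))
  expect_equal(modified_cosine(a, b)$score, 0)
  empty <- ms2_spectrum(300)
  expect_equal(modified_cosine(a, empty), list(score = 0, matched = 0L))
})

test_that("shifted peaks count through the precursor mass difference", {
  # same spectrum with half the peaks moved by the precursor delta
  a <- ms2_spectrum(300, mz = c(100, 150, 200, 250),
                    intensity = c(10, 40, 20, 30))
  b <- ms2_spectrum(314.0156, mz = c(100, 150, 214.0156, 264.0156),
                    intensity = c(10, 40, 20, 30))
  got <- modified_cosine(a, b)
  oracle <- brute_force_cosine(a, b)
  expect_equal(got$score, oracle$score, tolerance = 1e-9)
  expect_equal(got$matched, 4L)
  expect_equal(got$score, 1, tolerance = 1e-12)
})

test_that("the matching equals the brute-force assignment and is symmetric", {
  set.seed(101)
  for (k in 1:300) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    a <- random_spectrum(n1)
    n_shared <- sample(0:min(3, n1), 1)
    shared <- if (n_shared) a$mz[sample(n1, n_shared)] + rnorm(n_shared, 0, 0.008)
              else numeric(0)
    b <- ms2_spectrum(a$precursor_mz + rnorm(1, 0, 10),
                      mz = sort(c(shared, runif(n2, 60, 550))),
                      intensity = runif(n2 + n_shared, 1, 100))
    got <- modified_cosine(a, b)
    oracle <- brute_force_cosine(a, b)
    expect_equal(got$score, oracle$score, tolerance = 1e-9)
    rev <- modified_cosine(b, a)
    expect_equal(got$score, rev$score, tolerance = 1e-12)
    expect_equal(got$matched, rev$matched)
    expect_gte(got$score, 0); expect_lte(got$score, 1)
  }
})

test_that("network construction respects both edge thresholds", {
  a <- ms2_spectrum(300, mz = seq(100, 250, by = 25),
                    intensity = rep(10, 7), id = "s1")
  spectra <- list(a, ms2_spectrum(300, mz = a$mz, intensity = a$intensity,
                                  id = "s2"),
                  ms2_spectrum(300, mz = a$mz, intensity = a$intensity,
                               id = "s3"))
  g <- build_network(spectra, network_config())
  expect_equal(igraph::ecount(g), 3)          # a 3-clique
  expect_equal(igraph::vcount(g), 3)
  expect_equal(unique(igraph::vertex_attr(g, "component")), 1)

  # too few peaks for the matched-peak threshold: no edges
  small <- lapply(1:3, function(i) ms2_spectrum(300, mz = c(100, 150),
                                                intensity = c(5, 5)))
  expect_equal(igraph::ecount(build_network(small, network_config())), 0)

  expect_equal(igraph::vcount(build_network(list(), network_config())), 0)
})

test_that("raising the cosine threshold never adds edges", {
  set.seed(33)
  man <- paperlike_manifest()
  man <- man[man$kind == "series", ][seq(1, 38, by = 3), ]
  run <- suppressWarnings(generate_run(
    man, generator_config(seed = 13, decoys_per_spectrum = 0,
                          include_standards = FALSE)))
  edge_set <- function(min_cos) {
    g <- build_network(run$spectra,
                       network_config(min_cosine = min_cos))
    el <- igraph::as_edgelist(g, names = FALSE)
    paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  }
  e_lo <- edge_set(0.5); e_mid <- edge_set(0.7); e_hi <- edge_set(0.9)
  expect_true(all(e_mid %in% e_lo))
  expect_true(all(e_hi %in% e_mid))
})

test_that("top-K pruning is applied symmetrically and only removes edges", {
  sp <- lapply(1:5, function(i) {
    ms2_spectrum(300, mz = seq(100, 250, by = 25) + i * 1e-4,
                 intensity = rep(10, 7), id = paste0("n", i))
  })
  g_all <- build_network(sp, network_config())
  g_top <- build_network(sp, network_config(top_k = 1))
  expect_lte(igraph::ecount(g_top), igraph::ecount(g_all))
})

test_that("component purity counts within-component label agreement", {
  sp <- lapply(1:4, function(i) {
    ms2_spectrum(300, mz = seq(100, 250, by = 25),
                 intensity = rep(10, 7), id = paste0("n", i))
  })
  g <- build_network(sp, network_config(),
                     node_attrs = data.frame(
                       sidechain_type = c("1", "1", "2", "2")))
  p <- component_label_purity(g)
  # one 4-clique with two labels: 2 of 6 pairs agree
  expect_equal(p$n_pairs, 6)
  expect_equal(p$purity, 2 / 6)
})

test_that("GraphML export carries node and edge attributes", {
  sp <- lapply(1:3, function(i) ms2_spectrum(300, mz = seq(100, 250, 25),
                                             intensity = rep(10, 7),
                                             id = paste0("n", i)))
  g <- build_network(sp, network_config(),
                     node_attrs = data.frame(subfamily = c("A", "A", "B")))
  path <- tempfile(fileext = ".graphml")
  write_graphml(g, path)
  back <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(back), 3)
  expect_equal(igraph::vertex_attr(back, "subfamily"),
               c("A", "A", "B"))
  expect_true("cosine" %in% igraph::edge_attr_names(back))
})
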