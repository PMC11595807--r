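#' @title Minimal feature-based molecular networking
#' @name networking
#' @description
#' Modified-cosine spectral similarity (peaks match directly or shifted by
#' the precursor m/z difference, under a maximum-weight one-to-one
#' assignment of square-root-scaled, L2-normalised intensities) and
#' thresholded graph construction with connected-component labelling.
NULL

#' Networking configuration
#'
#' Defaults follow the feature-based molecular-networking parameters used
#' for this chemistry: 0.02 Da precursor and fragment tolerances, minimum
#' cosine 0.7, minimum 6 matched peaks; no top-K edge pruning unless
#' requested.
#'
#' @param precursor_tol,fragment_tol tolerances in Da (> 0).
#' @param min_cosine minimum cosine score for an edge, in `[0, 1]`.
#' @param min_matched minimum matched peak count for an edge (>= 1).
#' @param top_k optional per-node edge pruning (keep an edge only when it
#'   is within the top K of both endpoints); NULL disables.
#' @return list of class `network_config`.
#' @export
network_config <- function(precursor_tol = 0.02, fragment_tol = 0.02,
                           min_cosine = 0.7, min_matched = 6L,
                           top_k = NULL) {
  stopifnot(precursor_tol > 0, fragment_tol > 0,
            min_cosine >= 0, min_cosine <= 1, min_matched >= 1)
  structure(list(precursor_tol = precursor_tol, fragment_tol = fragment_tol,
                 min_cosine = min_cosine, min_matched = as.integer(min_matched),
                 top_k = top_k),
            class = "network_config")
}

# candidate peak pairs: direct, or shifted by the precursor m/z difference
.cosine_pairs <- function(a, b, frag_tol) {
  shift <- b$precursor_mz - a$precursor_mz
  pairs <- NULL
  for (s in unique(c(0, shift))) {
    d <- abs(outer(a$mz + s, b$mz, "-"))
    hit <- which(d <= frag_tol, arr.ind = TRUE)
    if (nrow(hit)) pairs <- rbind(pairs, hit)
  }
  if (is.null(pairs)) return(pairs)
  unique(as.data.frame(pairs))
}

#' Modified cosine similarity between two MS2 spectra
#'
#' Intensities are square-root scaled and L2-normalised per spectrum.
#' Peaks may match directly (within `frag_tol`) or after shifting one
#' spectrum by the precursor m/z difference; the score is the sum of
#' normalised intensity products over the maximum-weight one-to-one
#' assignment of candidate pairs (solved as a weighted bipartite
#' matching), so it lies in `[0, 1]` and is symmetric.
#'
#' @param a,b [ms2_spectrum()] objects.
#' @param frag_tol fragment tolerance in Da.
#' @return list with `score` and `matched` (peak-pair count). An empty
#'   spectrum gives score 0.
#' @export
modified_cosine <- function(a, b, frag_tol = 0.02) {
  if (!length(a$mz) || !length(b$mz)) return(list(score = 0, matched = 0L))
  na <- sqrt(a$intensity); na <- na / sqrt(sum(na^2))
  nb <- sqrt(b$intensity); nb <- nb / sqrt(sum(nb^2))
  pairs <- .cosine_pairs(a, b, frag_tol)
  if (is.null(pairs) || nrow(pairs) == 0) return(list(score = 0, matched = 0L))
  w <- na[pairs$row] * nb[pairs$col]
  keep <- w > 0
  pairs <- pairs[keep, , drop = FALSE]; w <- w[keep]
  if (!nrow(pairs)) return(list(score = 0, matched = 0L))
  ia <- match(pairs$row, sort(unique(pairs$row)))
  ib <- match(pairs$col, sort(unique(pairs$col)))
  nA <- max(ia); nB <- max(ib)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, nA), rep(TRUE, nB)),
    edges = as.vector(rbind(ia, nA + ib)))
  mm <- igraph::max_bipartite_match(g, weights = w)
  sel <- !is.na(mm$matching[seq_len(nA)])
  matched_pairs <- cbind(seq_len(nA)[sel], mm$matching[seq_len(nA)][sel] - nA)
  idx <- match(paste(matched_pairs[, 1], matched_pairs[, 2]), paste(ia, ib))
  list(score = min(1, sum(w[idx])), matched = nrow(matched_pairs))
}

#' Build a molecular network from MS2 spectra
#'
#' Computes modified-cosine similarities for all spectrum pairs and keeps
#' edges satisfying both the minimum cosine and the minimum matched-peak
#' count; optional top-K pruning is applied symmetrically (an edge
#' survives only if ranked within the top K at both endpoints). Connected
#' components are labelled on the result.
#'
#' @param spectra list of [ms2_spectrum()] objects.
#' @param cfg a [network_config()].
#' @param node_attrs optional data.frame of per-spectrum node attributes
#'   (one row per spectrum) overlaid onto the graph, e.g. annotation
#'   names and side-chain types.
#' @return an \pkg{igraph} graph with `cosine` and `matched` edge
#'   attributes and a `component` node attribute.
#' @export
build_network <- function(spectra, cfg = network_config(), node_attrs = NULL) {
  ns <- length(spectra)
  ids <- vapply(seq_len(ns), function(i) {
    id <- spectra[[i]]$id
    if (is.null(id)) sprintf("spectrum_%03d", i) else id
  }, "")
  g <- igraph::make_empty_graph(n = ns, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (!is.null(node_attrs)) {
    for (cl in names(node_attrs)) {
      g <- igraph::set_vertex_attr(g, cl, value = node_attrs[[cl]])
    }
  }
  edges <- list()
  if (ns >= 2) {
    # peak-count prefilter: the assignment size is bounded by the number
    # of candidate pairs, so pairs that cannot reach min_matched are
    # skipped without solving the matching
    for (i in seq_len(ns - 1)) {
      for (j in seq(i + 1, ns)) {
        pairs <- .cosine_pairs(spectra[[i]], spectra[[j]], cfg$fragment_tol)
        if (is.null(pairs) ||
            min(length(unique(pairs$row)), length(unique(pairs$col))) <
              cfg$min_matched) next
        mc <- modified_cosine(spectra[[i]], spectra[[j]], cfg$fragment_tol)
        if (mc$score >= cfg$min_cosine && mc$matched >= cfg$min_matched) {
          edges[[length(edges) + 1L]] <- data.frame(
            from = i, to = j, cosine = mc$score, matched = mc$matched)
        }
      }
    }
  }
  if (length(edges)) {
    ed <- do.call(rbind, edges)
    if (!is.null(cfg$top_k)) {
      keep_top <- function(node) {
        inc <- which(ed$from == node | ed$to == node)
        inc[order(-ed$cosine[inc])][seq_len(min(length(inc), cfg$top_k))]
      }
      kept <- lapply(seq_len(ns), keep_top)
      ok <- vapply(seq_len(nrow(ed)), function(k) {
        k %in% kept[[ed$from[k]]] && k %in% kept[[ed$to[k]]]
      }, logical(1))
      ed <- ed[ok, , drop = FALSE]
    }
    if (nrow(ed)) {
      g <- igraph::add_edges(g, as.vector(rbind(ed$from, ed$to)),
                             cosine = ed$cosine, matched = ed$matched)
    }
  }
  comp <- igraph::components(g)
  igraph::set_vertex_attr(g, "component", value = comp$membership)
}

#' Fraction of within-component node pairs sharing a label
#'
#' Used to quantify the clustering-by-side-chain-type observation:
#' components of size one contribute no pairs.
#'
#' @param graph a [build_network()] graph.
#' @param label node attribute name to compare.
#' @return list with `purity` (NaN when no pairs exist), `n_pairs`,
#'   `n_shared`.
#' @export
component_label_purity <- function(graph, label = "sidechain_type") {
  memb <- igraph::vertex_attr(graph, "component")
  lab <- igraph::vertex_attr(graph, label)
  shared <- 0L; total <- 0L
  for (cmp in unique(memb)) {
    v <- which(memb == cmp)
    if (length(v) < 2) next
    pr <- utils::combn(length(v), 2)
    total <- total + ncol(pr)
    shared <- shared + sum(lab[v[pr[1, ]]] == lab[v[pr[2, ]]])
  }
  list(purity = if (total) shared / total else NaN,
       n_pairs = total, n_shared = shared)
}

#' Export a network as GraphML
#' @param graph a [build_network()] graph.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
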