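# Feature-based molecular networking: modified-cosine spectral similarity
# with precursor-shift peak matching, score/matched-peak edge thresholds,
# mutual top-K pruning and molecular-family size capping.

#' Molecular-network parameters
#'
#' @param min_cosine edges require a cosine score strictly above this value.
#' @param min_matched_peaks minimum matched fragment pairs per edge; the
#'   default 7 encodes "more than six matched peaks". Set to 6 for
#'   compatibility with tools whose convention is "at least six".
#' @param top_k mutual rank threshold: an edge survives only if each node is
#'   among the other's `top_k` most similar nodes (ties at rank `top_k` are
#'   kept).
#' @param max_family_size molecular families (connected components) larger
#'   than this are pruned by removing their lowest-scoring edges.
#' @param fragment_tol_da fragment m/z tolerance for peak pairing, Da.
#' @param library_min_score,library_min_peaks thresholds for spectral
#'   library matches reported alongside the network.
#' @return a `network_params` list.
#' @export
network_params <- function(min_cosine = 0.7, min_matched_peaks = 7,
                           top_k = 10, max_family_size = 100,
                           fragment_tol_da = 0.02,
                           library_min_score = 0.7, library_min_peaks = 6) {
  if (min_cosine < 0 || min_cosine > 1.5) stopf("min_cosine out of range")
  if (min_matched_peaks < 1 || max_family_size < 1 || fragment_tol_da <= 0) {
    stopf("counts must be positive")
  }
  if (top_k < 0) stopf("top_k must be >= 0")
  structure(
    list(min_cosine = min_cosine,
         min_matched_peaks = as.integer(min_matched_peaks),
         top_k = as.integer(top_k),
         max_family_size = as.integer(max_family_size),
         fragment_tol_da = fragment_tol_da,
         library_min_score = library_min_score,
         library_min_peaks = as.integer(library_min_peaks)),
    class = "network_params"
  )
}

# exact maximum-weight one-to-one matching over candidate peak pairs by
# branch and bound (pairs visited in decreasing weight, suffix-sum pruning)
max_weight_matching <- function(ia, ib, w) {
  m <- length(w)
  if (m == 0) return(list(weight = 0, sel = integer(0)))
  o <- order(-w)
  ia <- ia[o]; ib <- ib[o]; w <- w[o]
  suffix <- rev(cumsum(rev(w)))
  env <- new.env(parent = emptyenv())
  env$best <- -1
  env$best_sel <- integer(0)
  usedA <- logical(max(ia))
  usedB <- logical(max(ib))
  sel <- logical(m)
  recurse <- function(k, acc) {
    if (k > m) {
      if (acc > env$best) {
        env$best <- acc
        env$best_sel <- which(sel)
      }
      return(invisible())
    }
    if (acc + suffix[k] <= env$best) return(invisible())
    i <- ia[k]; j <- ib[k]
    if (!usedA[i] && !usedB[j]) {
      usedA[i] <<- TRUE; usedB[j] <<- TRUE; sel[k] <<- TRUE
      recurse(k + 1, acc + w[k])
      usedA[i] <<- FALSE; usedB[j] <<- FALSE; sel[k] <<- FALSE
    }
    recurse(k + 1, acc)
  }
  recurse(1L, 0)
  list(weight = env$best, sel = o[env$best_sel])
}

#' Modified-cosine spectral similarity
#'
#' Fragment peaks pair either directly (|mz_a - mz_b| <= tol) or shifted by
#' the precursor mass difference (|mz_a + (prec_b - prec_a) - mz_b| <= tol),
#' capturing analog relationships between structurally related compounds.
#' Intensities are square-root transformed and L2-normalized per spectrum;
#' the score is the total product weight of an exact maximum-weight
#' one-to-one matching over the candidate pairs, so it lies in [0, 1],
#' equals 1 for identical spectra, and never reuses a peak.
#'
#' @param a,b [ms2_spectrum()] objects.
#' @param fragment_tol_da fragment pairing tolerance in Da.
#' @return a `spectral_match`: list with `score`, `n_matched_peaks`, and
#'   `pairs` (tibble: `index_a`, `index_b`, `shifted`).
#' @export
modified_cosine <- function(a, b, fragment_tol_da = 0.02) {
  empty <- list(score = 0, n_matched_peaks = 0L,
                pairs = tibble::tibble(index_a = integer(), index_b = integer(),
                                       shifted = logical()))
  class(empty) <- "spectral_match"
  if (n_peaks(a) == 0 || n_peaks(b) == 0) return(empty)
  wa <- scaled_intensities(a)
  wb <- scaled_intensities(b)
  shift <- b$precursor_mz - a$precursor_mz
  direct <- abs(outer(a$mz, b$mz, "-")) <= fragment_tol_da
  shifted <- abs(outer(a$mz + shift, b$mz, "-")) <= fragment_tol_da
  cand <- direct | shifted
  idx <- which(cand, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  ia <- idx[, 1]; ib <- idx[, 2]
  w <- wa[ia] * wb[ib]
  res <- max_weight_matching(ia, ib, w)
  sel <- res$sel
  out <- list(
    score = min(res$weight, 1),
    n_matched_peaks = length(sel),
    pairs = tibble::tibble(
      index_a = ia[sel], index_b = ib[sel],
      shifted = !direct[cbind(ia[sel], ib[sel])]
    )
  )
  class(out) <- "spectral_match"
  out
}

#' @export
print.spectral_match <- function(x, ...) {
  cat(sprintf("<spectral_match> score %.4f, %d matched peaks\n",
              x$score, x$n_matched_peaks))
  invisible(x)
}

#' All-pairs modified-cosine similarity
#'
#' @param spectra named list of [ms2_spectrum()] (names are node ids).
#' @param params a [network_params()].
#' @return tibble `u`, `v`, `score`, `n_matched` with one row per unordered
#'   pair (u < v in the input order), diagonal excluded.
#' @export
pairwise_similarity <- function(spectra, params = network_params()) {
  ids <- names(spectra) %||% as.character(seq_along(spectra))
  n <- length(spectra)
  m <- n * (n - 1) / 2
  u <- character(m); v <- character(m)
  score <- numeric(m); nm <- integer(m)
  k <- 0L
  for (i in seq_len(max(n - 1, 0))) {
    for (j in (i + 1):n) {
      k <- k + 1L
      sm <- modified_cosine(spectra[[i]], spectra[[j]], params$fragment_tol_da)
      u[k] <- ids[i]; v[k] <- ids[j]
      score[k] <- sm$score; nm[k] <- sm$n_matched_peaks
    }
  }
  tibble::tibble(u = u, v = v, score = score, n_matched = nm)
}

#' Mutual top-K edge pruning
#'
#' An edge (u, v) is retained iff v scores among u's `top_k` highest-scoring
#' neighbors and u among v's. Ties at rank `top_k` are all kept.
#'
#' @param edges tibble `u`, `v`, `score` (already thresholded).
#' @param params a [network_params()].
#' @return the retained subset of `edges`.
#' @export
apply_mutual_topk <- function(edges, params = network_params()) {
  k <- params$top_k
  if (k == 0 || nrow(edges) == 0) return(edges[0, ])
  nodes <- unique(c(edges$u, edges$v))
  cutoff <- vapply(nodes, function(nd) {
    s <- sort(c(edges$score[edges$u == nd], edges$score[edges$v == nd]),
              decreasing = TRUE)
    if (length(s) <= k) -Inf else s[k]
  }, numeric(1))
  names(cutoff) <- nodes
  keep <- edges$score >= cutoff[edges$u] & edges$score >= cutoff[edges$v]
  edges[keep, ]
}

edge_components <- function(edges, nodes = NULL) {
  all_nodes <- unique(c(edges$u, edges$v, nodes))
  g <- igraph::graph_from_data_frame(
    edges[, c("u", "v")], directed = FALSE,
    vertices = data.frame(name = all_nodes)
  )
  comp <- igraph::components(g)$membership
  comp[all_nodes]
}

#' Cap molecular-family size
#'
#' While any connected component exceeds `max_family_size`, the globally
#' lowest-scoring edge inside any over-sized component is removed (ties
#' broken by lexicographic node ids), so the pruning sequence is
#' deterministic.
#'
#' @param edges tibble `u`, `v`, `score` after mutual top-K pruning.
#' @param params a [network_params()].
#' @return pruned edge tibble.
#' @export
cap_family_size <- function(edges, params = network_params()) {
  cap <- params$max_family_size
  repeat {
    if (nrow(edges) == 0) return(edges)
    comp <- edge_components(edges)
    sizes <- table(comp)
    over <- names(sizes)[sizes > cap]
    if (length(over) == 0) return(edges)
    in_over <- comp[edges$u] %in% over
    cand <- which(in_over)
    key_a <- pmin(edges$u[cand], edges$v[cand])
    key_b <- pmax(edges$u[cand], edges$v[cand])
    ord <- order(edges$score[cand], key_a, key_b, method = "radix")
    edges <- edges[-cand[ord[1]], ]
  }
}

#' Build a molecular network from a processed feature table
#'
#' Scores all spectrum pairs, applies the score and matched-peak edge
#' thresholds, mutual top-K pruning and the family-size cap, and labels
#' connected components as molecular families (singletons included). Node
#' attributes carry consensus m/z and RT and, when the table is averaged
#' with metadata, the share of each node's summed intensity contributed by
#' fungal versus host samples.
#'
#' @param table an averaged `feature_table` whose features carry
#'   representative spectra.
#' @param params a [network_params()].
#' @return a `molecular_network`: list with `nodes` (tibble: `id`, `mz`,
#'   `rt`, `family`, `share_fungal`, `share_host`), `edges` (tibble: `u`,
#'   `v`, `score`, `n_matched`) and `params`.
#' @export
build_network <- function(table, params = network_params()) {
  ids <- as.character(table$features$row_id)
  spectra <- stats::setNames(table$features$spectrum, ids)
  sims <- pairwise_similarity(spectra, params)
  edges <- sims[sims$score > params$min_cosine &
                  sims$n_matched >= params$min_matched_peaks, ]
  names(edges)[names(edges) == "u"] <- "u"
  edges <- apply_mutual_topk(edges, params)
  edges <- cap_family_size(edges, params)
  comp <- edge_components(edges, nodes = ids)
  fam <- comp[ids]
  # renumber families deterministically by smallest member id
  first <- tapply(as.integer(ids), fam, min)
  fam_rank <- rank(first)
  family <- sprintf("FAM_%04d", fam_rank[as.character(fam)])
  share_fungal <- share_host <- rep(NA_real_, length(ids))
  if (!is.null(table$metadata)) {
    types <- column_sample_types(table)
    tot <- rowSums(table$intensity)
    f_cols <- which(types == "fungal")
    h_cols <- which(types %in% c("fraction", "crude"))
    share_fungal <- rowSums(table$intensity[, f_cols, drop = FALSE]) / tot
    share_host <- rowSums(table$intensity[, h_cols, drop = FALSE]) / tot
  }
  nodes <- tibble::tibble(
    id = ids, mz = table$features$mz, rt = table$features$rt,
    family = unname(family),
    share_fungal = share_fungal, share_host = share_host
  )
  structure(list(nodes = nodes, edges = edges, params = params),
            class = "molecular_network")
}

#' @export
print.molecular_network <- function(x, ...) {
  cat(sprintf("<molecular_network> %d nodes, %d edges, %d families\n",
              nrow(x$nodes), nrow(x$edges),
              length(unique(x$nodes$family))))
  invisible(x)
}

as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges, directed = FALSE,
    vertices = as.data.frame(network$nodes)
  )
}

#' Export a molecular network to GraphML
#'
#' Node attributes (m/z, RT, family, dataset intensity shares and any
#' annotation columns merged into `nodes`) and edge attributes (score,
#' matched peaks) are preserved, for viewing in standard graph tools.
#'
#' @param network a `molecular_network`.
#' @param path output GraphML path.
#' @return `path` invisibly.
#' @export
export_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}

#' Export network edges as a TSV edge list
#'
#' Columns `CLUSTERID1`, `CLUSTERID2`, `Cosine`, `MatchedPeaks`.
#'
#' @param network a `molecular_network`.
#' @param path output TSV path.
#' @return `path` invisibly.
#' @export
export_edgelist <- function(network, path) {
  df <- data.frame(CLUSTERID1 = network$edges$u,
                   CLUSTERID2 = network$edges$v,
                   Cosine = network$edges$score,
                   MatchedPeaks = network$edges$n_matched)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
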