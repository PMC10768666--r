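# Modified cosine, edge pruning, family capping and network assembly.

test_that("modified cosine is 1 on identical spectra and 0 with no pairable peaks", {
  sp <- ms2_spectrum(200, 1, c(81.1, 105.2, 150.9), c(0.2, 1, 0.5))
  self <- modified_cosine(sp, sp)
  expect_equal(self$score, 1, tolerance = 1e-12)
  expect_equal(self$n_matched_peaks, 3L)

  far <- ms2_spectrum(400, 1, c(60.5, 70.5), c(1, 1))
  none <- modified_cosine(sp, far)
  expect_equal(none$score, 0)
  expect_equal(none$n_matched_peaks, 0L)

  empty <- ms2_spectrum(200, 1)
  expect_equal(modified_cosine(sp, empty)$score, 0)
})

test_that("precursor-shifted fragments pair alongside direct matches", {
  a <- ms2_spectrum(200, 1, c(100, 150), c(1, 1))
  b <- ms2_spectrum(210, 1, c(100, 160), c(1, 1))
  m <- modified_cosine(a, b)
  expect_equal(m$n_matched_peaks, 2L)
  expect_equal(sum(m$pairs$shifted), 1L)  # 150 -> 160 via the +10 shift
  # two equal-intensity matched peaks out of two: score 1
  expect_equal(m$score, 1, tolerance = 1e-12)
  o <- oracle_modified_cosine(a, b)
  expect_equal(m$score, o$score, tolerance = 1e-12)
})

test_that("matching is one-to-one, symmetric and scale-invariant", {
  set.seed(606)
  for (rep in 1:100) {
    a <- random_spectrum()
    b <- if (runif(1) < 0.3) {
      # overlapping peaks to force real candidate pairs
      ms2_spectrum(a$precursor_mz + runif(1, -20, 20), 1,
                   a$mz + rnorm(n_peaks(a), 0, 0.01),
                   runif(n_peaks(a), 0.01, 1))
    } else {
      random_spectrum()
    }
    m <- modified_cosine(a, b)
    expect_true(m$score >= 0 && m$score <= 1 + 1e-12)
    expect_false(any(duplicated(m$pairs$index_a)))
    expect_false(any(duplicated(m$pairs$index_b)))
    expect_equal(modified_cosine(b, a)$score, m$score, tolerance = 1e-12)
    scaled <- ms2_spectrum(b$precursor_mz, b$rt, b$mz, b$intensity * 37)
    expect_equal(modified_cosine(a, scaled)$score, m$score, tolerance = 1e-12)
  }
})

test_that("pairwise similarity covers all unordered pairs consistently", {
  set.seed(707)
  spectra <- replicate(6, random_spectrum(), simplify = FALSE)
  names(spectra) <- sprintf("n%d", 1:6)
  p <- network_params()
  pw <- pairwise_similarity(spectra, p)
  expect_equal(nrow(pw), 15)
  for (k in sample(15, 5)) {
    m <- modified_cosine(spectra[[pw$u[k]]], spectra[[pw$v[k]]],
                         p$fragment_tol_da)
    expect_equal(pw$score[k], m$score)
  }
})

test_that("mutual top-k pruning matches the ranking oracle", {
  # hub with 12 neighbors of distinct scores at k = 10: two lowest removed
  hub <- tibble::tibble(u = "hub", v = sprintf("n%02d", 1:12),
                        score = seq(0.99, 0.77, length.out = 12))
  kept <- apply_mutual_topk(hub, network_params(top_k = 10))
  expect_equal(nrow(kept), 10)
  expect_equal(sort(kept$score, decreasing = TRUE)[10], sort(hub$score,
               decreasing = TRUE)[10])
  # triangle with k far above degree: everything stays
  tri <- tibble::tibble(u = c("a", "a", "b"), v = c("b", "c", "c"),
                        score = c(0.9, 0.8, 0.85))
  expect_equal(nrow(apply_mutual_topk(tri, network_params(top_k = 10))), 3)
  expect_equal(nrow(apply_mutual_topk(tri, network_params(top_k = 0))), 0)

  set.seed(808)
  for (rep in 1:40) {
    edges <- random_edge_set(sample(10:25, 1), p = 0.3)
    k <- sample(1:5, 1)
    got <- apply_mutual_topk(edges, network_params(top_k = k))
    want <- oracle_mutual_topk(edges, k)
    expect_equal(got[order(got$u, got$v), c("u", "v", "score")],
                 want[order(want$u, want$v), c("u", "v", "score")])
  }
})

test_that("family capping removes lowest-scoring edges until sizes comply", {
  path <- tibble::tibble(u = c("a", "b", "c", "d"), v = c("b", "c", "d", "e"),
                         score = c(0.9, 0.8, 0.95, 0.85))
  capped <- cap_family_size(path, network_params(max_family_size = 3))
  # 0.8 goes first, leaving components {a,b} and {c,d,e}
  expect_equal(nrow(capped), 3)
  expect_false(any(capped$score == 0.8))

  small <- random_edge_set(10, p = 0.2)
  expect_identical(cap_family_size(small, network_params(max_family_size = 100)),
                   small)

  set.seed(909)
  for (rep in 1:40) {
    edges <- random_edge_set(sample(10:30, 1), p = 0.25)
    cap <- sample(3:6, 1)
    got <- cap_family_size(edges, network_params(max_family_size = cap))
    want <- oracle_cap(edges, cap)
    expect_equal(got[order(got$u, got$v), ], want[order(want$u, want$v), ],
                 ignore_attr = TRUE)
    # postcondition: no component exceeds the cap
    if (nrow(got) > 0) {
      g <- igraph::graph_from_data_frame(got[, c("u", "v")], directed = FALSE)
      expect_true(max(igraph::components(g)$csize) <= cap)
    }
  }
})

test_that("raising min_cosine never adds edges (monotonicity)", {
  set.seed(111)
  edges <- random_edge_set(20, p = 0.3)
  edges$n_matched <- 8L
  lo <- edges[edges$score > 0.6, ]
  hi <- edges[edges$score > 0.8, ]
  klo <- apply_mutual_topk(lo, network_params(top_k = 3))
  khi <- apply_mutual_topk(hi, network_params(top_k = 3))
  key <- function(e) paste(e$u, e$v)
  # thresholded-then-pruned edge set is a subset of the thresholded set
  expect_true(all(key(klo) %in% key(lo)))
  expect_true(all(key(khi) %in% key(hi)))
})

test_that("zero-noise shared metabolites collapse into single families", {
  st <- tiny_study()
  tab <- process_features(st$samples$features, st$samples$metadata)
  net <- build_network(tab)
  expect_equal(nrow(net$nodes), nrow(tab$features))
  # every retained edge satisfies the thresholds
  p <- net$params
  expect_true(all(net$edges$score > p$min_cosine))
  expect_true(all(net$edges$n_matched >= p$min_matched_peaks))
  # distinct random fragmentation templates: no cross-metabolite edges
  metab_of <- tab$features$metabolite_id
  names(metab_of) <- as.character(tab$features$row_id)
  if (nrow(net$edges) > 0) {
    expect_true(all(metab_of[net$edges$u] == metab_of[net$edges$v]))
  }
  # impossible threshold isolates every node
  net1 <- build_network(tab, network_params(min_cosine = 1.01))
  expect_equal(nrow(net1$edges), 0)
  expect_equal(length(unique(net1$nodes$family)), nrow(tab$features))
})

test_that("graphml and edge-list exports round-trip", {
  st <- tiny_study()
  tab <- process_features(st$samples$features, st$samples$metadata)
  net <- build_network(tab, network_params(min_cosine = 0.5,
                                           min_matched_peaks = 4))
  path <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(net, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_setequal(igraph::vertex_attr(g, "family"), unique(net$nodes$family))
  expect_equal(sort(igraph::vertex_attr(g, "mz")), sort(net$nodes$mz))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_edgelist(net, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), nrow(net$edges))
  expect_named(back, c("CLUSTERID1", "CLUSTERID2", "Cosine", "MatchedPeaks"))

  empty <- net
  empty$nodes <- net$nodes[0, ]; empty$edges <- net$edges[0, ]
  path2 <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(empty, path2)
  expect_equal(igraph::vcount(igraph::read_graph(path2, format = "graphml")), 0)
})
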