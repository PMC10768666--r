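# Independent brute-force oracles used across the suite. Each re-derives
# the rule from its definition without reusing package internals, so
# agreement is a genuine cross-check.

# --- spectra ---------------------------------------------------------------

random_spectrum <- function(n_peaks_max = 8, mz_range = c(50, 500),
                            precursor = runif(1, mz_range[2], mz_range[2] + 100)) {
  k <- sample(seq_len(n_peaks_max), 1)
  ms2_spectrum(precursor, runif(1, 0, 8),
               sort(runif(k, mz_range[1], mz_range[2])),
               runif(k, 0.01, 1))
}

# exhaustive maximum-weight one-to-one matching over candidate peak pairs:
# plain include/exclude recursion, no ordering, no pruning by bound
oracle_modified_cosine <- function(a, b, tol = 0.02) {
  wa <- sqrt(a$intensity); wa <- wa / sqrt(sum(wa^2))
  wb <- sqrt(b$intensity); wb <- wb / sqrt(sum(wb^2))
  shift <- b$precursor_mz - a$precursor_mz
  cand <- list()
  for (i in seq_along(a$mz)) {
    for (j in seq_along(b$mz)) {
      if (abs(a$mz[i] - b$mz[j]) <= tol ||
          abs(a$mz[i] + shift - b$mz[j]) <= tol) {
        cand[[length(cand) + 1]] <- c(i, j, wa[i] * wb[j])
      }
    }
  }
  if (length(cand) == 0) return(list(score = 0, n_matched = 0L))
  best <- 0; best_n <- 0L
  recurse <- function(k, used_a, used_b, acc, n_acc) {
    if (k > length(cand)) {
      if (acc > best) { best <<- acc; best_n <<- n_acc }
      return(invisible())
    }
    p <- cand[[k]]
    if (!(p[1] %in% used_a) && !(p[2] %in% used_b)) {
      recurse(k + 1, c(used_a, p[1]), c(used_b, p[2]), acc + p[3], n_acc + 1L)
    }
    recurse(k + 1, used_a, used_b, acc, n_acc)
  }
  recurse(1L, integer(0), integer(0), 0, 0L)
  list(score = min(best, 1), n_matched = best_n)
}

# --- per-list grouping rules ----------------------------------------------

random_feature_list <- function(n, sample_id = "S1", replicate = 1L,
                                mz_range = c(100, 110), rt_range = c(1, 1.2)) {
  tibble::tibble(
    feature_id = seq_len(n), sample_id = sample_id, replicate = replicate,
    mz = runif(n, mz_range[1], mz_range[2]),
    rt = runif(n, rt_range[1], rt_range[2]),
    intensity = runif(n, 1, 100),
    spectrum = replicate(n, ms2_spectrum(200, 1, c(80, 90), c(1, 1)),
                         simplify = FALSE)
  )
}

# pairwise duplicate rule -> connected components -> most intense survivor
oracle_dedup <- function(features, ppm, rt_min) {
  n <- nrow(features)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dppm <- 2e6 * abs(features$mz[i] - features$mz[j]) /
        (features$mz[i] + features$mz[j])
      if (dppm <= ppm && abs(features$rt[i] - features$rt[j]) <= rt_min) {
        adj[i, j] <- TRUE
      }
    }
  }
  comp <- oracle_components(adj)
  keep <- vapply(unique(comp), function(cp) {
    grp <- which(comp == cp)
    grp[which.max(features$intensity[grp])]
  }, integer(1))
  sort(keep)
}

oracle_isotopes <- function(features, ppm, rt_min, max_charge) {
  n <- nrow(features)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (abs(features$rt[i] - features$rt[j]) > rt_min) next
      dmz <- abs(features$mz[i] - features$mz[j])
      tol <- ppm * 1e-6 * (features$mz[i] + features$mz[j]) / 2
      hit <- FALSE
      for (z in seq_len(max_charge)) {
        for (k in 1:2) {
          if (abs(dmz - k * 1.003355 / z) <= tol) hit <- TRUE
        }
      }
      adj[i, j] <- hit
    }
  }
  comp <- oracle_components(adj)
  keep <- vapply(unique(comp), function(cp) {
    grp <- which(comp == cp)
    grp[which.max(features$intensity[grp])]
  }, integer(1))
  sort(keep)
}

# BFS connected components on an adjacency matrix
oracle_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which((adj[v, ] | adj[, v]) & is.na(comp)))
    }
  }
  comp
}

# --- replicate / blank filter rules ---------------------------------------

# detection tensor: features x samples x replicates logical array; returns
# retained rows and presence matrix by direct application of the rule
oracle_replicate_filter <- function(det, intensities, bio, n_required,
                                    co_min) {
  n_feat <- dim(det)[1]; n_samp <- dim(det)[2]
  counts <- apply(det, c(1, 2), sum)
  retained <- integer(0)
  for (i in seq_len(n_feat)) {
    if (any(counts[i, bio] >= n_required)) retained <- c(retained, i)
  }
  presence <- counts[retained, , drop = FALSE] >= co_min
  list(retained = retained, presence = presence)
}

oracle_blank_filter <- function(sample_mean, blank_cols, bio_cols, ratio) {
  keep <- integer(0)
  for (i in seq_len(nrow(sample_mean))) {
    blank_mean <- mean(sample_mean[i, blank_cols])
    best_bio <- max(sample_mean[i, bio_cols])
    if (blank_mean <= ratio * best_bio) keep <- c(keep, i)
  }
  keep
}

# --- network rules ---------------------------------------------------------

# mutual top-k by explicit per-node neighbor ranking (ties at rank k kept)
oracle_mutual_topk <- function(edges, k) {
  if (k == 0 || nrow(edges) == 0) return(edges[0, ])
  in_top <- function(node, other) {
    nb <- rbind(
      data.frame(o = edges$v[edges$u == node], s = edges$score[edges$u == node]),
      data.frame(o = edges$u[edges$v == node], s = edges$score[edges$v == node])
    )
    nb <- nb[order(-nb$s), ]
    if (nrow(nb) <= k) return(TRUE)
    other %in% nb$o[nb$s >= nb$s[k]]
  }
  keep <- vapply(seq_len(nrow(edges)), function(e) {
    in_top(edges$u[e], edges$v[e]) && in_top(edges$v[e], edges$u[e])
  }, logical(1))
  edges[keep, ]
}

# greedy family-size cap: recompute components each step, drop the global
# minimum-score edge among over-sized components
oracle_cap <- function(edges, cap) {
  repeat {
    if (nrow(edges) == 0) return(edges)
    g <- igraph::graph_from_data_frame(edges[, c("u", "v")], directed = FALSE)
    mem <- igraph::components(g)$membership
    sizes <- table(mem)
    over <- names(sizes)[sizes > cap]
    if (length(over) == 0) return(edges)
    cand <- which(mem[edges$u] %in% over)
    sc <- edges$score[cand]
    lo <- cand[sc == min(sc)]
    if (length(lo) > 1) {
      key <- paste(pmin(edges$u[lo], edges$v[lo]),
                   pmax(edges$u[lo], edges$v[lo]))
      lo <- lo[order(key)][1]
    }
    edges <- edges[-lo, ]
  }
}

random_edge_set <- function(n_nodes, p = 0.1) {
  ids <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- t(combn(ids, 2))
  keep <- runif(nrow(pairs)) < p
  tibble::tibble(u = pairs[keep, 1], v = pairs[keep, 2],
                 score = round(runif(sum(keep), 0.5, 1), 6))
}

# --- small synthetic studies ----------------------------------------------

tiny_design <- function(n_strains = 4, n_fractions = 10,
                        noise = zero_noise(), seed = 11, lod = 1e4, ...) {
  ids <- sprintf("A%02d", seq_len(n_strains))
  study_design(
    strains = tibble::tibble(strain_id = ids,
                             taxon_id = paste0("t_", tolower(ids))),
    n_fractions = n_fractions, noise = noise, seed = seed, lod = lod, ...
  )
}

tiny_counts <- c(host_only = 8, strain_specific = 6, multi_strain = 2,
                 shared_host_strain = 4, contaminant = 2, media = 2)

tiny_study <- function(seed = 11, noise = zero_noise(), lod = 1e4,
                       counts = tiny_counts, ...) {
  ont <- generate_ontology(5, 2, seed = 1)
  des <- tiny_design(noise = noise, seed = seed, lod = lod, ...)
  truth <- generate_metabolome(ont, des, counts)
  samples <- simulate_samples(truth)
  list(ontology = ont, design = des, truth = truth, samples = samples)
}
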