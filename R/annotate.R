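# Annotation cascade: MS1 adduct matching restricted by taxonomy, MS2
# spectral-library search, taxonomically informed re-ranking,
# network-consensus chemical-class assignment, and identity matching
# against an in-house standards library.

TAX_RANKS <- c("species", "genus", "family", "order", "class", "phylum",
               "kingdom")

#' Common positive-mode adduct mass offsets (Da)
#' @export
POSITIVE_ADDUCTS <- c(
  "[M+H]+" = 1.007276,
  "[M+Na]+" = 22.989218,
  "[M+NH4]+" = 18.033823,
  "[M+K]+" = 38.963158,
  "[M+H-H2O]+" = -17.002740
)

#' Annotation parameters
#'
#' @param parent_tol_da precursor (parent) mass tolerance, Da.
#' @param msms_tol_da fragment tolerance for library spectral matching, Da.
#' @param min_cosine,min_peaks spectral-match acceptance thresholds.
#' @param n_candidates structure candidates retained per feature before
#'   re-ranking.
#' @param n_retained candidates kept after consensus re-ranking.
#' @param tax_weight weight of the taxonomic bonus added to the spectral
#'   score: `final = sigma + tax_weight * (R - d) / R` with `d` the rank
#'   distance to the nearest reported source taxon and `R` the distance of
#'   taxa sharing no ancestor below the root.
#' @param class_bonus additive bonus per ontology level on which a
#'   candidate's class triple matches the node's network consensus.
#' @param consensus_radius neighborhood radius (graph hops) pooled for the
#'   class consensus.
#' @param identity_tol_ppm,identity_min_score thresholds for confirming an
#'   identity against the standards library.
#' @param adducts named vector of adduct mass offsets for MS1 matching.
#' @return an `annotation_params` list.
#' @export
annotation_params <- function(parent_tol_da = 0.01, msms_tol_da = 0.01,
                              min_cosine = 0.2, min_peaks = 6,
                              n_candidates = 50, n_retained = 3,
                              tax_weight = 1.0, class_bonus = 0.1,
                              consensus_radius = 1,
                              identity_tol_ppm = 20,
                              identity_min_score = 0.8,
                              adducts = POSITIVE_ADDUCTS) {
  if (parent_tol_da <= 0 || msms_tol_da <= 0) stopf("tolerances must be positive")
  if (n_retained > n_candidates) stopf("n_retained must be <= n_candidates")
  structure(
    list(parent_tol_da = parent_tol_da, msms_tol_da = msms_tol_da,
         min_cosine = min_cosine, min_peaks = as.integer(min_peaks),
         n_candidates = as.integer(n_candidates),
         n_retained = as.integer(n_retained),
         tax_weight = tax_weight, class_bonus = class_bonus,
         consensus_radius = as.integer(consensus_radius),
         identity_tol_ppm = identity_tol_ppm,
         identity_min_score = identity_min_score,
         adducts = adducts),
    class = "annotation_params"
  )
}

#' Construct a taxonomy tree
#'
#' @param nodes tibble with `taxon_id`, `name`, `rank`, `parent_id`; ranks
#'   from species to kingdom plus a single `root` node.
#' @return a `taxonomy_tree` with `nodes` and the ordered `ranks` vector.
#' @export
taxonomy_tree <- function(nodes) {
  nodes <- tibble::as_tibble(nodes)
  stopifnot(all(c("taxon_id", "name", "rank", "parent_id") %in% names(nodes)))
  roots <- nodes$taxon_id[is.na(nodes$parent_id)]
  if (length(roots) != 1) stopf("taxonomy must have exactly one root")
  bad <- setdiff(nodes$rank, c(TAX_RANKS, "root"))
  if (length(bad) > 0) stopf("unknown taxonomy rank(s): %s", paste(bad, collapse = ", "))
  structure(list(nodes = nodes, ranks = TAX_RANKS, root = roots),
            class = "taxonomy_tree")
}

# lineage from a taxon up to (and including) the root
lineage <- function(tree, taxon) {
  idx <- match(taxon, tree$nodes$taxon_id)
  if (is.na(idx)) stopf("unknown taxon: '%s'", taxon)
  path <- character(0)
  while (!is.na(idx)) {
    path <- c(path, tree$nodes$taxon_id[idx])
    idx <- match(tree$nodes$parent_id[idx], tree$nodes$taxon_id)
  }
  path
}

#' Taxonomic distance in rank steps
#'
#' The 0-based index (counting from species) of the rank of the lowest
#' common ancestor of two taxa: 0 for the same species, 1 when only the
#' genus is shared, ... and `length(ranks)` (7) when the taxa share no
#' ancestor below the root (e.g. a plant and a fungus).
#'
#' @param taxon_a,taxon_b taxon ids present in the tree.
#' @param tree a [taxonomy_tree()].
#' @return integer rank distance.
#' @export
taxonomic_distance <- function(taxon_a, taxon_b, tree) {
  la <- lineage(tree, taxon_a)
  lb <- lineage(tree, taxon_b)
  common <- la[la %in% lb]
  if (length(common) == 0) return(length(tree$ranks))
  lca <- common[1]
  rk <- tree$nodes$rank[match(lca, tree$nodes$taxon_id)]
  if (rk == "root") return(length(tree$ranks))
  match(rk, tree$ranks) - 1L
}

# all taxa inside the family-level subtree containing `taxon`
family_subtree <- function(tree, taxon) {
  lin <- lineage(tree, taxon)
  rks <- tree$nodes$rank[match(lin, tree$nodes$taxon_id)]
  fam <- lin[rks == "family"]
  if (length(fam) == 0) return(character(0))
  in_subtree <- vapply(tree$nodes$taxon_id, function(t) {
    fam[1] %in% lineage(tree, t)
  }, logical(1))
  tree$nodes$taxon_id[in_subtree]
}

#' MS1 adduct matching restricted by taxonomy
#'
#' Candidates are the library entries whose neutral mass plus any common
#' adduct offset matches the feature's precursor within `parent_tol_da`,
#' restricted to entries reported from organisms inside the family-level
#' subtree of the analyzed sample's taxon.
#'
#' @param precursor_mz feature precursor m/z.
#' @param library a `spectral_library`.
#' @param sample_taxa taxon id(s) of the sample(s) the feature was
#'   detected in.
#' @param tree a [taxonomy_tree()].
#' @param params an [annotation_params()].
#' @return tibble `structure_id`, `adduct`, `mass_error_da`.
#' @export
ms1_adduct_match <- function(precursor_mz, library, sample_taxa, tree,
                             params = annotation_params()) {
  allowed <- unique(unlist(lapply(sample_taxa, function(t) family_subtree(tree, t))))
  in_taxa <- vapply(library$source_taxa, function(tx) any(tx %in% allowed),
                    logical(1))
  out <- list()
  for (i in which(in_taxa)) {
    err <- abs(library$monoisotopic_mass[i] + params$adducts - precursor_mz)
    hit <- which(err <= params$parent_tol_da)
    for (h in hit) {
      out[[length(out) + 1]] <- tibble::tibble(
        structure_id = library$structure_id[i],
        adduct = names(params$adducts)[h],
        mass_error_da = err[h]
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(structure_id = character(), adduct = character(),
                          mass_error_da = numeric()))
  }
  do.call(rbind, out)
}

#' MS2 spectral-library search
#'
#' Entries passing the parent-mass gate are scored with the modified-cosine
#' engine at `msms_tol_da`; candidates require score >= `min_cosine` and at
#' least `min_peaks` matched peaks; at most `n_candidates` are returned,
#' best score first (ties broken by structure id).
#'
#' @param spectrum the feature's [ms2_spectrum()] (or NULL).
#' @param library a `spectral_library`.
#' @param params an [annotation_params()].
#' @return tibble `structure_id`, `sigma`, `n_matched`, `pathway`,
#'   `superclass`, `class`, `source_taxa` (list-column).
#' @export
ms2_library_search <- function(spectrum, library, params = annotation_params()) {
  empty <- tibble::tibble(
    structure_id = character(), sigma = numeric(), n_matched = integer(),
    pathway = character(), superclass = character(), class = character(),
    source_taxa = list()
  )
  if (n_peaks(spectrum) == 0) {
    warnf("feature has no MS/MS spectrum; no candidates")
    return(empty)
  }
  prec <- vapply(library$spectrum, function(s) s$precursor_mz, numeric(1))
  gate <- which(abs(prec - spectrum$precursor_mz) <= params$parent_tol_da)
  if (length(gate) == 0) return(empty)
  sigma <- numeric(length(gate)); nm <- integer(length(gate))
  for (k in seq_along(gate)) {
    sm <- modified_cosine(spectrum, library$spectrum[[gate[k]]],
                          params$msms_tol_da)
    sigma[k] <- sm$score; nm[k] <- sm$n_matched_peaks
  }
  pass <- sigma >= params$min_cosine & nm >= params$min_peaks
  gate <- gate[pass]; sigma <- sigma[pass]; nm <- nm[pass]
  if (length(gate) == 0) return(empty)
  ord <- order(-sigma, library$structure_id[gate], method = "radix")
  ord <- ord[seq_len(min(length(ord), params$n_candidates))]
  tibble::tibble(
    structure_id = library$structure_id[gate][ord],
    sigma = sigma[ord], n_matched = nm[ord],
    pathway = library$pathway[gate][ord],
    superclass = library$superclass[gate][ord],
    class = library$class[gate][ord],
    source_taxa = library$source_taxa[gate][ord]
  )
}

#' Taxonomically informed candidate re-ranking
#'
#' Adds to each candidate's spectral score a bonus inversely related to the
#' taxonomic distance between the analyzed sample's taxon and the nearest
#' reported source organism of the candidate:
#' `final_score = sigma + tax_weight * (R - d) / R`. Candidates with no
#' resolvable source taxon get distance `R` (zero bonus). The set of
#' candidates never changes, only the order.
#'
#' @param candidates tibble from [ms2_library_search()].
#' @param sample_taxa taxon id(s) of the sample(s) the feature occurs in.
#' @param tree a [taxonomy_tree()].
#' @param params an [annotation_params()].
#' @return `candidates` with `distance`, `final_score`, `rank`, sorted by
#'   decreasing `final_score` (stable).
#' @export
reweight_candidates <- function(candidates, sample_taxa, tree,
                                params = annotation_params()) {
  R <- length(tree$ranks)
  known <- tree$nodes$taxon_id
  sample_taxa <- intersect(unique(sample_taxa), known)
  d <- vapply(candidates$source_taxa, function(tx) {
    tx <- intersect(tx, known)
    if (length(tx) == 0 || length(sample_taxa) == 0) return(R)
    min(vapply(sample_taxa, function(st) {
      min(vapply(tx, function(t) taxonomic_distance(st, t, tree), integer(1)))
    }, integer(1)))
  }, numeric(1))
  out <- candidates
  out$distance <- d
  out$final_score <- out$sigma + params$tax_weight * (R - d) / R
  ord <- order(-out$final_score)  # stable: preserves prior (sigma) order on ties
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  out
}

# weighted vote tally for one level; ties broken lexicographically
tally_level <- function(labels, weights) {
  ok <- !is.na(labels)
  if (!any(ok)) return(NA_character_)
  tot <- tapply(weights[ok], labels[ok], sum)
  names(tot)[order(-tot, names(tot), method = "radix")][1]
}

#' Network-consensus chemical class and final re-ranking
#'
#' For each node, the top-ranked candidate of the node and of its direct
#' network neighbors vote for class labels at each ontology level, weighted
#' by final score; the heaviest label per level is the node's consensus.
#' Candidates then receive `class_bonus` per level on which their triple
#' matches the consensus, are re-sorted, and the top `n_retained` are kept.
#'
#' @param network a `molecular_network`.
#' @param candidates_by_node named list (node id -> reweighted candidate
#'   tibble).
#' @param params an [annotation_params()].
#' @return list with `consensus` (tibble: `id`, `pathway`, `superclass`,
#'   `class`) and `candidates` (named list of re-ranked top-`n_retained`
#'   tibbles).
#' @export
consensus_class <- function(network, candidates_by_node,
                            params = annotation_params()) {
  ids <- network$nodes$id
  g <- as_igraph(network)
  levels <- c("pathway", "superclass", "class")
  top1 <- lapply(candidates_by_node, function(cc) {
    if (is.null(cc) || nrow(cc) == 0) NULL else cc[1, ]
  })
  consensus <- tibble::tibble(id = ids, pathway = NA_character_,
                              superclass = NA_character_, class = NA_character_)
  out_cand <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(ids)) {
    id <- ids[i]
    nb <- if (params$consensus_radius > 0) {
      names(igraph::ego(g, order = params$consensus_radius, nodes = id)[[1]])
    } else {
      id
    }
    voters <- Filter(Negate(is.null), top1[unique(c(id, nb))])
    if (length(voters) > 0) {
      w <- vapply(voters, function(v) v$final_score, numeric(1))
      for (lv in levels) {
        lab <- vapply(voters, function(v) v[[lv]], character(1))
        consensus[[lv]][i] <- tally_level(lab, w)
      }
    }
    cc <- candidates_by_node[[id]]
    if (!is.null(cc) && nrow(cc) > 0) {
      matched <- rep(0L, nrow(cc))
      for (lv in levels) {
        if (!is.na(consensus[[lv]][i])) {
          matched <- matched + as.integer(!is.na(cc[[lv]]) &
                                            cc[[lv]] == consensus[[lv]][i])
        }
      }
      cc$final_score <- cc$final_score + params$class_bonus * matched
      cc <- cc[order(-cc$final_score), ]
      cc$rank <- seq_len(nrow(cc))
      out_cand[[id]] <- utils::head(cc, params$n_retained)
    }
  }
  list(consensus = consensus, candidates = out_cand)
}

#' Identity match against a standards library
#'
#' An identity is confirmed iff the precursor matches within
#' `identity_tol_ppm` and the spectral score reaches
#' `identity_min_score`; confirmed hits form the highest annotation tier.
#'
#' @param spectrum the feature's [ms2_spectrum()].
#' @param standards a `spectral_library` of authentic standards.
#' @param params an [annotation_params()].
#' @return one-row tibble (`structure_id`, `sigma`, `n_matched`) or NULL.
#' @export
identity_match <- function(spectrum, standards, params = annotation_params()) {
  if (n_peaks(spectrum) == 0 || nrow(standards) == 0) return(NULL)
  prec <- vapply(standards$spectrum, function(s) s$precursor_mz, numeric(1))
  gate <- which(ppm_diff(prec, spectrum$precursor_mz) <= params$identity_tol_ppm)
  best <- NULL
  for (k in gate) {
    sm <- modified_cosine(spectrum, standards$spectrum[[k]], params$msms_tol_da)
    if (sm$score >= params$identity_min_score &&
        (is.null(best) || sm$score > best$sigma)) {
      best <- tibble::tibble(structure_id = standards$structure_id[k],
                             sigma = sm$score,
                             n_matched = sm$n_matched_peaks)
    }
  }
  best
}

#' Annotate a processed dataset
#'
#' Runs the full cascade per feature: identity matching against standards
#' (tier "confirmed"), MS2 library search, taxonomically informed
#' re-ranking using the taxa of the samples the feature is present in, and
#' network-consensus class assignment with final top-`n_retained`
#' retention. Features without MS2 candidates fall back to MS1 adduct
#' matches (tier "ms1").
#'
#' @param table an averaged `feature_table` with presence calls.
#' @param network the `molecular_network` built from `table`.
#' @param library a `spectral_library` of reference spectra.
#' @param tree a [taxonomy_tree()].
#' @param params an [annotation_params()].
#' @param standards optional standards `spectral_library`.
#' @return an `annotation_set`: list with `records` (tibble: `row_id`,
#'   `tier`, `rank`, `structure_id`, `sigma`, `n_matched`, `distance`,
#'   `final_score`, `pathway`, `superclass`, `class`), `consensus` (per
#'   node), and `coverage` (fraction of features annotated per level).
#' @export
annotate_dataset <- function(table, network, library, tree,
                             params = annotation_params(), standards = NULL) {
  ids <- as.character(table$features$row_id)
  taxa_by_sample <- stats::setNames(table$metadata$taxon_id,
                                    table$metadata$sample_id)
  pres <- table$presence
  cand <- stats::setNames(vector("list", length(ids)), ids)
  confirmed <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(ids)) {
    sp <- table$features$spectrum[[i]]
    samp <- colnames(pres)[pres[i, ]]
    staxa <- unique(stats::na.omit(taxa_by_sample[samp]))
    if (!is.null(standards)) {
      confirmed[[i]] <- identity_match(sp, standards, params)
    }
    cc <- suppressWarnings(ms2_library_search(sp, library, params))
    if (nrow(cc) > 0) {
      cc <- reweight_candidates(cc, staxa, tree, params)
    } else {
      cc$distance <- numeric(0); cc$final_score <- numeric(0)
      cc$rank <- integer(0)
    }
    cand[[i]] <- cc
  }
  cons <- consensus_class(network, cand, params)
  rows <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    if (!is.null(confirmed[[i]])) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        row_id = table$features$row_id[i], tier = "confirmed", rank = 0L,
        structure_id = confirmed[[i]]$structure_id,
        sigma = confirmed[[i]]$sigma, n_matched = confirmed[[i]]$n_matched,
        distance = NA_real_, final_score = NA_real_,
        pathway = NA_character_, superclass = NA_character_,
        class = NA_character_
      )
    }
    cc <- cons$candidates[[id]]
    if (!is.null(cc) && nrow(cc) > 0) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        row_id = table$features$row_id[i], tier = "ms2", rank = cc$rank,
        structure_id = cc$structure_id, sigma = cc$sigma,
        n_matched = cc$n_matched, distance = cc$distance,
        final_score = cc$final_score, pathway = cc$pathway,
        superclass = cc$superclass, class = cc$class
      )
    } else {
      sp <- table$features$spectrum[[i]]
      samp <- colnames(pres)[pres[i, ]]
      staxa <- unique(stats::na.omit(taxa_by_sample[samp]))
      prec <- if (n_peaks(sp) > 0) sp$precursor_mz else table$features$mz[i]
      m1 <- if (length(staxa) > 0) {
        ms1_adduct_match(prec, library, staxa, tree, params)
      } else {
        NULL
      }
      if (!is.null(m1) && nrow(m1) > 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          row_id = table$features$row_id[i], tier = "ms1",
          rank = seq_len(nrow(m1)), structure_id = m1$structure_id,
          sigma = NA_real_, n_matched = NA_integer_, distance = NA_real_,
          final_score = NA_real_, pathway = NA_character_,
          superclass = NA_character_, class = NA_character_
        )
      }
    }
  }
  records <- if (length(rows) > 0) do.call(rbind, rows) else tibble::tibble(
    row_id = integer(), tier = character(), rank = integer(),
    structure_id = character(), sigma = numeric(), n_matched = integer(),
    distance = numeric(), final_score = numeric(), pathway = character(),
    superclass = character(), class = character()
  )
  coverage <- vapply(c("pathway", "superclass", "class"), function(lv) {
    mean(!is.na(cons$consensus[[lv]]))
  }, numeric(1))
  structure(
    list(records = records, consensus = cons$consensus, coverage = coverage),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf(
    "<annotation_set> %d records over %d features; consensus coverage: pathway %.0f%%, superclass %.0f%%, class %.0f%%\n",
    nrow(x$records), length(unique(x$records$row_id)),
    100 * x$coverage[["pathway"]], 100 * x$coverage[["superclass"]],
    100 * x$coverage[["class"]]
  ))
  invisible(x)
}

#' Write annotation records as TSV
#'
#' @param annotations an `annotation_set`.
#' @param path output TSV path.
#' @return `path` invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
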