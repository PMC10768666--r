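# Host-versus-fungal-community comparison: shared features and molecular
# families, per-strain overlap, fractionation enrichment, chemical-class
# distributions, and ground-truth recovery scoring for synthetic runs.

#' Percentage with half-up rounding
#'
#' The single rounding rule used for every printed percentage in the
#' package's reports: `round_half_up(100 * n / total, digits)`.
#'
#' @param n numerator count.
#' @param total denominator count.
#' @param digits decimal places (0 for headline shared percentages, 1 for
#'   enrichment percentages).
#' @return percentage in [0, 100].
#' @export
#' @examples
#' pct_of(860, 24096)      # 4
#' pct_of(510, 13884, 1)   # 3.7
pct_of <- function(n, total, digits = 0) {
  if (total <= 0) return(NA_real_)
  round_half_up(100 * n / total, digits)
}

present_ids <- function(table) table$features$row_id

#' Features shared between the host and fungal datasets
#'
#' A feature is shared when it is called present (by the replicate
#' co-occurrence rule) in at least one host sample and at least one fungal
#' sample. The percentage is taken over the union of both datasets' feature
#' ids (the general dataset).
#'
#' @param host_table,fungal_table the split `feature_table`s (order
#'   irrelevant; the statistic is symmetric).
#' @param digits rounding for the percentage (default 0).
#' @return list `n_shared`, `n_total`, `pct_shared`, `ids`.
#' @export
shared_features <- function(host_table, fungal_table, digits = 0) {
  h <- present_ids(host_table)
  f <- present_ids(fungal_table)
  shared <- sort(intersect(h, f))
  total <- length(union(h, f))
  if (length(h) > 0 && length(f) > 0 && length(shared) == 0 &&
      (min(h) > max(f) || min(f) > max(h))) {
    # id ranges do not even overlap: the tables were not split from one
    # aligned general table
    stopf("tables do not share a feature id space")
  }
  list(n_shared = length(shared), n_total = total,
       pct_shared = pct_of(length(shared), total, digits), ids = shared)
}

#' Molecular families shared between host and fungal datasets
#'
#' A family is shared iff it contains at least one node present in the host
#' dataset and at least one present in the fungal dataset; a single node
#' present in both suffices.
#'
#' @param network a `molecular_network`.
#' @param host_ids,fungal_ids row ids present in each dataset.
#' @return list `n_shared_clusters`, `family_ids`.
#' @export
shared_clusters <- function(network, host_ids, fungal_ids) {
  nd <- network$nodes
  host_fam <- unique(nd$family[nd$id %in% as.character(host_ids)])
  fungal_fam <- unique(nd$family[nd$id %in% as.character(fungal_ids)])
  fam <- sort(intersect(host_fam, fungal_fam))
  list(n_shared_clusters = length(fam), family_ids = fam)
}

#' Per-strain overlap with the host metabolome
#'
#' For each fungal strain: the number of features present in at least one
#' of that strain's samples, the number of those also present in at least
#' one host sample, and the shared percentage of the strain's features.
#'
#' @param table the averaged general `feature_table` (with presence calls
#'   and metadata).
#' @param digits rounding for the per-strain percentage.
#' @return tibble `strain`, `n_features`, `n_shared`, `pct_shared`
#'   (`NA` for strains with zero features).
#' @export
per_strain_overlap <- function(table, digits = 1) {
  if (is.null(table$metadata) || is.null(table$presence)) {
    stopf("per_strain_overlap needs metadata and presence calls")
  }
  meta <- table$metadata
  pres <- table$presence
  host_samples <- meta$sample_id[meta$sample_type %in% c("fraction", "crude")]
  host_any <- rowSums(pres[, colnames(pres) %in% host_samples,
                           drop = FALSE]) > 0
  strains <- sort(unique(meta$organism[meta$sample_type == "fungal"]))
  out <- lapply(strains, function(st) {
    cols <- meta$sample_id[meta$sample_type == "fungal" & meta$organism == st]
    mine <- rowSums(pres[, colnames(pres) %in% cols, drop = FALSE]) > 0
    n <- sum(mine)
    n_shared <- sum(mine & host_any)
    tibble::tibble(
      strain = st, n_features = n, n_shared = n_shared,
      pct_shared = if (n == 0) NA_real_ else pct_of(n_shared, n, digits)
    )
  })
  do.call(rbind, out)
}

#' Crude-extract versus fractionation enrichment statistics
#'
#' Counts features present in the crude extract and in at least one
#' fraction, the crude share of the host dataset (1-decimal half-up), the
#' fold enrichment achieved by fractionation, and -- when the fungal table
#' is supplied -- the host-fungal overlap obtainable from crude-extract
#' profiling alone, as a percentage of the general dataset.
#'
#' @param host_table the split host `feature_table`.
#' @param fungal_table optional split fungal `feature_table`.
#' @return list `n_crude`, `n_fractions`, `n_host_total`, `pct_crude`,
#'   `fold_enrichment`, `has_crude`, and (with `fungal_table`)
#'   `n_shared_crude_only`, `pct_shared_crude_only`, `n_general_total`.
#' @export
enrichment_stats <- function(host_table, fungal_table = NULL) {
  meta <- host_table$metadata
  pres <- host_table$presence
  crude_samples <- meta$sample_id[meta$sample_type == "crude"]
  frac_samples <- meta$sample_id[meta$sample_type == "fraction"]
  has_crude <- length(intersect(crude_samples, colnames(pres))) > 0
  crude_rows <- rowSums(pres[, colnames(pres) %in% crude_samples,
                             drop = FALSE]) > 0
  frac_rows <- rowSums(pres[, colnames(pres) %in% frac_samples,
                            drop = FALSE]) > 0
  n_host_total <- nrow(host_table$features)
  out <- list(
    n_crude = sum(crude_rows),
    n_fractions = sum(frac_rows),
    n_host_total = n_host_total,
    pct_crude = if (has_crude) pct_of(sum(crude_rows), n_host_total, 1) else NA_real_,
    fold_enrichment = if (has_crude && sum(crude_rows) > 0) {
      sum(frac_rows) / sum(crude_rows)
    } else {
      NA_real_
    },
    has_crude = has_crude
  )
  if (!has_crude) warnf("host table has no crude-extract sample; partial report")
  if (!is.null(fungal_table)) {
    crude_ids <- host_table$features$row_id[crude_rows]
    fungal_ids <- present_ids(fungal_table)
    n_general <- length(union(present_ids(host_table), fungal_ids))
    shared_crude <- intersect(crude_ids, fungal_ids)
    out$n_shared_crude_only <- length(shared_crude)
    out$n_general_total <- n_general
    out$pct_shared_crude_only <- pct_of(length(shared_crude), n_general, 1)
  }
  out
}

#' Overlap report for a split dataset
#'
#' Combines [shared_features()], [shared_clusters()], [per_strain_overlap()]
#' and [enrichment_stats()] into one report satisfying the
#' inclusion-exclusion identity
#' `n_host_only + n_fungal_only + n_shared = n_total`.
#'
#' @param splits result of [split_datasets()].
#' @param network optional `molecular_network` on the general dataset.
#' @return an `overlap_report` list.
#' @export
overlap_report <- function(splits, network = NULL) {
  sf <- shared_features(splits$host, splits$fungal)
  h <- present_ids(splits$host); f <- present_ids(splits$fungal)
  rep <- list(
    n_total = sf$n_total,
    n_host_only = length(setdiff(h, f)),
    n_fungal_only = length(setdiff(f, h)),
    n_shared = sf$n_shared,
    pct_shared = sf$pct_shared,
    shared_ids = sf$ids,
    per_strain = per_strain_overlap(splits$general),
    crude_vs_fractions = enrichment_stats(splits$host, splits$fungal)
  )
  if (!is.null(network)) {
    sc <- shared_clusters(network, h, f)
    rep$n_shared_clusters <- sc$n_shared_clusters
    rep$shared_family_ids <- sc$family_ids
  }
  class(rep) <- "overlap_report"
  rep
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf(
    paste0("<overlap_report> %d features: %d host-only, %d fungal-only, ",
           "%d shared (%s%%)\n"),
    x$n_total, x$n_host_only, x$n_fungal_only, x$n_shared,
    format(x$pct_shared)
  ))
  if (!is.null(x$n_shared_clusters)) {
    cat(sprintf("  shared molecular families: %d\n", x$n_shared_clusters))
  }
  invisible(x)
}

#' Chemical-class distribution at one ontology level
#'
#' Counts features per consensus label at the given level among the
#' annotated features of a subset; unannotated features are excluded from
#' the denominator.
#'
#' @param annotations an `annotation_set`.
#' @param ids feature row ids of the subset (default: all).
#' @param level one of "pathway", "superclass", "class".
#' @param digits rounding for percentages.
#' @return a `class_distribution`: list with `level`, `table` (tibble
#'   `label`, `count`, `percent`), `n_annotated`, `n_total`.
#' @export
class_distribution <- function(annotations, ids = NULL,
                               level = c("pathway", "superclass", "class"),
                               digits = 1) {
  level <- match.arg(level)
  cons <- annotations$consensus
  if (!is.null(ids)) cons <- cons[cons$id %in% as.character(ids), ]
  n_total <- nrow(cons)
  lab <- cons[[level]]
  lab <- lab[!is.na(lab)]
  n_ann <- length(lab)
  tab <- if (n_ann > 0) {
    cnt <- sort(table(lab), decreasing = TRUE)
    tibble::tibble(
      label = names(cnt), count = as.integer(cnt),
      percent = vapply(as.integer(cnt), pct_of, numeric(1),
                       total = n_ann, digits = digits)
    )
  } else {
    tibble::tibble(label = character(), count = integer(), percent = numeric())
  }
  structure(list(level = level, table = tab, n_annotated = n_ann,
                 n_total = n_total),
            class = "class_distribution")
}

#' Export a three-level sunburst JSON
#'
#' Nested pathway -> superclass -> class counts built from the consensus
#' triples of fully annotated features; child counts sum to their parent's
#' count. A label observed under two different parents violates the
#' hierarchy and raises an error.
#'
#' @param annotations an `annotation_set`.
#' @param path output JSON path (NULL to return the structure).
#' @param ids optional feature subset.
#' @return the nested list, invisibly if written.
#' @export
sunburst_export <- function(annotations, path = NULL, ids = NULL) {
  cons <- annotations$consensus
  if (!is.null(ids)) cons <- cons[cons$id %in% as.character(ids), ]
  full <- !is.na(cons$pathway) & !is.na(cons$superclass) & !is.na(cons$class)
  cons <- cons[full, ]
  for (pair in list(c("superclass", "pathway"), c("class", "superclass"))) {
    par_of <- tapply(cons[[pair[2]]], cons[[pair[1]]],
                     function(x) length(unique(x)))
    if (any(par_of > 1)) {
      stopf("hierarchy violation: %s '%s' has multiple parents",
            pair[1], names(par_of)[par_of > 1][1])
    }
  }
  children_pw <- lapply(sort(unique(cons$pathway)), function(pw) {
    sub_pw <- cons[cons$pathway == pw, ]
    children_sc <- lapply(sort(unique(sub_pw$superclass)), function(sc) {
      sub_sc <- sub_pw[sub_pw$superclass == sc, ]
      children_cl <- lapply(sort(unique(sub_sc$class)), function(cl) {
        list(name = cl, count = sum(sub_sc$class == cl))
      })
      list(name = sc, count = nrow(sub_sc), children = children_cl)
    })
    list(name = pw, count = nrow(sub_pw), children = children_sc)
  })
  root <- list(name = "all", count = nrow(cons), children = children_pw)
  if (!is.null(path)) {
    jsonlite::write_json(root, path, auto_unbox = TRUE, digits = NA)
    return(invisible(root))
  }
  root
}

#' Map aligned features back to ground-truth metabolites
#'
#' Matches consensus m/z against the protonated metabolite mass (within
#' `ppm`) and consensus RT against the true RT (within `rt_tol` minutes);
#' the nearest metabolite wins.
#'
#' @param table a `feature_table`.
#' @param truth a `ground_truth`.
#' @param ppm m/z matching tolerance.
#' @param rt_tol RT matching tolerance, minutes.
#' @return character vector of metabolite ids (NA if unmatched), one per
#'   feature row.
#' @export
match_features_to_truth <- function(table, truth, ppm = 20, rt_tol = 0.1) {
  m <- truth$metabolites
  target_mz <- m$monoisotopic_mass + PROTON_MASS
  vapply(seq_len(nrow(table$features)), function(i) {
    dppm <- ppm_diff(table$features$mz[i], target_mz)
    drt <- abs(table$features$rt[i] - m$rt_true)
    ok <- which(dppm <= ppm & drt <= rt_tol)
    if (length(ok) == 0) return(NA_character_)
    m$id[ok[which.min(dppm[ok])]]
  }, character(1))
}

#' Ground-truth recovery report for a synthetic run
#'
#' Scores the shared / host-only / strain-specific calls against the
#' generator's membership ground truth (precision and recall per category;
#' reported as NA when undefined), plus rank-1 annotation accuracy over
#' features that map to a ground-truth metabolite.
#'
#' @param splits result of [split_datasets()].
#' @param truth the `ground_truth` behind the simulated data.
#' @param annotations optional `annotation_set` for rank-1 accuracy.
#' @return a `recovery_report` list.
#' @export
recovery_report <- function(splits, truth, annotations = NULL) {
  gen <- splits$general
  mapped <- match_features_to_truth(gen, truth)
  if (all(is.na(mapped)) && nrow(gen$features) > 0) {
    stopf("no feature could be mapped to the ground truth; id mismatch?")
  }
  ids <- gen$features$row_id
  h <- present_ids(splits$host); f <- present_ids(splits$fungal)
  call_of <- ifelse(ids %in% h & ids %in% f, "shared_host_strain",
                    ifelse(ids %in% h, "host_only", "strain_specific"))
  truth_cat <- truth$membership[mapped]
  # multi_strain metabolites are fungal-community members: their correct
  # call at the host/fungal level is strain_specific (not host-detected)
  truth_call <- ifelse(truth_cat == "multi_strain", "strain_specific", truth_cat)
  truth_n <- c(
    host_only = sum(truth$membership == "host_only"),
    strain_specific = sum(truth$membership %in%
                            c("strain_specific", "multi_strain")),
    shared_host_strain = sum(truth$membership == "shared_host_strain")
  )
  per_category <- lapply(
    stats::setNames(nm = names(truth_n)),
    function(cat) {
      pred <- !is.na(mapped) & call_of == cat
      pos <- !is.na(truth_call) & truth_call == cat
      tp <- sum(pred & pos)
      list(
        precision = if (sum(pred) == 0) NA_real_ else tp / sum(pred),
        recall = if (truth_n[[cat]] == 0) NA_real_ else
          length(unique(mapped[pred & pos])) / truth_n[[cat]],
        n_predicted = sum(pred), n_truth = truth_n[[cat]]
      )
    }
  )
  rank1 <- NA_real_
  if (!is.null(annotations)) {
    rec <- annotations$records
    top <- rec[rec$tier == "ms2" & rec$rank == 1, ]
    idx <- match(top$row_id, ids)
    ok <- !is.na(idx) & !is.na(mapped[idx])
    if (any(ok)) {
      rank1 <- mean(top$structure_id[ok] == paste0("STR_", mapped[idx][ok]))
    }
  }
  structure(
    list(per_category = per_category, rank1_accuracy = rank1,
         n_features = length(ids), n_mapped = sum(!is.na(mapped))),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  for (nm in names(x$per_category)) {
    pc <- x$per_category[[nm]]
    cat(sprintf("  %-20s precision %s recall %s (n_pred %d, n_truth %d)\n",
                nm, format(pc$precision), format(pc$recall),
                pc$n_predicted, pc$n_truth))
  }
  cat(sprintf("  rank-1 annotation accuracy: %s\n", format(x$rank1_accuracy)))
  invisible(x)
}

#' Write an overlap or recovery report as JSON
#'
#' @param report an `overlap_report` or `recovery_report`.
#' @param path output JSON path.
#' @return `path` invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
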