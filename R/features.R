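# Feature-list post-processing: duplicate removal, isotope grouping, MS2
# presence filter and join alignment into a features x (sample, replicate)
# table. Mirrors the usual LC-MS pre-processing stage applied after
# chromatogram deconvolution.

#' Alignment and per-list filter parameters
#'
#' Defaults follow common practice for high-resolution orbitrap data:
#' duplicate filter 8 ppm / 0.03 min, isotope grouper 8 ppm / 0.02 min with
#' maximum charge 2, join aligner 10 ppm / 0.04 min with equal m/z and RT
#' weights of 10. All ppm tolerances are evaluated on the mean of the two
#' masses; RT tolerances are absolute minutes.
#'
#' @param dedup_ppm,dedup_rt_min duplicate-filter tolerances.
#' @param iso_ppm,iso_rt_min,iso_max_charge isotope-grouper tolerances and
#'   maximum charge considered.
#' @param align_ppm,align_rt_min join-aligner tolerances.
#' @param weight_mz,weight_rt join-aligner score weights.
#' @return an `align_params` list.
#' @export
align_params <- function(dedup_ppm = 8, dedup_rt_min = 0.03,
                         iso_ppm = 8, iso_rt_min = 0.02, iso_max_charge = 2,
                         align_ppm = 10, align_rt_min = 0.04,
                         weight_mz = 10, weight_rt = 10) {
  p <- list(dedup_ppm = dedup_ppm, dedup_rt_min = dedup_rt_min,
            iso_ppm = iso_ppm, iso_rt_min = iso_rt_min,
            iso_max_charge = as.integer(iso_max_charge),
            align_ppm = align_ppm, align_rt_min = align_rt_min,
            weight_mz = weight_mz, weight_rt = weight_rt)
  if (any(unlist(p) <= 0)) stopf("all alignment parameters must be positive")
  structure(p, class = "align_params")
}

#' Feature-table filter parameters
#'
#' @param n_replicates_required replicates in which a feature must be
#'   detected, in at least one biological sample, to be retained (default 3:
#'   all replicates of at least one sample).
#' @param cooccurrence_min replicates required to call a retained feature
#'   "present" in any other sample (default 2).
#' @param blank_ratio a feature is discarded when its mean intensity across
#'   blank and media samples exceeds this fraction of its best biological
#'   sample mean.
#' @param ms2_required drop features without an MS/MS scan before alignment.
#' @return a `filter_params` list.
#' @export
filter_params <- function(n_replicates_required = 3, cooccurrence_min = 2,
                          blank_ratio = 0.1, ms2_required = TRUE) {
  if (cooccurrence_min > n_replicates_required) {
    stopf("cooccurrence_min must be <= n_replicates_required")
  }
  if (blank_ratio < 0) stopf("blank_ratio must be >= 0")
  structure(
    list(n_replicates_required = as.integer(n_replicates_required),
         cooccurrence_min = as.integer(cooccurrence_min),
         blank_ratio = blank_ratio, ms2_required = isTRUE(ms2_required)),
    class = "filter_params"
  )
}

# connected components over an edge list on vertices 1..n (without igraph
# overhead for tiny graphs): simple union-find
components_from_edges <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(from)) {
    a <- find(from[k]); b <- find(to[k])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  vapply(seq_len(n), find, integer(1))
}

#' Remove duplicate features within one sample replicate
#'
#' Features within both the m/z and RT tolerance are considered duplicates;
#' duplicate groups are resolved as connected components (a-b close and b-c
#' close places a, b, c in one group) and the highest-intensity member of
#' each group is kept.
#'
#' @param features feature tibble from a single sample x replicate.
#' @param params an [align_params()].
#' @return the deduplicated tibble.
#' @export
deduplicate <- function(features, params = align_params()) {
  n <- nrow(features)
  if (n < 2) return(features)
  dppm <- outer(features$mz, features$mz, ppm_diff)
  drt <- abs(outer(features$rt, features$rt, "-"))
  close <- dppm <= params$dedup_ppm & drt <= params$dedup_rt_min
  close[lower.tri(close, diag = TRUE)] <- FALSE
  idx <- which(close, arr.ind = TRUE)
  if (nrow(idx) == 0) return(features)
  comp <- components_from_edges(n, idx[, 1], idx[, 2])
  keep <- vapply(split(seq_len(n), comp), function(grp) {
    grp[which.max(features$intensity[grp])]
  }, integer(1))
  features[sort(keep), ]
}

#' Group isotopologue features within one sample replicate
#'
#' Features whose m/z values differ by approximately n * 1.003355 / z
#' (n in 1..2, z up to `iso_max_charge`) within the ppm tolerance and whose
#' RTs agree are grouped; each group is represented by its most intense
#' member (in practice the monoisotopic peak).
#'
#' @inheritParams deduplicate
#' @return tibble with isotope groups collapsed to their representative.
#' @export
group_isotopes <- function(features, params = align_params()) {
  n <- nrow(features)
  if (n < 2) return(features)
  spacings <- unique(as.vector(outer(1:2, seq_len(params$iso_max_charge),
                                     function(k, z) k * ISOTOPE_SPACING / z)))
  dmz <- abs(outer(features$mz, features$mz, "-"))
  tol_da <- params$iso_ppm * 1e-6 * outer(features$mz, features$mz, "+") / 2
  drt <- abs(outer(features$rt, features$rt, "-"))
  close <- matrix(FALSE, n, n)
  for (s in spacings) close <- close | abs(dmz - s) <= tol_da
  close <- close & drt <= params$iso_rt_min
  close[lower.tri(close, diag = TRUE)] <- FALSE
  idx <- which(close, arr.ind = TRUE)
  if (nrow(idx) == 0) return(features)
  from <- idx[, 1]; to <- idx[, 2]
  comp <- components_from_edges(n, from, to)
  keep <- vapply(split(seq_len(n), comp), function(grp) {
    grp[which.max(features$intensity[grp])]
  }, integer(1))
  features[sort(keep), ]
}

#' Keep only features carrying an MS/MS scan
#'
#' @param features feature tibble.
#' @return subset with a non-empty `spectrum`.
#' @export
filter_ms2 <- function(features) {
  has <- vapply(features$spectrum, function(s) n_peaks(s) > 0, logical(1))
  features[has, ]
}

# split a combined feature tibble into per-(sample, replicate) lists in
# deterministic order
split_feature_lists <- function(features) {
  key <- paste(features$sample_id, features$replicate, sep = "\r")
  lists <- split(features, key)
  lists[order(names(lists))]
}

#' Align per-sample feature lists into one feature table
#'
#' Greedy best-score-first join alignment: each incoming feature is scored
#' against every existing aligned row within both tolerances with
#' `score = weight_mz * (1 - ppm/align_ppm) + weight_rt * (1 - dRT/align_rt_min)`;
#' assignments are made in decreasing score order (ties broken by lower row
#' index, then lower feature id), at most one feature per row per list;
#' unmatched features open new rows. Row consensus m/z and RT are the means
#' of the members aligned so far and are updated after each list.
#'
#' @param per_sample_lists either a list of per-(sample, replicate) feature
#'   tibbles or one combined tibble carrying `sample_id` and `replicate`.
#' @param params an [align_params()].
#' @param metadata optional sample metadata tibble (one row per sample x
#'   replicate) attached to the table for downstream filtering.
#' @return a `feature_table`.
#' @export
align_join <- function(per_sample_lists, params = align_params(),
                       metadata = NULL) {
  if (is.data.frame(per_sample_lists)) {
    per_sample_lists <- split_feature_lists(per_sample_lists)
  }
  cols <- lapply(per_sample_lists, function(l) {
    if (nrow(l) == 0) return(c(NA_character_, NA_character_))
    c(l$sample_id[1], as.character(l$replicate[1]))
  })
  n_col <- length(per_sample_lists)

  row_mz_sum <- numeric(0); row_rt_sum <- numeric(0); row_n <- integer(0)
  row_best_int <- numeric(0)
  row_spec <- list(); row_metab <- character(0)
  cells <- vector("list", n_col)  # per column: (row, intensity, detected)

  for (l in seq_len(n_col)) {
    fl <- per_sample_lists[[l]]
    nf <- nrow(fl)
    assigned_row <- rep(NA_integer_, nf)
    n_rows <- length(row_n)
    if (nf > 0 && n_rows > 0) {
      row_mz <- row_mz_sum / row_n
      row_rt <- row_rt_sum / row_n
      dppm <- outer(fl$mz, row_mz, ppm_diff)
      drt <- abs(outer(fl$rt, row_rt, "-"))
      ok <- which(dppm <= params$align_ppm & drt <= params$align_rt_min,
                  arr.ind = TRUE)
      if (nrow(ok) > 0) {
        score <- params$weight_mz * (1 - dppm[ok] / params$align_ppm) +
          params$weight_rt * (1 - drt[ok] / params$align_rt_min)
        ord <- order(-score, ok[, 2], fl$feature_id[ok[, 1]])
        row_taken <- logical(n_rows)
        for (k in ord) {
          i <- ok[k, 1]; j <- ok[k, 2]
          if (is.na(assigned_row[i]) && !row_taken[j]) {
            assigned_row[i] <- j
            row_taken[j] <- TRUE
          }
        }
      }
    }
    if (nf > 0) {
      new_idx <- which(is.na(assigned_row))
      for (i in new_idx[order(fl$feature_id[new_idx])]) {
        row_mz_sum <- c(row_mz_sum, 0); row_rt_sum <- c(row_rt_sum, 0)
        row_n <- c(row_n, 0L); row_best_int <- c(row_best_int, -Inf)
        row_spec <- c(row_spec, list(NULL))
        row_metab <- c(row_metab, NA_character_)
        assigned_row[i] <- length(row_n)
      }
      for (i in seq_len(nf)) {
        j <- assigned_row[i]
        row_mz_sum[j] <- row_mz_sum[j] + fl$mz[i]
        row_rt_sum[j] <- row_rt_sum[j] + fl$rt[i]
        row_n[j] <- row_n[j] + 1L
        if (fl$intensity[i] > row_best_int[j] && n_peaks(fl$spectrum[[i]]) > 0) {
          row_best_int[j] <- fl$intensity[i]
          row_spec[[j]] <- fl$spectrum[[i]]
        }
        if (is.na(row_metab[j]) && "metabolite_id" %in% names(fl)) {
          row_metab[j] <- fl$metabolite_id[i]
        }
      }
      cells[[l]] <- cbind(row = assigned_row, intensity = fl$intensity)
    }
  }

  n_rows <- length(row_n)
  intensity <- matrix(0, nrow = n_rows, ncol = n_col)
  detection <- matrix(FALSE, nrow = n_rows, ncol = n_col)
  for (l in seq_len(n_col)) {
    cl <- cells[[l]]
    if (!is.null(cl) && nrow(cl) > 0) {
      intensity[cl[, "row"], l] <- cl[, "intensity"]
      detection[cl[, "row"], l] <- TRUE
    }
  }
  columns <- tibble::tibble(
    sample_id = vapply(cols, `[`, character(1), 1),
    replicate = suppressWarnings(as.integer(vapply(cols, `[`, character(1), 2)))
  )
  features <- tibble::tibble(
    row_id = seq_len(n_rows),
    mz = if (n_rows > 0) row_mz_sum / row_n else numeric(0),
    rt = if (n_rows > 0) row_rt_sum / row_n else numeric(0),
    n_members = row_n,
    spectrum = row_spec,
    metabolite_id = row_metab
  )
  new_feature_table(features, intensity, detection, columns, metadata)
}

new_feature_table <- function(features, intensity, detection, columns,
                              metadata = NULL, presence = NULL,
                              averaged = FALSE) {
  stopifnot(nrow(intensity) == nrow(features),
            ncol(intensity) == nrow(columns),
            all(dim(intensity) == dim(detection)))
  sample_meta <- NULL
  if (!is.null(metadata)) {
    keep <- c("sample_id", "sample_type", "organism", "taxon_id")
    keep <- intersect(keep, names(metadata))
    sample_meta <- unique(tibble::as_tibble(metadata)[, keep])
    bad <- setdiff(sample_meta$sample_type, SAMPLE_TYPES)
    if (length(bad) > 0) {
      stopf("unknown sample_type(s): %s", paste(bad, collapse = ", "))
    }
  }
  structure(
    list(features = features, intensity = intensity, detection = detection,
         columns = columns, metadata = sample_meta, presence = presence,
         averaged = averaged),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %d features x %d columns (%s)%s\n",
    nrow(x$features), ncol(x$intensity),
    if (x$averaged) "per-sample averages" else "sample x replicate",
    if (!is.null(x$presence)) ", with presence calls" else ""
  ))
  invisible(x)
}

#' Number of features in a table
#' @param table a `feature_table`.
#' @return integer count.
#' @export
n_features <- function(table) nrow(table$features)

# per-table lookup of sample types for each column's sample
column_sample_types <- function(table) {
  if (is.null(table$metadata)) {
    return(rep(NA_character_, nrow(table$columns)))
  }
  table$metadata$sample_type[match(table$columns$sample_id,
                                   table$metadata$sample_id)]
}

subset_feature_table <- function(table, rows = NULL, cols = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(table$features))
  if (is.null(cols)) cols <- seq_len(ncol(table$intensity))
  presence <- table$presence
  if (!is.null(presence)) {
    keep_samples <- unique(table$columns$sample_id[cols])
    presence <- presence[rows, colnames(presence) %in% keep_samples,
                         drop = FALSE]
  }
  new_feature_table(
    table$features[rows, ],
    table$intensity[rows, cols, drop = FALSE],
    table$detection[rows, cols, drop = FALSE],
    table$columns[cols, ],
    if (is.null(table$metadata)) NULL else
      table$metadata[table$metadata$sample_id %in%
                       unique(table$columns$sample_id[cols]), ],
    presence = presence,
    averaged = table$averaged
  )
}
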