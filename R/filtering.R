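# Feature-table filtering: blank subtraction, replicate-based detection
# calls, normalization/averaging and host/fungal dataset splitting.

# replicate-mean intensity per sample: features x samples matrix
sample_means <- function(table) {
  samples <- unique(table$columns$sample_id)
  out <- matrix(0, nrow = nrow(table$features), ncol = length(samples),
                dimnames = list(NULL, samples))
  for (s in samples) {
    cols <- which(table$columns$sample_id == s)
    out[, s] <- rowMeans(table$intensity[, cols, drop = FALSE])
  }
  out
}

# per-sample detection counts: features x samples integer matrix
detection_counts <- function(table) {
  samples <- unique(table$columns$sample_id)
  out <- matrix(0L, nrow = nrow(table$features), ncol = length(samples),
                dimnames = list(NULL, samples))
  for (s in samples) {
    cols <- which(table$columns$sample_id == s)
    out[, s] <- as.integer(rowSums(table$detection[, cols, drop = FALSE]))
  }
  out
}

#' Discard blank-borne features
#'
#' A feature row is removed when its mean intensity across blank and media
#' samples exceeds `blank_ratio` times its best mean intensity across
#' biological samples; blank and media columns are dropped from the output.
#' If the table carries no blank samples the table is returned unchanged
#' with a warning.
#'
#' @param table a `feature_table` with metadata marking blank samples.
#' @param params a [filter_params()].
#' @return filtered `feature_table` without blank columns.
#' @export
filter_blank <- function(table, params = filter_params()) {
  if (is.null(table$metadata)) stopf("filter_blank needs sample metadata")
  types <- column_sample_types(table)
  blank_cols <- which(types %in% c("blank", "media_blank"))
  if (length(blank_cols) == 0) {
    warnf("no blank or media samples present; table unchanged")
    return(table)
  }
  bio_cols <- which(types %in% BIOLOGICAL_TYPES)
  blank_mean <- rowMeans(table$intensity[, blank_cols, drop = FALSE])
  means <- sample_means(table)
  bio_samples <- unique(table$columns$sample_id[bio_cols])
  best_bio <- apply(means[, bio_samples, drop = FALSE], 1, max)
  keep <- which(blank_mean <= params$blank_ratio * best_bio)
  subset_feature_table(table, rows = keep,
                       cols = setdiff(seq_along(types), blank_cols))
}

#' Replicate-based retention and presence calls
#'
#' A feature row is retained iff it was detected in all
#' `n_replicates_required` replicates of at least one biological sample.
#' For retained rows, the feature is called present in any sample where it
#' was detected in at least `cooccurrence_min` replicates; detections below
#' that are zeroed out. The presence calls are stored in the returned
#' table's `presence` matrix (features x samples).
#'
#' @param table a `feature_table` (after blank filtering).
#' @param params a [filter_params()].
#' @return filtered `feature_table` with a `presence` matrix.
#' @export
filter_replicates <- function(table, params = filter_params()) {
  if (is.null(table$metadata)) stopf("filter_replicates needs sample metadata")
  types <- column_sample_types(table)
  samples <- unique(table$columns$sample_id)
  n_reps <- vapply(samples, function(s) sum(table$columns$sample_id == s),
                   integer(1))
  sample_types <- table$metadata$sample_type[match(samples,
                                                   table$metadata$sample_id)]
  bio <- sample_types %in% BIOLOGICAL_TYPES
  offenders <- samples[bio & n_reps != params$n_replicates_required]
  if (length(offenders) > 0) {
    stopf("samples with replicate count != %d: %s",
          params$n_replicates_required, paste(offenders, collapse = ", "))
  }
  counts <- detection_counts(table)
  retained <- which(apply(
    counts[, samples[bio], drop = FALSE] >= params$n_replicates_required,
    1, any
  ))
  presence <- counts[retained, , drop = FALSE] >= params$cooccurrence_min
  out <- subset_feature_table(table, rows = retained)
  # zero out sub-threshold co-occurrence intensities
  for (s in samples) {
    cols <- which(out$columns$sample_id == s)
    absent <- !presence[, s]
    if (any(absent)) {
      out$intensity[absent, cols] <- 0
      out$detection[absent, cols] <- FALSE
    }
  }
  out$presence <- presence
  out
}

#' Average replicates and normalize by feature
#'
#' Replicate means are computed per sample, then each feature row is scaled
#' so its intensity sum across samples equals 1.
#'
#' @param table a replicate-filtered `feature_table`.
#' @return an averaged `feature_table` (one column per sample).
#' @export
normalize_average <- function(table) {
  means <- sample_means(table)
  rs <- rowSums(means)
  if (any(rs == 0)) {
    stopf("cannot normalize all-zero feature row(s): %s",
          paste(table$features$row_id[rs == 0], collapse = ", "))
  }
  norm <- means / rs
  samples <- colnames(means)
  presence <- table$presence
  if (!is.null(presence)) {
    presence <- presence[, samples, drop = FALSE]
  } else {
    presence <- means > 0
  }
  new_feature_table(
    table$features,
    norm,
    presence,
    tibble::tibble(sample_id = samples, replicate = NA_integer_),
    table$metadata,
    presence = presence,
    averaged = TRUE
  )
}

#' Split a processed table into fungal, host and general datasets
#'
#' The fungal dataset holds the rows called present in at least one fungal
#' sample and only the fungal sample columns; the host dataset likewise for
#' fraction/crude samples; the general dataset is their union with all
#' columns. Row ids are preserved so overlap between datasets is computable.
#'
#' @param table an averaged `feature_table` with presence calls.
#' @return named list of `feature_table`s: `fungal`, `host`, `general`.
#' @export
split_datasets <- function(table) {
  if (is.null(table$metadata)) stopf("split_datasets needs sample metadata")
  if (is.null(table$presence)) stopf("split_datasets needs presence calls; run filter_replicates first")
  types <- column_sample_types(table)
  if (anyNA(types)) stopf("unknown sample_type for some samples")
  samples <- table$columns$sample_id
  fungal_samples <- samples[types == "fungal"]
  host_samples <- samples[types %in% c("fraction", "crude")]
  pres <- table$presence
  fungal_rows <- which(rowSums(pres[, colnames(pres) %in% fungal_samples,
                                    drop = FALSE]) > 0)
  host_rows <- which(rowSums(pres[, colnames(pres) %in% host_samples,
                                  drop = FALSE]) > 0)
  general_rows <- sort(union(fungal_rows, host_rows))
  list(
    fungal = subset_feature_table(table, rows = fungal_rows,
                                  cols = which(types == "fungal")),
    host = subset_feature_table(table, rows = host_rows,
                                cols = which(types %in% c("fraction", "crude"))),
    general = subset_feature_table(table, rows = general_rows)
  )
}

#' Run the full feature-table processing chain
#'
#' Deduplication, isotope grouping and (optionally) the MS2-presence filter
#' per sample replicate, then join alignment, blank subtraction, replicate
#' filtering, and replicate averaging with per-feature normalization.
#'
#' @param features combined per-sample feature tibble (e.g. from
#'   [simulate_samples()] or [read_mgf()]).
#' @param metadata sample metadata tibble.
#' @param align an [align_params()].
#' @param filter a [filter_params()].
#' @return averaged, filtered `feature_table`.
#' @export
process_features <- function(features, metadata, align = align_params(),
                             filter = filter_params()) {
  lists <- split_feature_lists(features)
  lists <- lapply(lists, function(l) {
    l <- deduplicate(l, align)
    l <- group_isotopes(l, align)
    if (filter$ms2_required) l <- filter_ms2(l)
    l
  })
  table <- align_join(lists, align, metadata)
  table <- filter_blank(table, filter)
  table <- filter_replicates(table, filter)
  normalize_average(table)
}

#' Export a feature table as CSV
#'
#' Writes an intensity CSV (`row_id`, `mz`, `rt`, one column per sample /
#' sample-replicate) and, when presence calls exist, a companion
#' detection-call CSV with 0/1 entries.
#'
#' @param table a `feature_table`.
#' @param path intensity CSV path; the companion file gets suffix
#'   `_presence.csv`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  labels <- ifelse(is.na(table$columns$replicate),
                   table$columns$sample_id,
                   paste0(table$columns$sample_id, "_r", table$columns$replicate))
  df <- data.frame(row_id = table$features$row_id,
                   mz = table$features$mz, rt = table$features$rt)
  intens <- as.data.frame(table$intensity)
  names(intens) <- labels
  utils::write.csv(cbind(df, intens), path, row.names = FALSE)
  if (!is.null(table$presence)) {
    pres <- as.data.frame(table$presence * 1L)
    utils::write.csv(cbind(df["row_id"], pres),
                     sub("\\.csv$", "_presence.csv", path), row.names = FALSE)
  }
  invisible(path)
}
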