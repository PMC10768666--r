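# Readers and writers for the plain-text interchange formats the pipeline
# consumes and produces: MGF feature spectra, MSP standards libraries, TSV
# sample metadata and taxonomy lineages.

#' Write per-sample features to an MGF file
#'
#' One `BEGIN IONS` block per feature, using GNPS-dialect keys
#' (`FEATURE_ID`, `PEPMASS`, `RTINSECONDS`, `CHARGE`) plus `SAMPLE_ID` /
#' `REPLICATE` fields so a whole dataset can live in a single file. Features
#' without an MS/MS scan are written with an empty peak list.
#'
#' @param features tibble with columns `feature_id`, `sample_id`,
#'   `replicate`, `mz`, `rt` (minutes), `intensity`, and a `spectrum`
#'   list-column of [ms2_spectrum()] or `NULL`; an optional `metabolite_id`
#'   column (ground-truth provenance) is preserved.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(features, path) {
  con <- tryCatch(file(path, "w"), error = function(e) {
    stopf("cannot open '%s' for writing: %s", path, conditionMessage(e))
  })
  on.exit(close(con))
  has_truth <- "metabolite_id" %in% names(features)
  n <- nrow(features)
  blocks <- character(n)
  for (i in seq_len(n)) {
    sp <- features$spectrum[[i]]
    hdr <- c(
      "BEGIN IONS",
      sprintf("FEATURE_ID=%d", features$feature_id[i]),
      sprintf("PEPMASS=%.9f %.6e", features$mz[i], features$intensity[i]),
      sprintf("RTINSECONDS=%.9f", features$rt[i] * 60),
      "CHARGE=1+",
      "MSLEVEL=2",
      sprintf("SAMPLE_ID=%s", features$sample_id[i]),
      sprintf("REPLICATE=%d", features$replicate[i])
    )
    if (has_truth && !is.na(features$metabolite_id[i])) {
      hdr <- c(hdr, sprintf("METABOLITE_ID=%s", features$metabolite_id[i]))
    }
    pk <- if (n_peaks(sp) > 0) sprintf("%.9f %.9e", sp$mz, sp$intensity) else character()
    blocks[i] <- paste(c(hdr, pk, "END IONS"), collapse = "\n")
  }
  writeLines(blocks, con)
  invisible(path)
}

#' Read an MGF feature file
#'
#' Accepts both the single-file layout written by [write_mgf()] (per-entry
#' `SAMPLE_ID`) and per-sample files (pass `sample_id` to fill the column).
#'
#' @param path MGF file path.
#' @param sample_id fallback sample id when entries carry none.
#' @return tibble in the layout accepted by [write_mgf()].
#' @export
read_mgf <- function(path, sample_id = NA_character_) {
  if (!file.exists(path)) stopf("MGF file not found: '%s'", path)
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends)) {
    stopf("corrupt MGF '%s': %d BEGIN IONS but %d END IONS",
          path, length(starts), length(ends))
  }
  n <- length(starts)
  feature_id <- integer(n); samp <- character(n); repl <- integer(n)
  mz <- numeric(n); rt <- numeric(n); inten <- numeric(n)
  metab <- rep(NA_character_, n)
  spectra <- vector("list", n)
  for (k in seq_len(n)) {
    block <- lines[(starts[k] + 1):(ends[k] - 1)]
    is_kv <- grepl("=", block, fixed = TRUE)
    kv <- block[is_kv]
    keys <- sub("=.*$", "", kv)
    vals <- sub("^[^=]*=", "", kv)
    names(vals) <- keys
    if (!all(c("FEATURE_ID", "PEPMASS", "RTINSECONDS") %in% keys)) {
      stopf("corrupt MGF '%s': entry %d lacks FEATURE_ID/PEPMASS/RTINSECONDS",
            path, k)
    }
    feature_id[k] <- as.integer(vals[["FEATURE_ID"]])
    pm <- strsplit(trimws(vals[["PEPMASS"]]), "\\s+")[[1]]
    mz[k] <- as.numeric(pm[1])
    inten[k] <- if (length(pm) > 1) as.numeric(pm[2]) else NA_real_
    rt[k] <- as.numeric(vals[["RTINSECONDS"]]) / 60
    samp[k] <- if ("SAMPLE_ID" %in% keys) vals[["SAMPLE_ID"]] else sample_id
    repl[k] <- if ("REPLICATE" %in% keys) as.integer(vals[["REPLICATE"]]) else 1L
    if ("METABOLITE_ID" %in% keys) metab[k] <- vals[["METABOLITE_ID"]]
    pk <- block[!is_kv]
    pk <- pk[nzchar(trimws(pk))]
    if (length(pk) > 0) {
      m <- suppressWarnings(
        do.call(rbind, lapply(strsplit(trimws(pk), "\\s+"), as.numeric))
      )
      if (anyNA(m)) stopf("corrupt MGF '%s': unparseable peak in entry %d", path, k)
      spectra[[k]] <- ms2_spectrum(mz[k], rt[k], m[, 1], m[, 2])
    } else {
      spectra[k] <- list(NULL)
    }
  }
  tibble::tibble(
    feature_id = feature_id, sample_id = samp, replicate = repl,
    mz = mz, rt = rt, intensity = inten,
    spectrum = spectra, metabolite_id = metab
  )
}

#' Write / read the sample metadata table
#'
#' TSV with one row per sample x replicate: `sample_id`, `replicate`,
#' `sample_type` (one of fungal, fraction, crude, blank, media_blank, qc),
#' `organism`, `taxon_id`.
#'
#' @param metadata metadata tibble.
#' @param path TSV path.
#' @return `path` invisibly (write) or a tibble (read).
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_metadata
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stopf("metadata file not found: '%s'", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "replicate", "sample_type", "organism", "taxon_id")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stopf("metadata '%s' lacks columns: %s", path, paste(missing, collapse = ", "))
  }
  tibble::as_tibble(df)
}

#' Write / read an MSP spectral library (standards)
#'
#' Minimal NIST-style MSP: `Name`, `PrecursorMZ`, `RETENTIONTIME`,
#' `Num Peaks` followed by `mz intensity` lines.
#'
#' @param library a spectral library tibble (see [spectral_library()]).
#' @param path MSP path.
#' @return `path` invisibly (write) or a library tibble (read).
#' @export
write_msp <- function(library, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(library))) {
    sp <- library$spectrum[[i]]
    writeLines(c(
      sprintf("Name: %s", library$name[i]),
      sprintf("Synon: $:00%s", library$structure_id[i]),
      sprintf("PrecursorMZ: %.9f", sp$precursor_mz),
      sprintf("RETENTIONTIME: %.6f", sp$rt),
      sprintf("MW: %.9f", library$monoisotopic_mass[i]),
      sprintf("Num Peaks: %d", n_peaks(sp)),
      sprintf("%.9f %.9e", sp$mz, sp$intensity),
      ""
    ), con)
  }
  invisible(path)
}

#' @rdname write_msp
#' @export
read_msp <- function(path) {
  if (!file.exists(path)) stopf("MSP file not found: '%s'", path)
  lines <- readLines(path)
  name_idx <- grep("^Name:", lines)
  out <- vector("list", length(name_idx))
  bounds <- c(name_idx, length(lines) + 1L)
  for (k in seq_along(name_idx)) {
    block <- lines[bounds[k]:(bounds[k + 1] - 1L)]
    getv <- function(key) {
      ln <- grep(paste0("^", key, ":"), block, value = TRUE)
      if (length(ln) == 0) return(NA_character_)
      trimws(sub("^[^:]*:", "", ln[1]))
    }
    nm <- getv("Name")
    sid <- getv("Synon")
    sid <- if (is.na(sid)) nm else sub("^\\$:00", "", sid)
    prec <- as.numeric(getv("PrecursorMZ"))
    rt <- suppressWarnings(as.numeric(getv("RETENTIONTIME")))
    mass <- suppressWarnings(as.numeric(getv("MW")))
    npk_line <- grep("^Num Peaks:", block)
    npk <- as.integer(trimws(sub("^Num Peaks:", "", block[npk_line[1]])))
    pk <- block[(npk_line[1] + 1):(npk_line[1] + npk)]
    m <- do.call(rbind, lapply(strsplit(trimws(pk), "\\s+"), as.numeric))
    out[[k]] <- tibble::tibble(
      structure_id = sid, name = nm,
      monoisotopic_mass = if (is.na(mass)) prec - PROTON_MASS else mass,
      spectrum = list(ms2_spectrum(prec, rt, m[, 1], m[, 2]))
    )
  }
  lib <- do.call(rbind, out)
  lib$pathway <- NA_character_
  lib$superclass <- NA_character_
  lib$class <- NA_character_
  lib$source_taxa <- replicate(nrow(lib), character(), simplify = FALSE)
  class(lib) <- c("spectral_library", class(lib))
  lib
}

#' Write / read a taxonomy lineage table
#'
#' TSV with columns `taxon_id`, `name`, `rank`, `parent_id`; see
#' [taxonomy_tree()] for the rank vocabulary.
#'
#' @param tree a `taxonomy_tree`.
#' @param path TSV path.
#' @return `path` invisibly (write) or a `taxonomy_tree` (read).
#' @export
write_taxonomy <- function(tree, path) {
  utils::write.table(tree$nodes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_taxonomy
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stopf("taxonomy file not found: '%s'", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  taxonomy_tree(tibble::as_tibble(df))
}
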