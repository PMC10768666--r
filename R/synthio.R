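# Synthetic study generator.
#
# Emulates a host-plus-endophyte metabolomics design: one host leaf profiled
# as chromatographic fractions plus a crude extract, a panel of cultured
# fungal strains extracted in two solvent phases, solvent and culture-media
# blanks, and analytical replicates of everything. Ground truth (who
# produces what, with which fragmentation spectrum and chemical class) is
# carried alongside so every downstream stage can be scored.

MEMBERSHIP_LEVELS <- c("host_only", "strain_specific", "multi_strain",
                       "shared_host_strain", "contaminant", "media")

SAMPLE_TYPES <- c("fungal", "fraction", "crude", "blank", "media_blank", "qc")
BIOLOGICAL_TYPES <- c("fungal", "fraction", "crude")

#' Generate a three-level chemical-class ontology
#'
#' Builds a pathway -> superclass -> class hierarchy in the style of
#' natural-product class taxonomies: each pathway has `branching`
#' superclasses and each superclass has `branching` classes.
#'
#' @param n_pathways number of top-level pathways (>= 1).
#' @param branching children per node at each level (>= 1).
#' @param seed integer seed (kept for interface symmetry; the construction
#'   is deterministic).
#' @return a `class_ontology`: list with `levels` (ordered level names),
#'   `nodes` (level -> label vector) and `parent` (named vector mapping each
#'   label to its parent at the level above).
#' @export
#' @examples
#' ont <- generate_ontology(3, 2, seed = 1)
#' lengths(ont$nodes)  # 3 pathways, 6 superclasses, 12 classes
generate_ontology <- function(n_pathways, branching, seed = 0L) {
  if (n_pathways < 1 || branching < 1) {
    stopf("n_pathways and branching must be >= 1")
  }
  n_pathways <- as.integer(n_pathways)
  branching <- as.integer(branching)
  pw <- sprintf("pathway_%02d", seq_len(n_pathways))
  sc <- character(0); sc_parent <- character(0)
  cl <- character(0); cl_parent <- character(0)
  for (i in seq_len(n_pathways)) {
    for (j in seq_len(branching)) {
      s <- sprintf("superclass_%02d_%02d", i, j)
      sc <- c(sc, s); sc_parent <- c(sc_parent, pw[i])
      for (k in seq_len(branching)) {
        cl <- c(cl, sprintf("class_%02d_%02d_%02d", i, j, k))
        cl_parent <- c(cl_parent, s)
      }
    }
  }
  parent <- c(stats::setNames(sc_parent, sc), stats::setNames(cl_parent, cl))
  structure(
    list(
      levels = c("pathway", "superclass", "class"),
      nodes = list(pathway = pw, superclass = sc, class = cl),
      parent = parent
    ),
    class = "class_ontology"
  )
}

#' Noise profile for the synthetic instrument
#'
#' @param sigma lognormal sd of multiplicative intensity noise.
#' @param mz_ppm sd of relative m/z jitter, ppm.
#' @param rt_min sd of retention-time jitter, minutes.
#' @param dropout per-observation probability a detection is missed.
#' @param n_decoy number of uniform decoy peaks added to each MS/MS scan.
#' @return named list.
#' @export
noise_profile <- function(sigma = 0.3, mz_ppm = 2, rt_min = 0.005,
                          dropout = 0.1, n_decoy = 3) {
  if (dropout < 0 || dropout > 1) stopf("dropout must be in [0, 1]")
  if (sigma < 0 || mz_ppm < 0 || rt_min < 0 || n_decoy < 0) {
    stopf("noise components must be >= 0")
  }
  list(sigma = sigma, mz_ppm = mz_ppm, rt_min = rt_min,
       dropout = dropout, n_decoy = as.integer(n_decoy))
}

#' @rdname noise_profile
#' @export
zero_noise <- function() noise_profile(0, 0, 0, 0, 0)

default_strains <- function(n = 15) {
  ids <- sprintf("A%02d", seq_len(n))
  tibble::tibble(strain_id = ids, taxon_id = paste0("t_", tolower(ids)))
}

#' Describe a synthetic study design
#'
#' Defaults mirror a design of 15 fungal strains extracted in two phases
#' (30 fungal extracts), 47 chromatographic fractions plus one crude
#' extract of a single host leaf, analytical triplicates, and solvent and
#' uninoculated-media blanks.
#'
#' @param strains tibble with `strain_id`, `taxon_id`.
#' @param n_fractions number of host fractions.
#' @param n_replicates analytical replicates per sample (>= 2).
#' @param include_crude include the unfractionated crude extract.
#' @param n_solvent_blanks,n_media_blanks,n_qc numbers of control samples.
#' @param phases named vector of extraction-phase abundance factors for
#'   fungal samples (names become sample-id suffixes).
#' @param crude_dilution crude-extract abundance as a fraction of a host
#'   metabolite's total abundance (the fractionation step concentrates
#'   metabolites; the crude extract sees each at this dilution).
#' @param noise a [noise_profile()].
#' @param lod limit-of-detection intensity.
#' @param isotope_rate probability a detected feature also emits its M+1
#'   isotope feature.
#' @param host_taxon taxon id of the host.
#' @param seed integer seed; fully determines simulated output.
#' @return a `study_design` list.
#' @export
study_design <- function(strains = default_strains(15),
                         n_fractions = 47,
                         n_replicates = 3,
                         include_crude = TRUE,
                         n_solvent_blanks = 2,
                         n_media_blanks = 2,
                         n_qc = 0,
                         phases = c(Et = 1.0, W = 0.5),
                         crude_dilution = 0.02,
                         noise = noise_profile(),
                         lod = 1e4,
                         isotope_rate = 1.0,
                         host_taxon = "t_host",
                         seed = 1L) {
  if (n_replicates < 2) stopf("n_replicates must be >= 2")
  if (n_fractions < 1) stopf("n_fractions must be >= 1")
  if (isotope_rate < 0 || isotope_rate > 1) stopf("isotope_rate must be in [0, 1]")
  if (crude_dilution < 0) stopf("crude_dilution must be >= 0")
  stopifnot(all(c("strain_id", "taxon_id") %in% names(strains)))
  structure(
    list(
      strains = tibble::as_tibble(strains),
      n_fractions = as.integer(n_fractions),
      n_replicates = as.integer(n_replicates),
      include_crude = isTRUE(include_crude),
      n_solvent_blanks = as.integer(n_solvent_blanks),
      n_media_blanks = as.integer(n_media_blanks),
      n_qc = as.integer(n_qc),
      phases = phases,
      crude_dilution = crude_dilution,
      noise = noise,
      lod = lod,
      isotope_rate = isotope_rate,
      host_taxon = host_taxon,
      seed = as.integer(seed)
    ),
    class = "study_design"
  )
}

# rejection-sample (mass, rt) pairs so no two metabolites sit within both a
# small RT window and a small mass window at any 1- or 2-proton isotope
# spacing; keeps distinct metabolites identifiable through dedup/isotope/
# alignment stages
draw_mass_rt <- function(n, mass_range, rt_range) {
  spacings <- c(0, ISOTOPE_SPACING / 2, ISOTOPE_SPACING, 2 * ISOTOPE_SPACING)
  mass <- numeric(0); rt <- numeric(0)
  guard <- 0L
  while (length(mass) < n) {
    guard <- guard + 1L
    if (guard > 100000L) stopf("could not place %d metabolites in the mass/RT window", n)
    m <- stats::runif(1, mass_range[1], mass_range[2])
    r <- stats::runif(1, rt_range[1], rt_range[2])
    ok <- TRUE
    if (length(mass) > 0) {
      close_rt <- abs(rt - r) < 0.1
      if (any(close_rt)) {
        dm <- abs(mass[close_rt] - m)
        for (s in spacings) if (any(abs(dm - s) < 0.05)) { ok <- FALSE; break }
      }
    }
    if (ok) { mass <- c(mass, m); rt <- c(rt, r) }
  }
  list(mass = mass, rt = rt)
}

#' Generate a ground-truth metabolome
#'
#' Draws metabolites with monoisotopic mass, retention time, chemical-class
#' triple, fragmentation template, base abundance and a producer set per
#' membership category. Host-produced metabolites additionally get a
#' fraction-elution profile (discretized Gaussian over fraction index,
#' normalized to sum 1).
#'
#' @param ontology a [generate_ontology()] result.
#' @param design a [study_design()].
#' @param counts named counts per membership category: `host_only`,
#'   `strain_specific`, `multi_strain`, `shared_host_strain`, and optional
#'   `contaminant` (solvent-borne, present everywhere including blanks) and
#'   `media` (culture-medium metabolites, present in fungal samples and
#'   media blanks).
#' @param seed integer seed.
#' @param mass_range neutral monoisotopic mass window in Da.
#' @param rt_range retention-time window in minutes (the simulated 7-min
#'   gradient plus 1-min isocratic hold).
#' @return a `ground_truth` list: `metabolites` tibble, `membership`
#'   (named vector id -> category), `fraction_profile` (matrix, host
#'   metabolites x fractions, rows sum to 1), `design`, `ontology`.
#' @export
generate_metabolome <- function(ontology, design, counts, seed = design$seed,
                                mass_range = c(130, 1950),
                                rt_range = c(0.3, 7.7)) {
  if (!inherits(ontology, "class_ontology")) stopf("ontology must be a class_ontology")
  if (length(ontology$nodes$class) == 0) stopf("ontology has no classes")
  counts <- counts[names(counts) %in% MEMBERSHIP_LEVELS]
  full <- stats::setNames(integer(length(MEMBERSHIP_LEVELS)), MEMBERSHIP_LEVELS)
  full[names(counts)] <- as.integer(counts)
  if (any(full < 0)) stopf("counts must be non-negative")
  n <- sum(full)
  categories <- rep(names(full), full)

  with_seed(seed, {
    if (n == 0) {
      metab <- tibble::tibble(
        id = character(), monoisotopic_mass = numeric(), rt_true = numeric(),
        pathway = character(), superclass = character(), class = character(),
        producers = list(), fragment_mz = list(), fragment_int = list(),
        base_abundance = numeric(), isotope_ratio = numeric()
      )
      fp <- matrix(numeric(0), nrow = 0, ncol = design$n_fractions)
      return(structure(
        list(metabolites = metab, membership = stats::setNames(character(), character()),
             fraction_profile = fp, design = design, ontology = ontology),
        class = "ground_truth"
      ))
    }
    pos <- draw_mass_rt(n, mass_range, rt_range)
    ids <- sprintf("M%03d", seq_len(n))
    cls <- sample(ontology$nodes$class, n, replace = TRUE)
    scl <- unname(ontology$parent[cls])
    pwy <- unname(ontology$parent[scl])
    strains <- design$strains$strain_id
    producers <- vector("list", n)
    frag_mz <- vector("list", n); frag_int <- vector("list", n)
    for (i in seq_len(n)) {
      producers[[i]] <- switch(
        categories[i],
        host_only = "HOST",
        strain_specific = sample(strains, 1),
        multi_strain = sample(strains, min(length(strains), sample(2:5, 1))),
        shared_host_strain = c("HOST", sample(strains, min(length(strains), sample(1:3, 1)))),
        contaminant = "SOLVENT",
        media = "MEDIA"
      )
      k <- sample(6:12, 1)
      fmz <- sort(stats::runif(k, 50, pos$mass[i] - 10))
      fin <- stats::runif(k, 0.05, 1)
      fin <- fin / max(fin)
      frag_mz[[i]] <- fmz; frag_int[[i]] <- fin
    }
    base <- stats::rlnorm(n, meanlog = log(1e6), sdlog = 0.8)
    iso_ratio <- stats::runif(n, 0.05, 0.4)
    metab <- tibble::tibble(
      id = ids, monoisotopic_mass = pos$mass, rt_true = pos$rt,
      pathway = pwy, superclass = scl, class = cls,
      producers = producers, fragment_mz = frag_mz, fragment_int = frag_int,
      base_abundance = base, isotope_ratio = iso_ratio
    )
    host_ids <- ids[vapply(producers, function(p) "HOST" %in% p, logical(1))]
    fp <- matrix(0, nrow = length(host_ids), ncol = design$n_fractions,
                 dimnames = list(host_ids, NULL))
    for (h in host_ids) {
      center <- stats::runif(1, 1, design$n_fractions)
      width <- stats::runif(1, 1.0, 2.5)
      prof <- stats::dnorm(seq_len(design$n_fractions), center, width)
      fp[h, ] <- prof / sum(prof)
    }
    structure(
      list(metabolites = metab,
           membership = stats::setNames(categories, ids),
           fraction_profile = fp,
           design = design, ontology = ontology),
      class = "ground_truth"
    )
  })
}

# sample sheet implied by a design: one row per sample (not replicate)
sample_sheet <- function(design) {
  rows <- list()
  for (i in seq_len(nrow(design$strains))) {
    for (ph in names(design$phases)) {
      rows[[length(rows) + 1]] <- list(
        sample_id = paste0(design$strains$strain_id[i], "_", ph),
        sample_type = "fungal",
        organism = design$strains$strain_id[i],
        taxon_id = design$strains$taxon_id[i]
      )
    }
  }
  for (f in seq_len(design$n_fractions)) {
    rows[[length(rows) + 1]] <- list(
      sample_id = sprintf("F%02d", f), sample_type = "fraction",
      organism = "HOST", taxon_id = design$host_taxon
    )
  }
  if (design$include_crude) {
    rows[[length(rows) + 1]] <- list(
      sample_id = "CRUDE", sample_type = "crude",
      organism = "HOST", taxon_id = design$host_taxon
    )
  }
  for (b in seq_len(design$n_solvent_blanks)) {
    rows[[length(rows) + 1]] <- list(
      sample_id = sprintf("BLK%02d", b), sample_type = "blank",
      organism = "SOLVENT", taxon_id = NA_character_
    )
  }
  for (b in seq_len(design$n_media_blanks)) {
    rows[[length(rows) + 1]] <- list(
      sample_id = sprintf("MED%02d", b), sample_type = "media_blank",
      organism = "MEDIA", taxon_id = NA_character_
    )
  }
  for (q in seq_len(design$n_qc)) {
    rows[[length(rows) + 1]] <- list(
      sample_id = sprintf("QC%02d", q), sample_type = "qc",
      organism = "QC", taxon_id = NA_character_
    )
  }
  do.call(rbind, lapply(rows, function(r) tibble::as_tibble(r)))
}

# expected (noise-free) abundance of every metabolite in one sample
expected_abundance <- function(truth, sample_row) {
  m <- truth$metabolites
  design <- truth$design
  out <- numeric(nrow(m))
  has_prod <- function(who) vapply(m$producers, function(p) who %in% p, logical(1))
  contaminant <- has_prod("SOLVENT")
  media <- has_prod("MEDIA")
  out[contaminant] <- m$base_abundance[contaminant]
  type <- sample_row$sample_type
  if (type == "fungal") {
    phase <- sub("^.*_", "", sample_row$sample_id)
    fac <- truth$design$phases[[phase]]
    mine <- has_prod(sample_row$organism)
    out[mine] <- m$base_abundance[mine] * fac
    out[media] <- m$base_abundance[media]
  } else if (type == "fraction") {
    f <- as.integer(sub("^F", "", sample_row$sample_id))
    hosty <- intersect(rownames(truth$fraction_profile), m$id)
    idx <- match(hosty, m$id)
    out[idx] <- m$base_abundance[idx] * truth$fraction_profile[hosty, f]
  } else if (type == "crude") {
    hosty <- rownames(truth$fraction_profile)
    idx <- match(hosty, m$id)
    out[idx] <- m$base_abundance[idx] * design$crude_dilution
  } else if (type == "media_blank") {
    out[media] <- m$base_abundance[media]
  } else if (type == "qc") {
    bio <- has_prod("HOST") | vapply(m$producers, function(p)
      any(p %in% design$strains$strain_id), logical(1))
    out[bio] <- m$base_abundance[bio] * 0.1
    out[media] <- m$base_abundance[media] * 0.1
  }
  out
}

#' Simulate per-sample feature lists from a ground-truth metabolome
#'
#' Each metabolite detected in a sample replicate contributes a protonated
#' adduct feature (m/z = mass + 1.007276, jittered), an M+1 isotope feature
#' at the design's `isotope_rate` (no MS/MS scan), and an MS/MS spectrum
#' equal to its fragmentation template plus uniform decoy peaks. A feature
#' is detected iff its realized intensity reaches the limit of detection
#' and it is not dropped out.
#'
#' @param truth a [generate_metabolome()] result.
#' @return list with `features` (tibble, one row per detected feature) and
#'   `metadata` (tibble, one row per sample x replicate).
#' @export
simulate_samples <- function(truth) {
  if (!inherits(truth, "ground_truth")) stopf("truth must be a ground_truth")
  design <- truth$design
  sheet <- sample_sheet(design)
  noise <- design$noise
  m <- truth$metabolites

  with_seed(design$seed + 1L, {
    meta <- sheet[rep(seq_len(nrow(sheet)), each = design$n_replicates), ]
    meta$replicate <- rep(seq_len(design$n_replicates), nrow(sheet))
    meta <- meta[, c("sample_id", "replicate", "sample_type", "organism", "taxon_id")]

    chunks <- list()
    for (s in seq_len(nrow(sheet))) {
      exp_ab <- expected_abundance(truth, sheet[s, ])
      present <- which(exp_ab > 0)
      if (length(present) == 0) next
      np <- length(present)
      for (r in seq_len(design$n_replicates)) {
        realized <- exp_ab[present] *
          if (noise$sigma > 0) stats::rlnorm(np, 0, noise$sigma) else 1
        dropped <- if (noise$dropout > 0) stats::runif(np) < noise$dropout
                   else rep(FALSE, np)
        keep <- realized >= design$lod & !dropped
        idx <- present[keep]
        if (length(idx) == 0) next
        nk <- length(idx)
        realized <- realized[keep]
        mz0 <- m$monoisotopic_mass[idx] + PROTON_MASS
        mz <- mz0 * (1 + if (noise$mz_ppm > 0)
          stats::rnorm(nk, 0, noise$mz_ppm * 1e-6) else 0)
        rt <- m$rt_true[idx] + if (noise$rt_min > 0)
          stats::rnorm(nk, 0, noise$rt_min) else 0
        rt <- pmax(rt, 0)
        spectra <- lapply(seq_len(nk), function(j) {
          fr_mz <- m$fragment_mz[[idx[j]]]
          fr_in <- m$fragment_int[[idx[j]]] * realized[j]
          if (noise$n_decoy > 0) {
            dmz <- stats::runif(noise$n_decoy, 50, mz0[j] - 10)
            din <- stats::runif(noise$n_decoy, 0.005, 0.05) * max(fr_in)
            fr_mz <- c(fr_mz, dmz); fr_in <- c(fr_in, din)
          }
          ms2_spectrum(mz[j], rt[j], fr_mz, fr_in)
        })
        chunk <- tibble::tibble(
          feature_id = NA_integer_, sample_id = sheet$sample_id[s],
          replicate = r, mz = mz, rt = rt, intensity = realized,
          spectrum = spectra, metabolite_id = m$id[idx]
        )
        # M+1 isotope companions (no MS/MS scan of their own)
        iso_int <- realized * m$isotope_ratio[idx]
        iso_roll <- if (design$isotope_rate >= 1) rep(TRUE, nk)
                    else stats::runif(nk) < design$isotope_rate
        iso_keep <- iso_int >= design$lod & iso_roll
        if (any(iso_keep)) {
          iso <- tibble::tibble(
            feature_id = NA_integer_, sample_id = sheet$sample_id[s],
            replicate = r, mz = mz[iso_keep] + ISOTOPE_SPACING,
            rt = rt[iso_keep], intensity = iso_int[iso_keep],
            spectrum = replicate(sum(iso_keep), NULL, simplify = FALSE),
            metabolite_id = m$id[idx][iso_keep]
          )
          chunk <- rbind(chunk, iso)
        }
        chunks[[length(chunks) + 1]] <- chunk
      }
    }
    features <- if (length(chunks) > 0) {
      do.call(rbind, chunks)
    } else {
      tibble::tibble(
        feature_id = integer(), sample_id = character(), replicate = integer(),
        mz = numeric(), rt = numeric(), intensity = numeric(),
        spectrum = list(), metabolite_id = character()
      )
    }
    features$feature_id <- seq_len(nrow(features))
    list(features = features, metadata = meta)
  })
}

#' Write / read a complete synthetic fixture
#'
#' Writes `features.mgf` (one entry per feature), `metadata.tsv` and
#' `ground_truth.json` into `dir`; `read_fixture()` round-trips them.
#'
#' @param truth a `ground_truth`.
#' @param samples result of [simulate_samples()].
#' @param dir target directory (created if absent).
#' @return `dir` invisibly (write); a list `(truth, features, metadata)`
#'   (read).
#' @export
write_fixture <- function(truth, samples, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_mgf(samples$features, file.path(dir, "features.mgf"))
  write_sample_metadata(samples$metadata, file.path(dir, "metadata.tsv"))
  truth_json <- list(
    membership = as.list(truth$membership),
    fraction_profile = stats::setNames(
      lapply(seq_len(nrow(truth$fraction_profile)),
             function(i) truth$fraction_profile[i, ]),
      rownames(truth$fraction_profile)
    ),
    metabolites = lapply(seq_len(nrow(truth$metabolites)), function(i) {
      r <- truth$metabolites[i, ]
      list(id = r$id, monoisotopic_mass = r$monoisotopic_mass,
           rt_true = r$rt_true,
           class_triple = c(r$pathway, r$superclass, r$class),
           producers = r$producers[[1]],
           fragment_mz = r$fragment_mz[[1]], fragment_int = r$fragment_int[[1]],
           base_abundance = r$base_abundance, isotope_ratio = r$isotope_ratio)
    }),
    design = list(
      strains = truth$design$strains,
      n_fractions = truth$design$n_fractions,
      n_replicates = truth$design$n_replicates,
      include_crude = truth$design$include_crude,
      n_solvent_blanks = truth$design$n_solvent_blanks,
      n_media_blanks = truth$design$n_media_blanks,
      n_qc = truth$design$n_qc,
      phases = as.list(truth$design$phases),
      crude_dilution = truth$design$crude_dilution,
      noise = truth$design$noise,
      lod = truth$design$lod,
      isotope_rate = truth$design$isotope_rate,
      host_taxon = truth$design$host_taxon,
      seed = truth$design$seed
    ),
    ontology = list(
      levels = truth$ontology$levels,
      nodes = truth$ontology$nodes,
      parent = as.list(truth$ontology$parent)
    )
  )
  jsonlite::write_json(truth_json, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = FALSE)
  d <- gt$design
  design <- study_design(
    strains = tibble::tibble(
      strain_id = vapply(d$strains, function(x) x$strain_id, character(1)),
      taxon_id = vapply(d$strains, function(x) x$taxon_id, character(1))
    ),
    n_fractions = d$n_fractions, n_replicates = d$n_replicates,
    include_crude = d$include_crude,
    n_solvent_blanks = d$n_solvent_blanks, n_media_blanks = d$n_media_blanks,
    n_qc = d$n_qc,
    phases = unlist(d$phases),
    crude_dilution = d$crude_dilution,
    noise = do.call(noise_profile, d$noise),
    lod = d$lod, isotope_rate = d$isotope_rate,
    host_taxon = d$host_taxon, seed = d$seed
  )
  ontology <- structure(
    list(levels = unlist(gt$ontology$levels),
         nodes = lapply(gt$ontology$nodes, unlist),
         parent = unlist(gt$ontology$parent)),
    class = "class_ontology"
  )
  mets <- gt$metabolites
  metab <- tibble::tibble(
    id = vapply(mets, function(x) x$id, character(1)),
    monoisotopic_mass = vapply(mets, function(x) x$monoisotopic_mass, numeric(1)),
    rt_true = vapply(mets, function(x) x$rt_true, numeric(1)),
    pathway = vapply(mets, function(x) x$class_triple[[1]], character(1)),
    superclass = vapply(mets, function(x) x$class_triple[[2]], character(1)),
    class = vapply(mets, function(x) x$class_triple[[3]], character(1)),
    producers = lapply(mets, function(x) unlist(x$producers)),
    fragment_mz = lapply(mets, function(x) unlist(x$fragment_mz)),
    fragment_int = lapply(mets, function(x) unlist(x$fragment_int)),
    base_abundance = vapply(mets, function(x) x$base_abundance, numeric(1)),
    isotope_ratio = vapply(mets, function(x) x$isotope_ratio, numeric(1))
  )
  fp_list <- gt$fraction_profile
  fp <- if (length(fp_list) > 0) {
    do.call(rbind, lapply(fp_list, unlist))
  } else {
    matrix(numeric(0), nrow = 0, ncol = design$n_fractions)
  }
  rownames(fp) <- names(fp_list)
  truth <- structure(
    list(metabolites = metab,
         membership = stats::setNames(
           vapply(gt$membership, identity, character(1)), names(gt$membership)),
         fraction_profile = fp, design = design, ontology = ontology),
    class = "ground_truth"
  )
  list(
    truth = truth,
    features = read_mgf(file.path(dir, "features.mgf")),
    metadata = read_sample_metadata(file.path(dir, "metadata.tsv"))
  )
}

#' Generate a taxonomy for a synthetic design
#'
#' Builds a two-kingdom lineage: the fungal strains are placed two per
#' genus, two genera per family and so on up to the fungal kingdom; the
#' host gets its own plant lineage. Both kingdoms join only at the root.
#'
#' @param design a [study_design()].
#' @return a [taxonomy_tree()].
#' @export
generate_taxonomy <- function(design) {
  rows <- list(
    list(taxon_id = "root", name = "root", rank = "root", parent_id = NA_character_),
    list(taxon_id = "k_fungi", name = "Fungi", rank = "kingdom", parent_id = "root"),
    list(taxon_id = "k_plantae", name = "Plantae", rank = "kingdom", parent_id = "root"),
    list(taxon_id = "p_asco", name = "Ascomycota", rank = "phylum", parent_id = "k_fungi"),
    list(taxon_id = "p_tracheo", name = "Tracheophyta", rank = "phylum", parent_id = "k_plantae"),
    list(taxon_id = "c_sordario", name = "Sordariomycetes", rank = "class", parent_id = "p_asco"),
    list(taxon_id = "c_liliopsida", name = "Liliopsida", rank = "class", parent_id = "p_tracheo"),
    list(taxon_id = "o_arecales", name = "Arecales", rank = "order", parent_id = "c_liliopsida"),
    list(taxon_id = "f_arecaceae", name = "Arecaceae", rank = "family", parent_id = "o_arecales"),
    list(taxon_id = "g_hostgenus", name = "HostGenus", rank = "genus", parent_id = "f_arecaceae"),
    list(taxon_id = design$host_taxon, name = "host_species", rank = "species",
         parent_id = "g_hostgenus")
  )
  n <- nrow(design$strains)
  n_gen <- ceiling(n / 2); n_fam <- ceiling(n_gen / 2); n_ord <- ceiling(n_fam / 2)
  for (o in seq_len(n_ord)) {
    rows[[length(rows) + 1]] <- list(
      taxon_id = sprintf("o_fun%02d", o), name = sprintf("FungalOrder%02d", o),
      rank = "order", parent_id = "c_sordario")
  }
  for (f in seq_len(n_fam)) {
    rows[[length(rows) + 1]] <- list(
      taxon_id = sprintf("f_fun%02d", f), name = sprintf("FungalFamily%02d", f),
      rank = "family", parent_id = sprintf("o_fun%02d", ceiling(f / 2)))
  }
  for (g in seq_len(n_gen)) {
    rows[[length(rows) + 1]] <- list(
      taxon_id = sprintf("g_fun%02d", g), name = sprintf("FungalGenus%02d", g),
      rank = "genus", parent_id = sprintf("f_fun%02d", ceiling(g / 2)))
  }
  for (i in seq_len(n)) {
    rows[[length(rows) + 1]] <- list(
      taxon_id = design$strains$taxon_id[i],
      name = paste0(design$strains$strain_id[i], "_species"),
      rank = "species", parent_id = sprintf("g_fun%02d", ceiling(i / 2)))
  }
  taxonomy_tree(do.call(rbind, lapply(rows, tibble::as_tibble)))
}

#' Build a spectral library from ground truth
#'
#' One entry per biological metabolite: the reference spectrum is the clean
#' fragmentation template (no decoy peaks) with the protonated precursor,
#' class triple and source taxa taken from the producer set. Optional decoy
#' entries with random masses, templates and taxa make library search
#' non-trivial.
#'
#' @param truth a `ground_truth`.
#' @param taxonomy the matching [generate_taxonomy()] tree.
#' @param n_decoy_entries number of random decoy entries to append.
#' @param seed seed for decoy generation.
#' @return a `spectral_library` tibble: `structure_id`, `name`,
#'   `monoisotopic_mass`, `spectrum`, `pathway`, `superclass`, `class`,
#'   `source_taxa` (list of taxon ids).
#' @export
truth_library <- function(truth, taxonomy, n_decoy_entries = 50,
                          seed = truth$design$seed + 2L) {
  m <- truth$metabolites
  bio <- !(truth$membership[m$id] %in% c("contaminant", "media"))
  m <- m[bio, ]
  taxon_of <- function(producers) {
    out <- character(0)
    for (p in producers) {
      if (p == "HOST") out <- c(out, truth$design$host_taxon)
      else {
        hit <- match(p, truth$design$strains$strain_id)
        if (!is.na(hit)) out <- c(out, truth$design$strains$taxon_id[hit])
      }
    }
    unique(out)
  }
  entries <- tibble::tibble(
    structure_id = paste0("STR_", m$id),
    name = paste0("compound_", m$id),
    monoisotopic_mass = m$monoisotopic_mass,
    spectrum = lapply(seq_len(nrow(m)), function(i) {
      ms2_spectrum(m$monoisotopic_mass[i] + PROTON_MASS, m$rt_true[i],
                   m$fragment_mz[[i]],
                   m$fragment_int[[i]])
    }),
    pathway = m$pathway, superclass = m$superclass, class = m$class,
    source_taxa = lapply(m$producers, taxon_of)
  )
  if (n_decoy_entries > 0) {
    all_taxa <- taxonomy$nodes$taxon_id[taxonomy$nodes$rank == "species"]
    ont <- truth$ontology
    decoys <- with_seed(seed, {
      mass <- stats::runif(n_decoy_entries, 130, 1950)
      tibble::tibble(
        structure_id = sprintf("DEC_%03d", seq_len(n_decoy_entries)),
        name = sprintf("decoy_%03d", seq_len(n_decoy_entries)),
        monoisotopic_mass = mass,
        spectrum = lapply(seq_len(n_decoy_entries), function(i) {
          k <- sample(6:12, 1)
          fmz <- sort(stats::runif(k, 50, mass[i] - 10))
          fin <- stats::runif(k, 0.05, 1); fin <- fin / max(fin)
          ms2_spectrum(mass[i] + PROTON_MASS, stats::runif(1, 0.3, 7.7), fmz, fin)
        }),
        class = sample(ont$nodes$class, n_decoy_entries, replace = TRUE),
        source_taxa = lapply(seq_len(n_decoy_entries),
                             function(i) sample(all_taxa, 1))
      )
    })
    decoys$superclass <- unname(ont$parent[decoys$class])
    decoys$pathway <- unname(ont$parent[decoys$superclass])
    decoys <- decoys[, names(entries)]
    entries <- rbind(entries, decoys)
  }
  class(entries) <- c("spectral_library", class(entries))
  entries
}

#' Construct a spectral library tibble
#'
#' @param structure_id,name,monoisotopic_mass,spectrum,pathway,superclass,class,source_taxa
#'   per-entry fields; `spectrum` and `source_taxa` are lists.
#' @return a `spectral_library` tibble.
#' @export
spectral_library <- function(structure_id, name = structure_id,
                             monoisotopic_mass, spectrum,
                             pathway = NA_character_,
                             superclass = NA_character_,
                             class = NA_character_,
                             source_taxa = replicate(length(structure_id),
                                                     character(),
                                                     simplify = FALSE)) {
  lib <- tibble::tibble(
    structure_id = structure_id, name = name,
    monoisotopic_mass = monoisotopic_mass, spectrum = spectrum,
    pathway = pathway, superclass = superclass, class = class,
    source_taxa = source_taxa
  )
  base::class(lib) <- c("spectral_library", base::class(lib))
  lib
}
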