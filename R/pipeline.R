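# End-to-end orchestration: staged runs (simulate -> process -> network ->
# annotate -> compare) driven by a validated config, with provenance
# sidecars and reproducible seeds.

PIPELINE_STAGES <- c("simulate", "process", "network", "annotate", "compare")

#' Build a validated pipeline configuration
#'
#' @param out_dir output directory for all stage artifacts.
#' @param seed integer master seed, applied to the study design.
#' @param mode ionization mode tag ("pos" or "neg"); carried into
#'   provenance, the processing itself is polarity-agnostic.
#' @param design a [study_design()] (for the simulate stage).
#' @param counts named metabolite counts per membership category.
#' @param align an [align_params()].
#' @param filter a [filter_params()].
#' @param network a [network_params()].
#' @param annotation an [annotation_params()].
#' @param n_decoy_entries decoy entries added to the synthetic library.
#' @param rounding list of rounding digits for reports.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            mode = c("pos", "neg"),
                            design = study_design(seed = seed),
                            counts = c(host_only = 40, strain_specific = 30,
                                       multi_strain = 10,
                                       shared_host_strain = 10,
                                       contaminant = 3, media = 3),
                            align = align_params(),
                            filter = filter_params(),
                            network = network_params(),
                            annotation = annotation_params(),
                            n_decoy_entries = 50,
                            rounding = list(shared = 0, enrichment = 1)) {
  mode <- match.arg(mode)
  design$seed <- as.integer(seed)
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), mode = mode,
         design = design, counts = counts, align = align, filter = filter,
         network = network, annotation = annotation,
         n_decoy_entries = n_decoy_entries, rounding = rounding),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' Recognized top-level keys: `out_dir`, `seed`, `mode`, `counts`,
#' `n_decoy_entries`, `rounding`, and parameter blocks `design`, `align`,
#' `filter`, `network`, `annotation` whose entries are passed to the
#' corresponding constructors. Unknown keys are rejected.
#'
#' @param path YAML file.
#' @param out_dir override for the output directory.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  known <- c("out_dir", "seed", "mode", "counts", "n_decoy_entries",
             "rounding", "design", "align", "filter", "network", "annotation")
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0) {
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  args <- list(
    out_dir = out_dir %||% y$out_dir %||% stopf("config needs out_dir"),
    seed = y$seed %||% 1L,
    mode = y$mode %||% "pos"
  )
  if (!is.null(y$counts)) args$counts <- unlist(y$counts)
  if (!is.null(y$n_decoy_entries)) args$n_decoy_entries <- y$n_decoy_entries
  if (!is.null(y$rounding)) args$rounding <- y$rounding
  ctor <- list(design = study_design, align = align_params,
               filter = filter_params, network = network_params,
               annotation = annotation_params)
  for (block in names(ctor)) {
    if (!is.null(y[[block]])) {
      blk <- y[[block]]
      if (block == "design" && !is.null(blk$noise)) {
        blk$noise <- do.call(noise_profile, blk$noise)
      }
      args[[block]] <- do.call(ctor[[block]], blk)
    }
  }
  do.call(pipeline_config, args)
}

config_fingerprint <- function(config) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  flat <- utils::capture.output(utils::str(config, max.level = 6,
                                           give.attr = FALSE))
  writeLines(flat, tmp)
  unname(tools::md5sum(tmp))
}

write_provenance <- function(config, stage, inputs, dir) {
  checksums <- if (length(inputs) > 0) {
    files <- inputs[file.exists(inputs)]
    as.list(tools::md5sum(files))
  } else {
    list()
  }
  prov <- list(
    stage = stage,
    config_hash = config_fingerprint(config),
    seed = config$seed,
    mode = config$mode,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("holometab")),
    input_checksums = checksums,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(prov, file.path(dir, paste0(stage, ".provenance.json")),
                       auto_unbox = TRUE, digits = NA)
}

require_upstream <- function(paths, stage) {
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stopf("stage '%s' needs missing upstream output(s): %s",
          stage, paste(missing, collapse = ", "))
  }
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (synthetic fixture + library + taxonomy), `process`
#' (feature-table chain), `network`, `annotate`, `compare`. Each stage
#' reads its upstream artifacts from `config$out_dir`, writes its outputs
#' there, and drops a provenance sidecar (config hash, seed, versions,
#' input checksums) next to them.
#'
#' @param stage stage name.
#' @param config a [pipeline_config()].
#' @return the stage's main in-memory result, invisibly.
#' @export
run_stage <- function(stage, config) {
  stage <- match.arg(stage, PIPELINE_STAGES)
  dir <- config$out_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  message(sprintf("[holometab] stage %s -> %s", stage, dir))

  if (stage == "simulate") {
    ont <- generate_ontology(7, 3, seed = config$seed)
    truth <- generate_metabolome(ont, config$design, config$counts)
    samples <- simulate_samples(truth)
    write_fixture(truth, samples, dir)
    tax <- generate_taxonomy(config$design)
    write_taxonomy(tax, file.path(dir, "taxonomy.tsv"))
    lib <- truth_library(truth, tax, n_decoy_entries = config$n_decoy_entries)
    write_provenance(config, stage, character(), dir)
    return(invisible(list(truth = truth, samples = samples,
                          taxonomy = tax, library = lib)))
  }

  if (stage == "process") {
    ins <- file.path(dir, c("features.mgf", "metadata.tsv"))
    require_upstream(ins, stage)
    features <- read_mgf(ins[1])
    metadata <- read_sample_metadata(ins[2])
    table <- process_features(features, metadata, config$align, config$filter)
    write_feature_table(table, file.path(dir, "feature_table.csv"))
    write_provenance(config, stage, ins, dir)
    return(invisible(table))
  }

  if (stage == "network") {
    res <- rebuild_processed(config)
    net <- build_network(res$table, config$network)
    export_graphml(net, file.path(dir, "network.graphml"))
    export_edgelist(net, file.path(dir, "network_edges.tsv"))
    write_provenance(config, stage,
                     file.path(dir, c("features.mgf", "metadata.tsv")), dir)
    return(invisible(net))
  }

  if (stage == "annotate") {
    res <- rebuild_processed(config)
    net <- build_network(res$table, config$network)
    ann <- annotate_dataset(res$table, net, res$library, res$taxonomy,
                            config$annotation)
    write_annotations(ann, file.path(dir, "annotations.tsv"))
    write_provenance(config, stage,
                     file.path(dir, c("features.mgf", "taxonomy.tsv")), dir)
    return(invisible(ann))
  }

  # compare
  res <- rebuild_processed(config)
  net <- build_network(res$table, config$network)
  ann <- annotate_dataset(res$table, net, res$library, res$taxonomy,
                          config$annotation)
  splits <- split_datasets(res$table)
  rep <- overlap_report(splits, net)
  write_report(rep, file.path(dir, "overlap_report.json"))
  utils::write.table(rep$per_strain, file.path(dir, "per_strain.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sunburst_export(ann, file.path(dir, "sunburst_general.json"))
  sunburst_export(ann, file.path(dir, "sunburst_shared.json"),
                  ids = rep$shared_ids)
  rec <- recovery_report(splits, res$truth, ann)
  write_report(rec, file.path(dir, "recovery_report.json"))
  write_provenance(config, stage,
                   file.path(dir, c("features.mgf", "metadata.tsv")), dir)
  invisible(list(overlap = rep, recovery = rec, annotations = ann,
                 network = net, splits = splits))
}

# reload fixture artifacts and reprocess the table (stages downstream of
# simulate share this)
rebuild_processed <- function(config) {
  dir <- config$out_dir
  ins <- file.path(dir, c("features.mgf", "metadata.tsv",
                          "ground_truth.json", "taxonomy.tsv"))
  require_upstream(ins, "downstream")
  fx <- read_fixture(dir)
  taxonomy <- read_taxonomy(ins[4])
  table <- process_features(fx$features, fx$metadata, config$align,
                            config$filter)
  library <- truth_library(fx$truth, taxonomy,
                           n_decoy_entries = config$n_decoy_entries)
  list(table = table, truth = fx$truth, taxonomy = taxonomy,
       library = library)
}

#' Run the full pipeline
#'
#' @param config a [pipeline_config()].
#' @return the compare stage's result, invisibly.
#' @export
run_pipeline <- function(config) {
  for (stage in c("simulate", "process")) run_stage(stage, config)
  run_stage("compare", config)
}
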