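# Overlap statistics, class distributions, sunburst aggregation and
# ground-truth recovery reports.

processed_study <- function(...) {
  st <- tiny_study(...)
  tab <- process_features(st$samples$features, st$samples$metadata)
  sp <- split_datasets(tab)
  c(st, list(table = tab, splits = sp))
}

test_that("printed-percentage arithmetic uses half-up rounding at fixed precision", {
  expect_equal(pct_of(860, 24096), 4)
  expect_equal(pct_of(693, 10792), 6)
  expect_equal(pct_of(510, 13884, 1), 3.7)
  expect_equal(pct_of(70, 24096, 1), 0.3)
  # half-up, not half-even
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(3.65, 1), 3.7)
  expect_equal(round_half_up(-0.25, 1), -0.3)
})

test_that("shared features intersect presence calls and respect symmetry", {
  ps <- processed_study()
  sf <- shared_features(ps$splits$host, ps$splits$fungal)
  sf_rev <- shared_features(ps$splits$fungal, ps$splits$host)
  expect_equal(sf$n_shared, sf_rev$n_shared)
  expect_setequal(sf$ids, sf_rev$ids)
  # zero-noise truth: exactly the shared_host_strain metabolites
  truth_shared <- names(ps$truth$membership)[
    ps$truth$membership == "shared_host_strain"]
  got <- ps$table$features$metabolite_id[
    match(sf$ids, ps$table$features$row_id)]
  expect_setequal(got, truth_shared)
  # inclusion-exclusion identity
  rep <- overlap_report(ps$splits)
  expect_equal(rep$n_host_only + rep$n_fungal_only + rep$n_shared,
               rep$n_total)
})

test_that("disjoint feature id spaces are rejected", {
  ps <- processed_study()
  broken <- ps$splits$host
  broken$features$row_id <- broken$features$row_id + 10000L
  expect_error(shared_features(broken, ps$splits$fungal), "id space")
})

test_that("shared clusters need presence on both sides of a family", {
  nodes <- tibble::tibble(
    id = c("1", "2", "3", "4"),
    mz = 1:4, rt = 1:4,
    family = c("FAM_A", "FAM_A", "FAM_B", "FAM_C"),
    share_fungal = NA_real_, share_host = NA_real_
  )
  net <- structure(list(nodes = nodes, edges = NULL,
                        params = network_params()),
                   class = "molecular_network")
  # family A: host node 1 + fungal node 2 -> shared; B: host-only singleton;
  # C: one node present in both datasets -> shared
  sc <- shared_clusters(net, host_ids = c(1, 3, 4), fungal_ids = c(2, 4))
  expect_equal(sc$n_shared_clusters, 2)
  expect_setequal(sc$family_ids, c("FAM_A", "FAM_C"))

  set.seed(42)
  for (rep in 1:30) {
    n <- sample(5:20, 1)
    fam <- sample(sprintf("FAM_%d", 1:5), n, replace = TRUE)
    nd <- tibble::tibble(id = as.character(1:n), mz = 1, rt = 1, family = fam,
                         share_fungal = NA_real_, share_host = NA_real_)
    netr <- structure(list(nodes = nd, edges = NULL,
                           params = network_params()),
                      class = "molecular_network")
    h <- sample(1:n, sample(0:n, 1))
    f <- sample(1:n, sample(0:n, 1))
    got <- shared_clusters(netr, h, f)$family_ids
    want <- sort(Filter(function(fm) {
      any(nd$id[nd$family == fm] %in% as.character(h)) &&
        any(nd$id[nd$family == fm] %in% as.character(f))
    }, unique(fam)))
    expect_equal(got, want)
  }
})

test_that("per-strain overlap tallies match an exhaustive count", {
  ps <- processed_study()
  per <- per_strain_overlap(ps$splits$general)
  tab <- ps$splits$general
  meta <- tab$metadata
  pres <- tab$presence
  host_cols <- meta$sample_id[meta$sample_type %in% c("fraction", "crude")]
  for (k in seq_len(nrow(per))) {
    st_cols <- meta$sample_id[meta$organism == per$strain[k] &
                                meta$sample_type == "fungal"]
    mine <- which(rowSums(pres[, st_cols, drop = FALSE]) > 0)
    shared <- sum(rowSums(pres[mine, host_cols, drop = FALSE]) > 0)
    expect_equal(per$n_features[k], length(mine))
    expect_equal(per$n_shared[k], shared)
    expect_equal(per$pct_shared[k],
                 round_half_up(100 * shared / length(mine), 1))
  }
  # strain with every feature shared reports 100
  all_shared <- per[per$n_features == per$n_shared & per$n_features > 0, ]
  if (nrow(all_shared) > 0) expect_true(all(all_shared$pct_shared == 100))
})

test_that("enrichment statistics count crude and fraction features consistently", {
  ps <- processed_study(lod = 3e4)  # a lod high enough to starve the crude extract
  es <- enrichment_stats(ps$splits$host, ps$splits$fungal)
  expect_true(es$has_crude)
  expect_lte(es$n_crude, es$n_fractions)
  expect_equal(es$pct_crude,
               round_half_up(100 * es$n_crude / es$n_host_total, 1))
  # restricting the host side to the crude extract never increases sharing
  full <- shared_features(ps$splits$host, ps$splits$fungal)
  expect_lte(es$n_shared_crude_only, full$n_shared)
  expect_equal(es$pct_shared_crude_only,
               round_half_up(100 * es$n_shared_crude_only / es$n_general_total, 1))
})

test_that("class distribution counts consensus labels with fixed rounding", {
  cons <- tibble::tibble(
    id = as.character(1:12),
    pathway = c(rep("fatty_acids", 4), rep("terpenoids", 6), NA, NA),
    superclass = NA_character_, class = NA_character_
  )
  ann <- structure(list(consensus = cons, records = NULL, coverage = NULL),
                   class = "annotation_set")
  cd <- class_distribution(ann, level = "pathway")
  expect_equal(cd$n_annotated, 10)
  expect_equal(cd$n_total, 12)
  expect_equal(cd$table$percent[cd$table$label == "fatty_acids"], 40)
  expect_equal(cd$table$percent[cd$table$label == "terpenoids"], 60)
  expect_equal(sum(cd$table$count), cd$n_annotated)
  # subsetting excludes ids outside the subset
  cd2 <- class_distribution(ann, ids = 1:6, level = "pathway")
  expect_equal(cd2$table$count[cd2$table$label == "fatty_acids"], 4)
})

test_that("sunburst nesting conserves counts and rejects broken hierarchies", {
  cons <- tibble::tibble(
    id = as.character(1:10),
    pathway = c(rep("P1", 3), rep("P2", 7)),
    superclass = c(rep("S1", 3), rep("S2", 4), rep("S3", 3)),
    class = c("C1", "C1", "C2", rep("C3", 4), rep("C4", 3))
  )
  ann <- structure(list(consensus = cons), class = "annotation_set")
  sb <- sunburst_export(ann)
  expect_equal(sb$count, 10)
  root_counts <- vapply(sb$children, function(x) x$count, numeric(1))
  expect_equal(sort(root_counts), c(3, 7))
  # child counts sum to each parent count
  for (pw in sb$children) {
    expect_equal(sum(vapply(pw$children, function(x) x$count, numeric(1))),
                 pw$count)
    for (sc in pw$children) {
      expect_equal(sum(vapply(sc$children, function(x) x$count, numeric(1))),
                   sc$count)
    }
  }
  # leaf re-aggregation reproduces the pathway distribution
  leaf_total <- sum(unlist(lapply(sb$children, function(pw)
    lapply(pw$children, function(sc)
      vapply(sc$children, function(cl) cl$count, numeric(1))))))
  expect_equal(leaf_total, 10)

  bad <- cons
  bad$superclass[1] <- "S3"  # S3 now under both P1 and P2
  annb <- structure(list(consensus = bad), class = "annotation_set")
  expect_error(sunburst_export(annb), "hierarchy violation")
})

test_that("recovery on zero-noise data is perfect for every category", {
  ps <- processed_study()
  net <- build_network(ps$table)
  tax <- generate_taxonomy(ps$design)
  lib <- truth_library(ps$truth, tax, n_decoy_entries = 20)
  ann <- annotate_dataset(ps$table, net, lib, tax)
  rec <- recovery_report(ps$splits, ps$truth, ann)
  for (cat in names(rec$per_category)) {
    expect_equal(rec$per_category[[cat]]$precision, 1)
    expect_equal(rec$per_category[[cat]]$recall, 1)
  }
  expect_equal(rec$rank1_accuracy, 1)
})

test_that("reports serialize to JSON", {
  ps <- processed_study()
  net <- build_network(ps$table)
  rep <- overlap_report(ps$splits, net)
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$n_shared, rep$n_shared)
  expect_equal(back$n_total,
               back$n_host_only + back$n_fungal_only + back$n_shared)
})
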