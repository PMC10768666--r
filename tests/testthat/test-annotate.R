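# Annotation cascade: adduct arithmetic, taxonomic distances, re-ranking,
# consensus classes and identity matching.

fixture_taxonomy <- function() generate_taxonomy(tiny_design())

test_that("MS1 adduct matching applies adduct arithmetic and the taxonomy gate", {
  tax <- fixture_taxonomy()
  lib <- spectral_library(
    structure_id = c("GLC", "OUT"),
    monoisotopic_mass = c(180.063388, 180.063388),
    spectrum = list(ms2_spectrum(181.070664, 1, c(60, 85), c(1, 0.5)),
                    ms2_spectrum(181.070664, 1, c(60, 85), c(1, 0.5))),
    source_taxa = list("t_host", "t_a01")  # plant vs fungal source
  )
  # 180.063388 + 22.989218 (sodiated) = 203.052606
  hits <- ms1_adduct_match(203.0526, lib, "t_host", tax)
  expect_equal(hits$structure_id, "GLC")
  expect_equal(hits$adduct, "[M+Na]+")
  expect_lt(hits$mass_error_da, 0.01)
  # no adduct reaches 210.0
  expect_equal(nrow(ms1_adduct_match(210.0, lib, "t_host", tax)), 0)
  # fungal-sourced entry excluded for a plant sample, included for a strain
  hits2 <- ms1_adduct_match(203.0526, lib, "t_a01", tax)
  expect_equal(hits2$structure_id, "OUT")
  expect_error(ms1_adduct_match(203.0526, lib, "t_unknown", tax),
               "unknown taxon")
})

test_that("taxonomic distance counts rank steps to the lowest common ancestor", {
  tax <- fixture_taxonomy()
  expect_equal(taxonomic_distance("t_a01", "t_a01", tax), 0)
  # strains A01 and A02 share their genus
  expect_equal(taxonomic_distance("t_a01", "t_a02", tax), 1)
  # A01 and A03 share only the family
  expect_equal(taxonomic_distance("t_a01", "t_a03", tax), 2)
  # plant and fungus meet only at the root
  expect_equal(taxonomic_distance("t_host", "t_a01", tax), 7)
  expect_error(taxonomic_distance("t_host", "nope", tax), "unknown taxon")
})

test_that("reweighting follows the linear distance bonus and flips ranks", {
  tax <- fixture_taxonomy()
  cand <- tibble::tibble(
    structure_id = c("far", "near"), sigma = c(0.6, 0.5),
    n_matched = c(8L, 8L), pathway = NA_character_,
    superclass = NA_character_, class = NA_character_,
    source_taxa = list("t_host", "t_a01")
  )
  out <- reweight_candidates(cand, "t_a01", tax, annotation_params(tax_weight = 1))
  # sigma 0.5 at distance 0 -> 1.5; sigma 0.6 at distance 7 -> 0.6
  expect_equal(out$final_score[out$structure_id == "near"], 1.5)
  expect_equal(out$final_score[out$structure_id == "far"], 0.6)
  expect_equal(out$structure_id[1], "near")
  expect_equal(out$rank, 1:2)
})

test_that("reweighting is monotone and never changes the candidate set", {
  tax <- fixture_taxonomy()
  params <- annotation_params()
  set.seed(314)
  species <- tax$nodes$taxon_id[tax$nodes$rank == "species"]
  for (rep in 1:60) {
    n <- sample(2:10, 1)
    cand <- tibble::tibble(
      structure_id = sprintf("c%02d", 1:n), sigma = round(runif(n), 3),
      n_matched = 8L, pathway = NA_character_, superclass = NA_character_,
      class = NA_character_,
      source_taxa = lapply(1:n, function(i) sample(species, sample(1:2, 1)))
    )
    out <- reweight_candidates(cand, sample(species, 1), tax, params)
    expect_setequal(out$structure_id, cand$structure_id)
    # final score increases with sigma at fixed distance, decreases with
    # distance at fixed sigma
    expect_equal(out$final_score,
                 out$sigma + params$tax_weight * (7 - out$distance) / 7)
    expect_true(all(diff(out$final_score) <= 1e-12))
  }
})

test_that("consensus pools neighbor votes and the bonus reorders equal scores", {
  # 3-node path: n1 - n2 - n3; neighbors vote unanimously for class X
  nodes <- tibble::tibble(id = c("n1", "n2", "n3"),
                          mz = 1:3, rt = 1:3, family = "FAM_0001",
                          share_fungal = NA_real_, share_host = NA_real_)
  edges <- tibble::tibble(u = c("n1", "n2"), v = c("n2", "n3"),
                          score = c(0.9, 0.9), n_matched = 8L)
  net <- structure(list(nodes = nodes, edges = edges,
                        params = network_params()),
                   class = "molecular_network")
  mk <- function(sid, pw, sc, cl, sigma, final) {
    tibble::tibble(structure_id = sid, sigma = sigma, n_matched = 8L,
                   pathway = pw, superclass = sc, class = cl,
                   distance = 0, final_score = final, rank = 1L)
  }
  cand <- list(
    n1 = mk("a", "P1", "S1", "X", 0.9, 1.9),
    n2 = rbind(mk("y", "P1", "S1", "Y", 0.8, 1.8),
               mk("x", "P1", "S1", "X", 0.8, 1.8)),
    n3 = mk("b", "P1", "S1", "X", 0.9, 1.9)
  )
  out <- consensus_class(net, cand, annotation_params(class_bonus = 0.1))
  expect_equal(out$consensus$class[out$consensus$id == "n2"], "X")
  # the X candidate overtakes the equally scored Y candidate
  expect_equal(out$candidates$n2$structure_id[1], "x")

  # isolated node with a single unanimous candidate list keeps its order
  iso_nodes <- nodes[1, ]
  iso_net <- structure(list(nodes = iso_nodes, edges = edges[0, ],
                            params = network_params()),
                       class = "molecular_network")
  iso <- consensus_class(iso_net, cand["n1"], annotation_params())
  expect_equal(iso$consensus$class, "X")
  expect_equal(iso$candidates$n1$structure_id, "a")
})

test_that("consensus tallies match a hand-computed weighted majority", {
  # 5-node star: center n0 with 4 leaves; votes weighted by final score
  nodes <- tibble::tibble(id = c("n0", sprintf("n%d", 1:4)),
                          mz = 1:5, rt = 1:5, family = "FAM_0001",
                          share_fungal = NA_real_, share_host = NA_real_)
  edges <- tibble::tibble(u = "n0", v = sprintf("n%d", 1:4),
                          score = 0.9, n_matched = 8L)
  net <- structure(list(nodes = nodes, edges = edges,
                        params = network_params()),
                   class = "molecular_network")
  top <- function(cl, w) {
    tibble::tibble(structure_id = cl, sigma = w, n_matched = 8L,
                   pathway = paste0("P_", cl), superclass = paste0("S_", cl),
                   class = cl, distance = 0, final_score = w, rank = 1L)
  }
  cand <- list(n0 = top("A", 0.5), n1 = top("B", 0.9), n2 = top("B", 0.8),
               n3 = top("A", 0.7), n4 = top("A", 0.6))
  # A: 0.5 + 0.7 + 0.6 = 1.8 ; B: 0.9 + 0.8 = 1.7 -> A wins at every level
  out <- consensus_class(net, cand, annotation_params())
  expect_equal(out$consensus$class[out$consensus$id == "n0"], "A")
  expect_equal(out$consensus$pathway[out$consensus$id == "n0"], "P_A")
  # leaves see only themselves and the center
  expect_equal(out$consensus$class[out$consensus$id == "n1"], "B")
})

test_that("identity confirmation requires both the ppm gate and the score gate", {
  sp <- ms2_spectrum(301.107276, 4.1, c(100, 150.5, 200.2, 220.1, 250.3, 280.4),
                     c(1, 0.3, 0.5, 0.2, 0.8, 0.4))
  std <- spectral_library(
    structure_id = "STD", monoisotopic_mass = 300.1,
    spectrum = list(sp)
  )
  p <- annotation_params()
  expect_equal(identity_match(sp, std, p)$structure_id, "STD")
  # 25 ppm mass error: rejected regardless of a perfect spectrum
  off <- ms2_spectrum(301.107276 * (1 + 25e-6), 4.1, sp$mz, sp$intensity)
  expect_null(identity_match(off, std, p))
  # degraded spectrum below 0.8: rejected
  weak <- ms2_spectrum(301.107276, 4.1, sp$mz + c(0, 0.5, 0.5, 0.5, 0.5, 0.5),
                       sp$intensity)
  expect_null(identity_match(weak, std, p))
})

test_that("library search honors thresholds, truncation and ordering", {
  set.seed(2718)
  target <- ms2_spectrum(500.2, 3, sort(runif(8, 50, 480)), runif(8, 0.1, 1))
  # 60 passing entries: all share the target spectrum, tiny sigma jitter
  n <- 60
  lib <- spectral_library(
    structure_id = sprintf("E%02d", 1:n),
    monoisotopic_mass = 500.2 - 1.007276,
    spectrum = replicate(n, {
      keep <- sample(8, 7)
      ms2_spectrum(500.2, 3, target$mz[keep], target$intensity[keep])
    }, simplify = FALSE)
  )
  got <- ms2_library_search(target, lib, annotation_params())
  expect_equal(nrow(got), 50)
  expect_true(all(diff(got$sigma) <= 1e-12))
  expect_true(all(got$sigma >= 0.2 & got$n_matched >= 6))
  # exact self-entry ranks first with sigma 1
  lib2 <- rbind(lib, spectral_library("SELF", monoisotopic_mass = 499.19,
                                      spectrum = list(target)))
  got2 <- ms2_library_search(target, lib2, annotation_params())
  expect_equal(got2$structure_id[1], "SELF")
  expect_equal(got2$sigma[1], 1, tolerance = 1e-12)
  # empty library, no crash
  expect_equal(nrow(ms2_library_search(target, lib[0, ], annotation_params())), 0)
})

test_that("distance-zero true structures never rank worse after reweighting", {
  tax <- fixture_taxonomy()
  params <- annotation_params()
  species <- tax$nodes$taxon_id[tax$nodes$rank == "species"]
  set.seed(1618)
  for (rep in 1:100) {
    n <- sample(3:12, 1)
    true_pos <- sample(n, 1)
    sample_taxon <- sample(species, 1)
    cand <- tibble::tibble(
      structure_id = sprintf("c%02d", 1:n),
      sigma = sort(round(runif(n), 3), decreasing = TRUE),
      n_matched = 8L, pathway = NA_character_, superclass = NA_character_,
      class = NA_character_,
      source_taxa = lapply(1:n, function(i) {
        if (i == true_pos) sample_taxon else sample(species, 1)
      })
    )
    before <- match(cand$structure_id[true_pos], cand$structure_id)
    out <- reweight_candidates(cand, sample_taxon, tax, params)
    after <- match(cand$structure_id[true_pos], out$structure_id)
    expect_lte(after, before)
  }
})

test_that("zero-noise annotation with a complete library is exact; empty library is safe", {
  st <- tiny_study()
  tab <- process_features(st$samples$features, st$samples$metadata)
  net <- build_network(tab)
  tax <- generate_taxonomy(st$design)
  lib <- truth_library(st$truth, tax, n_decoy_entries = 20)
  ann <- annotate_dataset(tab, net, lib, tax)
  top1 <- ann$records[ann$records$tier == "ms2" & ann$records$rank == 1, ]
  truth_str <- paste0("STR_", tab$features$metabolite_id[
    match(top1$row_id, tab$features$row_id)])
  expect_equal(top1$structure_id, truth_str)
  # consensus triple equals the true class triple for every annotated node
  m <- st$truth$metabolites
  idx <- match(tab$features$metabolite_id[match(ann$consensus$id,
                                                as.character(tab$features$row_id))],
               m$id)
  expect_equal(ann$consensus$class, m$class[idx])

  empty <- lib[0, ]
  ann0 <- annotate_dataset(tab, net, empty, tax)
  expect_true(all(is.na(ann0$consensus$pathway)))
  expect_equal(sum(ann0$records$tier == "ms2"), 0)
})
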