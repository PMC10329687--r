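test_that("the same seed reproduces the dataset exactly", {
  p <- sim_params(n_regions = 2, samples_per_region = 4, n_genes_neutral = 2,
                  n_genes_selected = 2, gene_length = 30, seed = 77)
  b1 <- suppressWarnings(simulate_dataset(p))
  b2 <- suppressWarnings(simulate_dataset(p))
  expect_identical(b1$meta, b2$meta)
  expect_identical(lapply(b1$alignments, unclass),
                   lapply(b2$alignments, unclass))
  expect_identical(ape::write.tree(b1$species_tree),
                   ape::write.tree(b2$species_tree))

  # and the written bundle is byte-identical
  d1 <- tempfile(); d2 <- tempfile()
  suppressWarnings(simulate_dataset(p, out_dir = d1))
  suppressWarnings(simulate_dataset(p, out_dir = d2))
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("zero mutation and no selection copy the root to every tip", {
  p <- sim_params(n_regions = 2, samples_per_region = 3, mutation_rate = 0,
                  selection_strength = 0, gene_length = 20, seed = 3)
  gen <- simulate_genealogy(p)
  sim <- simulate_alignment(gen$tree, gen$meta, p, selected = FALSE, seed = 4)
  m <- unclass(sim$aln)
  expect_true(all(apply(m, 2, function(col) length(unique(col)) == 1)))
  expect_equal(paste(m[1, 1:3], collapse = ""), "ATG")
})

test_that("full-strength selection makes within-region tips identical at constrained sites", {
  p <- sim_params(n_regions = 3, samples_per_region = 4, mutation_rate = 0.05,
                  selection_strength = 1, selection_fraction = 1,
                  gene_length = 30, seed = 11)
  gen <- simulate_genealogy(p)
  sim <- simulate_alignment(gen$tree, gen$meta, p, selected = TRUE, seed = 12)
  m <- unclass(sim$aln)
  con <- sim$truth$constrained_sites
  expect_gt(length(con), 0)
  reg <- setNames(gen$meta$region, gen$meta$tip_id)
  for (r in unique(reg)) {
    tips <- names(reg)[reg == r]
    sub <- m[tips, con, drop = FALSE]
    same <- apply(sub, 2, function(col) length(unique(col)) == 1)
    # identical except where an overwrite would have created a stop codon
    # (a few percent of third positions sit in TA-/TG- backgrounds)
    expect_gt(mean(same), 0.9)
  }
  # regions carry distinct preferred bases at every constrained site
  pref <- do.call(rbind, sim$truth$preferred)
  expect_true(all(apply(pref, 2, function(x) !anyDuplicated(x))))
})

test_that("neutral diversity grows with the mutation rate", {
  pis <- sapply(c(0.01, 0.05, 0.2), function(mu) {
    mean(sapply(1:8, function(i) {
      p <- sim_params(n_regions = 2, samples_per_region = 4,
                      mutation_rate = mu, gene_length = 60,
                      seed = 100 + i)
      gen <- simulate_genealogy(p)
      sim <- simulate_alignment(gen$tree, gen$meta, p, selected = FALSE,
                                seed = 200 + i)
      mean_pi(sim$aln)
    }))
  })
  expect_true(all(diff(pis) > 0))
})

test_that("the single-region genealogy matches the Kingman expectation", {
  p <- sim_params(n_regions = 1, samples_per_region = 2, migration_rate = 0,
                  cities_per_region = 2)
  tm <- sapply(1:2000, function(i)
    simulate_genealogy(p, seed = i)$tmrca)
  se <- stats::sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 1), 3 * se)
})

test_that("weak migration separates regions; strong migration approaches panmixia", {
  # m small: between-region distances exceed within-region distances
  deeper <- sapply(1:100, function(i) {
    p <- sim_params(n_regions = 2, samples_per_region = 4,
                    migration_rate = 0.05, seed = 1000 + i)
    gen <- simulate_genealogy(p)
    D <- patristic_distances(gen$tree)
    reg <- setNames(gen$meta$region, gen$meta$tip_id)[rownames(D)]
    same <- outer(reg, reg, "==")
    ut <- upper.tri(D)
    mean(D[ut & !same]) > mean(D[ut & same])
  })
  expect_gte(mean(deeper), 0.95)

  # m large: between/within mean distance ratio near 1
  ratios <- sapply(1:400, function(i) {
    p <- sim_params(n_regions = 2, samples_per_region = 4,
                    migration_rate = 20, seed = 3000 + i)
    gen <- simulate_genealogy(p)
    D <- patristic_distances(gen$tree)
    reg <- setNames(gen$meta$region, gen$meta$tip_id)[rownames(D)]
    same <- outer(reg, reg, "==")
    ut <- upper.tri(D)
    c(mean(D[ut & !same]), mean(D[ut & same]))
  })
  expect_equal(sum(ratios[1, ]) / sum(ratios[2, ]), 1, tolerance = 0.05)
})

test_that("migration with multiple isolated regions is rejected up front", {
  p <- sim_params(n_regions = 3, migration_rate = 0)
  expect_error(simulate_genealogy(p), "migration")
})

test_that("bundles are internally consistent and round-trip through the readers", {
  p <- sim_params(n_regions = 2, samples_per_region = 4, n_genes_neutral = 3,
                  n_genes_selected = 3, gene_length = 40, seed = 21)
  d <- tempfile()
  b <- suppressWarnings(simulate_dataset(p, out_dir = d))

  # truth/annotation consistency: organelle genes are all neutral
  grp <- assign_groups(names(b$alignments), b$annotations)
  org <- names(grp)[grp == "organelle"]
  expect_true(all(org %in% b$truth$neutral_gene_ids))
  expect_true(all(grp[b$truth$neutral_gene_ids] == "organelle"))

  # files round-trip cleanly
  sp <- read_newick(file.path(d, "species.nwk"))
  expect_setequal(sp$tip.label, b$meta$tip_id)
  trees <- read_gene_trees(file.path(d, "genes"))
  expect_setequal(names(trees), names(b$gene_trees))
  alns <- read_gene_alignments(file.path(d, "genes"))
  expect_identical(unclass(alns[["gene001"]]),
                   unclass(b$alignments[["gene001"]]))
  meta <- read_tip_metadata(file.path(d, "meta.tsv"))
  expect_equal(meta$tip_id, b$meta$tip_id)
  ann <- read_annotations(file.path(d, "annotations.tsv"))
  expect_equal(ann$gene_id, b$annotations$gene_id)

  # duplicate-city tips exercise the filter: duplicates removed
  D <- patristic_distances(sp)
  flt <- filter_tips(D, meta)
  dups <- grep("d$", meta$tip_id, value = TRUE)
  expect_gt(length(dups), 0)
  expect_true(all(!dups %in% flt$kept))
})
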