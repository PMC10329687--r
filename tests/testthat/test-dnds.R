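test_that("variable-gene selection ignores gap-only variation", {
  alns <- list(
    inv  = codon_alignment(c(a = "ATGAAA", b = "ATGAAA")),
    snp  = codon_alignment(c(a = "ATGAAA", b = "ATGAAG")),
    gapv = codon_alignment(c(a = "ATGAA-", b = "ATGAAN")))
  expect_equal(select_variable_genes(alns), "snp")
})

test_that("framing enforces bacterial start codons and trims trailing stops", {
  fr <- frame_and_trim(codon_alignment(c(a = "ATGAAATAA", b = "ATGAAATAA")))
  expect_equal(fr$status, "ok")
  expect_equal(ncol(fr$aln), 6L)
  expect_equal(paste(fr$aln[1, ], collapse = ""), "ATGAAA")

  # TTG and GTG are valid bacterial starts
  expect_equal(frame_and_trim(codon_alignment(c(a = "TTGGCC",
                                                b = "TTGGCC")))$status, "ok")
  expect_equal(frame_and_trim(codon_alignment(c(a = "GTGGCCAAA",
                                                b = "GTGGCCAAA")))$status,
               "ok")

  no_start <- frame_and_trim(codon_alignment(c(a = "CCCAAA", b = "CCCAAA")))
  expect_equal(no_start$status, "excluded")
  expect_equal(no_start$reason, "no_start")

  # length truncated to a codon multiple
  fr2 <- frame_and_trim(codon_alignment(c(a = "ATGAAACC", b = "ATGAAACC")))
  expect_equal(ncol(fr2$aln), 6L)
})

test_that("NG86 handles identical sequences and the TTT/TTC pair", {
  same <- ng86(codon_alignment(c(a = "ATGAAA", b = "ATGAAA")))
  expect_equal(same$syn_diffs, 0)
  expect_equal(same$nonsyn_diffs, 0)
  expect_true(is.na(same$ratio))

  r <- ng86(codon_alignment(c(a = "TTT", b = "TTC")))
  expect_equal(r$syn_diffs, 1)
  expect_equal(r$nonsyn_diffs, 0)
  expect_equal(r$dn, 0)
  expect_equal(r$syn_sites, oracle_codon_sites("TTT"), tolerance = 1e-9)
})

test_that("site counts match the enumeration oracle and conserve S + N", {
  set.seed(41)
  sense <- setdiff(names(geophylo:::.GENETIC_CODE_11),
                   c("TAA", "TAG", "TGA"))
  for (codon in sample(sense, 12)) {
    r <- ng86(codon_alignment(c(a = codon, b = codon)))
    expect_equal(r$syn_sites, oracle_codon_sites(codon), tolerance = 1e-9,
                 label = codon)
    expect_equal(r$syn_sites + r$nonsyn_sites, 3, tolerance = 1e-6)
  }
  # multi-codon gene: S + N = 3 x compared codons
  aln <- codon_alignment(c(a = "ATGAAACCCGGG", b = "ATGAAACCCGGG"))
  r <- ng86(aln)
  expect_equal(r$syn_sites + r$nonsyn_sites, 12, tolerance = 1e-6)
})

test_that("pathway averaging matches brute-force enumeration on codon pairs", {
  pairs <- list(c("TTT", "GTA"), c("ATG", "AAA"), c("CCC", "GGG"),
                c("TGT", "AGA"), c("AAA", "AGC"), c("CTG", "CAT"))
  for (p in pairs) {
    r <- ng86(codon_alignment(c(a = p[1], b = p[2])))
    o <- oracle_path_diffs(p[1], p[2])
    expect_equal(r$syn_diffs, o[1], tolerance = 1e-9,
                 label = paste(p, collapse = "/"))
    expect_equal(r$nonsyn_diffs, o[2], tolerance = 1e-9,
                 label = paste(p, collapse = "/"))
  }
})

test_that("NG86 is symmetric in sequence order and skips gapped codons per pair", {
  a <- "ATGAAACCTGGGTTT"; b <- "ATGAGACCAGGCTTC"
  r1 <- ng86(codon_alignment(c(x = a, y = b)))
  r2 <- ng86(codon_alignment(c(x = b, y = a)))
  expect_equal(r1$syn_diffs, r2$syn_diffs)
  expect_equal(r1$nonsyn_diffs, r2$nonsyn_diffs)
  expect_equal(r1$ratio, r2$ratio)

  # a gap codon in one sequence removes that codon from the pair
  g1 <- ng86(codon_alignment(c(x = "ATGAAATTT", y = "ATGAAATTC")))
  g2 <- ng86(codon_alignment(c(x = "ATGAAATTT", y = "ATG---TTC")))
  expect_equal(g2$syn_diffs, g1$syn_diffs)  # difference is in the TTT codon
})

test_that("the gene-wise table applies selection, framing and status rules", {
  alns <- list(
    ok     = codon_alignment(c(a = "ATGAAATTT", b = "ATGAGATTC")),
    invar  = codon_alignment(c(a = "ATGCCC", b = "ATGCCC")),
    nostart = codon_alignment(c(a = "CCCAAA", b = "CCCAAG")))
  tab <- dnds_table(alns)
  expect_equal(tab$reason[tab$gene_id == "invar"], "invariant")
  expect_equal(tab$reason[tab$gene_id == "nostart"], "no_start")
  expect_true(is.finite(tab$S[tab$gene_id == "ok"]))
})

test_that("dnds group contrast delegates to the rank pipeline", {
  set.seed(43)
  dn <- data.frame(gene_id = paste0("g", 1:20),
                   ratio = c(runif(10, 0.8, 1.6), runif(10, 0.05, 0.4)))
  grp <- setNames(rep(c("membrane", "organelle"), each = 10), dn$gene_id)
  cmp <- dnds_group_contrast(dn, grp)
  expect_lt(cmp$kruskal_p, 0.05)
  expect_gt(cmp$group_medians[["membrane"]],
            cmp$group_medians[["organelle"]])

  # undefined ratios are excluded, with usable n reported
  dn$ratio[1:3] <- NA
  cmp2 <- dnds_group_contrast(dn, grp)
  expect_equal(unname(cmp2$group_n[c("membrane", "organelle")]), c(7L, 10L))

  # all ratios equal -> p = 1
  dn2 <- data.frame(gene_id = paste0("g", 1:8), ratio = 1)
  grp2 <- setNames(rep(c("membrane", "organelle"), each = 4), dn2$gene_id)
  expect_equal(dnds_group_contrast(dn2, grp2)$kruskal_p, 1)
})

test_that("regionally selected genes show elevated dN/dS relative to neutral genes", {
  p <- sim_params(n_regions = 2, samples_per_region = 5,
                  n_genes_selected = 10, n_genes_neutral = 10,
                  gene_length = 100, seed = 42)
  b <- suppressWarnings(simulate_dataset(p))
  grp <- assign_groups(names(b$alignments), b$annotations)
  tab <- suppressWarnings(dnds_table(b$alignments))
  ok <- tab[tab$status == "ok", ]
  med <- tapply(ok$ratio, grp[ok$gene_id], median)
  # the amino-acid-changing regional overwrite raises dN in selected
  # (membrane/metabolic) genes; neutral organelle genes hover near 1
  expect_gt(med[["membrane"]], med[["organelle"]])
  expect_gt(med[["metabolic"]], med[["organelle"]])
})

test_that("neutral simulated genes are not pushed above dN/dS = 1", {
  ratios <- sapply(1:20, function(i) {
    p <- sim_params(n_regions = 1, samples_per_region = 6,
                    migration_rate = 0, n_genes_selected = 0,
                    n_genes_neutral = 1, gene_length = 60,
                    dup_tips_per_region = 0, seed = 300 + i)
    b <- suppressWarnings(simulate_dataset(p))
    suppressWarnings(dnds_table(b$alignments))$ratio[1]
  })
  n_above <- sum(ratios > 1, na.rm = TRUE)
  n_fin <- sum(is.finite(ratios))
  sign_p <- stats::binom.test(n_above, n_fin,
                              alternative = "greater")$p.value
  expect_gt(sign_p, 0.05)
})
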