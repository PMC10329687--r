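#' Parameters for the region-structured simulator
#'
#' Defaults define the standard simulated study condition used throughout
#' the package's recovery tests: 3 regions x 8 samples, migration 0.1
#' per lineage per coalescent unit, 30 regionally selected and 30 neutral
#' genes of 300 codons, mutation rate 0.05 per site per coalescent unit,
#' selection acting on 10\% of third codon positions with overwrite
#' probability 0.8, one city per sample plus one injected duplicate-city
#' tip per region.
#'
#' @param n_regions number of demes (>= 2 unless simulating panmixia).
#' @param samples_per_region tips sampled per deme.
#' @param migration_rate per-lineage backward migration rate (coalescent
#'   units); 0 is only valid with a single region.
#' @param pop_scale within-deme coalescent time scale (pairwise coalescence
#'   rate is \code{choose(k,2)/pop_scale}).
#' @param n_genes_neutral,n_genes_selected gene counts per class.
#' @param gene_length gene length in codons (including the start codon).
#' @param mutation_rate substitutions per site per coalescent unit.
#' @param selection_fraction fraction of alignment sites under regional
#'   selection in selected genes; constrained sites are placed at first and
#'   second codon positions so the overwrite changes the protein.
#' @param selection_strength probability a constrained site is overwritten
#'   by its region's preferred base.
#' @param cities_per_region distinct cities per region (tips assigned
#'   round-robin).
#' @param dup_tips_per_region extra duplicate-city tips injected per region
#'   (same city as an existing tip, lower dedup score) to exercise the
#'   pre-test filter.
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the parameters and this seed.
#' @return list of class \code{sim_params}.
#' @export
sim_params <- function(n_regions = 3, samples_per_region = 8,
                       migration_rate = 0.1, pop_scale = 1,
                       n_genes_neutral = 30, n_genes_selected = 30,
                       gene_length = 300, mutation_rate = 0.05,
                       selection_fraction = 0.1, selection_strength = 0.8,
                       cities_per_region = samples_per_region,
                       dup_tips_per_region = 1, seed = 1) {
  p <- list(n_regions = n_regions, samples_per_region = samples_per_region,
            migration_rate = migration_rate, pop_scale = pop_scale,
            n_genes_neutral = n_genes_neutral,
            n_genes_selected = n_genes_selected,
            gene_length = gene_length, mutation_rate = mutation_rate,
            selection_fraction = selection_fraction,
            selection_strength = selection_strength,
            cities_per_region = cities_per_region,
            dup_tips_per_region = dup_tips_per_region, seed = seed)
  .check(p$n_regions >= 1, "need at least one region")
  .check(p$migration_rate >= 0 && p$mutation_rate >= 0 && p$pop_scale > 0,
         "rates must be nonnegative, pop_scale positive")
  .check(p$selection_fraction >= 0 && p$selection_fraction <= 1 &&
           p$selection_strength >= 0 && p$selection_strength <= 1,
         "selection_fraction and selection_strength must lie in [0, 1]")
  .check(p$gene_length >= 2, "gene_length must be >= 2 codons")
  class(p) <- "sim_params"
  p
}

#' Simulate a genealogy under the island-model structured coalescent
#'
#' Backward-time Gillespie simulation: within each region, every lineage
#' pair coalesces at rate \code{1/pop_scale}; every lineage migrates at
#' rate \code{migration_rate} to a uniformly chosen other region. Branch
#' lengths are in coalescent units. With a single region this is the
#' Kingman coalescent (expected pairwise MRCA time \code{pop_scale}).
#'
#' @param params a \code{sim_params}.
#' @param seed optional override of \code{params$seed}.
#' @return list with \code{tree} (\code{ape::phylo}) and \code{meta} (tip
#'   metadata data.frame with tip_id, sample_id, city, region,
#'   dedup_score).
#' @export
simulate_genealogy <- function(params, seed = params$seed) {
  .check(!(params$migration_rate == 0 && params$n_regions > 1),
         "migration_rate = 0 with multiple regions never finds an MRCA")
  with_seed(seed, .simulate_genealogy_impl(params))
}

.simulate_genealogy_impl <- function(params) {
  n_r <- params$n_regions
  n_s <- params$samples_per_region
  m <- params$migration_rate
  scale <- params$pop_scale

  tip_id <- sprintf("s%03d", seq_len(n_r * n_s))
  region <- rep(sprintf("region%d", seq_len(n_r)), each = n_s)
  city <- unlist(lapply(seq_len(n_r), function(r)
    sprintf("r%dcity%d", r,
            rep_len(seq_len(params$cities_per_region), n_s))))
  meta <- data.frame(tip_id = tip_id, sample_id = paste0("sample_", tip_id),
                     city = city, region = region,
                     dedup_score = round(stats::runif(n_r * n_s, 0.5, 1), 4),
                     stringsAsFactors = FALSE)

  # active lineages: newick fragment, region index, birth time
  frag <- tip_id
  reg <- rep(seq_len(n_r), each = n_s)
  born <- rep(0, n_r * n_s)
  t_now <- 0
  while (length(frag) > 1L) {
    k_r <- tabulate(reg, nbins = n_r)
    coal_r <- choose(k_r, 2) / scale
    mig <- length(frag) * m
    tot <- sum(coal_r) + mig
    t_now <- t_now + stats::rexp(1L, tot)
    if (stats::runif(1L) < sum(coal_r) / tot) {
      r <- sample.int(n_r, 1L, prob = coal_r)
      pair <- sample(which(reg == r), 2L)
      i <- pair[1L]; j <- pair[2L]
      new_frag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], t_now - born[i],
                          frag[j], t_now - born[j])
      frag[i] <- new_frag; born[i] <- t_now
      frag <- frag[-j]; reg <- reg[-j]; born <- born[-j]
    } else {
      i <- sample.int(length(frag), 1L)
      reg[i] <- if (n_r == 1L) reg[i] else
        sample(setdiff(seq_len(n_r), reg[i]), 1L)
    }
  }
  tree <- read_newick(text = paste0(frag, ";"))
  list(tree = tree, meta = meta, tmrca = t_now)
}

# 61 sense codons of translation table 11
.sense_codons <- function() {
  all <- names(.GENETIC_CODE_11)
  all[!(all %in% .STOP_CODONS)]
}

#' Simulate a codon alignment down a genealogy
#'
#' The root sequence is an ATG start codon followed by random sense codons.
#' Sequences evolve down the tree under Jukes-Cantor mutation: the number
#' of substitutions per branch is Poisson with mean
#' \code{mutation_rate x branch length x sites}, each at a uniform site
#' with a uniform alternative base; mutations that would create an in-frame
#' stop codon are resampled. For a selected gene, a fraction
#' \code{selection_fraction} of the alignment's sites is constrained, the
#' constrained sites drawn from first and second codon positions past the
#' start codon (so the regional signal is amino-acid changing): every
#' region is assigned a preferred base, distinct between regions at each
#' site, and every tip's state at a constrained site is overwritten with
#' probability \code{selection_strength} by its region's preferred base
#' (skipped where the overwrite would create a stop in that tip's
#' background). The start codon itself never mutates.
#'
#' @param tree \code{ape::phylo} genealogy with branch lengths in
#'   coalescent units.
#' @param meta tip metadata carrying each tip's region.
#' @param params a \code{sim_params}.
#' @param selected logical; apply regional selection?
#' @param seed integer seed.
#' @return list with \code{aln} (a \code{codon_aln}) and \code{truth}
#'   (constrained site indices and per-region preferred bases, empty when
#'   neutral).
#' @export
simulate_alignment <- function(tree, meta, params, selected = FALSE,
                               seed = params$seed) {
  with_seed(seed, .simulate_alignment_impl(tree, meta, params, selected))
}

.simulate_alignment_impl <- function(tree, meta, params, selected) {
  n_sites <- params$gene_length * 3L
  bases <- c("A", "C", "G", "T")
  sense <- .sense_codons()
  root <- c("A", "T", "G",
            unlist(strsplit(sample(sense, params$gene_length - 1L,
                                   replace = TRUE), "")))

  has_stop <- function(seq_chars, site) {
    cod_i <- (site - 1L) %/% 3L
    cod <- paste(seq_chars[(3L * cod_i + 1L):(3L * cod_i + 3L)],
                 collapse = "")
    cod %in% .STOP_CODONS
  }

  mutate_branch <- function(seq_chars, len) {
    # the start codon is held invariant (sites 4..n mutate): real start
    # codons are under strong purifying selection, and downstream framing
    # rules key on them
    n_mut <- stats::rpois(1L, params$mutation_rate * len * (n_sites - 3L))
    for (k in seq_len(n_mut)) {
      for (attempt in 1:50) {
        site <- sample.int(n_sites - 3L, 1L) + 3L
        old <- seq_chars[site]
        new <- sample(bases[bases != old], 1L)
        seq_chars[site] <- new
        if (!has_stop(seq_chars, site)) break
        seq_chars[site] <- old
      }
    }
    seq_chars
  }

  # propagate sequences from root to tips along the edge list
  tr <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- length(tr$tip.label)
  seqs <- vector("list", n_tip + tr$Nnode)
  root_node <- n_tip + 1L
  seqs[[root_node]] <- root
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
    seqs[[child]] <- mutate_branch(seqs[[par]], tr$edge.length[e])
  }
  aln <- do.call(rbind, seqs[seq_len(n_tip)])
  rownames(aln) <- tr$tip.label

  truth <- list(constrained_sites = integer(0),
                preferred = list())
  if (selected && params$selection_fraction > 0) {
    # candidate sites: first and second codon positions past the start
    # codon, where a regional overwrite changes the protein — the selected
    # signal is amino-acid level, which the dN/dS contrast keys on
    cand <- setdiff(seq(4L, n_sites), seq(6L, n_sites, by = 3L))
    n_con <- min(length(cand),
                 max(1L, round(params$selection_fraction * n_sites)))
    con <- sort(sample(cand, n_con))
    regions <- sort(unique(meta$region))
    # regionally differentiated preferred states: distinct bases per region
    # at each constrained site (recycled when regions outnumber bases)
    pref_mat <- vapply(seq_along(con), function(j)
      rep_len(sample(bases), length(regions)), character(length(regions)))
    if (length(regions) == 1L) pref_mat <- matrix(pref_mat, nrow = 1L)
    pref <- lapply(seq_along(regions), function(i) pref_mat[i, ])
    names(pref) <- regions
    tip_region <- stats::setNames(meta$region, meta$tip_id)
    for (i in seq_len(nrow(aln))) {
      r <- tip_region[[rownames(aln)[i]]]
      hit <- stats::runif(length(con)) < params$selection_strength
      for (j in which(hit)) {
        old <- aln[i, con[j]]
        aln[i, con[j]] <- pref[[r]][j]
        if (has_stop(aln[i, ], con[j])) aln[i, con[j]] <- old
      }
    }
    truth <- list(constrained_sites = con, preferred = pref)
  }
  list(aln = codon_alignment(aln), truth = truth)
}

#' Simulate a full region-structured dataset with known truth
#'
#' One genealogy is simulated per dataset (the shared species history);
#' every gene's alignment evolves on it, selected genes with regional
#' overwrite and neutral genes without. Gene trees are rebuilt by neighbor
#' joining from each gene's alignment, so tree-estimation noise is part of
#' every recovery test. Selected genes are labeled half \code{membrane} and
#' half left unannotated or labeled with another term (both pooled as
#' metabolic downstream); all neutral genes are labeled \code{organelle},
#' so the organelle group is neutral by construction. Duplicate-city tips
#' (identical sequences, lower dedup score) are injected to exercise
#' \code{\link{filter_tips}}.
#'
#' @param params a \code{sim_params}.
#' @param out_dir optional directory; when given, writes species.nwk,
#'   genes/*.fasta, genes/*.nwk, meta.tsv, annotations.tsv and truth.json.
#' @return list with \code{species_tree}, \code{gene_trees},
#'   \code{alignments}, \code{meta}, \code{annotations}, \code{truth}
#'   (selected gene ids, per-gene constrained sites, params) and
#'   \code{params}.
#' @export
simulate_dataset <- function(params, out_dir = NULL) {
  bundle <- with_seed(params$seed, .simulate_dataset_impl(params))
  if (!is.null(out_dir)) .write_bundle(bundle, out_dir)
  bundle
}

.simulate_dataset_impl <- function(params) {
  gen <- .simulate_genealogy_impl(params)
  meta <- gen$meta

  # inject duplicate-city tips: a re-binned genome from an already sampled
  # city, identical sequence, strictly lower dedup score
  dup_src <- character(0)
  if (params$dup_tips_per_region > 0) {
    for (r in unique(meta$region)) {
      cand <- meta$tip_id[meta$region == r]
      dup_src <- c(dup_src,
                   sample(cand, min(params$dup_tips_per_region,
                                    length(cand))))
    }
    dup_rows <- meta[match(dup_src, meta$tip_id), , drop = FALSE]
    dup_rows$tip_id <- paste0(dup_src, "d")
    dup_rows$sample_id <- paste0(dup_rows$sample_id, "_rebin")
    dup_rows$dedup_score <- round(dup_rows$dedup_score -
                                    stats::runif(nrow(dup_rows), 0.05, 0.3), 4)
    meta <- rbind(meta, dup_rows)
  }

  n_sel <- params$n_genes_selected
  n_neu <- params$n_genes_neutral
  gene_ids <- sprintf("gene%03d", seq_len(n_sel + n_neu))
  selected_ids <- gene_ids[seq_len(n_sel)]
  neutral_ids <- setdiff(gene_ids, selected_ids)

  # annotations: selected -> membrane (first half) / other-or-absent
  # (second half, pooled as metabolic); neutral -> organelle
  sel_membrane <- selected_ids[seq_len(ceiling(n_sel / 2))]
  sel_other <- setdiff(selected_ids, sel_membrane)
  sel_other_labeled <- sel_other[seq_len(length(sel_other) %/% 2)]
  ann <- rbind(
    data.frame(gene_id = sel_membrane,
               cc_labels = rep_len("membrane", length(sel_membrane)),
               stringsAsFactors = FALSE),
    data.frame(gene_id = sel_other_labeled,
               cc_labels = rep_len("cytoplasm", length(sel_other_labeled)),
               stringsAsFactors = FALSE),
    data.frame(gene_id = neutral_ids,
               cc_labels = rep_len("organelle", length(neutral_ids)),
               stringsAsFactors = FALSE))

  alignments <- list(); gene_trees <- list(); gene_truth <- list()
  for (g in gene_ids) {
    sim <- .simulate_alignment_impl(gen$tree, gen$meta, params,
                                    selected = g %in% selected_ids)
    m <- unclass(sim$aln)
    if (length(dup_src) > 0) {
      dup <- m[dup_src, , drop = FALSE]
      rownames(dup) <- paste0(dup_src, "d")
      m <- rbind(m, dup)
    }
    aln <- codon_alignment(m)
    alignments[[g]] <- aln
    # JC-corrected distances: uncorrected p-distances saturate and compress
    # the deep between-region divergence, biasing NJ branch lengths
    D <- suppressWarnings(p_distance_matrix(aln, correction = "jukes_cantor"))
    gene_trees[[g]] <- suppressWarnings(neighbor_joining(D))
    gene_truth[[g]] <- sim$truth
  }

  # species tree: true genealogy with duplicate tips grafted at zero distance
  sp_newick <- ape::write.tree(gen$tree)
  for (s in dup_src) {
    sp_newick <- sub(sprintf("%s:", s),
                     sprintf("(%s:0,%sd:0):", s, s), sp_newick, fixed = TRUE)
  }
  species_tree <- read_newick(text = sp_newick)

  truth <- list(selected_gene_ids = selected_ids,
                neutral_gene_ids = neutral_ids,
                per_gene = gene_truth,
                tmrca = gen$tmrca,
                params = unclass(params))
  # consistency by construction: organelle-labeled genes are all neutral
  org <- ann$gene_id[ann$cc_labels == "organelle"]
  stopifnot(all(org %in% neutral_ids))

  list(species_tree = species_tree, gene_trees = gene_trees,
       alignments = alignments, meta = meta, annotations = ann,
       truth = truth, params = params)
}

.write_bundle <- function(bundle, out_dir) {
  dir.create(file.path(out_dir, "genes"), recursive = TRUE,
             showWarnings = FALSE)
  write_newick(bundle$species_tree, file.path(out_dir, "species.nwk"))
  for (g in names(bundle$gene_trees)) {
    write_newick(bundle$gene_trees[[g]],
                 file.path(out_dir, "genes", paste0(g, ".nwk")))
    write_alignment(bundle$alignments[[g]],
                    file.path(out_dir, "genes", paste0(g, ".fasta")))
  }
  utils::write.table(bundle$meta, file.path(out_dir, "meta.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(bundle$annotations,
                     file.path(out_dir, "annotations.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(bundle$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
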