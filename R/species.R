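#' Geographic-clustering test for one species and its gene trees
#'
#' Applies the pre-test tip filter (\code{\link{filter_tips}}) and then
#' \code{\link{permanova}} with region as the grouping factor to the species
#' tree and to every gene tree. Gene trees are analysed only when they carry
#' at least three tips before filtering, the minimum from which a tree can
#' be inferred. Trees that fail the filter are reported with
#' \code{status = "untestable"}, never silently dropped.
#'
#' @param species_tree \code{ape::phylo} species tree, or \code{NULL}.
#' @param gene_trees named list of \code{ape::phylo} gene trees.
#' @param meta tip metadata (see \code{\link{read_tip_metadata}}).
#' @param n_perm permutations per test.
#' @param seed integer; per-tree seeds are derived deterministically.
#' @return object of class \code{species_report}: list with
#'   \code{species_result} (a \code{permanova_result} or NULL),
#'   \code{gene_results} (named list), and a tidy \code{table} (data.frame
#'   with unit_id, level, n_tips, n_regions, r2, pseudo_f, p, status).
#' @export
test_species <- function(species_tree = NULL, gene_trees = list(), meta,
                         n_perm = 999, seed) {
  validate_tip_metadata(meta)
  run_one <- function(tree, sub_seed) {
    D <- patristic_distances(tree)
    flt <- filter_tips(D, meta)
    if (flt$status == "untestable") {
      return(list(r2 = NA_real_, pseudo_f = NA_real_, p_value = NA_real_,
                  n_permutations = 0L, n_tips = nrow(flt$D),
                  n_regions = length(unique(flt$meta$region)),
                  filter = flt, status = "untestable"))
    }
    groups <- stats::setNames(flt$meta$region, flt$meta$tip_id)
    res <- permanova(flt$D, groups, n_perm = n_perm, seed = sub_seed)
    res$filter <- flt
    res
  }
  species_result <- NULL
  if (!is.null(species_tree))
    species_result <- run_one(species_tree, seed)
  gene_results <- list()
  if (length(gene_trees) > 0L) {
    .check(!is.null(names(gene_trees)), "gene_trees must be named")
    for (i in seq_along(gene_trees)) {
      gid <- names(gene_trees)[i]
      tr <- gene_trees[[i]]
      if (length(tr$tip.label) < 3L) {
        gene_results[[gid]] <- list(r2 = NA_real_, pseudo_f = NA_real_,
                                    p_value = NA_real_, n_permutations = 0L,
                                    n_tips = length(tr$tip.label),
                                    n_regions = NA_integer_,
                                    status = "untestable")
      } else {
        gene_results[[gid]] <- run_one(tr, seed + i)
      }
    }
  }
  row_of <- function(id, level, r)
    data.frame(unit_id = id, level = level, n_tips = r$n_tips,
               n_regions = r$n_regions, r2 = r$r2, pseudo_f = r$pseudo_f,
               p = r$p_value, status = r$status,
               stringsAsFactors = FALSE)
  tab <- do.call(rbind, c(
    if (!is.null(species_result))
      list(row_of("species", "species", species_result)),
    lapply(names(gene_results), function(g)
      row_of(g, "gene", gene_results[[g]]))))
  out <- list(species_result = species_result, gene_results = gene_results,
              table = tab)
  class(out) <- "species_report"
  out
}

#' BH correction across the species trees of one run
#'
#' The multiple-testing family is the set of species trees tested in one
#' run; gene-tree p-values are not adjusted because downstream group
#' comparisons consume the R2 values, not the p-values.
#'
#' @param reports list of \code{species_report} objects (one per species).
#' @return the same list with \code{p_adjusted} added to each tested
#'   species-level result.
#' @export
adjust_species_reports <- function(reports) {
  ps <- vapply(reports, function(r)
    if (!is.null(r$species_result)) r$species_result$p_value else NA_real_,
    numeric(1))
  adj <- rep(NA_real_, length(ps))
  tested <- !is.na(ps)
  adj[tested] <- benjamini_hochberg(ps[tested])
  for (i in seq_along(reports))
    if (!is.null(reports[[i]]$species_result))
      reports[[i]]$species_result$p_adjusted <- adj[i]
  reports
}
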