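#' Assign genes to membrane / organelle / metabolic groups
#'
#' Stratifies genes by their top-level cellular-component labels: genes
#' labeled \code{membrane} form the membrane group, genes labeled
#' \code{organelle} the organelle group, and everything else — any other
#' top-level term or no annotation at all — is pooled into the collapsed
#' \code{metabolic} group (in real annotations the large unannotated
#' fraction is dominated by metabolic-pathway genes, hence the name). A gene
#' carrying both \code{membrane} and \code{organelle} labels is assigned to
#' membrane, since surface exposure drives the selection hypothesis; the
#' number of such conflicts is reported via a message.
#'
#' @param gene_ids character vector of all genes to classify.
#' @param annotations data.frame with columns \code{gene_id} and
#'   \code{cc_labels} (semicolon-separated top-level CC terms); genes absent
#'   from the table are unannotated.
#' @return named character vector gene_id -> group.
#' @export
assign_groups <- function(gene_ids, annotations = NULL) {
  .check(!anyDuplicated(gene_ids), "gene_ids must be unique")
  grp <- stats::setNames(rep("metabolic", length(gene_ids)), gene_ids)
  if (is.null(annotations) || nrow(annotations) == 0L) return(grp)
  .check(all(c("gene_id", "cc_labels") %in% names(annotations)),
         "annotations need columns gene_id, cc_labels")
  ann <- annotations[annotations$gene_id %in% gene_ids, , drop = FALSE]
  labs <- strsplit(tolower(ann$cc_labels), ";", fixed = TRUE)
  labs <- lapply(labs, trimws)
  has_mem <- vapply(labs, function(x) "membrane" %in% x, logical(1))
  has_org <- vapply(labs, function(x) "organelle" %in% x, logical(1))
  n_conflict <- sum(has_mem & has_org)
  if (n_conflict > 0L)
    message(n_conflict,
            " gene(s) labeled both membrane and organelle -> membrane")
  grp[ann$gene_id[has_org]] <- "organelle"
  grp[ann$gene_id[has_mem]] <- "membrane"   # membrane wins conflicts
  grp
}

#' Regional entropy of a tree's tip composition
#'
#' Shannon entropy (natural log, nats) of the proportions of tips per
#' region: \eqn{-\sum_i p_i \log p_i}. Zero-count regions contribute
#' nothing; a single represented region gives 0. Bounded above by
#' \eqn{\log} of the number of represented regions.
#'
#' @param region_counts named nonnegative numeric vector of tips per region.
#' @return entropy in nats.
#' @export
regional_entropy <- function(region_counts) {
  .check(all(region_counts >= 0), "counts must be nonnegative")
  tot <- sum(region_counts)
  .check(tot > 0, "all-zero region counts")
  p <- region_counts[region_counts > 0] / tot
  -sum(p * log(p))
}

#' Per-gene records for group comparisons and bias diagnostics
#'
#' Combines each gene's clustering result with its covariates: alignment
#' length (positions), mean pi, regional entropy of the tested tips, and
#' the number of tips after filtering.
#'
#' @param report a \code{species_report} from \code{\link{test_species}}.
#' @param alignments named list of \code{codon_aln}, one per gene.
#' @param groups named vector gene_id -> group from
#'   \code{\link{assign_groups}}.
#' @return data.frame with columns gene_id, group, length, mean_pi,
#'   regional_entropy, n_tips, r2, p_value, status.
#' @export
gene_records <- function(report, alignments, groups) {
  gids <- names(report$gene_results)
  .check(all(gids %in% names(alignments)), "alignment missing for some gene")
  .check(all(gids %in% names(groups)), "group missing for some gene")
  rows <- lapply(gids, function(g) {
    res <- report$gene_results[[g]]
    aln <- alignments[[g]]
    ent <- if (!is.null(res$filter) && nrow(res$filter$meta) > 0L)
      regional_entropy(table(res$filter$meta$region)) else NA_real_
    data.frame(gene_id = g, group = unname(groups[g]),
               length = ncol(aln),
               mean_pi = mean_pi(aln),
               regional_entropy = ent,
               n_tips = res$n_tips, r2 = res$r2, p_value = res$p_value,
               status = res$status, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare a per-gene value between functional groups
#'
#' Kruskal-Wallis test (tie-corrected H, chi-squared p on k-1 df) across
#' the groups, followed by pairwise two-sided Wilcoxon rank-sum tests.
#' Wilcoxon tests are exact when both groups have at most 25 members and no
#' ties occur, otherwise the normal approximation with tie and continuity
#' correction is used. Pairwise p-values are BH-adjusted within the call;
#' they are flagged as reportable only when the (possibly externally
#' adjusted) Kruskal-Wallis p clears \code{alpha}, mirroring the
#' screen-then-localize design. Groups with fewer than 2 finite values are
#' excluded from pairwise testing.
#'
#' @param records data.frame from \code{\link{gene_records}}, optionally
#'   with a \code{dnds} column.
#' @param value which column to compare: \code{"r2"} or \code{"dnds"}.
#' @param alpha screening level for the pairwise stage.
#' @param kw_adjusted_p optionally, the externally BH-adjusted KW p for this
#'   species (family = all species tested in a run); defaults to the raw p.
#' @return object of class \code{group_comparison}: list with
#'   \code{kruskal_h}, \code{kruskal_p}, \code{kw_adjusted_p},
#'   \code{pairwise} (data.frame group_a, group_b, w, p, p_adj, n_a, n_b),
#'   \code{pairwise_reported}, \code{group_means}, \code{group_n}.
#' @export
compare_groups <- function(records, value = c("r2", "dnds"), alpha = 0.05,
                           kw_adjusted_p = NULL) {
  value <- match.arg(value)
  .check(value %in% names(records), paste0("records lack a ", value, " column"))
  x <- records[[value]]
  g <- records$group
  ok <- is.finite(x)
  x <- x[ok]; g <- factor(g[ok])
  g <- droplevels(g)
  .check(nlevels(g) >= 2L, "need at least 2 non-empty groups")

  if (stats::var(x) == 0) {
    # all values identical: no rank variation, H = 0 by convention
    kw <- list(statistic = c(H = 0), p.value = 1)
  } else {
    kw <- stats::kruskal.test(x, g)
  }
  kw_p <- unname(kw$p.value)
  if (is.null(kw_adjusted_p)) kw_adjusted_p <- kw_p

  lev <- levels(g)
  sizes <- table(g)
  pairs <- utils::combn(lev, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    xa <- x[g == a]; xb <- x[g == b]
    if (length(xa) < 2L || length(xb) < 2L)
      return(data.frame(group_a = a, group_b = b, w = NA_real_,
                        p = NA_real_, n_a = length(xa), n_b = length(xb),
                        stringsAsFactors = FALSE))
    ties <- anyDuplicated(c(xa, xb)) > 0L
    exact <- length(xa) <= 25L && length(xb) <= 25L && !ties
    wt <- suppressWarnings(stats::wilcox.test(xa, xb, exact = exact,
                                              correct = TRUE))
    data.frame(group_a = a, group_b = b, w = unname(wt$statistic),
               p = unname(wt$p.value), n_a = length(xa), n_b = length(xb),
               stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, rows)
  pw$p_adj <- benjamini_hochberg(pw$p)

  out <- list(kruskal_h = unname(kw$statistic), kruskal_p = kw_p,
              kw_adjusted_p = kw_adjusted_p,
              pairwise = pw,
              pairwise_reported = is.finite(kw_adjusted_p) &&
                kw_adjusted_p < alpha,
              group_means = tapply(x, g, mean),
              group_medians = tapply(x, g, stats::median),
              group_n = as.integer(sizes))
  names(out$group_n) <- names(sizes)
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.4f, p = %.4g (adjusted %.4g)\n",
              x$kruskal_h, x$kruskal_p, x$kw_adjusted_p))
  cat("group means:\n"); print(round(x$group_means, 4))
  if (x$pairwise_reported) {
    cat("pairwise Wilcoxon (BH-adjusted):\n")
    print(x$pairwise)
  } else cat("pairwise tests not reported (screen not significant)\n")
  invisible(x)
}

#' Covariate bias diagnostics for geographic R2
#'
#' Pearson correlation of per-gene R2 with the number of tips, mean pi,
#' gene length and regional entropy, with two-sided p-values and BH
#' adjustment across the four covariates. A species in which any covariate
#' correlates significantly with R2 is flagged so the user can decide
#' whether its group contrast is trustworthy (flag, never auto-drop).
#' Zero-variance covariates give an NA coefficient, not an error.
#'
#' @param records data.frame from \code{\link{gene_records}}.
#' @param alpha significance level for the flag.
#' @return data.frame: covariate, pcc, p, p_adj, flagged; attribute
#'   \code{species_flagged} (logical).
#' @export
covariate_diagnostics <- function(records, alpha = 0.05) {
  covs <- c("n_tips", "mean_pi", "length", "regional_entropy")
  ok <- is.finite(records$r2)
  .check(sum(ok) >= 3L, "need >= 3 genes with finite r2")
  r2 <- records$r2[ok]
  rows <- lapply(covs, function(cv) {
    v <- records[[cv]][ok]
    fin <- is.finite(v)
    if (sum(fin) < 3L || stats::sd(v[fin]) == 0 || stats::sd(r2[fin]) == 0)
      return(data.frame(covariate = cv, pcc = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    ct <- stats::cor.test(r2[fin], v[fin], method = "pearson")
    data.frame(covariate = cv, pcc = unname(ct$estimate),
               p = unname(ct$p.value), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- benjamini_hochberg(tab$p)
  tab$flagged <- !is.na(tab$p_adj) & tab$p_adj < alpha
  attr(tab, "species_flagged") <- any(tab$flagged)
  tab
}
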