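#' One-factor PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance of a single grouping
#' factor (region of origin) on a distance matrix, in the Gower-centered
#' trace formulation. With \eqn{A = -\frac{1}{2} D \circ D} and
#' \eqn{G = J A J}, \eqn{J = I - \mathbf{1}\mathbf{1}^T/n}:
#' \deqn{SS_{total} = tr(G), \quad SS_{model} = tr(H G H),}
#' where \eqn{H} is the projection onto the group-indicator design
#' (including the intercept). Then \eqn{R^2 = SS_{model}/SS_{total}} and
#' \eqn{F = \frac{SS_{model}/(k-1)}{SS_{resid}/(n-k)}}. The permutation null
#' permutes group labels with a seeded generator and the p-value uses the
#' add-one correction \eqn{p = (1 + \#\{F_\pi \ge F_{obs}\})/(1 + P)}, so it
#' is never exactly zero.
#'
#' On a Euclidean-embeddable matrix \eqn{R^2 \in [0,1]} and the numbers
#' coincide with classical one-way ANOVA on the embedded coordinates; on
#' non-Euclidean input (negative eigenvalues of \eqn{G}) \eqn{R^2} can be
#' negative — the "worse than a horizontal line" case that short
#' low-variance genes can produce.
#'
#' @param D symmetric labeled distance matrix.
#' @param groups named character/factor vector (names = tip ids) or an
#'   unnamed vector aligned with \code{rownames(D)}.
#' @param n_perm number of label permutations (default 999).
#' @param seed integer seed for the permutation generator (required).
#' @param permutations optional integer matrix (n x P) of label orderings
#'   replacing random permutations, e.g. an exhaustive enumeration.
#' @return object of class \code{permanova_result}: list with \code{r2},
#'   \code{pseudo_f}, \code{p_value}, \code{n_permutations}, \code{n_tips},
#'   \code{n_regions}, \code{ss} (model/resid/total) and \code{status}.
#' @export
permanova <- function(D, groups, n_perm = 999, seed, permutations = NULL) {
  .check(is.matrix(D) && nrow(D) == ncol(D), "D must be a square matrix")
  n <- nrow(D)
  labels <- rownames(D)
  if (!is.null(names(groups))) {
    .check(all(labels %in% names(groups)),
           "every matrix label needs a group")
    g <- factor(unname(groups[labels]))
  } else {
    .check(length(groups) == n, "groups length must match matrix order")
    g <- factor(groups)
  }
  g <- droplevels(g)
  k <- nlevels(g)
  .check(k >= 2L, "need at least 2 groups")
  .check(max(abs(D - t(D))) < 1e-8, "D must be symmetric")

  G <- .gower_center(D)
  ss_total <- sum(diag(G))
  if (ss_total <= .Machine$double.eps * n) {
    res <- list(r2 = NA_real_, pseudo_f = NA_real_, p_value = NA_real_,
                n_permutations = 0L, n_tips = n, n_regions = k,
                ss = c(model = 0, resid = 0, total = ss_total),
                status = "untestable")
    class(res) <- "permanova_result"
    return(res)
  }

  gi <- as.integer(g)
  ss_model <- .ss_between(G, matrix(gi, ncol = 1L))[1L]
  ss_resid <- ss_total - ss_model
  f_obs <- (ss_model / (k - 1)) / (ss_resid / (n - k))

  if (is.null(permutations)) {
    .check(n_perm >= 1L, "n_perm must be >= 1")
    perm_idx <- with_seed(seed, replicate(n_perm, sample.int(n)))
    perm_g <- matrix(gi[perm_idx], nrow = n)
  } else {
    .check(nrow(permutations) == n, "permutation matrix must have n rows")
    perm_g <- permutations
    n_perm <- ncol(permutations)
  }
  ss_b <- .ss_between(G, perm_g)
  f_perm <- (ss_b / (k - 1)) / ((ss_total - ss_b) / (n - k))
  p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)

  res <- list(r2 = ss_model / ss_total, pseudo_f = f_obs, p_value = p,
              n_permutations = as.integer(n_perm), n_tips = n,
              n_regions = k,
              ss = c(model = ss_model, resid = ss_resid, total = ss_total),
              status = "tested")
  class(res) <- "permanova_result"
  res
}

# Gower double-centering of -1/2 * squared distances
.gower_center <- function(D) {
  A <- -0.5 * D * D
  rm <- rowMeans(A); cm <- colMeans(A); gm <- mean(A)
  sweep(sweep(A, 1L, rm), 2L, cm) + gm
}

# between-group SS tr(HGH) for each column of group codes; with the block
# projection H (H_ij = 1/n_g within a group) and centered G this equals
# sum_g (1/n_g) * sum_{i,j in g} G_ij, computed for all label columns at once
.ss_between <- function(G, group_codes) {
  k <- max(group_codes)
  n <- nrow(G)
  out <- numeric(ncol(group_codes))
  for (lev in seq_len(k)) {
    Z <- group_codes == lev               # n x P indicator
    storage.mode(Z) <- "double"
    ng <- colSums(Z)
    out <- out + colSums(Z * (G %*% Z)) / ng
  }
  out
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("PERMANOVA (one factor):",
      sprintf("n = %d tips, %d groups, status = %s", x$n_tips, x$n_regions,
              x$status), "\n")
  if (x$status == "tested")
    cat(sprintf("  R2 = %.4f  pseudo-F = %.4f  p = %.4g (%d permutations)\n",
                x$r2, x$pseudo_f, x$p_value, x$n_permutations))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate control; a thin wrapper over
#' \code{stats::p.adjust(method = "BH")} kept as the single named entry
#' point every driver in this package routes corrections through.
#'
#' @param p numeric vector of p-values in [0, 1] (NAs carried through).
#' @return adjusted p-values, same order and length.
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  .check(all(is.na(p) | (p >= 0 & p <= 1)), "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
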