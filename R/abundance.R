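#' Expected coverage of a genome from mapped read counts
#'
#' Probability that a given base of a genome of length \code{g} is covered
#' by at least one of \code{r} reads of length \code{l} placed uniformly:
#' \deqn{c = 1 - (1 - l/g)^r.}
#' Monotone nondecreasing in \code{r}, 0 at \code{r = 0}, and 1 when a
#' single read spans the genome.
#'
#' @param l mean read length (bp).
#' @param g genome length (bp), \code{g >= l}.
#' @param r number of mapped reads (vectorized).
#' @return expected covered fraction in [0, 1].
#' @export
expected_coverage <- function(l, g, r) {
  .check(all(l > 0) && all(g > 0), "lengths must be positive")
  .check(all(l <= g), "read length cannot exceed genome length")
  .check(all(r >= 0), "read counts must be nonnegative")
  1 - (1 - l / g)^r
}

#' Zero out cells with implausibly low observed coverage
#'
#' Compares the observed covered fraction of each sample x genome cell with
#' the coverage expected from its read count (\code{\link{expected_coverage}})
#' and zeroes counts where the ratio falls below the threshold: a genome
#' whose reads pile up on a small fraction of its length is likely a
#' spurious mapping, not a present organism. Cells with zero counts have
#' expected coverage 0 and are kept as zero.
#'
#' @param counts samples x genomes integer matrix.
#' @param observed_fraction matrix of observed covered fractions in [0, 1],
#'   same shape as \code{counts}.
#' @param genome_lengths vector of genome lengths (bp), one per column.
#' @param read_length mean read length (bp).
#' @param threshold minimum observed/expected ratio (default 0.5).
#' @param direction \code{"observed_over_expected"} (default) or
#'   \code{"expected_over_observed"}; the wording of the source protocol is
#'   ambiguous, so the direction is an explicit flag.
#' @return filtered count matrix.
#' @export
coverage_filter <- function(counts, observed_fraction, genome_lengths,
                            read_length, threshold = 0.5,
                            direction = c("observed_over_expected",
                                          "expected_over_observed")) {
  direction <- match.arg(direction)
  .check(all(dim(counts) == dim(observed_fraction)),
         "counts and observed_fraction must have the same shape")
  .check(length(genome_lengths) == ncol(counts),
         "one genome length per column")
  .check(all(observed_fraction >= 0 & observed_fraction <= 1),
         "observed fractions must lie in [0, 1]")
  exp_cov <- t(vapply(seq_len(nrow(counts)), function(i)
    expected_coverage(read_length, genome_lengths, counts[i, ]),
    numeric(ncol(counts))))
  if (nrow(counts) == 1L) exp_cov <- matrix(exp_cov, nrow = 1L)
  ratio <- if (direction == "observed_over_expected")
    observed_fraction / exp_cov else exp_cov / observed_fraction
  drop <- is.finite(ratio) & ratio < threshold
  counts[drop] <- 0L
  counts
}

#' Rarefy counts to a common depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric, via \code{vegan::rrarefy}) so every retained row sums to
#' exactly \code{depth}; one seeded draw per sample, not an average over
#' draws. Samples with fewer total reads than \code{depth} are dropped with
#' a warning. Absent genomes stay absent.
#'
#' @param counts samples x genomes integer matrix.
#' @param depth target depth; defaults to the minimum row sum.
#' @param seed integer seed.
#' @return rarefied count matrix (possibly fewer rows).
#' @export
rarefy_counts <- function(counts, depth = NULL, seed) {
  .check(all(counts >= 0), "counts must be nonnegative")
  tot <- rowSums(counts)
  if (is.null(depth)) depth <- min(tot)
  .check(depth > 0, "depth must be positive")
  keep <- tot >= depth
  if (!all(keep))
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped")
  .check(any(keep), "no sample reaches the requested depth")
  sub <- counts[keep, , drop = FALSE]
  # rrarefy warns when counts look rescaled; ours are raw subsample targets
  with_seed(seed, suppressWarnings(vegan::rrarefy(sub, depth)))
}

#' Transcripts per kilobase million
#'
#' Length-normalized, library-normalized abundance: each count is divided
#' by its genome length in kb, and rates are rescaled per sample to sum to
#' one million. All-zero samples give all-zero rows.
#'
#' @param counts samples x genomes matrix.
#' @param genome_lengths bp per genome (columns).
#' @return matrix of TPM values, rows summing to 1e6 (or 0).
#' @export
tpm <- function(counts, genome_lengths) {
  .check(length(genome_lengths) == ncol(counts),
         "one genome length per column")
  .check(all(genome_lengths > 0), "genome lengths must be positive")
  rate <- sweep(counts, 2L, genome_lengths / 1000, "/")
  tot <- rowSums(rate)
  zero <- tot == 0
  if (any(zero)) warning(sum(zero), " all-zero sample(s) left as zero")
  tot[zero] <- 1
  sweep(rate, 1L, tot, "/") * 1e6
}

#' Shannon diversity of one abundance profile
#'
#' \eqn{H = -\sum_i q_i \log q_i} in nats with \eqn{q_i} the relative
#' abundances; scale-invariant, so TPM and raw proportions agree.
#'
#' @param x nonnegative abundance vector with positive sum.
#' @return diversity in nats (NA for an all-zero vector).
#' @export
shannon_diversity <- function(x) {
  .check(all(x >= 0), "abundances must be nonnegative")
  if (sum(x) == 0) return(NA_real_)
  q <- x[x > 0] / sum(x)
  -sum(q * log(q))
}

#' Two-sample Kolmogorov-Smirnov comparison of composition profiles
#'
#' Compares two samples of per-taxon relative frequencies via the
#' two-sample KS statistic \eqn{D = \sup_x |ECDF_A(x) - ECDF_B(x)|} with
#' the asymptotic two-sided p-value. Used to ask whether two communities
#' (e.g. two environments' phylum profiles) draw their abundances from the
#' same distribution.
#'
#' @param freq_a,freq_b numeric vectors of frequencies.
#' @return list with \code{D} and \code{p}.
#' @export
composition_ks <- function(freq_a, freq_b) {
  .check(length(freq_a) > 0L && length(freq_b) > 0L,
         "both frequency vectors must be non-empty")
  kt <- suppressWarnings(stats::ks.test(freq_a, freq_b, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}
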