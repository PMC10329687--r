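#' In-frame codon alignments
#'
#' A codon alignment is stored as an upper-case character matrix with one row
#' per sequence (rownames are tip ids) and one column per nucleotide
#' position. Allowed symbols are A, C, G, T, the gap \code{-} and the
#' ambiguity code N.
#'
#' @param seqs named character vector of equal-length nucleotide strings, or
#'   a character matrix of single characters with rownames.
#' @return an object of class \code{codon_aln} (a character matrix).
#' @export
codon_alignment <- function(seqs) {
  if (is.matrix(seqs)) {
    m <- toupper(seqs)
  } else {
    .check(!is.null(names(seqs)) && !anyDuplicated(names(seqs)),
           "sequences must carry unique names")
    lens <- nchar(seqs)
    .check(length(unique(lens)) == 1L, "all sequences must have equal length")
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(m) <- names(seqs)
  }
  .check(!is.null(rownames(m)) && !anyDuplicated(rownames(m)),
         "alignment rows must have unique names")
  bad <- setdiff(unique(as.vector(m)), c("A", "C", "G", "T", "-", "N"))
  .check(length(bad) == 0L,
         paste0("invalid alignment symbols: ", paste(bad, collapse = ", ")))
  class(m) <- c("codon_aln", class(m))
  m
}

#' Read a FASTA alignment
#'
#' @param path FASTA file with aligned nucleotide sequences.
#' @return a \code{codon_aln}.
#' @export
read_alignment <- function(path) {
  dna <- ape::read.FASTA(path)
  .check(length(dna) >= 1L, "empty FASTA file")
  m <- toupper(as.character(as.matrix(dna)))
  m[!(m %in% c("A", "C", "G", "T", "-"))] <- "N"
  rownames(m) <- names(dna)
  codon_alignment(m)
}

#' Write a codon alignment as FASTA
#'
#' @param aln a \code{codon_aln}.
#' @param path output path.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(unclass(aln), 1L, paste, collapse = "")
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  invisible(path)
}

# pairwise p-distance with pairwise deletion of gap/N sites; returns a list
# with the p matrix and the number of compared sites per pair
.pairwise_p <- function(aln) {
  m <- unclass(aln)
  n <- nrow(m)
  ok <- m == "A" | m == "C" | m == "G" | m == "T"
  p <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  comp <- matrix(0L, n, n, dimnames = dimnames(p))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    use <- ok[i, ] & ok[j, ]
    nc <- sum(use)
    comp[i, j] <- comp[j, i] <- nc
    pij <- if (nc > 0L) sum(m[i, use] != m[j, use]) / nc else NA_real_
    p[i, j] <- p[j, i] <- pij
  }
  list(p = p, compared = comp)
}

#' Pairwise sequence distance matrix
#'
#' Uncorrected p-distance (mismatches over compared sites) between every
#' sequence pair, ignoring positions where either sequence has a gap or N
#' (pairwise deletion). With \code{correction = "jukes_cantor"} the
#' Jukes-Cantor transform \eqn{d = -3/4 \log(1 - 4p/3)} is applied; pairs at
#' or beyond the JC saturation point (\eqn{p \ge 0.75}) are set to
#' \code{saturation_cap} with a warning so downstream tree building stays
#' finite.
#'
#' @param aln a \code{codon_aln} with at least two sequences.
#' @param correction \code{"none"} or \code{"jukes_cantor"}.
#' @param saturation_cap distance assigned to JC-saturated pairs
#'   (substitutions/site).
#' @return symmetric labeled distance matrix with zero diagonal.
#' @export
p_distance_matrix <- function(aln, correction = c("none", "jukes_cantor"),
                              saturation_cap = 5) {
  correction <- match.arg(correction)
  .check(nrow(aln) >= 2L, "need at least two sequences")
  pw <- .pairwise_p(aln)
  d <- pw$p
  if (any(is.na(d[upper.tri(d)])))
    warning("some pairs share no compared sites; their distance is NA")
  if (correction == "jukes_cantor") {
    sat <- !is.na(d) & d >= 0.75
    d <- -0.75 * log(pmax(1 - 4 * d / 3, .Machine$double.eps))
    if (any(sat[upper.tri(sat)])) {
      warning("JC-saturated pairs (p >= 0.75) capped at ", saturation_cap)
      d[sat] <- saturation_cap
    }
  }
  diag(d) <- 0
  d
}

#' Mean pairwise fraction of varying sites (mean pi)
#'
#' The mean over all unordered sequence pairs of the fraction of compared
#' sites (pairwise gap/N deletion) at which the two sequences differ. Used
#' as a gene-variation covariate. Pairs with zero compared sites are
#' excluded with a warning.
#'
#' @param aln a \code{codon_aln} with at least two sequences.
#' @return a single number in [0, 1].
#' @export
mean_pi <- function(aln) {
  .check(nrow(aln) >= 2L, "need at least two sequences")
  pw <- .pairwise_p(aln)
  v <- pw$p[upper.tri(pw$p)]
  if (anyNA(v)) {
    warning(sum(is.na(v)), " pair(s) with no compared sites excluded")
    v <- v[!is.na(v)]
  }
  .check(length(v) > 0L, "no comparable sequence pairs")
  mean(v)
}
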