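# Bacterial translation table 11: codon -> one-letter amino acid, "*" = stop.
# Identical codon/amino-acid assignments to the standard code; table 11
# differs only in which codons may initiate, handled by frame_and_trim().
.GENETIC_CODE_11 <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

.STOP_CODONS <- c("TAA", "TAG", "TGA")
.START_CODONS <- c("ATG", "TTG", "GTG")

.translate_codon <- function(codon) unname(.GENETIC_CODE_11[codon])

#' Select genes with genetic variation between samples
#'
#' A gene is variable when at least one alignment column holds two or more
#' distinct unambiguous bases. Columns varying only between a base and a
#' gap or N do not count as variation. Only variable genes enter the dN/dS
#' calculation.
#'
#' @param alns named list of \code{codon_aln}.
#' @return character vector of variable gene ids.
#' @export
select_variable_genes <- function(alns) {
  .check(length(alns) > 0L && !is.null(names(alns)), "alns must be named")
  is_var <- vapply(alns, function(aln) {
    m <- unclass(aln)
    any(apply(m, 2L, function(col) {
      b <- col[col %in% c("A", "C", "G", "T")]
      length(unique(b)) >= 2L
    }))
  }, logical(1))
  names(alns)[is_var]
}

#' Frame and trim a codon alignment for dN/dS
#'
#' Enforces the in-frame contract: the consensus (majority, gaps/N ignored)
#' first codon must be a bacterial start (ATG, TTG or GTG), the alignment
#' is truncated to a multiple of 3, and trailing consensus stop codons
#' (TAA/TAG/TGA) are removed. A gene failing the start check is excluded
#' with a reason code rather than an error.
#'
#' @param aln a \code{codon_aln} of length >= 6.
#' @return list with \code{aln} (framed alignment or NULL), \code{status}
#'   (\code{"ok"} or \code{"excluded"}), \code{reason} (\code{""},
#'   \code{"no_start"} or \code{"too_short"}).
#' @export
frame_and_trim <- function(aln) {
  m <- unclass(aln)
  if (ncol(m) < 6L)
    return(list(aln = NULL, status = "excluded", reason = "too_short"))
  consensus_codon <- function(cols) {
    paste(apply(m[, cols, drop = FALSE], 2L, function(col) {
      b <- col[col %in% c("A", "C", "G", "T")]
      if (length(b) == 0L) return("N")
      tb <- sort(table(b), decreasing = TRUE)
      # majority base; ties broken alphabetically for determinism
      names(tb)[tb == max(tb)][1L]
    }), collapse = "")
  }
  if (!(consensus_codon(1:3) %in% .START_CODONS))
    return(list(aln = NULL, status = "excluded", reason = "no_start"))
  len <- 3L * (ncol(m) %/% 3L)
  m <- m[, seq_len(len), drop = FALSE]
  while (ncol(m) >= 6L &&
         consensus_codon((ncol(m) - 2L):ncol(m)) %in% .STOP_CODONS)
    m <- m[, seq_len(ncol(m) - 3L), drop = FALSE]
  out <- m
  class(out) <- c("codon_aln", class(out))
  list(aln = out, status = "ok", reason = "")
}

# --- NG86 site counting -----------------------------------------------------

# synonymous site fraction of one codon: per position, the fraction of
# non-stop single-base mutations that preserve the amino acid; stop-creating
# mutations are excluded from the denominator so each position contributes
# exactly one site (S + N = 3 per codon)
.codon_sites <- function(codon) {
  if (is.na(.translate_codon(codon)) || codon %in% .STOP_CODONS)
    return(c(S = NA_real_, N = NA_real_))
  aa <- .translate_codon(codon)
  bases <- c("A", "C", "G", "T")
  s <- 0
  chars <- strsplit(codon, "")[[1L]]
  for (pos in 1:3) {
    alt <- bases[bases != chars[pos]]
    muts <- vapply(alt, function(b) {
      x <- chars; x[pos] <- b; paste(x, collapse = "")
    }, character(1))
    keep <- !(muts %in% .STOP_CODONS)
    if (!any(keep)) next  # position contributes nothing if all paths stop
    s <- s + sum(.translate_codon(muts[keep]) == aa) / sum(keep)
  }
  c(S = s, N = 3 - s)
}

# all single-step mutation pathways between two codons; returns the mean
# synonymous and nonsynonymous step counts over pathways that never pass
# through a stop codon, or NA if every pathway does
.codon_path_diffs <- function(c1, c2) {
  ch1 <- strsplit(c1, "")[[1L]]; ch2 <- strsplit(c2, "")[[1L]]
  diff_pos <- which(ch1 != ch2)
  nd <- length(diff_pos)
  if (nd == 0L) return(c(Sd = 0, Nd = 0))
  perms <- if (nd == 1L) list(diff_pos) else {
    idx <- .permutations(nd)
    lapply(seq_len(nrow(idx)), function(i) diff_pos[idx[i, ]])
  }
  acc <- matrix(NA_real_, length(perms), 2L)
  for (k in seq_along(perms)) {
    cur <- ch1; sd <- 0; ndiff <- 0; valid <- TRUE
    for (pos in perms[[k]]) {
      nxt <- cur; nxt[pos] <- ch2[pos]
      from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
      if (to %in% .STOP_CODONS || from %in% .STOP_CODONS) { valid <- FALSE; break }
      if (.translate_codon(from) == .translate_codon(to)) sd <- sd + 1
      else ndiff <- ndiff + 1
      cur <- nxt
    }
    if (valid) acc[k, ] <- c(sd, ndiff)
  }
  ok <- stats::complete.cases(acc)
  if (!any(ok)) return(c(Sd = NA_real_, Nd = NA_real_))
  c(Sd = mean(acc[ok, 1L]), Nd = mean(acc[ok, 2L]))
}

# all permutations of 1..n as a matrix (n <= 3 in practice)
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Nei-Gojobori (1986) dN/dS for one gene
#'
#' The unweighted pathway-counting estimator: synonymous (S) and
#' nonsynonymous (N) site counts are computed per sequence by enumerating
#' the three single-base mutations of every codon position (mutations to
#' stop codons are excluded from the denominator) and averaged over
#' sequences; synonymous (Sd) and nonsynonymous (Nd) differences are
#' counted per sequence pair by averaging over all shortest substitution
#' pathways with equal weight, excluding pathways that pass through a stop
#' codon, and averaged over pairs. Codons containing a gap or N in either
#' sequence of a pair are skipped for that pair. Proportions pS = Sd/S and
#' pN = Nd/N are Jukes-Cantor corrected,
#' \eqn{d = -\frac{3}{4}\log(1 - \frac{4p}{3})}; a proportion at or above
#' 3/4 leaves the corrected value undefined, and dS = 0 leaves the ratio
#' undefined (reported, excluded from group tests).
#'
#' @param aln a framed \code{codon_aln} (see \code{\link{frame_and_trim}})
#'   with >= 2 sequences and length a multiple of 3.
#' @param gene_id optional id carried into the result.
#' @return object of class \code{dnds_result}: list with gene_id,
#'   syn_sites, nonsyn_sites, syn_diffs, nonsyn_diffs, dn, ds, ratio,
#'   status.
#' @export
ng86 <- function(aln, gene_id = NA_character_) {
  m <- unclass(aln)
  .check(nrow(m) >= 2L, "need >= 2 sequences")
  .check(ncol(m) %% 3L == 0L, "alignment length must be a multiple of 3")
  ncod <- ncol(m) %/% 3L
  codons <- function(i) vapply(seq_len(ncod), function(k)
    paste(m[i, (3L * k - 2L):(3L * k)], collapse = ""), character(1))
  cod <- t(vapply(seq_len(nrow(m)), codons, character(ncod)))
  if (ncod == 1L) cod <- matrix(cod, ncol = 1L)
  clean <- matrix(!grepl("[-N]", cod), nrow(cod), ncod)

  # per-sequence site counts over that sequence's clean, non-stop codons
  site_cache <- new.env(parent = emptyenv())
  sites_of <- function(codon) {
    v <- site_cache[[codon]]
    if (is.null(v)) { v <- .codon_sites(codon); site_cache[[codon]] <- v }
    v
  }
  per_seq <- t(vapply(seq_len(nrow(cod)), function(i) {
    cs <- cod[i, clean[i, ]]
    if (length(cs) == 0L) return(c(S = NA_real_, N = NA_real_))
    vals <- vapply(cs, sites_of, numeric(2))
    rowSums(vals, na.rm = TRUE)
  }, numeric(2)))
  S <- mean(per_seq[, 1L], na.rm = TRUE)
  N <- mean(per_seq[, 2L], na.rm = TRUE)

  # pairwise pathway-averaged differences
  path_cache <- new.env(parent = emptyenv())
  diffs_of <- function(c1, c2) {
    key <- paste0(c1, c2)
    v <- path_cache[[key]]
    if (is.null(v)) { v <- .codon_path_diffs(c1, c2); path_cache[[key]] <- v }
    v
  }
  npair <- 0L; Sd_sum <- 0; Nd_sum <- 0
  for (i in seq_len(nrow(cod) - 1L)) for (j in (i + 1L):nrow(cod)) {
    use <- clean[i, ] & clean[j, ] &
      !(cod[i, ] %in% .STOP_CODONS) & !(cod[j, ] %in% .STOP_CODONS)
    if (!any(use)) next
    sd <- 0; ndf <- 0
    for (k in which(use)) {
      d <- diffs_of(cod[i, k], cod[j, k])
      if (anyNA(d)) next  # all pathways stop-passing: skip codon for pair
      sd <- sd + d[["Sd"]]; ndf <- ndf + d[["Nd"]]
    }
    npair <- npair + 1L
    Sd_sum <- Sd_sum + sd; Nd_sum <- Nd_sum + ndf
  }
  Sd <- if (npair > 0L) Sd_sum / npair else NA_real_
  Nd <- if (npair > 0L) Nd_sum / npair else NA_real_

  jc <- function(p) if (!is.finite(p) || p >= 0.75) NA_real_
    else -0.75 * log(1 - 4 * p / 3)
  ds <- jc(Sd / S)
  dn <- jc(Nd / N)
  ratio <- if (is.finite(dn) && is.finite(ds) && ds > 0) dn / ds else NA_real_
  status <- if (is.finite(ratio)) "ok"
    else if (is.finite(ds) && ds == 0) "ds_zero" else "undefined"
  out <- list(gene_id = gene_id, syn_sites = S, nonsyn_sites = N,
              syn_diffs = Sd, nonsyn_diffs = Nd, dn = dn, ds = ds,
              ratio = ratio, status = status)
  class(out) <- "dnds_result"
  out
}

#' @export
print.dnds_result <- function(x, ...) {
  cat(sprintf("NG86: S = %.3f N = %.3f Sd = %.3f Nd = %.3f\n",
              x$syn_sites, x$nonsyn_sites, x$syn_diffs, x$nonsyn_diffs))
  cat(sprintf("  dN = %s dS = %s dN/dS = %s (%s)\n",
              format(x$dn), format(x$ds), format(x$ratio), x$status))
  invisible(x)
}

#' Gene-wise dN/dS over a set of alignments
#'
#' Applies the variable-gene selection, framing rules and NG86 estimator to
#' every gene, returning one row per gene with a status/reason column for
#' excluded or undefined cases.
#'
#' @param alns named list of \code{codon_aln}.
#' @return data.frame: gene_id, S, N, Sd, Nd, dn, ds, ratio, status, reason.
#' @export
dnds_table <- function(alns) {
  .check(!is.null(names(alns)), "alns must be named")
  variable <- select_variable_genes(alns)
  rows <- lapply(names(alns), function(g) {
    base <- data.frame(gene_id = g, S = NA_real_, N = NA_real_,
                       Sd = NA_real_, Nd = NA_real_, dn = NA_real_,
                       ds = NA_real_, ratio = NA_real_,
                       status = "excluded", reason = "",
                       stringsAsFactors = FALSE)
    if (!(g %in% variable)) { base$reason <- "invariant"; return(base) }
    fr <- frame_and_trim(alns[[g]])
    if (fr$status != "ok") { base$reason <- fr$reason; return(base) }
    r <- ng86(fr$aln, gene_id = g)
    data.frame(gene_id = g, S = r$syn_sites, N = r$nonsyn_sites,
               Sd = r$syn_diffs, Nd = r$nonsyn_diffs, dn = r$dn, ds = r$ds,
               ratio = r$ratio, status = r$status, reason = "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Contrast dN/dS between functional groups
#'
#' Joins per-gene ratios to their groups and delegates to
#' \code{\link{compare_groups}}; genes with undefined ratios are excluded
#' and the usable n per group is carried in the result.
#'
#' @param dnds data.frame from \code{\link{dnds_table}}.
#' @param groups named vector gene_id -> group.
#' @param ... passed to \code{\link{compare_groups}}.
#' @return a \code{group_comparison}.
#' @export
dnds_group_contrast <- function(dnds, groups, ...) {
  .check(all(dnds$gene_id %in% names(groups)), "group missing for some gene")
  rec <- data.frame(gene_id = dnds$gene_id,
                    group = unname(groups[dnds$gene_id]),
                    dnds = dnds$ratio, stringsAsFactors = FALSE)
  compare_groups(rec, value = "dnds", ...)
}
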