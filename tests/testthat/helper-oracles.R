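# Independent oracles used to freeze expected values. These deliberately
# take different routes than the package code: classical ANOVA instead of
# trace algebra, explicit path enumeration with seqinr translation instead
# of the cached NG86 recursion, and direct formula evaluation.

# classical one-way ANOVA R2 and F on coordinates
anova_oracle <- function(x, g) {
  fit <- stats::aov(x ~ g)
  tab <- summary(fit)[[1]]
  ss <- tab[["Sum Sq"]]
  list(r2 = ss[1] / sum(ss), f = tab[["F value"]][1])
}

# Anderson's group-sum formulation of PERMANOVA sums of squares
anderson_ss <- function(D, g) {
  n <- nrow(D)
  tot <- sum(D[upper.tri(D)]^2) / n
  within <- 0
  for (lev in unique(g)) {
    idx <- which(g == lev)
    sub <- D[idx, idx, drop = FALSE]
    within <- within + sum(sub[upper.tri(sub)]^2) / length(idx)
  }
  list(total = tot, within = within, between = tot - within)
}

# all distinct assignments of a balanced two-group labelling (n choose n/2)
enumerate_balanced_labels <- function(n) {
  half <- n / 2
  sets <- utils::combn(n, half)
  vapply(seq_len(ncol(sets)), function(j) {
    g <- rep(2L, n); g[sets[, j]] <- 1L; g
  }, integer(n))
}

# translation via seqinr, an independent genetic-code source
aa_of <- function(codon)
  seqinr::translate(strsplit(codon, "")[[1]], numcode = 11)

oracle_is_stop <- function(codon) aa_of(codon) == "*"

# NG86 synonymous site count of one codon by direct enumeration
oracle_codon_sites <- function(codon) {
  chars <- strsplit(codon, "")[[1]]
  aa <- aa_of(codon)
  s <- 0
  for (pos in 1:3) {
    alts <- setdiff(c("A", "C", "G", "T"), chars[pos])
    muts <- sapply(alts, function(b) {
      x <- chars; x[pos] <- b; paste(x, collapse = "")
    })
    keep <- !sapply(muts, oracle_is_stop)
    if (any(keep))
      s <- s + sum(sapply(muts[keep], aa_of) == aa) / sum(keep)
  }
  s
}

# all orderings of positions, as list of vectors (n <= 3)
all_orderings <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in all_orderings(v[-i]))
      out <- c(out, list(c(v[i], rest)))
  out
}

# pathway-averaged syn/nonsyn differences between two codons by brute force
oracle_path_diffs <- function(c1, c2) {
  ch1 <- strsplit(c1, "")[[1]]; ch2 <- strsplit(c2, "")[[1]]
  dp <- which(ch1 != ch2)
  if (length(dp) == 0) return(c(0, 0))
  paths <- all_orderings(dp)
  res <- NULL
  for (ord in paths) {
    cur <- ch1; sd <- 0; nd <- 0; ok <- TRUE
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- ch2[pos]
      if (oracle_is_stop(paste(nxt, collapse = ""))) { ok <- FALSE; break }
      if (aa_of(paste(cur, collapse = "")) ==
          aa_of(paste(nxt, collapse = ""))) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) res <- rbind(res, c(sd, nd))
  }
  if (is.null(res)) return(c(NA_real_, NA_real_))
  colMeans(res)
}

# small metadata table builder
make_meta <- function(tip_id, city, region, score = NULL) {
  data.frame(tip_id = tip_id, sample_id = paste0("smp_", tip_id),
             city = city, region = region,
             dedup_score = if (is.null(score)) seq_along(tip_id) / 10
                           else score,
             stringsAsFactors = FALSE)
}

# Euclidean distance matrix from a coordinate vector/matrix with labels
coord_dist <- function(x, labels = NULL) {
  D <- as.matrix(stats::dist(x))
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(D)))
  dimnames(D) <- list(labels, labels)
  D
}
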