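test_that("zero within-group distance gives R2 = 1", {
  D <- coord_dist(c(0, 0, 0, 10, 10, 10))
  g <- setNames(rep(c("a", "b"), each = 3), rownames(D))
  r <- permanova(D, g, n_perm = 99, seed = 1)
  expect_equal(r$r2, 1)
})

test_that("PERMANOVA on Euclidean configurations equals classical one-way ANOVA", {
  set.seed(5)
  for (rep in 1:4) {
    n <- sample(6:10, 1)
    x <- rnorm(n, mean = rep(c(0, 2), length.out = n))
    g <- factor(rep(c("a", "b"), length.out = n))
    D <- coord_dist(x)
    r <- permanova(D, setNames(as.character(g), rownames(D)),
                   n_perm = 9, seed = 1)
    o <- anova_oracle(x, g)
    expect_equal(r$r2, o$r2, tolerance = 1e-9)
    expect_equal(r$pseudo_f, o$f, tolerance = 1e-9)
  }
  # and a 2-d configuration with 3 groups
  xy <- matrix(rnorm(18), 9, 2) + cbind(rep(c(0, 3, 6), each = 3), 0)
  g3 <- factor(rep(c("a", "b", "c"), each = 3))
  r3 <- permanova(coord_dist(xy), as.character(g3), n_perm = 9, seed = 1)
  fit <- stats::manova(xy ~ g3)
  ss_m <- sum(diag(crossprod(fitted(fit)) -
                     nrow(xy) * tcrossprod(colMeans(xy))))
  ss_t <- sum(diag(crossprod(scale(xy, scale = FALSE))))
  expect_equal(r3$r2, ss_m / ss_t, tolerance = 1e-9)
})

test_that("trace-based sums of squares match Anderson's group-sum formula", {
  set.seed(8)
  x <- rnorm(8)
  D <- coord_dist(x)
  g <- rep(c("a", "b"), each = 4)
  r <- permanova(D, g, n_perm = 9, seed = 1)
  o <- anderson_ss(D, g)
  expect_equal(unname(r$ss["total"]), o$total, tolerance = 1e-9)
  expect_equal(unname(r$ss["model"]), o$between, tolerance = 1e-9)
  expect_equal(unname(r$ss["resid"]), o$within, tolerance = 1e-9)
})

test_that("permutation p equals exact enumeration over all balanced assignments", {
  set.seed(2)
  x <- c(rnorm(3), rnorm(3, 2))
  D <- coord_dist(x)
  labels_all <- enumerate_balanced_labels(6)   # all 20 assignments
  r <- permanova(D, rep(c("a", "b"), each = 3), seed = 1,
                 permutations = labels_all)
  # brute force through classical ANOVA F on the coordinates
  f_all <- apply(labels_all, 2, function(g) anova_oracle(x, factor(g))$f)
  f_obs <- anova_oracle(x, factor(rep(1:2, each = 3)))$f
  p_exact <- (1 + sum(f_all >= f_obs - 1e-12)) / (1 + length(f_all))
  expect_equal(r$p_value, p_exact)
})

test_that("results agree with vegan's adonis2 on the same permutations", {
  set.seed(9)
  x <- matrix(rnorm(20), 10, 2)
  g <- rep(c("a", "b"), 5)
  D <- coord_dist(x)
  r <- permanova(D, g, n_perm = 199, seed = 4)
  v <- vegan::adonis2(as.dist(D) ~ grp,
                      data = data.frame(grp = g), permutations = 199)
  expect_equal(r$r2, v$R2[1], tolerance = 1e-9)
  expect_equal(r$pseudo_f, v$F[1], tolerance = 1e-9)
})

test_that("PERMANOVA is invariant to joint relabeling and never returns p = 0", {
  set.seed(10)
  x <- rnorm(8); D <- coord_dist(x)
  g <- rep(c("a", "b"), 4)
  r1 <- permanova(D, g, n_perm = 99, seed = 3)
  perm <- sample(8)
  r2 <- permanova(D[perm, perm], g[perm], n_perm = 99, seed = 3)
  expect_equal(r2$r2, r1$r2, tolerance = 1e-12)
  expect_equal(r2$pseudo_f, r1$pseudo_f, tolerance = 1e-12)
  expect_gt(r1$p_value, 0)
  # strongly separated groups: p is small but strictly positive (the only
  # permutations reaching F_obs are the group-preserving ones, ~2.9%)
  xs <- c(0, 0, 0, 0, 50, 50, 50, 50)
  rs <- permanova(coord_dist(xs), g[order(g)], n_perm = 99, seed = 3)
  expect_gt(rs$p_value, 0)
  expect_lte(rs$p_value, 0.12)
})

test_that("a non-Euclidean distance matrix can yield negative R2", {
  D <- matrix(c(0, 4, 0.2, 0.2,
                4, 0, 0.2, 0.2,
                0.2, 0.2, 0, 4,
                0.2, 0.2, 4, 0), 4, 4,
              dimnames = list(paste0("t", 1:4), paste0("t", 1:4)))
  ev <- eigen(-0.5 * (diag(4) - 1 / 4) %*% (D * D) %*% (diag(4) - 1 / 4),
              symmetric = TRUE, only.values = TRUE)$values
  expect_lt(min(ev), -1e-9)  # genuinely non-embeddable
  r <- permanova(D, c("a", "a", "b", "b"), n_perm = 99, seed = 1)
  expect_lt(r$r2, 0)
})

test_that("identical points are flagged untestable", {
  D <- matrix(0, 4, 4, dimnames = list(paste0("t", 1:4), paste0("t", 1:4)))
  r <- permanova(D, c("a", "a", "b", "b"), n_perm = 9, seed = 1)
  expect_equal(r$status, "untestable")
  expect_true(is.na(r$r2))
})

test_that("adding a constant to all between-point distances never lowers total SS", {
  set.seed(12)
  D <- coord_dist(rnorm(7))
  base <- permanova(D, rep(c("a", "b"), length.out = 7), n_perm = 9,
                    seed = 1)$ss[["total"]]
  D2 <- D + 0.7; diag(D2) <- 0
  shifted <- permanova(D2, rep(c("a", "b"), length.out = 7), n_perm = 9,
                       seed = 1)$ss[["total"]]
  expect_gte(shifted, base)
})

test_that("BH adjustment follows the step-up procedure", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(benjamini_hochberg(numeric(0)), numeric(0))
  set.seed(13)
  p <- runif(25)
  adj <- benjamini_hochberg(p)
  expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
  # monotone in the ranks of the raw p-values
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})
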