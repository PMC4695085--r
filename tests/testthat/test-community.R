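test_that("square-root relative transform normalizes each sample", {
  expect_equal(unname(sqrt_relative(matrix(c(1, 0, 0), 1,
                                           dimnames = list("s", NULL)))[1, ]),
               c(1, 0, 0))
  tr <- sqrt_relative(matrix(c(25, 75), 1, dimnames = list("s", NULL)))
  expect_equal(round(unname(tr[1, ]), 4), c(0.5, 0.8660))
  set.seed(2)
  m <- matrix(rpois(50, 8), 5, 10, dimnames = list(paste0("s", 1:5), NULL))
  expect_equal(unname(rowSums(sqrt_relative(m)^2)), rep(1, 5))
  m[2, ] <- 0
  expect_warning(tr <- sqrt_relative(m), "zero-sum")
  expect_equal(nrow(tr), 4)
})

test_that("Bray-Curtis matches the definition and vegan", {
  u <- c(0.5, 0.8660); v <- c(0.8660, 0.5)
  m <- rbind(a = u, b = v)
  d <- as.matrix(bray_curtis(m))
  expect_equal(round(d["a", "b"], 4), 0.2679)
  expect_equal(d["a", "a"], 0)
  expect_equal(as.numeric(as.matrix(bray_curtis(rbind(a = c(1, 0),
                                                      b = c(0, 1))))[1, 2]), 1)
  set.seed(3)
  for (i in 1:5) {
    x <- matrix(runif(60), 6, 10, dimnames = list(paste0("s", 1:6), NULL))
    expect_equal(as.matrix(bray_curtis(x)), as.matrix(oracle_bray(x)),
                 tolerance = 1e-12)
    expect_equal(as.matrix(bray_curtis(x)),
                 as.matrix(vegan::vegdist(x, "bray")), tolerance = 1e-12)
  }
})

test_that("group mean dissimilarities follow the pair-weighting rules", {
  m <- matrix(0.4, 4, 4); diag(m) <- 0
  g <- c("a", "a", "b", "b")
  r <- group_mean_dissimilarity(m, g)
  expect_equal(unlist(r), c(overall = 0.4, within = 0.4, between = 0.4))
  # within pairs 0, cross pairs 1
  m2 <- outer(g, g, "!=") * 1
  r2 <- group_mean_dissimilarity(m2, g)
  expect_equal(unlist(r2), c(overall = 4 / 6, within = 0, between = 1))
  expect_true(is.na(group_mean_dissimilarity(m, rep("a", 4))$between))
})

test_that("PERMANOVA partitions SS correctly and matches the exact oracle", {
  # constant dissimilarities: R2 = (g-1)/(n-1), F ~ 1
  n <- 9
  m <- matrix(0.7, n, n); diag(m) <- 0
  g <- rep(c("a", "b", "c"), each = 3)
  r <- permanova(as.dist(m), ~ grp, data.frame(grp = g), n_perm = 99,
                 seed = 1)
  expect_equal(r$R2[1], (3 - 1) / (n - 1), tolerance = 1e-12)
  expect_equal(r$pseudo_F[1], 1, tolerance = 1e-9)
  # n = 4 two groups: exact enumeration of all 24 permutations
  set.seed(5)
  x <- rbind(matrix(rnorm(6), 2, 3), matrix(rnorm(6, 4), 2, 3))
  rownames(x) <- paste0("s", 1:4)
  d <- dist(x)
  g <- c("p", "p", "q", "q")
  perms <- all_permutations(4)
  r <- permanova(d, ~ grp, data.frame(grp = g), permutations = perms)
  f_oracle <- oracle_permanova_F(d, g)
  expect_equal(r$pseudo_F[1], f_oracle, tolerance = 1e-10)
  f_all <- apply(perms, 1, function(p)
    oracle_permanova_F(as.matrix(d)[p, p], g))
  expect_equal(r$p_value[1],
               (sum(f_all >= f_oracle - 1e-12) + 1) / (nrow(perms) + 1))
  # agreement with adonis2 on a larger one-way and a two-way design
  set.seed(6)
  y <- matrix(rpois(120, 10), 12, 10, dimnames = list(paste0("s", 1:12), NULL))
  dv <- bray_curtis(sqrt_relative(y))
  dat <- data.frame(pool = rep(c("300", "400"), 6),
                    comp = rep(c("w", "s", "c"), each = 4))
  mine <- permanova(dv, ~ comp * pool, dat, n_perm = 99, seed = 2)
  ref <- vegan::adonis2(dv ~ comp * pool, dat, permutations = 99,
                        by = "terms")
  expect_equal(mine$SS[1:3], ref$SumOfSqs[1:3], tolerance = 1e-10)
  expect_equal(mine$pseudo_F[1:3], ref$F[1:3], tolerance = 1e-10)
  expect_equal(mine$R2[1:3], ref$R2[1:3], tolerance = 1e-10)
})

test_that("PERMANOVA R2 is invariant to duplicating every sample", {
  set.seed(7)
  y <- matrix(rpois(60, 10), 6, 10, dimnames = list(paste0("s", 1:6), NULL))
  g <- rep(c("300", "400"), 3)
  d1 <- bray_curtis(sqrt_relative(y))
  y2 <- rbind(y, y); rownames(y2) <- paste0("s", 1:12)
  d2 <- bray_curtis(sqrt_relative(y2))
  r1 <- permanova(d1, ~ g, data.frame(g = g), n_perm = 49, seed = 1)
  r2 <- permanova(d2, ~ g, data.frame(g = c(g, g)), n_perm = 49, seed = 1)
  expect_equal(r1$R2[1], r2$R2[1], tolerance = 1e-10)
})

test_that("NMDS embeds easy geometries at near-zero stress", {
  m <- matrix(1, 3, 3); diag(m) <- 0
  rownames(m) <- colnames(m) <- paste0("s", 1:3)
  r <- nmds(m, k = 2, n_starts = 5, seed = 1)
  expect_lt(r$stress, 1e-3)
  # points on a line embed exactly in 2D
  set.seed(8)
  x <- sort(runif(10))
  d <- dist(cbind(x, 0))
  attr(d, "Labels") <- paste0("s", 1:10)
  r <- nmds(d, k = 2, n_starts = 5, seed = 2)
  expect_lt(r$stress, 0.01)
  expect_true(all(r$stress >= 0, r$stress <= 1))
  # determinism under a fixed seed
  r2 <- nmds(d, k = 2, n_starts = 5, seed = 2)
  expect_identical(r$points, r2$points)
})
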