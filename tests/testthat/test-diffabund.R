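make_sim_counts <- function(n_per_pool = 10, nt = 12, fold = NULL,
                            depth_mean = 1000, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_pool
  pool <- rep(c("300", "400"), each = n_per_pool)
  base <- rep(1 / nt, nt)
  prop <- matrix(rep(base, n), n, nt, byrow = TRUE,
                 dimnames = list(paste0("s", seq_len(n)),
                                 paste0("t", seq_len(nt))))
  if (!is.null(fold)) prop[pool == "300", names(fold)] <-
    sweep(prop[pool == "300", names(fold), drop = FALSE], 2, fold, "*")
  prop <- prop / rowSums(prop)
  depth <- pmax(100, round(rlnorm(n, log(depth_mean), log(1.6))))
  y <- t(vapply(seq_len(n), function(s) rmultinom(1, depth[s], prop[s, ])[, 1],
                integer(nt)))
  dimnames(y) <- dimnames(prop)
  ct <- count_table(y, toy_metadata(rownames(y), pool = pool))
  attr(ct, "prop") <- prop
  ct
}

test_that("abundance filter applies the strict 0.1% rule", {
  m <- matrix(c(11, 10, 9979), 1, dimnames = list("s1", c("a", "b", "c")))
  ct <- count_table(m, toy_metadata("s1"))
  f <- filter_taxa(ct, 0.001)
  expect_setequal(colnames(f$counts), c("a", "c"))
  expect_equal(attr(f, "dropped"), "b")
  # brute-force fraction recomputation on random tables
  set.seed(12)
  for (i in 1:5) {
    y <- matrix(rpois(80, 3), 8, 10,
                dimnames = list(paste0("s", 1:8), paste0("t", 1:10)))
    ct <- count_table(y, toy_metadata(rownames(y)))
    f <- filter_taxa(ct, 0.01)
    expect_setequal(colnames(f$counts),
                    colnames(y)[colSums(y) > 0.01 * sum(y)])
  }
  expect_error(filter_taxa(count_table(matrix(0L, 1, 1,
    dimnames = list("s1", "t")), toy_metadata("s1"))), "empty")
})

test_that("sum taxon equals per-sample depth", {
  m <- matrix(c(10, 30), 1, dimnames = list("s1", c("a", "b")))
  ws <- add_sum_taxon(count_table(m, toy_metadata("s1")))
  expect_equal(unname(ws$counts[, "sum"]), 40L)
  set.seed(13)
  for (i in 1:10) {
    y <- matrix(rpois(40, 5), 4, 10,
                dimnames = list(paste0("s", 1:4), paste0("t", 1:10)))
    ws <- add_sum_taxon(count_table(y, toy_metadata(rownames(y))))
    expect_equal(unname(ws$counts[, "sum"]), unname(rowSums(y)))
  }
})

test_that("the PLN model recovers null and planted effects", {
  # no planted effect: contrasts near zero
  ct0 <- make_sim_counts(seed = 3)
  ws0 <- add_sum_taxon(ct0)
  fit0 <- fit_pln(ws0, iterations = 4000, burnin = 1500, thin = 3, seed = 1)
  contr <- fit0$beta[, paste0("t", 1:12)] - fit0$beta[, "sum"]
  z <- abs(colMeans(contr)) / apply(contr, 2, sd)
  expect_true(all(z < 4))
  # 8-fold planted effect detected with a covering credible interval
  ct <- make_sim_counts(fold = c(t3 = 8), seed = 4)
  ws <- add_sum_taxon(ct)
  fit <- fit_pln(ws, iterations = 4000, burnin = 1500, thin = 3, seed = 1)
  s <- summarize_diff(fit)
  # realized fold after renormalization (other taxa shrink slightly)
  realized <- mean(attr(ct, "prop")[1:10, "t3"]) /
    mean(attr(ct, "prop")[11:20, "t3"])
  row <- s[s$taxon == "t3", ]
  expect_true(row$significant)
  expect_gt(row$fold_change, 4)
  expect_true(row$fold_lo <= realized * 1.35 && row$fold_hi >= realized / 1.35)
  expect_error(fit_pln(ws, iterations = 100, burnin = 200), "iterations")
})

test_that("relative abundances are invariant to sequencing depth", {
  ct <- make_sim_counts(nt = 8, seed = 5)
  ws <- add_sum_taxon(ct)
  fit1 <- fit_pln(ws, iterations = 4000, burnin = 1500, thin = 3, seed = 2)
  ct2 <- count_table(ct$counts * 2L, ct$metadata)
  ws2 <- add_sum_taxon(ct2)
  fit2 <- fit_pln(ws2, iterations = 4000, burnin = 1500, thin = 3, seed = 2)
  s1 <- summarize_diff(fit1); s2 <- summarize_diff(fit2)
  expect_equal(s1$relabund_pool400, s2$relabund_pool400, tolerance = 0.1)
  expect_equal(log(s1$fold_change), log(s2$fold_change), tolerance = 0.15)
})

test_that("MCMC summaries are deterministic given the seed", {
  ct <- make_sim_counts(n_per_pool = 4, nt = 5, seed = 6)
  ws <- add_sum_taxon(ct)
  f1 <- fit_pln(ws, iterations = 1500, burnin = 500, thin = 2, seed = 9)
  f2 <- fit_pln(ws, iterations = 1500, burnin = 500, thin = 2, seed = 9)
  expect_identical(f1$beta, f2$beta)
  expect_identical(summarize_diff(f1), summarize_diff(f2))
})

test_that("posterior summaries follow the z-score and BH definitions", {
  set.seed(30)
  nd <- 1000
  beta <- cbind(t1 = rnorm(nd, 2, 0.3), t2 = rnorm(nd, 0.5, 0.3),
                t3 = rnorm(nd, 0, 0.3), t4 = rep(0, nd), sum = rep(0, nd))
  fit <- structure(list(alpha = beta * 0, beta = beta,
                        sigma_e = rep(1, nd), sigma_u = rep(1, nd),
                        taxa = colnames(beta), seed = 1),
                   class = "sym_pln")
  s <- NULL
  expect_warning(s <- summarize_diff(fit), "degenerate")
  contr <- sweep(beta[, 1:4], 1, beta[, "sum"])
  z <- abs(colMeans(contr)) / apply(contr, 2, sd)
  p <- 2 * (1 - pnorm(z)); p[4] <- 1
  expect_equal(s$z[1:3], unname(z[1:3]))
  expect_equal(s$p_value, unname(p))
  expect_equal(s$significant, unname(p.adjust(p, "BH") <= 0.1))
  # fold-change credible limits bracket the posterior mean
  expect_true(all(s$fold_lo <= s$fold_change & s$fold_change <= s$fold_hi))
})
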