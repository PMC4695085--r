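test_that("reference database generation is deterministic and on target", {
  db1 <- make_reference_db(seed = 20)
  db2 <- make_reference_db(seed = 20)
  expect_identical(db1$records, db2$records)
  expect_identical(lapply(db1$trees, ape::write.tree),
                   lapply(db2$trees, ape::write.tree))
  expect_equal(nrow(db1$records), 20)
  # realized within-clade identity near the divergence target
  divs <- vapply(c(21, 22, 23), function(s) {
    db <- make_reference_db(n_per_clade = 4, within_clade_divergence = 0.05,
                            seed = s)
    rec <- db$records
    ids <- unlist(lapply(unique(rec$clade), function(cl) {
      sq <- rec$sequence[rec$clade == cl]
      unlist(lapply(seq_len(length(sq) - 1), function(i)
        symcomm:::.cpp_identity_batch(sq[i], sq[(i + 1):length(sq)])))
    }))
    mean(1 - ids)
  }, 0)
  # leaves split the root-to-tip divergence along the tree, so mean
  # pairwise divergence is of the order of 2x the per-leaf target
  expect_true(all(divs > 0.01 & divs < 0.15))
  expect_error(make_reference_db(within_clade_divergence = 0.3,
                                 between_clade_divergence = 0.2))
})

test_that("community simulation honors proportions, folds, and depths", {
  db <- make_reference_db(seed = 24)
  sc <- default_scenario(db, seed = 1)
  expect_true(all(vapply(sc$base_mixture, function(p)
    abs(sum(p) - 1) < 1e-9, TRUE)))
  comm <- simulate_community(sc$design, sc$base_mixture, sc$fold_changes,
                             sc$gradient, sc$depth_params, seed = 2)
  tp <- attr(comm, "truth")$proportions
  expect_equal(unname(rowSums(tp)), rep(1, nrow(tp)), tolerance = 1e-9)
  expect_equal(unname(rowSums(comm$counts)), attr(comm, "truth")$depths)
  # planted fold realized in the truth (up to renormalization)
  f100 <- names(sc$fold_changes)[1]
  md <- comm$metadata
  coral3 <- md$compartment == "coral" & md$pool == "300"
  coral4 <- md$compartment == "coral" & md$pool == "400"
  # realized fold is the planted fold over the pool-300 renormalizer
  # (all planted folds inflate/deflate the denominator; the gradient adds
  # per-sample wiggle)
  pm <- sc$base_mixture$coral
  renorm <- 1 + sum(pm[names(sc$fold_changes)] * (sc$fold_changes - 1))
  realized <- unname(100 / renorm)
  expect_equal(mean(tp[coral3, f100]) / mean(tp[coral4, f100]), realized,
               tolerance = 0.25)
  expect_gt(realized, 40)
  # exchangeable pools when nothing is planted: same compartment, either
  # pool, shares the same true proportions
  c0 <- simulate_community(sc$design, sc$base_mixture, seed = 3)
  tp0 <- attr(c0, "truth")$proportions
  w300 <- which(sc$design$compartment == "water" & sc$design$pool == "300")[1]
  w400 <- which(sc$design$compartment == "water" & sc$design$pool == "400")[1]
  expect_equal(unname(tp0[w300, ]), unname(tp0[w400, ]), tolerance = 1e-12)
  # determinism
  c1 <- simulate_community(sc$design, sc$base_mixture, sc$fold_changes,
                           sc$gradient, sc$depth_params, seed = 2)
  expect_identical(comm$counts, c1$counts)
})

test_that("library sizes follow the log-normal depth model", {
  set.seed(26)
  depth <- rlnorm(1000, log(1011), log(3.8))
  gm <- exp(mean(log(depth)))
  expect_true(gm > 900 && gm < 1130)
  gsd <- exp(sd(log(depth)))
  expect_equal(gsd, 3.8, tolerance = 0.1)
})

test_that("read simulation has the stated error structure", {
  db <- make_reference_db(n_per_clade = 2, seed = 27)
  md <- toy_metadata("s1")
  y <- matrix(2000L, 1, 1, dimnames = list("s1", db$records$name[1]))
  ct <- count_table(y, md)
  r0 <- simulate_reads(ct, db, error_rate = 0, seed = 1)
  expect_true(all(r0$sequence == db$records$sequence[1]))
  r1 <- simulate_reads(ct, db, error_rate = 0.01, seed = 2)
  src <- strsplit(db$records$sequence[1], "")[[1]]
  edits <- vapply(strsplit(r1$sequence, ""), function(ch)
    sum(ch != src), 0L)
  expect_equal(mean(edits), 0.01 * length(src), tolerance = 0.1)
  # truth labels attached for every read; determinism
  expect_equal(nrow(attr(r1, "truth")), nrow(r1))
  r1b <- simulate_reads(ct, db, error_rate = 0.01, seed = 2)
  expect_identical(r1$sequence, r1b$sequence)
  # unmapped taxon errors out
  bad <- count_table(matrix(1L, 1, 1, dimnames = list("s1", "ghost")), md)
  expect_error(simulate_reads(bad, db), "ghost")
  # indel mode produces length variation for the homopolymer filter
  ri <- simulate_reads(ct, db, error_rate = 0, indel_rate = 0.01, seed = 3)
  expect_gt(sd(nchar(ri$sequence)), 0)
  # primers are attached verbatim when requested
  rp <- simulate_reads(ct, db, error_rate = 0,
                       primers = list(forward = "ACGTACGTAA",
                                      reverse = "TTGCATGCAT"), seed = 4)
  expect_true(all(startsWith(rp$sequence, "ACGTACGTAA")))
})
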