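test_that("quality trimming matches the exhaustive suffix-window oracle", {
  s100 <- strrep("A", 100)
  expect_equal(nchar(quality_trim(s100, rep(40, 100))$sequence), 100)
  expect_equal(nchar(quality_trim(s100, rep(10, 100))$sequence), 0)
  # mixed-quality read: good 5' half, collapsing 3' half
  q <- c(rep(40, 50), rep(2, 50))
  tr <- quality_trim(s100, q, q_threshold = 25, window = 10)
  expect_equal(nchar(tr$sequence), oracle_quality_trim(q))
  # randomized profiles against the oracle
  set.seed(11)
  for (i in 1:20) {
    q <- sample(0:40, 80, replace = TRUE)
    expect_equal(nchar(quality_trim(strrep("A", 80), q)$sequence),
                 oracle_quality_trim(q))
  }
  expect_warning(quality_trim("ACGT", NULL), "skipped")
})

test_that("homopolymer filter discards runs above six bases", {
  expect_true(filter_homopolymer("ACGTACGT"))
  expect_false(filter_homopolymer(paste0("ACGT", strrep("A", 7), "CGT")))
  expect_true(filter_homopolymer(paste0("ACGT", strrep("A", 6), "CGT")))
})

test_that("primer trimming recovers the insert and honors the error budget", {
  set.seed(21)
  fwd <- "GTGAATTGCAGAACTCCGTG"
  rev <- "CCTCCGCTTACTTATATGCTT"
  insert <- random_dna(200)
  read <- paste0(fwd, insert, symcomm:::iupac_revcomp(rev))
  expect_equal(trim_primers(read, fwd, rev), insert)
  # 4 substitutions in the forward primer exceed the budget of 3
  bad <- paste0(substitute_at(fwd, c(2, 6, 11, 16)), insert)
  expect_true(is.na(trim_primers(bad, fwd, rev)))
  # 3 edits (1 insertion + 2 substitutions) still within budget
  fwd3 <- substitute_at(fwd, c(6, 11))
  fwd3 <- paste0(substr(fwd3, 1, 9), "T", substr(fwd3, 10, nchar(fwd3)))
  expect_equal(oracle_edit_locate(fwd, fwd3), 3)
  read3 <- paste0(fwd3, insert)
  expect_equal(trim_primers(read3, fwd, rev), insert)
  # missing reverse primer: forward-only trim
  expect_equal(trim_primers(paste0(fwd, insert), fwd, rev), insert)
  # IUPAC code in the primer matches its set
  expect_equal(trim_primers(paste0("ACGTAACGTA", insert),
                            "ACGTRACGTA", NULL), insert)
})

test_that("clade assignment applies the e-value and next-best-ratio rules", {
  db <- toy_db()
  rec <- db$records
  for (i in seq_len(nrow(rec))) {
    r <- assign_clade(rec$sequence[i], db)
    expect_equal(r$clade, rec$clade[i])
    expect_lt(r$e_value, 1e-20)
  }
  # midpoint sequence between clades A and C fails the ratio rule
  a <- rec$sequence[rec$name == "A1"]; c1 <- rec$sequence[rec$name == "C1"]
  ach <- strsplit(a, "")[[1]]; cch <- strsplit(c1, "")[[1]]
  diff <- which(ach != cch)
  mid <- ach; mid[diff[seq(1, length(diff), by = 2)]] <-
    cch[diff[seq(1, length(diff), by = 2)]]
  r <- assign_clade(paste(mid, collapse = ""), db)
  expect_true(is.na(r$clade))
  # random sequences fail the e-value cutoff
  set.seed(31)
  for (i in 1:10)
    expect_true(is.na(assign_clade(random_dna(300), db)$clade))
  expect_true(is.na(assign_clade("", db)$clade))
})

test_that("subtype assignment yields leaves, LCA placements, and novelty", {
  db <- toy_db()
  rec <- db$records
  expect_equal(assign_subtype(rec$sequence[rec$name == "C3"], "C", db)$label,
               "C3")
  # read equidistant between sister leaves C1 and C2 -> LCA node 2
  c1 <- rec$sequence[rec$name == "C1"]
  mid <- substitute_at(c1, c(11, 52)) # 2 of the 4 C1/C2 differences
  st <- assign_subtype(mid, "C", db)
  expect_equal(st$kind, "internal")
  expect_equal(st$label, "C_i:2")
  # a read equally far from all four leaves places at the root (node 1)
  # 95%-identical read fails the similarity rule -> novel
  far <- substitute_at(c1, seq(3, 330, by = 20))
  st <- assign_subtype(far, "C", db)
  expect_equal(st$kind, "new")
  expect_error(assign_subtype(c1, "Z", db), "clade")
})

test_that("de novo clustering equals the brute-force greedy oracle", {
  base <- random_dna(100, seed = 41)
  reads <- data.frame(
    read_id = paste0("r", 1:10),
    sequence = c(rep(base, 3),                      # abundance-3 centroid
                 rep(substitute_at(base, 1:2), 2),  # 98% of base
                 rep(substitute_at(base, seq(1, 30, 3)), 3), # 90%, new
                 substitute_at(base, 1:5),          # 95% of base, near 2nd?
                 random_dna(100)),
    clade = "C", stringsAsFactors = FALSE)
  got <- cluster_denovo(reads)
  # oracle: unique sequences in decreasing abundance, ties by smallest id
  groups <- split(reads$read_id, reads$sequence)
  uniq <- data.frame(sequence = names(groups), abundance = lengths(groups),
                     min_id = vapply(groups, function(x) min(sort(x)), ""))
  uniq <- uniq[order(-uniq$abundance, uniq$min_id), ]
  oracle <- oracle_greedy_clusters(uniq$sequence, seq_len(nrow(uniq)), 0.97)
  expected <- setNames(sprintf("C_d:%d", oracle), uniq$sequence)
  expect_equal(got$label, unname(expected[reads$sequence]))
  # degenerate cases
  ten <- data.frame(read_id = paste0("x", 1:10), sequence = base, clade = "C")
  expect_equal(unique(cluster_denovo(ten)$label), "C_d:1")
  two <- data.frame(read_id = c("a", "b"),
                    sequence = c(base, substitute_at(base, seq(1, 30, 3))),
                    clade = "C")
  expect_equal(sort(unique(cluster_denovo(two)$label)), c("C_d:1", "C_d:2"))
})

test_that("count table construction conserves reads and validates samples", {
  md <- toy_metadata(c("s1", "s2"))
  asn <- data.frame(sample_id = c("s1", "s1", "s2"),
                    label = c("C3", "C3", "C_d:1"))
  ct <- build_count_table(asn, md)
  expect_equal(ct$counts["s1", "C3"], 2L)
  expect_equal(ct$counts["s2", "C_d:1"], 1L)
  expect_error(build_count_table(
    data.frame(sample_id = "ghost", label = "C3"), md), "ghost")
  # unassigned excluded from counts but tallied in QC
  asn2 <- rbind(asn, data.frame(sample_id = "s2", label = "unassigned"))
  ct2 <- build_count_table(asn2, md)
  expect_equal(sum(ct2$counts["s2", ]), 1L)
  expect_equal(attr(ct2, "qc")$unassigned, c(0L, 1L))
  # empty assignment set
  ct0 <- build_count_table(asn[0, ], md)
  expect_equal(dim(ct0$counts), c(2L, 0L))
})

test_that("taxonomy round trip on error-free reads recovers the truth", {
  db <- make_reference_db(n_per_clade = 3, seed = 5)
  md <- toy_metadata(c("s1", "s2"))
  rec <- db$records
  reads <- data.frame(read_id = paste0("r", seq_len(nrow(rec))),
                      sample_id = rep(c("s1", "s2"), length.out = nrow(rec)),
                      sequence = rec$sequence, stringsAsFactors = FALSE)
  asn <- assign_taxonomy(reads, db)
  expect_equal(asn$clade, rec$clade)
  # leaf recovery guaranteed only without a >= 97%-identical neighbor
  for (i in seq_len(nrow(rec))) {
    sel <- rec$clade == rec$clade[i] & rec$name != rec$name[i]
    if (!any(sel)) next
    nb <- max(symcomm:::.cpp_identity_batch(rec$sequence[i],
                                            rec$sequence[sel]))
    if (nb < 0.97) expect_equal(asn$label[i], rec$name[i])
  }
  ct <- build_count_table(asn, md)
  expect_equal(unname(rowSums(ct$counts) + attr(ct, "qc")$unassigned),
               as.vector(table(factor(reads$sample_id,
                                      levels = md$sample_id))))
})

test_that("label grammar parses and re-serializes identically", {
  labels <- c("C3", "C_i:52", "A_d:7", "unassigned")
  parsed <- parse_taxon_label(labels)
  expect_equal(parsed$kind, c("leaf", "internal", "denovo", "unassigned"))
  expect_equal(parsed$clade, c(NA, "C", "A", NA))
  expect_equal(parsed$label, labels)
})
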