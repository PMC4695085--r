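# Shared fixtures and independent brute-force oracles.

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute the bases at `pos` with a fixed different base
substitute_at <- function(seq, pos) {
  ch <- strsplit(seq, "")[[1]]
  ch[pos] <- vapply(ch[pos], function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                    "")
  paste(ch, collapse = "")
}

# A hand-built database: clade C is four leaves on the known topology
# ((C1,C2),(C3,C4)) with C1/C2 a close pair; one distant reference in each
# other clade. Internal preorder numbers: root = 1, (C1,C2) = 2,
# (C3,C4) = 3.
toy_db <- function(seed = 7) {
  set.seed(seed)
  base <- random_dna(330)
  c1 <- base
  c2 <- substitute_at(base, c(11, 52, 90, 130))      # 4 diffs from C1
  c34 <- substitute_at(base, seq(5, 300, by = 12))   # distant cousin pair
  c3 <- c34
  c4 <- substitute_at(c34, c(17, 61, 99, 140))
  others <- vapply(1:4, function(i) random_dna(330), "")
  seqs <- c(C1 = c1, C2 = c2, C3 = c3, C4 = c4,
            A1 = others[1], D1 = others[2], F1 = others[3], G1 = others[4])
  tree <- ape::read.tree(text = "((C1:0.01,C2:0.01):0.1,(C3:0.01,C4:0.01):0.1);")
  tree <- symcomm:::number_internal_nodes(tree)
  reference_db(seqs, c("C", "C", "C", "C", "A", "D", "F", "G"),
               trees = list(C = tree))
}

toy_metadata <- function(samples, pool = NULL, compartment = "water") {
  n <- length(samples)
  data.frame(sample_id = samples,
             pool = if (is.null(pool)) rep(c("300", "400"), length.out = n)
                    else pool,
             compartment = rep(compartment, length.out = n),
             species = NA_character_, latitude = NA_real_,
             longitude = NA_real_, depth = NA_real_,
             stringsAsFactors = FALSE)
}

# --- oracles -----------------------------------------------------------

# exhaustive suffix-window scan for the 3' quality trim point
oracle_quality_trim <- function(quals, q = 25, w = 10) {
  n <- length(quals)
  w <- min(w, n)
  for (i in n:w) if (mean(quals[(i - w + 1):i]) >= q) return(i)
  0L
}

# full-DP semi-global edit distance of a pattern inside a text
oracle_edit_locate <- function(pattern, text) {
  p <- strsplit(pattern, "")[[1]]; t <- strsplit(text, "")[[1]]
  m <- length(p); n <- length(t)
  D <- matrix(0L, m + 1, n + 1)
  D[, 1] <- 0:m
  for (i in 1:m) for (j in 1:n)
    D[i + 1, j + 1] <- min(D[i, j] + (p[i] != t[j]), D[i, j + 1] + 1L,
                           D[i + 1, j] + 1L)
  min(D[m + 1, ])
}

# Bray-Curtis from the definition, one pair at a time
oracle_bray <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in 1:n) for (j in 1:n)
    d[i, j] <- sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
  d
}

# one-way PERMANOVA F from per-group sums of squared dissimilarities
oracle_permanova_F <- function(d, groups) {
  m <- as.matrix(d)^2
  n <- nrow(m)
  ss_tot <- sum(m[lower.tri(m)]) / n
  ss_w <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ss_w <- ss_w + sum(m[idx, idx][lower.tri(m[idx, idx])]) / length(idx)
  }
  ss_b <- ss_tot - ss_w
  g <- length(unique(groups))
  (ss_b / (g - 1)) / (ss_w / (n - g))
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(1:n, function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# greedy centroid clustering straight from a precomputed identity matrix
oracle_greedy_clusters <- function(seqs, order_idx, threshold) {
  idm <- outer(seq_along(seqs), seq_along(seqs),
               Vectorize(function(i, j)
                 symcomm:::.cpp_global_identity(seqs[i], seqs[j])))
  centroids <- integer(0)
  assign <- integer(length(seqs))
  for (i in order_idx) {
    hit <- 0L
    for (k in seq_along(centroids))
      if (idm[i, centroids[k]] >= threshold) { hit <- k; break }
    if (hit == 0L) { centroids <- c(centroids, i); hit <- length(centroids) }
    assign[i] <- hit
  }
  assign
}
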