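#' Quality-trim a read's 3' end by running mean
#'
#' Scans trailing windows of `window` bases from the 3' end toward the 5'
#' end and truncates the read at the last position whose trailing window
#' mean is at least `q_threshold`; a read with no qualifying window is
#' emptied. Reads shorter than the window are judged on their full length.
#'
#' @param sequence Read sequence.
#' @param qualities Integer Phred scores, one per base (NULL skips trimming
#'   with a warning).
#' @param q_threshold Minimum acceptable running mean (Phred), default 25.
#' @param window Window length in bases, default 10.
#' @return List with trimmed `sequence` and `qualities`.
#' @export
quality_trim <- function(sequence, qualities, q_threshold = 25, window = 10) {
  n <- nchar(sequence)
  if (is.null(qualities)) {
    warning("read has no qualities; quality trimming skipped")
    return(list(sequence = sequence, qualities = NULL))
  }
  stopifnot(length(qualities) == n)
  if (n == 0) return(list(sequence = "", qualities = integer(0)))
  w <- min(window, n)
  cs <- c(0, cumsum(qualities))
  # trailing mean of the window ending at position i (i >= w)
  keep <- 0L
  for (i in n:w) {
    if ((cs[i + 1] - cs[i + 1 - w]) / w >= q_threshold) { keep <- i; break }
  }
  if (keep == 0L && w < window) keep <- if (mean(qualities) >= q_threshold) n else 0L
  list(sequence = substr(sequence, 1, keep),
       qualities = qualities[seq_len(keep)])
}

#' Homopolymer filter
#'
#' @param sequence Read sequence.
#' @param max_run Longest tolerated single-base run; reads with a run
#'   exceeding it are discarded (default 6).
#' @return TRUE to keep the read, FALSE to discard.
#' @export
filter_homopolymer <- function(sequence, max_run = 6) {
  if (!nzchar(sequence)) return(TRUE)
  runs <- rle(strsplit(sequence, "")[[1]])$lengths
  max(runs) <= max_run
}

iupac_revcomp <- function(x) {
  comp <- chartr("ACGTURYSWKMBDHVNacgturyswkmbdhvn",
                 "TGCAAYRSWMKVHDBNtgcaayrswmkvhdbn", x)
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""), "")
}

#' Locate and trim PCR primers
#'
#' The forward primer is searched semi-globally (IUPAC-aware, unit-cost
#' edits); reads without a forward match within `max_errors` are rejected.
#' The reverse primer is searched as its reverse complement near the 3'
#' end; when absent the read is trimmed on the forward side only. Matched
#' spans (and bases outside them) are removed.
#'
#' @param sequence Read sequence.
#' @param forward,reverse Primer sequences (5'->3', IUPAC codes allowed).
#' @param max_errors Maximum edit distance per primer (default 3).
#' @return The trimmed insert sequence, or NA if the forward primer is
#'   absent.
#' @export
trim_primers <- function(sequence, forward, reverse = NULL, max_errors = 3) {
  if (!nzchar(sequence)) return(NA_character_)
  fh <- .cpp_locate_primer(forward, sequence)
  if (fh$distance > max_errors) return(NA_character_)
  out <- substr(sequence, fh$end + 1, nchar(sequence))
  if (!is.null(reverse) && nzchar(out)) {
    rh <- .cpp_locate_primer(iupac_revcomp(reverse), out)
    if (rh$distance <= max_errors) out <- substr(out, 1, rh$start - 1)
  }
  out
}

#' Run the full read-level QC chain on a set of reads
#'
#' Quality trimming (when qualities are present), homopolymer filtering,
#' and primer trimming, with per-sample accounting of discarded reads.
#'
#' @param reads Data.frame with columns `read_id`, `sample_id`, `sequence`.
#' @param qualities Optional named list of Phred vectors by read id.
#' @param forward,reverse Optional primer sequences.
#' @param q_threshold,window,max_errors QC parameters.
#' @param min_length Minimum surviving insert length (default 50).
#' @return `reads` restricted to surviving reads with trimmed sequences;
#'   attribute `qc` tabulates per-sample input/surviving counts.
#' @export
qc_reads <- function(reads, qualities = NULL, forward = NULL, reverse = NULL,
                     q_threshold = 25, window = 10, max_errors = 3,
                     min_length = 50) {
  stopifnot(all(c("read_id", "sample_id", "sequence") %in% names(reads)))
  n_in <- table(reads$sample_id)
  seqs <- reads$sequence
  if (!is.null(qualities)) {
    for (i in seq_len(nrow(reads))) {
      q <- qualities[[reads$read_id[i]]]
      if (!is.null(q))
        seqs[i] <- quality_trim(seqs[i], q, q_threshold, window)$sequence
    }
  }
  keep_hp <- vapply(seqs, filter_homopolymer, TRUE, USE.NAMES = FALSE)
  if (!is.null(forward)) {
    seqs <- vapply(seqs, function(s)
      if (nzchar(s)) trim_primers(s, forward, reverse, max_errors)
      else NA_character_, "", USE.NAMES = FALSE)
  }
  keep <- keep_hp & !is.na(seqs) & nchar(ifelse(is.na(seqs), "", seqs)) >= min_length
  out <- reads[keep, , drop = FALSE]
  out$sequence <- seqs[keep]
  n_out <- table(factor(out$sample_id, levels = names(n_in)))
  attr(out, "qc") <- data.frame(sample_id = names(n_in),
                                reads_in = as.integer(n_in),
                                reads_surviving = as.integer(n_out),
                                stringsAsFactors = FALSE)
  out
}

# Karlin-Altschul parameters for the default local-alignment scoring
# (match +1, mismatch -2, gap open -5, gap extend -2), fitted once by
# moment-matching a Gumbel to maximal local scores of random reads
# against shuffled reference sets (see calibrate_evalue()).
KA_DEFAULT <- list(lambda = 1.23, K = 0.06)

#' E-value of a local alignment score
#'
#' Karlin-Altschul statistics: `E = K * m * n * exp(-lambda * S)` for query
#' length `m` against a search space of total length `n`.
#'
#' @param score Raw local alignment score(s).
#' @param m Query length.
#' @param n Total reference length searched.
#' @param ka List with `lambda` and `K`.
#' @return E-value(s).
#' @export
evalue <- function(score, m, n, ka = KA_DEFAULT) {
  ka$K * m * n * exp(-ka$lambda * score)
}

#' Calibrate Karlin-Altschul parameters on shuffled-sequence nulls
#'
#' Draws random reads, records their maximal local score against the
#' reference set, and fits a Gumbel by the method of moments
#' (`lambda = pi / (sd * sqrt(6))`, `K = exp(lambda * mu) / (m * n)`).
#'
#' @param db A `ref_db`.
#' @param n_reads Number of null reads.
#' @param read_length Null read length.
#' @param seed RNG seed.
#' @return List with `lambda` and `K`.
#' @export
calibrate_evalue <- function(db, n_reads = 200, read_length = 330, seed = 1) {
  set.seed(seed)
  refs <- db$records$sequence
  ntot <- sum(nchar(refs))
  smax <- vapply(seq_len(n_reads), function(i) {
    rd <- paste(sample(c("A", "C", "G", "T"), read_length, replace = TRUE),
                collapse = "")
    max(.cpp_sw_score_batch(rd, refs))
  }, 0)
  lambda <- pi / (sd(smax) * sqrt(6))
  mu <- mean(smax) - 0.5772156649 / lambda
  list(lambda = lambda, K = exp(lambda * mu) / (read_length * ntot))
}

#' Assign a read to a Symbiodinium clade
#'
#' Scores the read by local alignment against every reference of each
#' clade, converts best scores to e-values, and assigns the best clade
#' only when its e-value passes `e_cutoff` and is at least
#' `1/ratio_cutoff`-fold stronger than the next best clade (a database
#' with hits in a single clade satisfies the ratio rule trivially).
#'
#' @param sequence Read sequence.
#' @param db A `ref_db`.
#' @param e_cutoff Clade-level e-value cutoff (default 1e-20).
#' @param ratio_cutoff Maximum allowed `best_e / next_best_e`
#'   (default 1e-5).
#' @param ka Karlin-Altschul parameters.
#' @return List with `clade` (NA when unassigned), `e_value`, and the
#'   per-clade best e-values `by_clade`.
#' @export
assign_clade <- function(sequence, db, e_cutoff = 1e-20, ratio_cutoff = 1e-5,
                         ka = KA_DEFAULT) {
  if (!nzchar(sequence))
    return(list(clade = NA_character_, e_value = NA_real_, by_clade = NULL))
  rec <- db$records
  scores <- .cpp_sw_score_batch(sequence, rec$sequence)
  m <- nchar(sequence)
  clades <- sort(unique(rec$clade))
  best_e <- vapply(clades, function(cl) {
    sel <- rec$clade == cl
    evalue(max(scores[sel]), m, sum(nchar(rec$sequence[sel])), ka)
  }, 0)
  ord <- order(best_e)
  top <- best_e[ord[1]]
  if (top > e_cutoff)
    return(list(clade = NA_character_, e_value = top, by_clade = best_e))
  if (length(best_e) > 1) {
    ratio <- top / best_e[ord[2]]
    if (!(ratio <= ratio_cutoff))
      return(list(clade = NA_character_, e_value = top, by_clade = best_e))
  }
  list(clade = clades[ord[1]], e_value = top, by_clade = best_e)
}

#' Assign a clade-classified read to the subtype level
#'
#' Local alignment against the references of the read's clade; qualifying
#' hits need `e <= e_cutoff`, identity above `min_identity` (matches over
#' alignment columns, gaps counted), and alignment span covering more
#' than `min_ref_coverage` of the reference length. A unique best hit
#' yields that leaf; ties (scores equal within 1e-9 relative tolerance
#' and identities equal to 4 decimals) are placed at the lowest common
#' ancestor of the tied leaves on the clade guide tree; no qualifying hit
#' marks the read "new" for de novo clustering.
#'
#' @param sequence Read sequence.
#' @param clade Clade from [assign_clade()].
#' @param db A `ref_db`.
#' @param e_cutoff,min_identity,min_ref_coverage Assignment thresholds.
#' @param ka Karlin-Altschul parameters.
#' @return List with `kind` ("leaf", "internal", or "new"), `label`,
#'   `identity`, and `e_value`.
#' @export
assign_subtype <- function(sequence, clade, db, e_cutoff = 1e-20,
                           min_identity = 0.97, min_ref_coverage = 0.90,
                           ka = KA_DEFAULT) {
  rec <- db$records[db$records$clade == clade, , drop = FALSE]
  if (!nrow(rec)) stop("clade ", clade, " absent from reference database")
  hits <- .cpp_sw_batch(sequence, rec$sequence)
  e <- evalue(hits[, "score"], nchar(sequence), sum(nchar(rec$sequence)), ka)
  ok <- e <= e_cutoff & hits[, "identity"] > min_identity &
    hits[, "ref_coverage"] > min_ref_coverage
  if (!any(ok))
    return(list(kind = "new", label = NA_character_,
                identity = max(hits[, "identity"]), e_value = min(e)))
  sc <- hits[, "score"]
  top <- max(sc[ok])
  tied <- ok & abs(sc - top) <= 1e-9 * max(1, abs(top)) &
    round(hits[, "identity"], 4) == round(max(hits[ok & abs(sc - top) <=
      1e-9 * max(1, abs(top)), "identity"]), 4)
  tied_names <- rec$name[tied]
  if (length(tied_names) == 1)
    return(list(kind = "leaf", label = tied_names,
                identity = hits[tied, "identity"], e_value = e[tied]))
  node <- lca_node(db$trees[[clade]], tied_names)
  list(kind = "internal", label = sprintf("%s_i:%d", clade, node),
       identity = max(hits[tied, "identity"]), e_value = min(e[tied]))
}

#' Greedy de novo clustering of novel reads at 97% identity
#'
#' Within each clade, unique sequences are processed in decreasing
#' abundance (ties broken by the lexicographically smallest read id); a
#' sequence joins the earliest-founded centroid with global identity at
#' least `identity_threshold`, otherwise it founds the next cluster.
#' Clusters are numbered in founding order from 1.
#'
#' @param reads Data.frame with columns `read_id`, `sequence`, `clade`.
#' @param identity_threshold Global identity threshold (default 0.97).
#' @return Data.frame `read_id`, `label` (`<clade>_d:<cluster>`).
#' @export
cluster_denovo <- function(reads, identity_threshold = 0.97) {
  stopifnot(all(c("read_id", "sequence", "clade") %in% names(reads)))
  out <- data.frame(read_id = character(0), label = character(0),
                    stringsAsFactors = FALSE)
  for (cl in sort(unique(reads$clade))) {
    sub <- reads[reads$clade == cl, , drop = FALSE]
    groups <- split(sub$read_id, sub$sequence)
    uniq <- data.frame(sequence = names(groups),
                       abundance = lengths(groups),
                       min_id = vapply(groups, function(x) min(sort(x)), ""),
                       stringsAsFactors = FALSE)
    uniq <- uniq[order(-uniq$abundance, uniq$min_id), , drop = FALSE]
    centroids <- character(0)
    assignment <- integer(nrow(uniq))
    for (i in seq_len(nrow(uniq))) {
      hit <- 0L
      if (length(centroids)) {
        ids <- .cpp_identity_batch(uniq$sequence[i], centroids)
        j <- which(ids >= identity_threshold)
        if (length(j)) hit <- j[1]
      }
      if (hit == 0L) {
        centroids <- c(centroids, uniq$sequence[i])
        hit <- length(centroids)
      }
      assignment[i] <- hit
    }
    for (i in seq_len(nrow(uniq))) {
      ids <- groups[[uniq$sequence[i]]]
      out <- rbind(out, data.frame(
        read_id = ids,
        label = sprintf("%s_d:%d", cl, assignment[i]),
        stringsAsFactors = FALSE))
    }
  }
  out[match(reads$read_id, out$read_id), , drop = FALSE]
}

#' Assign taxonomy to a set of reads
#'
#' Orchestrates clade assignment, subtype assignment with LCA placement,
#' and de novo clustering of novel sequences. Identical sequences are
#' assigned once and the result broadcast to all copies.
#'
#' @param reads Data.frame with `read_id`, `sample_id`, `sequence`.
#' @param db A `ref_db`.
#' @param config A `sym_config` (thresholds; see [default_config()]).
#' @param ka Karlin-Altschul parameters.
#' @return Data.frame `read_id`, `sample_id`, `label`, `kind`, `clade`,
#'   `evalue`, `identity`; unassigned reads carry label "unassigned".
#' @export
assign_taxonomy <- function(reads, db, config = default_config(),
                            ka = KA_DEFAULT) {
  stopifnot(all(c("read_id", "sample_id", "sequence") %in% names(reads)))
  useq <- unique(reads$sequence)
  res <- data.frame(sequence = useq, label = NA_character_,
                    kind = "unassigned", clade = NA_character_,
                    evalue = NA_real_, identity = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(useq)) {
    cl <- assign_clade(useq[i], db, config$e_cutoff, config$ratio_cutoff, ka)
    res$evalue[i] <- cl$e_value
    if (is.na(cl$clade)) next
    res$clade[i] <- cl$clade
    st <- assign_subtype(useq[i], cl$clade, db, config$e_cutoff,
                         config$min_identity, config$min_ref_coverage, ka)
    res$kind[i] <- st$kind
    res$label[i] <- st$label
    res$identity[i] <- st$identity
    res$evalue[i] <- min(cl$e_value, st$e_value)
  }
  new <- which(res$kind == "new")
  if (length(new)) {
    dn <- cluster_denovo(data.frame(read_id = as.character(new),
                                    sequence = res$sequence[new],
                                    clade = res$clade[new],
                                    stringsAsFactors = FALSE),
                         config$cluster_identity)
    res$label[new] <- dn$label
    res$kind[new] <- "denovo"
  }
  res$label[res$kind == "unassigned"] <- "unassigned"
  i <- match(reads$sequence, res$sequence)
  data.frame(read_id = reads$read_id, sample_id = reads$sample_id,
             label = res$label[i], kind = res$kind[i], clade = res$clade[i],
             evalue = res$evalue[i], identity = res$identity[i],
             stringsAsFactors = FALSE)
}

#' Merge per-read assignments into a sample-by-taxon count table
#'
#' Unassigned reads are excluded from the table but tallied in the
#' attached QC report.
#'
#' @param assignments Data.frame with `sample_id` and `label` per read.
#' @param metadata Metadata data.frame covering every sample.
#' @return A `sym_counts` object; attribute `qc` holds per-sample
#'   assigned/unassigned totals.
#' @export
build_count_table <- function(assignments, metadata) {
  metadata <- validate_metadata(metadata)
  missing <- setdiff(unique(assignments$sample_id), metadata$sample_id)
  if (length(missing))
    stop("samples in assignments missing from metadata: ",
         paste(missing, collapse = ", "))
  samples <- metadata$sample_id
  unas <- assignments$label == "unassigned"
  qc <- data.frame(
    sample_id = samples,
    assigned = as.integer(table(factor(assignments$sample_id[!unas],
                                       levels = samples))),
    unassigned = as.integer(table(factor(assignments$sample_id[unas],
                                         levels = samples))),
    stringsAsFactors = FALSE)
  kept <- assignments[!unas, , drop = FALSE]
  taxa <- sort(unique(kept$label))
  m <- matrix(0L, length(samples), length(taxa),
              dimnames = list(samples, taxa))
  if (nrow(kept)) {
    tab <- table(factor(kept$sample_id, levels = samples),
                 factor(kept$label, levels = taxa))
    m[] <- as.integer(tab)
  }
  out <- count_table(m, metadata)
  attr(out, "qc") <- qc
  out
}
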