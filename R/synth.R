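rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

mutate_bases <- function(chars, rate) {
  hit <- which(runif(length(chars)) < rate)
  if (length(hit)) {
    for (i in hit) {
      alt <- setdiff(c("A", "C", "G", "T"), chars[i])
      chars[i] <- alt[sample.int(3, 1)]
    }
  }
  chars
}

#' Simulate a clade-structured ITS2 reference database
#'
#' Evolves an ITS2-like root sequence into five clade ancestors and then
#' into leaf references along a random coalescent tree per clade, under a
#' simple substitution process. The generating trees double as guide
#' trees (internal nodes numbered in preorder), so LCA placements can be
#' scored against the truth.
#'
#' @param n_per_clade References per clade (recycled over A/C/D/F/G).
#' @param within_clade_divergence Expected substitutions per site from
#'   clade ancestor to leaf.
#' @param between_clade_divergence Expected substitutions per site from
#'   root to clade ancestor; must exceed the within-clade divergence.
#' @param root_length Root sequence length (default 330 nt).
#' @param seed RNG seed; identical seeds give identical databases.
#' @return A `ref_db`; attribute `truth` holds the root, ancestors, and
#'   generating trees.
#' @export
make_reference_db <- function(n_per_clade = 4, within_clade_divergence = 0.05,
                              between_clade_divergence = 0.3,
                              root_length = 330, seed = 1) {
  stopifnot(between_clade_divergence > within_clade_divergence,
            between_clade_divergence > 0, between_clade_divergence < 1,
            within_clade_divergence >= 0, within_clade_divergence < 1)
  set.seed(seed)
  n_per_clade <- rep(n_per_clade, length.out = length(CLADES))
  root <- sample(c("A", "C", "G", "T"), root_length, replace = TRUE)
  seqs <- character(0); clades <- character(0); trees <- list()
  ancestors <- list()
  for (ci in seq_along(CLADES)) {
    cl <- CLADES[ci]
    anc <- mutate_bases(root, between_clade_divergence)
    ancestors[[cl]] <- paste(anc, collapse = "")
    n <- n_per_clade[ci]
    nm <- paste0(cl, seq_len(n))
    if (n == 1) {
      leaf_seqs <- setNames(paste(mutate_bases(anc, within_clade_divergence),
                                  collapse = ""), nm)
    } else {
      tr <- ape::rcoal(n, tip.label = nm)
      depth <- max(ape::node.depth.edgelength(tr))
      if (depth > 0 && within_clade_divergence > 0)
        tr$edge.length <- tr$edge.length * within_clade_divergence / depth
      else tr$edge.length[] <- 0
      # evolve down the tree: node sequences indexed by ape node number
      tr <- ape::reorder.phylo(tr, "cladewise")
      node_seq <- vector("list", n + tr$Nnode)
      node_seq[[n + 1]] <- anc
      for (e in seq_len(nrow(tr$edge))) {
        from <- tr$edge[e, 1]; to <- tr$edge[e, 2]
        node_seq[[to]] <- mutate_bases(node_seq[[from]],
                                       min(1, tr$edge.length[e]))
      }
      leaf_seqs <- setNames(vapply(seq_len(n), function(i)
        paste(node_seq[[i]], collapse = ""), ""), tr$tip.label)[nm]
      trees[[cl]] <- number_internal_nodes(tr)
    }
    seqs <- c(seqs, leaf_seqs)
    clades <- c(clades, rep(cl, n))
  }
  db <- reference_db(seqs, clades,
                     trees = if (length(trees)) trees else NULL)
  attr(db, "truth") <- list(root = paste(root, collapse = ""),
                            ancestors = ancestors, trees = trees,
                            seed = seed)
  db
}

#' Default survey design of the two-pool study system
#'
#' Two backreef pools (300: highly variable, 400: moderately variable)
#' sampled in three habitat compartments: water along three shore-
#' parallel transects (n = 28 and 30), sediment scattered through each
#' pool (n = 30 each), and ten coral species (5 colonies per species per
#' pool). GPS coordinates are laid out over realistic pool extents
#' (roughly 100 x 40 m) near Ofu Island, American Samoa (UTM zone 2S).
#'
#' @param seed RNG seed for the sample positions.
#' @return A metadata data.frame ready for [simulate_community()].
#' @export
default_design <- function(seed = 1) {
  set.seed(seed)
  species <- c("Psammocora contigua", "Porites mound", "Porites annae",
               "Pocillopora damicornis", "Pavona venosa", "Leptoria phrygia",
               "Goniastrea retiformis", "Favia matthaii",
               "Acropora pagoensis", "Acropora austera")
  rows <- list()
  mk <- function(n, pool, compartment, sp = NA_character_) {
    data.frame(pool = pool, compartment = compartment, species = sp,
               n = n, stringsAsFactors = FALSE)
  }
  design <- rbind(mk(28, "300", "water"), mk(30, "400", "water"),
                  mk(30, "300", "sediment"), mk(30, "400", "sediment"),
                  do.call(rbind, lapply(species, function(s)
                    rbind(mk(5, "300", "coral", s), mk(5, "400", "coral", s)))))
  # pool centres ~400 m apart along shore; local extents ~100 x 40 m
  centre <- list(`300` = c(-169.6600, -14.1840), `400` = c(-169.6560, -14.1835))
  out <- list()
  for (i in seq_len(nrow(design))) {
    n <- design$n[i]; pool <- design$pool[i]; comp <- design$compartment[i]
    cx <- centre[[pool]][1]; cy <- centre[[pool]][2]
    mdeg_x <- 1 / (111320 * cos(cy * pi / 180)) # meters -> degrees lon
    mdeg_y <- 1 / 110574
    if (comp == "water") {
      # three transects parallel to shore at increasing distance
      per <- ceiling(n / 3)
      tx <- rep(seq(-45, 45, length.out = per), 3)[seq_len(n)]
      ty <- rep(c(-15, 0, 15), each = per)[seq_len(n)]
    } else {
      tx <- runif(n, -50, 50)
      ty <- runif(n, -18, 18)
    }
    out[[i]] <- data.frame(
      pool = pool, compartment = comp, species = design$species[i],
      longitude = cx + tx * mdeg_x, latitude = cy + ty * mdeg_y,
      depth = round(runif(n, 0.3, 2), 1), stringsAsFactors = FALSE)
  }
  md <- do.call(rbind, out)
  tag <- ifelse(md$compartment == "coral",
                paste0("c", as.integer(factor(md$species))),
                substr(md$compartment, 1, 1))
  md$sample_id <- paste0(tag, md$pool, "_",
                         stats::ave(seq_len(nrow(md)),
                                    paste(tag, md$pool), FUN = seq_along))
  md[, c("sample_id", "pool", "compartment", "species",
         "latitude", "longitude", "depth")]
}

#' Default synthetic scenario
#'
#' Couples the survey design with compartment-level clade mixtures
#' (water dominated by C and A; sediment by C, A, and D; coral by C and
#' D), within-clade Dirichlet spread over the reference taxa, planted
#' between-pool fold-changes (including a hundredfold clade-D increase in
#' pool 300 corals and moderate shifts in water and sediment), a
#' cross-shore spatial gradient favouring clade A inshore in water, and
#' the log-normal library-size distribution (geometric mean 1011,
#' geometric sd 3.8).
#'
#' @param db A `ref_db` whose leaves are the simulated taxa.
#' @param seed RNG seed (controls the within-clade mixture draw and
#'   sample positions).
#' @return List with `design`, `base_mixture`, `fold_changes`,
#'   `gradient`, `depth_params`.
#' @export
default_scenario <- function(db, seed = 1) {
  set.seed(seed)
  rec <- db$records
  clade_mix <- list(
    water = c(A = 0.20, C = 0.72, D = 0.02, F = 0.04, G = 0.02),
    sediment = c(A = 0.17, C = 0.62, D = 0.15, F = 0.04, G = 0.02),
    coral = c(A = 0.045, C = 0.85, D = 0.10, F = 0.004, G = 0.001))
  base_mixture <- lapply(clade_mix, function(mix) {
    p <- numeric(nrow(rec)); names(p) <- rec$name
    for (cl in names(mix)) {
      sel <- rec$clade == cl
      if (any(sel)) p[sel] <- mix[[cl]] * rdirichlet1(rep(2, sum(sel)))
    }
    p / sum(p)
  })
  taxon_of <- function(cl, k = 1) rec$name[rec$clade == cl][k]
  # the hundredfold taxon must be rare at baseline or renormalization caps
  # the realized fold at 1/p; mirror a rare thermotolerant clade-D type
  d100 <- taxon_of("D")
  for (comp in names(base_mixture)) {
    base_mixture[[comp]][d100] <- 8e-4
    base_mixture[[comp]] <- base_mixture[[comp]] / sum(base_mixture[[comp]])
  }
  # pool-300 effects: hundredfold clade-D rise, dominant C type declines,
  # a second C type and two A types shift moderately in either direction
  fold_changes <- c(100, 0.25, 4, 3, 0.5)
  names(fold_changes) <- c(d100, taxon_of("C"), taxon_of("C", 2),
                           taxon_of("A"), taxon_of("A", 2))
  gradient <- setNames(rep(0.03, sum(rec$clade == "A")),
                       rec$name[rec$clade == "A"])
  design <- default_design(seed)
  list(design = design, base_mixture = base_mixture,
       fold_changes = fold_changes, gradient = gradient,
       depth_params = list(geomean = 1011, gsd = 3.8))
}

#' Simulate a truth-known community count table
#'
#' Per sample, true proportions are the compartment base mixture times
#' the pool-300 fold-changes (pool 300 only) times `exp(slope * x)` for
#' taxa with a planted cross-shore gradient (`x` is the centered
#' projected easting within the pool, in meters), renormalized. Library
#' size is log-normal and counts are multinomial.
#'
#' @param design Metadata data.frame (see [default_design()]).
#' @param base_mixture Named list compartment -> taxon proportion vector.
#' @param fold_changes Named vector, taxon -> multiplicative pool-300
#'   effect (default none).
#' @param gradient Named vector, taxon -> slope per meter (default none).
#' @param depth_params List with `geomean` and `gsd` of library size.
#' @param seed RNG seed.
#' @return A `sym_counts`; attribute `truth` holds the per-sample true
#'   proportions, depths, and planted parameters.
#' @export
simulate_community <- function(design, base_mixture, fold_changes = NULL,
                               gradient = NULL,
                               depth_params = list(geomean = 1011, gsd = 3.8),
                               seed = 1) {
  set.seed(seed)
  taxa <- names(base_mixture[[1]])
  stopifnot(all(vapply(base_mixture, function(p)
    isTRUE(all.equal(sum(p), 1)) && all(p >= 0), TRUE)))
  n <- nrow(design)
  # centered cross-shore coordinate within each pool for the gradient
  xpos <- numeric(n)
  if (!is.null(gradient) && !all(is.na(design$longitude))) {
    pos <- suppressWarnings(
      project_positions(design$latitude, design$longitude, design$sample_id))
    i <- match(pos$sample_id, design$sample_id)
    for (pl in unique(design$pool[i]))
      xpos[i][design$pool[i] == pl] <-
        pos$x[design$pool[i] == pl] - mean(pos$x[design$pool[i] == pl])
  }
  prop <- matrix(0, n, length(taxa), dimnames = list(design$sample_id, taxa))
  for (s in seq_len(n)) {
    p <- base_mixture[[design$compartment[s]]][taxa]
    if (!is.null(fold_changes) && design$pool[s] == "300")
      p[names(fold_changes)] <- p[names(fold_changes)] * fold_changes
    if (!is.null(gradient))
      p[names(gradient)] <- p[names(gradient)] * exp(gradient * xpos[s])
    prop[s, ] <- p / sum(p)
  }
  depth <- pmax(1, round(rlnorm(n, log(depth_params$geomean),
                                log(depth_params$gsd))))
  counts <- t(vapply(seq_len(n), function(s)
    rmultinom(1, depth[s], prop[s, ])[, 1], integer(length(taxa))))
  dimnames(counts) <- dimnames(prop)
  out <- count_table(counts, design)
  attr(out, "truth") <- list(proportions = prop, depths = depth,
                             fold_changes = fold_changes,
                             gradient = gradient, xpos = xpos, seed = seed)
  out
}

#' Simulate reads from a count table
#'
#' Emits `counts[s, t]` copies of each taxon's source sequence per
#' sample, with independent substitution errors at `error_rate` (and
#' optional insertion/deletion errors at `indel_rate`, which produce the
#' homopolymer artifacts the QC filter targets). Primer sequences can be
#' attached to exercise primer trimming.
#'
#' @param x A `sym_counts` whose taxa are reference leaf names (or
#'   entries of `novel_seqs`).
#' @param db A `ref_db`.
#' @param error_rate Per-base substitution probability (default 0.005).
#' @param indel_rate Per-base insertion/deletion probability (default 0).
#' @param novel_seqs Optional named sequences for taxa absent from the
#'   database (to exercise de novo clustering).
#' @param primers Optional list(forward=, reverse=) appended around each
#'   read.
#' @param seed RNG seed.
#' @return Data.frame `read_id`, `sample_id`, `sequence`; attribute
#'   `truth` maps read id to the source taxon.
#' @export
simulate_reads <- function(x, db, error_rate = 0.005, indel_rate = 0,
                           novel_seqs = NULL, primers = NULL, seed = 1) {
  set.seed(seed)
  counts <- x$counts
  src <- setNames(db$records$sequence, db$records$name)
  if (!is.null(novel_seqs)) src <- c(src, novel_seqs)
  missing <- setdiff(colnames(counts), names(src))
  if (length(missing))
    stop("taxa without a source sequence: ", paste(missing, collapse = ", "))
  out <- vector("list", sum(counts > 0))
  k <- 0L
  bases <- c("A", "C", "G", "T")
  for (s in rownames(counts)) for (t in colnames(counts)[counts[s, ] > 0]) {
    nread <- counts[s, t]
    tmpl <- strsplit(src[[t]], "")[[1]]
    len <- length(tmpl)
    m <- matrix(rep(tmpl, nread), nrow = nread, byrow = TRUE)
    hit <- which(matrix(runif(nread * len) < error_rate, nread, len))
    if (length(hit)) {
      cur <- m[hit]
      sub <- bases[(match(cur, bases) - 1 + sample.int(3, length(hit),
                                                       replace = TRUE)) %% 4 + 1]
      m[hit] <- sub
    }
    seqs <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
    if (indel_rate > 0) {
      seqs <- vapply(seqs, function(sq) {
        ch <- strsplit(sq, "")[[1]]
        ins <- runif(length(ch)) < indel_rate
        del <- runif(length(ch)) < indel_rate
        ch <- ch[!del | ins] # deletion unless also duplicated
        paste(rep(ch, times = 1 + ins[!del | ins]), collapse = "")
      }, "", USE.NAMES = FALSE)
    }
    k <- k + 1L
    out[[k]] <- data.frame(
      sample_id = s, taxon = t, sequence = seqs, stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, out[seq_len(k)])
  reads$read_id <- sprintf("r%07d", seq_len(nrow(reads)))
  if (!is.null(primers))
    reads$sequence <- paste0(primers$forward, reads$sequence,
                             iupac_revcomp(primers$reverse))
  truth <- data.frame(read_id = reads$read_id, taxon = reads$taxon,
                      stringsAsFactors = FALSE)
  reads <- reads[, c("read_id", "sample_id", "sequence")]
  attr(reads, "truth") <- truth
  reads
}
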