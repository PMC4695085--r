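#' Square-root transformed relative abundances
#'
#' Each sample's counts are divided by its total and square-root
#' transformed (Hellinger-style), so that squared entries sum to one per
#' sample; this balances the influence of dominant and rare taxa in
#' downstream Bray-Curtis dissimilarities.
#'
#' @param x A `sym_counts` object or count matrix (samples in rows).
#' @return Numeric matrix of transformed relative abundances; zero-sum
#'   samples are dropped with a warning.
#' @export
sqrt_relative <- function(x) {
  m <- if (inherits(x, "sym_counts")) x$counts else as.matrix(x)
  rs <- rowSums(m)
  if (any(rs == 0)) {
    warning("dropping zero-sum sample(s): ",
            paste(rownames(m)[rs == 0], collapse = ", "))
    m <- m[rs > 0, , drop = FALSE]
    rs <- rs[rs > 0]
  }
  sqrt(sweep(m, 1, rs, "/"))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(u, v) = sum |u - v| / sum (u + v)` between sample rows.
#'
#' @param x Non-negative matrix with samples in rows (typically the output
#'   of [sqrt_relative()]).
#' @return A `dist` object with sample labels.
#' @export
bray_curtis <- function(x) {
  m <- as.matrix(x)
  if (any(m < 0)) stop("abundances must be non-negative")
  if (sum(rowSums(m) == 0) > 1)
    stop("Bray-Curtis undefined between all-zero samples")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    num <- colSums(abs(t(m[(i + 1):n, , drop = FALSE]) - m[i, ]))
    den <- colSums(t(m[(i + 1):n, , drop = FALSE]) + m[i, ])
    d[(i + 1):n, i] <- d[i, (i + 1):n] <- num / den
  }
  as.dist(d)
}

#' Overall, within-group, and between-group mean dissimilarities
#'
#' `overall` averages every unordered sample pair; `within` is the
#' pair-count-weighted average of per-group means (groups of size one
#' contribute no pairs); `between` averages all cross-group pairs.
#'
#' @param d A `dist` or symmetric matrix.
#' @param groups Grouping vector aligned with the rows of `d`.
#' @return List with `overall`, `within`, and `between` (NA with a single
#'   group).
#' @export
group_mean_dissimilarity <- function(d, groups) {
  m <- as.matrix(d)
  n <- nrow(m)
  stopifnot(length(groups) == n)
  lt <- lower.tri(m)
  same <- outer(groups, groups, "==")[lt]
  vals <- m[lt]
  list(overall = mean(vals),
       within = if (any(same)) mean(vals[same]) else NA_real_,
       between = if (any(!same)) mean(vals[!same]) else NA_real_)
}

# Gower-centered matrix of -d^2/2; tr of its projections partitions SS.
gower_center <- function(d) {
  a <- -0.5 * as.matrix(d)^2
  n <- nrow(a)
  j <- diag(n) - 1 / n
  j %*% a %*% j
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the total sum of squares of a dissimilarity matrix by one
#' factor or two crossed factors with interaction, using sequential
#' (Type I) sums of squares on the Gower-centered matrix of `-d^2/2`.
#' P-values come from free permutation of sample labels with the usual
#' `(exceedances + 1) / (n_perm + 1)` correction.
#'
#' @param d A `dist` or symmetric dissimilarity matrix.
#' @param formula Right-hand-side formula over `data` columns, e.g.
#'   `~ pool` or `~ compartment * pool`.
#' @param data Data.frame of sample factors aligned with `d`.
#' @param n_perm Number of permutations (default 9999).
#' @param seed RNG seed for the permutations.
#' @param permutations Optional explicit permutation matrix (rows are
#'   permutations of `1:n`); overrides `n_perm`/`seed`, enabling exhaustive
#'   enumeration on tiny designs.
#' @return Data.frame of class `sym_permanova` with per-term df, SS,
#'   pseudo-F, R2, and permutation p-values, plus Residual and Total rows.
#' @export
permanova <- function(d, formula, data, n_perm = 9999, seed = 1,
                      permutations = NULL) {
  m <- as.matrix(d)
  n <- nrow(m)
  stopifnot(nrow(data) == n)
  tl <- attr(stats::terms(formula), "term.labels")
  if (!length(tl)) stop("formula must contain at least one factor")
  for (v in all.vars(formula)) {
    data[[v]] <- factor(data[[v]])
    if (nlevels(data[[v]]) < 2)
      stop("factor '", v, "' has a single level")
  }
  g <- gower_center(m)
  ss_total <- sum(diag(g))
  # cumulative orthonormal bases for intercept + terms 1..k
  qs <- vector("list", length(tl))
  rank0 <- 1L
  dfs <- integer(length(tl))
  for (k in seq_along(tl)) {
    mm <- stats::model.matrix(stats::as.formula(paste("~", paste(tl[seq_len(k)],
                                                                 collapse = "+"))),
                              data)
    qr_k <- qr(mm)
    qs[[k]] <- qr.Q(qr_k)[, seq_len(qr_k$rank), drop = FALSE]
    dfs[k] <- qr_k$rank - rank0
    rank0 <- qr_k$rank
  }
  df_res <- n - rank0
  stat <- function(gp) {
    tr <- vapply(qs, function(q) sum(q * (gp %*% q)), 0)
    # the intercept projection of the centered matrix contributes zero
    ss <- diff(c(0, tr))
    ss_res <- sum(diag(gp)) - tr[length(tr)]
    list(ss = ss, ss_res = ss_res,
         f = (ss / dfs) / (ss_res / df_res))
  }
  obs <- stat(g)
  if (is.null(permutations)) {
    set.seed(seed)
    permutations <- t(vapply(seq_len(n_perm), function(i) sample.int(n),
                             integer(n)))
  }
  nperm <- nrow(permutations)
  exceed <- numeric(length(tl))
  for (i in seq_len(nperm)) {
    p <- permutations[i, ]
    fp <- stat(g[p, p])$f
    exceed <- exceed + (fp >= obs$f - 1e-12)
  }
  pval <- (exceed + 1) / (nperm + 1)
  out <- data.frame(
    term = c(tl, "Residual", "Total"),
    df = c(dfs, df_res, n - 1),
    SS = c(obs$ss, obs$ss_res, ss_total),
    pseudo_F = c(obs$f, NA, NA),
    R2 = c(obs$ss, obs$ss_res, ss_total) / ss_total,
    p_value = c(pval, NA, NA),
    stringsAsFactors = FALSE)
  attr(out, "n_perm") <- nperm
  attr(out, "seed") <- seed
  class(out) <- c("sym_permanova", "data.frame")
  out
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Minimizes Kruskal stress-1 by monotone regression (via
#' `vegan::monoMDS`) over multiple starts: the first start is the metric
#' (principal coordinates) configuration, the rest are random. The best
#' configuration is returned; convergence is declared when a later start
#' reproduces the best stress within `1e-6` or matches it after Procrustes
#' rotation with RMSE below `1e-5`.
#'
#' @param d A `dist` or symmetric dissimilarity matrix.
#' @param k Number of ordination axes (default 2).
#' @param n_starts Number of starts (default 20).
#' @param max_iter Iteration cap per start.
#' @param seed RNG seed for the random starts.
#' @return List of class `sym_nmds` with `points`, `stress`, `n_starts`,
#'   `converged`.
#' @export
nmds <- function(d, k = 2, n_starts = 20, max_iter = 500, seed = 1) {
  m <- as.matrix(d)
  n <- nrow(m)
  stopifnot(n >= k + 1)
  dd <- as.dist(m)
  set.seed(seed)
  best <- NULL
  converged <- FALSE
  init0 <- cmdscale(dd, k = k)
  if (ncol(init0) < k)
    init0 <- cbind(init0, matrix(rnorm(n * (k - ncol(init0)), sd = 1e-4),
                                 n, k - ncol(init0)))
  for (s in seq_len(n_starts)) {
    init <- if (s == 1) init0 else matrix(rnorm(n * k), n, k)
    fit <- vegan::monoMDS(dd, y = init, k = k, maxit = max_iter)
    if (is.null(best) || fit$stress < best$stress - 1e-6) {
      best <- fit
    } else if (fit$stress <= best$stress + 1e-6) {
      pr <- vegan::procrustes(best$points, fit$points, symmetric = TRUE)
      if (sqrt(mean(pr$Yrot - pr$X)^2) < 1e-5 ||
          abs(fit$stress - best$stress) < 1e-6) converged <- TRUE
    }
  }
  pts <- best$points
  rownames(pts) <- rownames(m)
  colnames(pts) <- paste0("NMDS", seq_len(k))
  structure(list(points = pts, stress = best$stress, n_starts = n_starts,
                 converged = converged), class = "sym_nmds")
}

#' @export
print.sym_nmds <- function(x, ...) {
  cat(sprintf("<sym_nmds> %d samples, %d axes, stress = %.4f (%s)\n",
              nrow(x$points), ncol(x$points), x$stress,
              if (x$converged) "converged" else "no convergent restart"))
  invisible(x)
}

#' Weighted-average taxon scores for NMDS biplots
#'
#' @param ord A `sym_nmds` result.
#' @param comm Abundance matrix (samples x taxa) on the ordination's
#'   samples.
#' @return Matrix of taxon coordinates.
#' @export
nmds_taxon_scores <- function(ord, comm) {
  comm <- as.matrix(comm)[rownames(ord$points), , drop = FALSE]
  vegan::wascores(ord$points, comm)
}

#' Per-compartment and per-species dissimilarity and pool-effect table
#'
#' For every compartment and coral species in a count table, computes the
#' sample size, the overall / within-pool / between-pool mean Bray-Curtis
#' dissimilarities of square-root transformed relative abundances, and
#' the one-way PERMANOVA pool effect (R2 and permutation p-value) - the
#' summary table format of between-pool community comparisons.
#'
#' @param x A `sym_counts` with pool/compartment/species metadata.
#' @param n_perm Permutations for each PERMANOVA (default 9999).
#' @param seed RNG seed.
#' @return Data.frame with one row per subset.
#' @export
dissimilarity_table <- function(x, n_perm = 9999, seed = 1) {
  md <- x$metadata
  subsets <- c(as.list(COMPARTMENTS),
               as.list(sort(setdiff(unique(md$species[md$compartment ==
                 "coral"]), NA))))
  rows <- list()
  for (ss in subsets) {
    comp <- if (ss %in% COMPARTMENTS) ss else "coral"
    sp <- if (ss %in% COMPARTMENTS) NULL else ss
    sub <- subset_counts(x, compartment = comp, species = sp)
    if (nrow(sub$counts) < 4 || length(unique(sub$metadata$pool)) < 2) next
    d <- bray_curtis(sqrt_relative(sub))
    pool <- sub$metadata$pool[match(labels(d), sub$metadata$sample_id)]
    gm <- group_mean_dissimilarity(d, pool)
    pm <- permanova(d, ~ pool, data.frame(pool = pool), n_perm = n_perm,
                    seed = seed)
    rows[[ss]] <- data.frame(
      subset = ss, n = length(pool), overall = gm$overall,
      within_pool = gm$within, between_pool = gm$between,
      R2 = pm$R2[1], p_value = pm$p_value[1], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
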