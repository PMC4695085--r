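#' Filter taxa by within-subset relative abundance
#'
#' Retains taxa whose total count strictly exceeds `min_fraction` of the
#' grand total of the (already subset) table; taxa below the threshold are
#' excluded from differential-abundance testing only, never from
#' beta-diversity analyses.
#'
#' @param x A `sym_counts` object, typically one compartment or species.
#' @param min_fraction Fraction of all sequences (default 0.001, i.e.
#'   0.1%).
#' @return Filtered `sym_counts`; attribute `dropped` lists removed taxa.
#' @export
filter_taxa <- function(x, min_fraction = 0.001) {
  stopifnot(inherits(x, "sym_counts"))
  if (!length(x$counts) || sum(x$counts) == 0) stop("empty count table")
  tot <- colSums(x$counts)
  keep <- tot > min_fraction * sum(tot)
  if (!any(keep)) warning("no taxa exceed the abundance threshold")
  out <- count_table(x$counts[, keep, drop = FALSE], x$metadata)
  attr(out, "dropped") <- colnames(x$counts)[!keep]
  out
}

#' Append the artificial sum-taxon
#'
#' Adds a taxon `"sum"` whose count per sample equals that sample's total
#' sequencing depth. Modeled alongside the real taxa, it serves as the
#' normalization reference that controls for depth differences among
#' samples and pools. Depths should be the pre-filter totals, so the
#' normalizer reflects true sample depth even after [filter_taxa()].
#'
#' @param x A `sym_counts` object.
#' @param totals Optional per-sample depths (defaults to row sums of `x`).
#' @return A `sym_counts` with the extra `"sum"` column; zero-depth
#'   samples are dropped with a warning.
#' @export
add_sum_taxon <- function(x, totals = NULL) {
  stopifnot(inherits(x, "sym_counts"))
  if (is.null(totals)) totals <- rowSums(x$counts)
  stopifnot(length(totals) == nrow(x$counts))
  if ("sum" %in% colnames(x$counts)) stop("table already has a sum taxon")
  m <- cbind(x$counts, sum = as.integer(totals))
  if (any(totals == 0)) {
    warning("dropping zero-depth sample(s): ",
            paste(rownames(m)[totals == 0], collapse = ", "))
    m <- m[totals > 0, , drop = FALSE]
  }
  count_table(m, x$metadata)
}

half_cauchy_lp <- function(sigma, scale = 2.5) -log1p((sigma / scale)^2)

#' Fit the Bayesian Poisson-lognormal differential abundance model
#'
#' Counts are modeled as `y[s,t] ~ Poisson(lambda[s,t])` with
#' `log lambda[s,t] = alpha[t] + beta[t] * I(pool[s] == "300") + u[s] +
#' eps[s,t]`: per-taxon intercepts, a per-taxon pool effect, a lognormal
#' sample (size) random effect `u`, and a lognormal overdispersion term
#' `eps`. Priors are Normal(0, 10^2) on fixed effects and half-Cauchy(2.5)
#' on the standard deviations. Sampling is adaptive Metropolis-within-
#' Gibbs with elementwise proposals, extra decorrelating shift moves
#' between intercepts and their residuals, and adaptation confined to
#' burn-in; results are deterministic given the seed.
#'
#' @param x A `sym_counts` including the `"sum"` taxon (see
#'   [add_sum_taxon()]); its metadata must contain `pool` with both
#'   levels present.
#' @param iterations,burnin,thin MCMC controls (defaults 15000/5000/10).
#' @param prior_sd Fixed-effect prior standard deviation (default 10).
#' @param cauchy_scale Half-Cauchy scale of the variance components.
#' @param seed RNG seed.
#' @return List of class `sym_pln` with draw matrices `alpha`, `beta`
#'   (taxa in columns), vectors `sigma_e`, `sigma_u`, the taxon names,
#'   and per-parameter diagnostics (`ess`, `rhat` for the pool
#'   contrasts).
#' @export
fit_pln <- function(x, iterations = 15000, burnin = 5000, thin = 10,
                    prior_sd = 10, cauchy_scale = 2.5, seed = 1) {
  stopifnot(inherits(x, "sym_counts"), iterations > burnin, thin >= 1)
  y <- x$counts
  if (any(y != round(y))) stop("counts must be integers")
  if (!"sum" %in% colnames(y)) stop("table lacks the 'sum' taxon")
  pool <- x$metadata$pool
  if (length(unique(pool)) < 2) stop("both pools must be present")
  if (min(table(pool)) < 2) stop("need >= 2 samples per pool")
  n <- nrow(y); nt <- ncol(y)
  xs <- as.numeric(pool == "300")
  set.seed(seed)
  alpha <- log(colMeans(y) + 0.1)
  beta <- numeric(nt)
  u <- numeric(n)
  eps <- matrix(0, n, nt)
  sig_e <- 0.5; sig_u <- 0.5
  pv <- prior_sd^2
  s_eps <- 0.8; s_al <- 0.3; s_be <- 0.3; s_u <- 0.3; s_sg <- 0.4
  acc <- c(eps = 0, al = 0, be = 0, u = 0, se = 0, su = 0)
  batch <- 50
  eta_base <- function() outer(u, alpha, "+") + outer(xs, beta, "*")
  lam <- exp(eta_base() + eps)
  ry <- rowSums(y); cy <- colSums(y); cy3 <- colSums(y * xs)
  n_keep <- floor((iterations - burnin) / thin)
  dr_alpha <- matrix(NA_real_, n_keep, nt, dimnames = list(NULL, colnames(y)))
  dr_beta <- dr_alpha
  dr_se <- numeric(n_keep); dr_su <- numeric(n_keep)
  ki <- 0L
  for (it in seq_len(iterations)) {
    # overdispersion residuals, elementwise
    d <- matrix(rnorm(n * nt, sd = s_eps), n, nt)
    lam2 <- lam * exp(d)
    lacc <- y * d - (lam2 - lam) - ((eps + d)^2 - eps^2) / (2 * sig_e^2)
    a <- matrix(log(runif(n * nt)), n, nt) < lacc
    eps[a] <- eps[a] + d[a]
    lam[a] <- lam2[a]
    acc["eps"] <- acc["eps"] + mean(a)
    # per-taxon intercepts
    cl <- colSums(lam)
    d <- rnorm(nt, sd = s_al)
    lacc <- d * cy - (exp(d) - 1) * cl -
      ((alpha + d)^2 - alpha^2) / (2 * pv)
    a <- log(runif(nt)) < lacc
    if (any(a)) {
      alpha[a] <- alpha[a] + d[a]
      lam[, a] <- lam[, a, drop = FALSE] %*% diag(exp(d[a]), sum(a))
    }
    acc["al"] <- acc["al"] + mean(a)
    # per-taxon pool effects (pool 300 rows only)
    cl3 <- colSums(lam * xs)
    d <- rnorm(nt, sd = s_be)
    lacc <- d * cy3 - (exp(d) - 1) * cl3 -
      ((beta + d)^2 - beta^2) / (2 * pv)
    a <- log(runif(nt)) < lacc
    if (any(a)) {
      beta[a] <- beta[a] + d[a]
      lam[xs == 1, a] <- lam[xs == 1, a, drop = FALSE] %*%
        diag(exp(d[a]), sum(a))
    }
    acc["be"] <- acc["be"] + mean(a)
    # sample random effects
    rl <- rowSums(lam)
    d <- rnorm(n, sd = s_u)
    lacc <- d * ry - (exp(d) - 1) * rl - ((u + d)^2 - u^2) / (2 * sig_u^2)
    a <- log(runif(n)) < lacc
    if (any(a)) {
      u[a] <- u[a] + d[a]
      lam[a, ] <- lam[a, , drop = FALSE] * exp(d[a])
    }
    acc["u"] <- acc["u"] + mean(a)
    # decorrelating shifts: alpha[t] + d, eps[, t] - d leaves lambda fixed
    d <- rnorm(nt, sd = s_al)
    lacc <- -((alpha + d)^2 - alpha^2) / (2 * pv) -
      (colSums(sweep(eps, 2, d, "-")^2) - colSums(eps^2)) / (2 * sig_e^2)
    a <- log(runif(nt)) < lacc
    alpha[a] <- alpha[a] + d[a]
    eps[, a] <- sweep(eps[, a, drop = FALSE], 2, d[a], "-")
    # and u[s] + d, eps[s, ] - d
    d <- rnorm(n, sd = s_u)
    lacc <- -((u + d)^2 - u^2) / (2 * sig_u^2) -
      (rowSums((eps - d)^2) - rowSums(eps^2)) / (2 * sig_e^2)
    a <- log(runif(n)) < lacc
    u[a] <- u[a] + d[a]
    eps[a, ] <- eps[a, , drop = FALSE] - d[a]
    # variance components on the log scale (with Jacobian)
    d <- rnorm(1, sd = s_sg)
    sg2 <- sig_e * exp(d)
    lacc <- (-n * nt * log(sg2) - sum(eps^2) / (2 * sg2^2) +
             half_cauchy_lp(sg2, cauchy_scale) + log(sg2)) -
            (-n * nt * log(sig_e) - sum(eps^2) / (2 * sig_e^2) +
             half_cauchy_lp(sig_e, cauchy_scale) + log(sig_e))
    if (log(runif(1)) < lacc) { sig_e <- sg2; acc["se"] <- acc["se"] + 1 }
    d <- rnorm(1, sd = s_sg)
    sg2 <- sig_u * exp(d)
    lacc <- (-n * log(sg2) - sum(u^2) / (2 * sg2^2) +
             half_cauchy_lp(sg2, cauchy_scale) + log(sg2)) -
            (-n * log(sig_u) - sum(u^2) / (2 * sig_u^2) +
             half_cauchy_lp(sig_u, cauchy_scale) + log(sig_u))
    if (log(runif(1)) < lacc) { sig_u <- sg2; acc["su"] <- acc["su"] + 1 }
    # adapt proposal scales during burn-in only
    if (it <= burnin && it %% batch == 0) {
      rate <- acc / batch
      s_eps <- s_eps * exp((rate["eps"] - 0.44) / 2)
      s_al <- s_al * exp((rate["al"] - 0.44) / 2)
      s_be <- s_be * exp((rate["be"] - 0.44) / 2)
      s_u <- s_u * exp((rate["u"] - 0.44) / 2)
      s_sg <- s_sg * exp(((rate["se"] + rate["su"]) / 2 - 0.44) / 2)
      acc[] <- 0
    }
    if (it %% 200 == 0) lam <- exp(eta_base() + eps) # guard against drift
    if (it > burnin && (it - burnin) %% thin == 0) {
      ki <- ki + 1L
      dr_alpha[ki, ] <- alpha
      dr_beta[ki, ] <- beta
      dr_se[ki] <- sig_e
      dr_su[ki] <- sig_u
    }
  }
  contrast <- dr_beta[, setdiff(colnames(y), "sum"), drop = FALSE] -
    dr_beta[, "sum"]
  structure(list(alpha = dr_alpha, beta = dr_beta, sigma_e = dr_se,
                 sigma_u = dr_su, taxa = colnames(y), seed = seed,
                 ess = apply(contrast, 2, ess_draws),
                 rhat = apply(contrast, 2, split_rhat)),
            class = "sym_pln")
}

# effective sample size from the autocorrelation of one chain
ess_draws <- function(x) {
  n <- length(x)
  if (var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 100), plot = FALSE)$acf[-1]
  pos <- which(ac < 0.05)
  s <- if (length(pos)) sum(ac[seq_len(pos[1] - 1)]) else sum(ac)
  n / (1 + 2 * max(0, s))
}

# split-Rhat of a single chain halved
split_rhat <- function(x) {
  n <- floor(length(x) / 2)
  a <- x[seq_len(n)]; b <- x[n + seq_len(n)]
  w <- (var(a) + var(b)) / 2
  if (w == 0) return(1)
  m <- mean(c(mean(a), mean(b)))
  bv <- n * ((mean(a) - m)^2 + (mean(b) - m)^2)
  sqrt(((n - 1) / n * w + bv / n) / w)
}

#' Summarize differential abundance from the model posterior
#'
#' Per taxon and pool, the relative abundance is
#' `exp(eta[t, pool] - eta[sum, pool])` per draw; the pool-300 / pool-400
#' fold-change is the per-draw ratio of relative abundances. The z-score
#' uses the posterior of the between-pool contrast
#' `beta[t] - beta[sum]`: `z = |mean| / sd`, `p = 2 * (1 - Phi(z))`,
#' flagged by Benjamini-Hochberg at FDR `q`.
#'
#' @param fit A `sym_pln` posterior.
#' @param q FDR level (default 0.1).
#' @return Data.frame of class `sym_diffabund`: per taxon the posterior
#'   mean and 95% credible limits of relative abundance in each pool, the
#'   fold-change with credible limits, `z`, `p_value`, `p_adj`, and
#'   `significant`.
#' @export
summarize_diff <- function(fit, q = 0.1) {
  stopifnot(inherits(fit, "sym_pln"))
  if (nrow(fit$beta) < 200)
    stop("need >= 200 retained draws for stable summaries")
  taxa <- setdiff(fit$taxa, "sum")
  eta300 <- fit$alpha + fit$beta
  eta400 <- fit$alpha
  qs <- function(m) t(apply(m, 2, function(v)
    c(mean = mean(v), lo = unname(quantile(v, 0.025)),
      hi = unname(quantile(v, 0.975)))))
  rel300 <- qs(exp(eta300[, taxa, drop = FALSE] - eta300[, "sum"]))
  rel400 <- qs(exp(eta400[, taxa, drop = FALSE] - eta400[, "sum"]))
  fold <- qs(exp(fit$beta[, taxa, drop = FALSE] - fit$beta[, "sum"]))
  contrast <- fit$beta[, taxa, drop = FALSE] - fit$beta[, "sum"]
  sdc <- apply(contrast, 2, sd)
  z <- ifelse(sdc > 0, abs(colMeans(contrast)) / sdc, 0)
  p <- 2 * (1 - pnorm(z))
  if (any(sdc == 0)) {
    warning("degenerate posterior sd for some taxa; p set to 1")
    p[sdc == 0] <- 1
  }
  p_adj <- p.adjust(p, method = "BH")
  out <- data.frame(
    taxon = taxa,
    relabund_pool300 = rel300[, "mean"], rel300_lo = rel300[, "lo"],
    rel300_hi = rel300[, "hi"],
    relabund_pool400 = rel400[, "mean"], rel400_lo = rel400[, "lo"],
    rel400_hi = rel400[, "hi"],
    fold_change = fold[, "mean"], fold_lo = fold[, "lo"],
    fold_hi = fold[, "hi"],
    z = z, p_value = p, p_adj = p_adj,
    significant = p_adj <= q,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "q") <- q
  class(out) <- c("sym_diffabund", "data.frame")
  out
}

#' Differential abundance between pools in one compartment or species
#'
#' Convenience wrapper: subset, filter taxa to those above `min_fraction`
#' of subset sequences, append the sum taxon from pre-filter depths, fit
#' the Poisson-lognormal model, and summarize.
#'
#' @param x A `sym_counts` table.
#' @param compartment,species Optional subset selectors.
#' @param min_fraction Abundance filter (default 0.001).
#' @param q FDR level (default 0.1).
#' @param seed RNG seed.
#' @param ... Passed to [fit_pln()] (e.g. `iterations`, `burnin`, `thin`).
#' @return A `sym_diffabund` data.frame; the fit is in attribute `fit`.
#' @export
diff_abundance <- function(x, compartment = NULL, species = NULL,
                           min_fraction = 0.001, q = 0.1, seed = 1, ...) {
  sub <- subset_counts(x, compartment = compartment, species = species)
  depths <- rowSums(sub$counts)
  filt <- filter_taxa(sub, min_fraction)
  withsum <- add_sum_taxon(filt, totals = depths)
  fit <- fit_pln(withsum, seed = seed, ...)
  out <- summarize_diff(fit, q = q)
  attr(out, "fit") <- fit
  out
}
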