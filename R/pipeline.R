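#' Run the full analysis pipeline
#'
#' Executes, in order: read-level taxonomy assignment (when reads are
#' supplied), beta-diversity (square-root transformed Bray-Curtis, NMDS,
#' group mean dissimilarities), PERMANOVA (a two-way compartment x pool
#' test on all samples, then one-way pool tests per compartment and coral
#' species), differential abundance (only for subsets whose one-way pool
#' effect is significant, unless `force_diffabund`), and Mantel tests of
#' spatial autocorrelation per compartment/species and pool. All tables
#' are written under `out_dir` together with the resolved configuration
#' and a summary report.
#'
#' @param out_dir Output directory (created).
#' @param metadata Metadata data.frame or TSV path.
#' @param db A `ref_db` (required when `reads` are supplied).
#' @param reads Optional read data.frame (`read_id`, `sample_id`,
#'   `sequence`); when absent, `counts` must be given.
#' @param counts Optional `sym_counts` table (skips taxonomy).
#' @param config A `sym_config`; see [default_config()].
#' @param force_diffabund Run differential abundance regardless of the
#'   PERMANOVA gate.
#' @return Invisible list with `counts`, `permanova`, `diffabund`,
#'   `mantel`, `nmds`, `dissimilarity`.
#' @export
run_pipeline <- function(out_dir, metadata, db = NULL, reads = NULL,
                         counts = NULL, config = default_config(),
                         force_diffabund = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  write_config(config, file.path(out_dir, "config.yaml"))
  cfg_hash <- sprintf("%08x", sum(utf8ToInt(paste(
    yaml::as.yaml(unclass(config)), collapse = ""))))

  # --- taxonomy ---------------------------------------------------------
  if (is.null(counts)) {
    if (is.null(reads) || is.null(db))
      stop("[stage assign] supply either counts or reads + db")
    asn <- stage("assign", assign_taxonomy(reads, db, config))
    counts <- stage("assign", build_count_table(asn, metadata))
    write.table(asn, file.path(out_dir, "assignments.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write.table(attr(counts, "qc"), file.path(out_dir, "qc_report.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  } else if (!inherits(counts, "sym_counts")) {
    counts <- count_table(counts, metadata)
  }
  write_counts(counts, file.path(out_dir, "count_table.csv"))

  md <- counts$metadata
  subsets <- c(
    lapply(COMPARTMENTS, function(cc) list(name = cc, compartment = cc,
                                           species = NULL)),
    lapply(setdiff(unique(md$species[md$compartment == "coral"]), NA),
           function(sp) list(name = sp, compartment = "coral", species = sp)))

  # --- beta diversity ---------------------------------------------------
  beta <- stage("beta", {
    lapply(setNames(subsets, vapply(subsets, `[[`, "", "name")), function(ss) {
      sub <- subset_counts(counts, compartment = ss$compartment,
                           species = ss$species)
      if (nrow(sub$counts) < 4 || ncol(sub$counts) < 2) return(NULL)
      tr <- sqrt_relative(sub)
      d <- bray_curtis(tr)
      grp <- sub$metadata$pool[match(labels(d), sub$metadata$sample_id)]
      list(d = d, transformed = tr, pool = grp,
           means = group_mean_dissimilarity(d, grp), meta = sub$metadata)
    })
  })
  for (nm in names(beta)) if (!is.null(beta[[nm]]))
    write.table(as.matrix(beta[[nm]]$d),
                file.path(out_dir, sprintf("bray_curtis_%s.csv",
                                           gsub("[^A-Za-z0-9]", "_", nm))),
                sep = ",", col.names = NA, quote = FALSE)

  ords <- stage("nmds", {
    lapply(beta[COMPARTMENTS], function(b) {
      if (is.null(b)) return(NULL)
      nmds(b$d, k = config$nmds_k, n_starts = config$nmds_starts,
           seed = config$seed)
    })
  })
  for (nm in names(ords)) if (!is.null(ords[[nm]]))
    write.table(data.frame(sample_id = rownames(ords[[nm]]$points),
                           ords[[nm]]$points, stress = ords[[nm]]$stress),
                file.path(out_dir, sprintf("nmds_%s.csv", nm)), sep = ",",
                row.names = FALSE, quote = FALSE)

  # --- permanova --------------------------------------------------------
  perm <- stage("permanova", {
    twoway <- {
      tr <- sqrt_relative(counts)
      d <- bray_curtis(tr)
      dat <- md[match(labels(d), md$sample_id), , drop = FALSE]
      permanova(d, ~ compartment * pool, dat,
                n_perm = config$n_perm_permanova, seed = config$seed)
    }
    oneway <- lapply(beta, function(b) {
      if (is.null(b) || length(unique(b$pool)) < 2) return(NULL)
      permanova(b$d, ~ pool, data.frame(pool = b$pool),
                n_perm = config$n_perm_permanova, seed = config$seed)
    })
    list(twoway = twoway, oneway = oneway)
  })
  ptab <- do.call(rbind, c(list(cbind(subset = "all", perm$twoway)),
    lapply(names(perm$oneway), function(nm) {
      if (is.null(perm$oneway[[nm]])) return(NULL)
      cbind(subset = nm, perm$oneway[[nm]])
    })))
  write.table(ptab, file.path(out_dir, "permanova.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)

  # --- differential abundance (gated on the one-way pool effect) --------
  diffs <- stage("diffabund", {
    res <- list()
    for (nm in names(perm$oneway)) {
      pw <- perm$oneway[[nm]]
      if (is.null(pw)) next
      p <- pw$p_value[pw$term == "pool"]
      if (!force_diffabund && (is.na(p) || p >= 0.05)) next
      ss <- subsets[[which(vapply(subsets, `[[`, "", "name") == nm)]]
      res[[nm]] <- diff_abundance(
        counts, compartment = ss$compartment, species = ss$species,
        min_fraction = config$min_fraction, q = config$fdr_q,
        seed = config$seed, iterations = config$mcmc$iterations,
        burnin = config$mcmc$burnin, thin = config$mcmc$thin)
      write.table(res[[nm]],
                  file.path(out_dir, sprintf("diffabund_%s.tsv",
                                             gsub("[^A-Za-z0-9]", "_", nm))),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
    res
  })

  # --- spatial autocorrelation -----------------------------------------
  mant <- stage("mantel", {
    res <- list()
    for (ss in subsets) for (pl in POOLS) {
      key <- paste0(ss$name, "_pool", pl)
      r <- tryCatch(withCallingHandlers(
        spatial_autocorrelation(counts, compartment = ss$compartment,
                                pool = pl, species = ss$species,
                                n_perm = config$n_perm_mantel,
                                seed = config$seed),
        warning = function(w) invokeRestart("muffleWarning")),
        error = function(e) NULL)
      if (!is.null(r)) res[[key]] <- r
    }
    res
  })
  if (length(mant)) {
    mtab <- data.frame(subset = names(mant),
                       r = vapply(mant, `[[`, 0, "r"),
                       p_value = vapply(mant, `[[`, 0, "p_value"),
                       n_perm = vapply(mant, `[[`, 0L, "n_perm"))
    write.table(mtab, file.path(out_dir, "mantel.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }

  # --- summary ----------------------------------------------------------
  summary_lines <- c(
    sprintf("config_hash\t%s", cfg_hash),
    sprintf("n_samples\t%d", nrow(counts$counts)),
    sprintf("n_taxa\t%d", ncol(counts$counts)),
    sprintf("total_reads\t%d", sum(counts$counts)),
    sprintf("diffabund_subsets\t%s",
            paste(names(diffs), collapse = ",")))
  writeLines(summary_lines, file.path(out_dir, "summary.tsv"))
  invisible(list(counts = counts, beta = beta, nmds = ords,
                 permanova = perm, diffabund = diffs, mantel = mant,
                 config_hash = cfg_hash))
}
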