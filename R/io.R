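#' Read a FASTA file
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  x <- Biostrings::DNAStringSet(unlist(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read per-read Phred qualities
#'
#' A two-column TSV: read id, space-separated integer Phred scores.
#'
#' @param path Path to the quality TSV.
#' @return Named list of integer vectors.
#' @export
read_quals <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("read_id", "quals"))
  out <- lapply(strsplit(x$quals, " +"), as.integer)
  names(out) <- x$read_id
  out
}

#' Read and validate a sample metadata table
#'
#' Expects a TSV with header
#' `sample_id pool compartment species latitude longitude depth`.
#' Pool must be one of 300/400 and compartment one of
#' water/sediment/coral; species may be empty for non-coral samples and
#' coordinates may be missing (those samples are dropped from spatial
#' analyses only).
#'
#' @param path Path to the metadata TSV.
#' @return A data.frame with one row per sample.
#' @export
read_metadata <- function(path) {
  md <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  validate_metadata(md)
}

#' @rdname read_metadata
#' @param metadata A metadata data.frame to validate in place of a file.
#' @export
validate_metadata <- function(metadata) {
  req <- c("sample_id", "pool", "compartment")
  miss <- setdiff(req, names(metadata))
  if (length(miss))
    stop("metadata is missing required columns: ", paste(miss, collapse = ", "))
  for (col in c("species", "latitude", "longitude", "depth"))
    if (is.null(metadata[[col]])) metadata[[col]] <- NA
  metadata$sample_id <- as.character(metadata$sample_id)
  metadata$pool <- as.character(metadata$pool)
  metadata$compartment <- as.character(metadata$compartment)
  if (anyDuplicated(metadata$sample_id))
    stop("duplicated sample ids in metadata: ",
         paste(unique(metadata$sample_id[duplicated(metadata$sample_id)]),
               collapse = ", "))
  bad_pool <- setdiff(unique(metadata$pool), POOLS)
  if (length(bad_pool))
    stop("unknown pool level(s): ", paste(bad_pool, collapse = ", "),
         " (expected ", paste(POOLS, collapse = "/"), ")")
  bad_comp <- setdiff(unique(metadata$compartment), COMPARTMENTS)
  if (length(bad_comp))
    stop("unknown compartment(s): ", paste(bad_comp, collapse = ", "),
         " (expected ", paste(COMPARTMENTS, collapse = "/"), ")")
  metadata$latitude <- as.numeric(metadata$latitude)
  metadata$longitude <- as.numeric(metadata$longitude)
  if (any(abs(metadata$latitude) > 90, na.rm = TRUE) ||
      any(abs(metadata$longitude) > 180, na.rm = TRUE))
    stop("latitude/longitude out of range")
  metadata
}

#' Sample-by-taxon count table
#'
#' Couples an integer count matrix (samples in rows, taxa in columns) with
#' validated sample metadata; the pivot between taxonomy assignment and all
#' downstream statistics.
#'
#' @param counts Non-negative integer matrix with sample ids as rownames
#'   and taxon labels as colnames.
#' @param metadata Metadata data.frame covering every sample in `counts`.
#' @return An object of class `sym_counts`.
#' @export
count_table <- function(counts, metadata) {
  counts <- as.matrix(counts)
  if (nrow(counts) > 0 && is.null(rownames(counts)))
    stop("counts must have sample ids as rownames")
  metadata <- validate_metadata(metadata)
  missing <- setdiff(rownames(counts), metadata$sample_id)
  if (length(missing))
    stop("samples absent from metadata: ", paste(missing, collapse = ", "))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  metadata <- metadata[match(rownames(counts), metadata$sample_id), ,
                       drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(counts = counts, metadata = metadata), class = "sym_counts")
}

#' @export
print.sym_counts <- function(x, ...) {
  cat(sprintf("<sym_counts> %d samples x %d taxa, %s reads\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  comp <- table(x$metadata$compartment, x$metadata$pool)
  print(comp)
  invisible(x)
}

#' @export
dim.sym_counts <- function(x) dim(x$counts)

#' Subset a count table by metadata
#'
#' @param x A `sym_counts` object.
#' @param compartment,pool,species Optional values to keep.
#' @param drop_empty_taxa Drop taxa with zero total count after subsetting.
#' @return A `sym_counts` object.
#' @export
subset_counts <- function(x, compartment = NULL, pool = NULL, species = NULL,
                          drop_empty_taxa = TRUE) {
  stopifnot(inherits(x, "sym_counts"))
  keep <- rep(TRUE, nrow(x$counts))
  if (!is.null(compartment)) keep <- keep & x$metadata$compartment %in% compartment
  if (!is.null(pool)) keep <- keep & x$metadata$pool %in% as.character(pool)
  if (!is.null(species)) keep <- keep & x$metadata$species %in% species
  counts <- x$counts[keep, , drop = FALSE]
  if (drop_empty_taxa) counts <- counts[, colSums(counts) > 0, drop = FALSE]
  count_table(counts, x$metadata[keep, , drop = FALSE])
}

#' Read / write a count table CSV
#'
#' The CSV stores samples in rows (first column `sample_id`) and taxa in
#' columns.
#'
#' @param path CSV path.
#' @param metadata Metadata data.frame (or path to a metadata TSV).
#' @return `read_counts`: a `sym_counts` object.
#' @export
read_counts <- function(path, metadata) {
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  df <- read.table(path, sep = ",", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  count_table(m, metadata)
}

#' @rdname read_counts
#' @param x A `sym_counts` object or bare count matrix.
#' @export
write_counts <- function(x, path) {
  m <- if (inherits(x, "sym_counts")) x$counts else as.matrix(x)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a newick guide tree
#'
#' @param path Path to a newick file with one rooted tree.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path), error = function(e)
    stop("malformed newick in ", path, ": ", conditionMessage(e)))
  if (is.null(tr)) stop("malformed newick in ", path)
  tr
}

#' Default run configuration
#'
#' All thresholds of the pipeline in one list: clade-level e-value cutoff
#' and next-best ratio, subtype identity/coverage rules, de novo clustering
#' identity, quality-trimming controls, differential-abundance filters, and
#' permutation counts. Values can be overridden and the resolved
#' configuration is written beside every pipeline run.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `sym_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    e_cutoff = 1e-20, ratio_cutoff = 1e-5,
    min_identity = 0.97, min_ref_coverage = 0.90,
    cluster_identity = 0.97,
    q_threshold = 25, window = 10, max_primer_errors = 3,
    min_fraction = 0.001, fdr_q = 0.1,
    n_perm_permanova = 9999, n_perm_mantel = 999,
    nmds_k = 2, nmds_starts = 20,
    mcmc = list(iterations = 15000, burnin = 5000, thin = 10),
    seed = 1
  )
  over <- list(...)
  stopifnot(all(nzchar(names(over))))
  structure(modifyList(cfg, over), class = "sym_config")
}

#' @rdname default_config
#' @param path YAML path.
#' @export
read_config <- function(path) {
  structure(modifyList(unclass(default_config()), yaml::read_yaml(path)),
            class = "sym_config")
}

#' @rdname default_config
#' @param config A `sym_config` list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
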