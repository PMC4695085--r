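#' Clade-labelled ITS2 reference database
#'
#' Bundles reference sequences, their clade labels (A/C/D/F/G), and one
#' rooted guide tree per clade whose leaves are that clade's reference
#' names. Guide trees carry integer internal-node numbers (preorder from
#' the root) used for lowest-common-ancestor placement of ambiguous
#' subtype hits. Trees are built automatically by neighbor-joining when
#' not supplied.
#'
#' @param sequences Named character vector of reference sequences.
#' @param clades Character vector of clade labels, parallel to `sequences`.
#' @param trees Optional named list (by clade) of rooted `phylo` trees with
#'   integer internal node labels; missing clades are built by
#'   [build_guide_trees()].
#' @return An object of class `ref_db` with elements `records` (data.frame
#'   name/clade/sequence) and `trees`.
#' @export
reference_db <- function(sequences, clades, trees = NULL) {
  stopifnot(length(sequences) == length(clades), !is.null(names(sequences)))
  nm <- names(sequences)
  if (anyDuplicated(nm)) stop("reference names must be unique")
  clades <- as.character(clades)
  bad <- setdiff(unique(clades), CLADES)
  if (length(bad)) stop("unknown clade label(s): ", paste(bad, collapse = ", "))
  records <- data.frame(name = nm, clade = clades,
                        sequence = toupper(unname(sequences)),
                        stringsAsFactors = FALSE)
  if (any(!nzchar(records$sequence))) stop("empty reference sequence")
  db <- structure(list(records = records, trees = NULL), class = "ref_db")
  built <- build_guide_trees(db)
  if (!is.null(trees)) {
    for (cl in names(trees)) {
      validate_guide_tree(trees[[cl]], records$name[records$clade == cl], cl)
      built[[cl]] <- trees[[cl]]
    }
  }
  db$trees <- built
  db
}

#' @export
print.ref_db <- function(x, ...) {
  cat(sprintf("<ref_db> %d references in %d clades (%s)\n",
              nrow(x$records), length(unique(x$records$clade)),
              paste(sprintf("%s:%d", names(table(x$records$clade)),
                            table(x$records$clade)), collapse = ", ")))
  invisible(x)
}

validate_guide_tree <- function(tree, leaf_names, clade) {
  if (!inherits(tree, "phylo")) stop("guide tree for clade ", clade,
                                     " is not a phylo object")
  extra <- setdiff(tree$tip.label, leaf_names)
  if (length(extra))
    stop("guide tree for clade ", clade, " has leaves not in the database: ",
         paste(extra, collapse = ", "))
  if (is.null(tree$node.label) ||
      anyNA(suppressWarnings(as.integer(tree$node.label))))
    stop("guide tree for clade ", clade,
         " must carry integer internal node labels")
  if (anyDuplicated(tree$node.label))
    stop("internal node numbers must be unique within clade ", clade)
  invisible(TRUE)
}

#' Build per-clade guide trees by neighbor-joining
#'
#' Trees are built from pairwise global alignment distances
#' (1 - identity), midpoint-rooted, with internal nodes numbered by
#' preorder from 1 so that node identity is deterministic.
#'
#' @param db A `ref_db` (its `trees` slot is ignored).
#' @return Named list of `phylo` trees, one per clade with >= 2 references.
#' @export
build_guide_trees <- function(db) {
  records <- db$records
  out <- list()
  for (cl in unique(records$clade)) {
    rec <- records[records$clade == cl, , drop = FALSE]
    if (nrow(rec) < 2) next
    n <- nrow(rec)
    d <- matrix(0, n, n, dimnames = list(rec$name, rec$name))
    for (i in seq_len(n - 1)) {
      ids <- .cpp_identity_batch(rec$sequence[i],
                                 rec$sequence[(i + 1):n])
      d[i, (i + 1):n] <- d[(i + 1):n, i] <- 1 - ids
    }
    tr <- if (n == 2) {
      ape::read.tree(text = sprintf("(%s:%f,%s:%f);", rec$name[1],
                                    d[1, 2] / 2, rec$name[2], d[1, 2] / 2))
    } else {
      phangorn::midpoint(ape::nj(as.dist(d)))
    }
    out[[cl]] <- number_internal_nodes(tr)
  }
  out
}

# Assign integer node labels 1..Nnode in preorder (cladewise) from the root.
number_internal_nodes <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree$tip.label)
  ord <- unique(c(ntip + 1L, tree$edge[, 2]))
  internal <- ord[ord > ntip]
  lab <- integer(tree$Nnode)
  lab[internal - ntip] <- seq_along(internal)
  tree$node.label <- as.character(lab)
  tree
}

#' Lowest common ancestor node number of a set of leaves
#'
#' @param tree A guide tree with integer internal node labels.
#' @param leaves Character vector of >= 2 tip names.
#' @return The integer node number of the LCA.
#' @export
lca_node <- function(tree, leaves) {
  stopifnot(length(leaves) >= 2)
  missing <- setdiff(leaves, tree$tip.label)
  if (length(missing))
    stop("leaves absent from guide tree: ", paste(missing, collapse = ", "))
  ntip <- length(tree$tip.label)
  mrca <- if (length(unique(leaves)) == ntip) ntip + 1L else
    ape::getMRCA(tree, unique(leaves))
  as.integer(tree$node.label[mrca - ntip])
}

#' Read a reference database from disk
#'
#' @param fasta Path to the reference FASTA.
#' @param taxonomy Path to a 2-column TSV (name, clade), no header.
#' @param trees_dir Optional directory with `<clade>.nwk` guide trees.
#' @return A `ref_db` object.
#' @export
read_reference_db <- function(fasta, taxonomy, trees_dir = NULL) {
  seqs <- read_fasta(fasta)
  tax <- read.table(taxonomy, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE, col.names = c("name", "clade"))
  missing <- setdiff(names(seqs), tax$name)
  if (length(missing))
    stop("references without a taxonomy entry: ",
         paste(missing, collapse = ", "))
  clades <- tax$clade[match(names(seqs), tax$name)]
  trees <- NULL
  if (!is.null(trees_dir)) {
    files <- list.files(trees_dir, pattern = "\\.nwk$", full.names = TRUE)
    trees <- lapply(files, read_newick)
    names(trees) <- sub("\\.nwk$", "", basename(files))
  }
  reference_db(seqs, clades, trees)
}

#' Write a reference database to disk
#'
#' @param db A `ref_db`.
#' @param dir Output directory (created if needed); writes `refs.fasta`,
#'   `taxonomy.tsv` and `trees/<clade>.nwk`.
#' @export
write_reference_db <- function(db, dir) {
  dir.create(file.path(dir, "trees"), recursive = TRUE, showWarnings = FALSE)
  write_fasta(setNames(db$records$sequence, db$records$name),
              file.path(dir, "refs.fasta"))
  write.table(db$records[, c("name", "clade")],
              file.path(dir, "taxonomy.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  for (cl in names(db$trees))
    ape::write.tree(db$trees[[cl]], file.path(dir, "trees",
                                              paste0(cl, ".nwk")))
  invisible(dir)
}

#' Parse or construct hierarchical taxon labels
#'
#' Labels follow three grammars: a bare reference (leaf) name, an internal
#' placement `<clade>_i:<node>`, or a de novo cluster `<clade>_d:<cluster>`;
#' `"unassigned"` marks reads failing clade assignment.
#'
#' @param label Character vector of labels.
#' @param db Optional `ref_db` used to resolve leaf clades.
#' @return A data.frame with columns `label`, `kind`
#'   (leaf/internal/denovo/unassigned), and `clade` (NA when unassigned).
#' @export
parse_taxon_label <- function(label, db = NULL) {
  kind <- rep("leaf", length(label))
  clade <- rep(NA_character_, length(label))
  internal <- grepl("^[ACDFG]_i:[0-9]+$", label)
  denovo <- grepl("^[ACDFG]_d:[0-9]+$", label)
  kind[internal] <- "internal"
  kind[denovo] <- "denovo"
  kind[label == "unassigned"] <- "unassigned"
  clade[internal | denovo] <- substr(label[internal | denovo], 1, 1)
  if (!is.null(db)) {
    i <- match(label, db$records$name)
    clade[kind == "leaf"] <- db$records$clade[i][kind == "leaf"]
  }
  data.frame(label = label, kind = kind, clade = clade,
             stringsAsFactors = FALSE)
}
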