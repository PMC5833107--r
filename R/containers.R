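#' Validate and normalize a taxonomic profile
#'
#' A taxonomic profile is a named numeric vector of relative abundances over
#' taxa. Abundances must be non-negative and are renormalized to sum to 1
#' (within 1e-12) unless they already do.
#'
#' @param x named numeric vector of abundances (relative or raw counts).
#' @param renormalize divide by the total so the result sums to 1.
#' @return named numeric vector of class-free relative abundances, sum 1.
#' @examples
#' as_taxonomic_profile(c(A = 2, B = 2))
#' @export
as_taxonomic_profile <- function(x, renormalize = TRUE) {
  if (!is.numeric(x)) stop("abundances must be numeric")
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == ""))
    stop("abundances must be named by taxon id")
  if (anyDuplicated(names(x))) stop("duplicated taxon ids")
  if (anyNA(x)) stop("abundances contain NA")
  if (any(x < 0)) stop("abundances must be non-negative")
  tot <- sum(x)
  if (tot <= 0) stop("profile has zero total abundance")
  if (renormalize) x <- x / tot
  else if (abs(tot - 1) > 1e-12) stop("abundances do not sum to 1")
  x
}

#' Number of taxa with non-zero abundance
#' @param profile taxonomic profile (named numeric vector).
#' @return integer count of taxa with abundance > 0.
#' @export
n_nonzero_taxa <- function(profile) sum(profile > 0)

#' Construct a genome-content matrix
#'
#' Holds per-taxon gene-family copy numbers together with 16S rRNA copy
#' numbers, the reference needed to map taxonomic profiles to functional
#' profiles and to compute gene-distribution features.
#'
#' @param copy_numbers numeric matrix, taxa in rows, gene families (functions)
#'   in columns, entries are genomic copy numbers (>= 0). Must have row and
#'   column names.
#' @param rrna_copies named numeric vector of 16S copy numbers per taxon
#'   (> 0); names must cover the rownames of \code{copy_numbers}. Defaults
#'   to 1 for every taxon.
#' @return an object of class \code{genome_content} with elements
#'   \code{copy_numbers} and \code{rrna_copies}.
#' @export
genome_content <- function(copy_numbers, rrna_copies = NULL) {
  copy_numbers <- as.matrix(copy_numbers)
  if (is.null(rownames(copy_numbers)) || is.null(colnames(copy_numbers)))
    stop("copy_numbers must have taxon rownames and function colnames")
  if (anyDuplicated(rownames(copy_numbers))) stop("duplicated taxon ids")
  if (anyDuplicated(colnames(copy_numbers))) stop("duplicated function ids")
  if (anyNA(copy_numbers) || any(copy_numbers < 0))
    stop("copy numbers must be non-negative and non-missing")
  if (is.null(rrna_copies)) {
    rrna_copies <- stats::setNames(rep(1, nrow(copy_numbers)),
                                   rownames(copy_numbers))
  }
  missing <- setdiff(rownames(copy_numbers), names(rrna_copies))
  if (length(missing))
    stop("taxa missing 16S copy numbers: ", paste(missing, collapse = ", "))
  rrna_copies <- rrna_copies[rownames(copy_numbers)]
  if (any(rrna_copies <= 0)) stop("16S copy numbers must be > 0")
  structure(list(copy_numbers = copy_numbers, rrna_copies = rrna_copies),
            class = "genome_content")
}

#' @export
print.genome_content <- function(x, ...) {
  cat("Genome-content matrix:", nrow(x$copy_numbers), "taxa x",
      ncol(x$copy_numbers), "gene families\n")
  invisible(x)
}

#' Construct an OTU count table
#'
#' @param counts integer matrix of read counts, taxa in rows, samples in
#'   columns, with dimnames.
#' @param taxonomy optional named character vector of lineage strings per
#'   taxon (names matching rownames of \code{counts}).
#' @param metadata optional data.frame of per-sample metadata with rownames
#'   matching colnames of \code{counts}; conventionally carries
#'   \code{environment} and \code{subsite} columns.
#' @return an object of class \code{count_table}.
#' @export
count_table <- function(counts, taxonomy = NULL, metadata = NULL) {
  counts <- as.matrix(counts)
  # a 0-row table (all taxa filtered out) is legal and has no rownames
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      is.null(colnames(counts)))
    stop("counts must have taxon rownames and sample colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicated taxon ids")
  if (anyDuplicated(colnames(counts))) stop("duplicated sample ids")
  if (anyNA(counts)) stop("counts contain NA")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers")
  storage.mode(counts) <- "double"
  if (!is.null(taxonomy)) {
    taxonomy <- taxonomy[rownames(counts)]
    names(taxonomy) <- rownames(counts)
  }
  if (!is.null(metadata)) {
    if (!all(colnames(counts) %in% rownames(metadata)))
      stop("metadata rownames must cover all sample ids")
    metadata <- metadata[colnames(counts), , drop = FALSE]
  }
  structure(list(counts = counts, taxonomy = taxonomy, metadata = metadata),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("OTU count table:", nrow(x$counts), "taxa x", ncol(x$counts),
      "samples\n")
  invisible(x)
}

#' Extract one sample of a count table as a taxonomic profile
#'
#' @param table a \code{count_table}.
#' @param sample sample id or column index.
#' @param drop_zero drop taxa with zero counts (default TRUE).
#' @return relative-abundance profile (named numeric vector, sum 1).
#' @export
sample_profile <- function(table, sample, drop_zero = TRUE) {
  stopifnot(inherits(table, "count_table"))
  x <- table$counts[, sample]
  if (drop_zero) x <- x[x > 0]
  as_taxonomic_profile(x)
}

#' Construct a gene-family to pathway hierarchy
#'
#' A many-to-many map from gene-family identifiers to pathway identifiers
#' (one row per membership), optionally with a pathway-to-superpathway map.
#'
#' @param mapping data.frame with columns \code{function_id} and
#'   \code{pathway_id}; repeated \code{function_id} rows encode
#'   multi-membership.
#' @param superpathways optional data.frame with columns \code{pathway_id}
#'   and \code{superpathway_id}.
#' @return an object of class \code{pathway_hierarchy}.
#' @export
pathway_hierarchy <- function(mapping, superpathways = NULL) {
  mapping <- as.data.frame(mapping)
  if (!all(c("function_id", "pathway_id") %in% names(mapping)))
    stop("mapping needs columns function_id and pathway_id")
  mapping <- unique(mapping[, c("function_id", "pathway_id")])
  mapping[] <- lapply(mapping, as.character)
  if (nrow(mapping) == 0) stop("empty pathway hierarchy")
  if (!is.null(superpathways)) {
    superpathways <- as.data.frame(superpathways)
    if (!all(c("pathway_id", "superpathway_id") %in% names(superpathways)))
      stop("superpathways needs columns pathway_id and superpathway_id")
    superpathways[] <- lapply(superpathways, as.character)
  }
  structure(list(mapping = mapping, superpathways = superpathways),
            class = "pathway_hierarchy")
}

#' @export
print.pathway_hierarchy <- function(x, ...) {
  cat("Pathway hierarchy:", length(unique(x$mapping$function_id)),
      "gene families ->", length(unique(x$mapping$pathway_id)),
      "pathways\n")
  invisible(x)
}

# internal: check the leaves of a tree cover a set of taxa
check_taxa_on_tree <- function(taxa, tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("taxa absent from tree leaves: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}
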