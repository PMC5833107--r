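#' Read an OTU table from TSV or BIOM-style JSON
#'
#' TSV tables are taxa x samples with a header row of sample ids and taxon
#' ids in the first column; an optional \code{taxonomy} column carries
#' lineage strings. BIOM-style JSON (format version 1, dense or sparse) is
#' read through the biomformat package.
#'
#' @param path file path; format is inferred from the extension
#'   (\code{.biom}/\code{.json} -> BIOM, otherwise TSV) unless given.
#' @param format one of \code{"auto"}, \code{"tsv"}, \code{"biom"}.
#' @param metadata optional data.frame of per-sample metadata (rownames =
#'   sample ids).
#' @return a \code{\link{count_table}}.
#' @export
read_otu_table <- function(path, format = c("auto", "tsv", "biom"),
                           metadata = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(biom|json)$", path, ignore.case = TRUE))
      "biom" else "tsv"
  }
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM files requires the biomformat package")
    b <- biomformat::read_biom(path)
    counts <- as.matrix(biomformat::biom_data(b))
    taxonomy <- NULL
    om <- biomformat::observation_metadata(b)
    if (!is.null(om) && length(om)) {
      tax_strings <- vapply(seq_len(nrow(counts)), function(i) {
        row <- if (is.data.frame(om)) unlist(om[i, ]) else unlist(om[[i]])
        paste(row[!is.na(row) & row != ""], collapse = "; ")
      }, character(1))
      taxonomy <- stats::setNames(tax_strings, rownames(counts))
    }
    return(count_table(counts, taxonomy = taxonomy, metadata = metadata))
  }
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("malformed OTU table: need taxon ids plus samples")
  taxa <- as.character(df[[1]])
  df <- df[, -1, drop = FALSE]
  taxonomy <- NULL
  if ("taxonomy" %in% names(df)) {
    taxonomy <- stats::setNames(as.character(df$taxonomy), taxa)
    df$taxonomy <- NULL
  }
  bad <- !vapply(df, is.numeric, logical(1))
  if (any(bad))
    stop("non-numeric count column(s): ", paste(names(df)[bad], collapse = ", "))
  counts <- as.matrix(df)
  rownames(counts) <- taxa
  count_table(counts, taxonomy = taxonomy, metadata = metadata)
}

#' Write an OTU table as TSV
#'
#' @param table a \code{\link{count_table}}.
#' @param path output path.
#' @param comment optional character vector written as leading
#'   \code{#}-prefixed header lines (parameters, seeds).
#' @export
write_otu_table <- function(table, path, comment = NULL) {
  stopifnot(inherits(table, "count_table"))
  df <- data.frame(taxon_id = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(table$taxonomy)) df$taxonomy <- unname(table$taxonomy)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genome-content matrix from TSV
#'
#' Expects taxa in rows (ids in the first column) and gene families in
#' columns. A column named by \code{rrna_col} (default \code{"rrna_16S"}),
#' when present, supplies 16S copy numbers; otherwise all taxa get 1.
#'
#' @param path TSV path.
#' @param rrna_col name of the 16S copy-number column.
#' @return a \code{\link{genome_content}}.
#' @export
read_genome_content <- function(path, rrna_col = "rrna_16S") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  taxa <- as.character(df[[1]])
  df <- df[, -1, drop = FALSE]
  rrna <- NULL
  if (rrna_col %in% names(df)) {
    rrna <- stats::setNames(as.numeric(df[[rrna_col]]), taxa)
    df[[rrna_col]] <- NULL
  }
  bad <- !vapply(df, is.numeric, logical(1))
  if (any(bad))
    stop("non-numeric copy-number column(s): ",
         paste(names(df)[bad], collapse = ", "))
  m <- as.matrix(df)
  rownames(m) <- taxa
  genome_content(m, rrna)
}

#' Write a genome-content matrix as TSV
#' @param content a \code{\link{genome_content}}.
#' @param path output path.
#' @param comment optional \code{#}-prefixed header lines.
#' @export
write_genome_content <- function(content, path, comment = NULL) {
  stopifnot(inherits(content, "genome_content"))
  df <- data.frame(taxon_id = rownames(content$copy_numbers),
                   rrna_16S = unname(content$rrna_copies),
                   content$copy_numbers, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-family to pathway hierarchy from two-column TSV
#'
#' One row per (function, pathway) membership; repeated function ids encode
#' multi-membership, mirroring how KO-to-pathway maps are distributed.
#'
#' @param path TSV with columns \code{function_id}, \code{pathway_id} and
#'   optionally \code{superpathway_id}.
#' @return a \code{\link{pathway_hierarchy}}.
#' @export
read_pathway_hierarchy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  sp <- NULL
  if ("superpathway_id" %in% names(df))
    sp <- unique(df[, c("pathway_id", "superpathway_id")])
  pathway_hierarchy(df[, c("function_id", "pathway_id")], superpathways = sp)
}

#' Read all inputs of a robustness analysis
#'
#' Convenience wrapper parsing the OTU table, the rooted phylogeny, the
#' genome-content matrix and (optionally) the pathway hierarchy, and
#' cross-checking that profile taxa are covered by the tree leaves and the
#' content matrix.
#'
#' @param otu_table path to OTU table (TSV or BIOM-style JSON).
#' @param tree path to newick tree whose leaves cover the taxa.
#' @param genome_content path to genome-content TSV.
#' @param hierarchy optional path to function-to-pathway TSV.
#' @param metadata optional path to per-sample metadata TSV (first column =
#'   sample id).
#' @return list with elements \code{table}, \code{tree}, \code{content},
#'   \code{hierarchy}.
#' @export
read_inputs <- function(otu_table, tree, genome_content, hierarchy = NULL,
                        metadata = NULL) {
  md <- NULL
  if (!is.null(metadata)) {
    md <- utils::read.delim(metadata, stringsAsFactors = FALSE,
                            comment.char = "#")
    rownames(md) <- as.character(md[[1]])
  }
  table <- read_otu_table(otu_table, metadata = md)
  phy <- ape::read.tree(tree)
  if (is.null(phy)) stop("malformed newick tree: ", tree)
  content <- read_genome_content(genome_content)
  hier <- if (!is.null(hierarchy)) read_pathway_hierarchy(hierarchy) else NULL
  taxa <- rownames(table$counts)
  check_taxa_on_tree(taxa, phy)
  missing <- setdiff(taxa, rownames(content$copy_numbers))
  if (length(missing))
    stop("taxa absent from genome-content matrix: ",
         paste(missing, collapse = ", "))
  list(table = table, tree = phy, content = content, hierarchy = hier)
}

#' Remove chloroplast reads from a count table
#'
#' Drops taxa whose lineage string matches a label (case-insensitive
#' substring, default \code{"chloroplast"}), the standard cleanup for plant
#' chloroplast 16S contamination in OTU tables.
#'
#' @param table a \code{\link{count_table}} with taxonomy labels.
#' @param label substring identifying chloroplast lineages.
#' @return filtered \code{count_table}.
#' @export
filter_chloroplast <- function(table, label = "chloroplast") {
  stopifnot(inherits(table, "count_table"))
  if (is.null(table$taxonomy))
    stop("count table has no taxonomy labels; cannot filter chloroplasts")
  hit <- grepl(label, table$taxonomy, ignore.case = TRUE, fixed = FALSE)
  hit[is.na(hit)] <- FALSE
  if (!any(hit)) return(table)
  if (all(hit)) warning("all taxa matched the chloroplast label")
  count_table(table$counts[!hit, , drop = FALSE],
              taxonomy = table$taxonomy[!hit], metadata = table$metadata)
}

#' Quality-filter samples and rarefy to even depth
#'
#' Removes samples with fewer than \code{min_taxa} non-zero taxa or fewer
#' than \code{min_reads} total reads, then rarefies each retained sample to
#' exactly \code{depth} reads by sampling without replacement
#' (multivariate hypergeometric, via \code{vegan::rrarefy}).
#'
#' @param table a \code{\link{count_table}}.
#' @param min_taxa minimum number of non-zero taxa per sample (default 10).
#' @param min_reads minimum total reads per sample (default 5000).
#' @param depth rarefaction depth (default 5000); must not exceed
#'   \code{min_reads}.
#' @param seed integer RNG seed.
#' @return a \code{count_table} of the retained, rarefied samples, with
#'   attribute \code{removed_samples} naming the dropped samples.
#' @export
qc_filter_and_rarefy <- function(table, min_taxa = 10, min_reads = 5000,
                                 depth = 5000, seed = 1L) {
  stopifnot(inherits(table, "count_table"))
  if (depth > min_reads)
    stop("rarefaction depth (", depth, ") exceeds min_reads (", min_reads, ")")
  totals <- colSums(table$counts)
  richness <- colSums(table$counts > 0)
  keep <- totals >= min_reads & richness >= min_taxa
  removed <- colnames(table$counts)[!keep]
  if (!any(keep)) stop("no samples pass the QC thresholds")
  kept <- table$counts[, keep, drop = FALSE]
  set.seed(seed)
  # counts are validated upstream; silence vegan's are-these-counts heuristic
  rar <- t(suppressWarnings(vegan::rrarefy(t(kept), depth)))
  dimnames(rar) <- dimnames(kept)
  md <- if (!is.null(table$metadata))
    table$metadata[keep, , drop = FALSE] else NULL
  out <- count_table(rar, taxonomy = table$taxonomy, metadata = md)
  attr(out, "removed_samples") <- removed
  out
}

#' Pool bilaterally symmetric body subsites
#'
#' Relabels subsites according to a mapping (e.g. left/right antecubital
#' fossa to a single label) in the sample metadata.
#'
#' @param table a \code{\link{count_table}} with metadata containing
#'   \code{subsite_col}.
#' @param mapping named character vector: names are original subsite labels,
#'   values the pooled label.
#' @param subsite_col metadata column holding subsite labels.
#' @return \code{count_table} with relabeled metadata.
#' @export
pool_subsites <- function(table, mapping, subsite_col = "subsite") {
  stopifnot(inherits(table, "count_table"))
  if (is.null(table$metadata) || !subsite_col %in% names(table$metadata))
    stop("metadata with a '", subsite_col, "' column is required")
  lab <- as.character(table$metadata[[subsite_col]])
  hit <- lab %in% names(mapping)
  lab[hit] <- unname(mapping[lab[hit]])
  table$metadata[[subsite_col]] <- lab
  table
}

#' Subsample a profile to a fixed number of OTUs
#'
#' Retains exactly \code{k} taxa by weighted sampling without replacement,
#' with retention probability proportional to relative abundance, then
#' renormalizes. Used as a diversity control: it preserves the shape of the
#' abundance distribution while equalizing richness across communities.
#'
#' @param profile taxonomic profile (named numeric, sum 1).
#' @param k number of OTUs to retain (default 10).
#' @param seed integer RNG seed.
#' @return taxonomic profile over the k retained taxa, sum 1.
#' @export
subsample_otus <- function(profile, k = 10, seed = 1L) {
  profile <- as_taxonomic_profile(profile)
  nz <- profile[profile > 0]
  if (length(nz) < k)
    stop("profile has ", length(nz), " non-zero taxa; need at least ", k)
  set.seed(seed)
  keep <- sample(names(nz), size = k, replace = FALSE, prob = nz)
  as_taxonomic_profile(nz[keep])
}
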