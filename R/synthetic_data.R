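#' Generate a random rooted tree over named taxa
#'
#' Random bifurcating topology with exponential branch lengths; leaf names
#' are the taxon ids used throughout the synthetic scenario.
#'
#' @param n_taxa number of leaves (>= 2).
#' @param seed integer RNG seed.
#' @param taxon_ids optional leaf names (default \code{taxon_1 ...}).
#' @return rooted \code{phylo} tree.
#' @export
generate_tree <- function(n_taxa, seed = 1L,
                          taxon_ids = paste0("taxon_", seq_len(n_taxa))) {
  if (n_taxa < 2) stop("need at least 2 taxa for a tree")
  stopifnot(length(taxon_ids) == n_taxa)
  set.seed(seed)
  tree <- ape::rtree(n_taxa, rooted = TRUE, br = stats::rexp)
  tree$tip.label <- taxon_ids
  tree
}

#' Generate a genome-content matrix with tunable redundancy
#'
#' A core/accessory architecture spanning the redundancy contrast: one
#' shared single-copy marker function, a core of
#' \code{floor(redundancy * (n_functions - 1))} functions present in every
#' genome, and the remaining accessory functions assigned to single taxa
#' round-robin. \code{redundancy = 1} yields identical genomes (maximal
#' functional overlap); \code{redundancy = 0} yields pairwise-disjoint
#' repertoires over the minimal shared marker. Copy numbers are drawn from
#' \{1, 2, 3\} and 16S copy numbers from \{1, ..., 5\} to exercise
#' copy-number normalization.
#'
#' @param n_taxa number of genomes.
#' @param n_functions number of gene families (>= 2).
#' @param redundancy shared-core fraction in [0, 1].
#' @param seed integer RNG seed.
#' @param taxon_ids optional taxon names.
#' @return a \code{\link{genome_content}}.
#' @export
generate_genome_content <- function(n_taxa, n_functions, redundancy,
                                    seed = 1L,
                                    taxon_ids = paste0("taxon_",
                                                       seq_len(n_taxa))) {
  stopifnot(n_taxa >= 1, n_functions >= 2,
            redundancy >= 0, redundancy <= 1)
  set.seed(seed)
  fun_ids <- c("marker", paste0("fn_", seq_len(n_functions - 1)))
  n_core <- floor(redundancy * (n_functions - 1))
  cn <- matrix(0, n_taxa, n_functions,
               dimnames = list(taxon_ids, fun_ids))
  cn[, "marker"] <- 1
  core_cols <- if (n_core > 0) 1 + seq_len(n_core) else integer(0)
  # the core is one shared genome: copy number varies by function, not taxon
  if (length(core_cols))
    cn[, core_cols] <- rep(sample(1:3, length(core_cols), replace = TRUE),
                           each = n_taxa)
  acc_cols <- setdiff(seq_len(n_functions)[-1], core_cols)
  if (length(acc_cols)) {
    owner <- rep_len(seq_len(n_taxa), length(acc_cols))
    cn[cbind(owner, acc_cols)] <- sample(1:3, length(acc_cols),
                                         replace = TRUE)
  }
  rrna <- stats::setNames(sample(1:5, n_taxa, replace = TRUE), taxon_ids)
  genome_content(cn, rrna)
}

#' Generate a long-tailed community abundance profile
#'
#' Relative abundances proportional to lognormal(0, sigma) draws — the
#' standard long-tailed shape of microbial relative-abundance
#' distributions. \code{sigma = 0} gives the uniform profile.
#'
#' @param n_taxa number of taxa.
#' @param sigma lognormal shape parameter (default 1).
#' @param seed integer RNG seed.
#' @param taxon_ids optional taxon names.
#' @return taxonomic profile (named numeric, sum 1).
#' @export
generate_community <- function(n_taxa, sigma = 1, seed = 1L,
                               taxon_ids = paste0("taxon_",
                                                  seq_len(n_taxa))) {
  stopifnot(n_taxa >= 1, sigma >= 0)
  set.seed(seed)
  x <- stats::rlnorm(n_taxa, meanlog = 0, sdlog = sigma)
  as_taxonomic_profile(stats::setNames(x, taxon_ids))
}

#' Generate a complete synthetic scenario
#'
#' Bundles a tree, a genome-content matrix at the requested redundancy, and
#' a set of communities over the same taxa, so every stage of the
#' robustness workflow can run without external reference data. Per-part
#' seeds are derived deterministically from the scenario seed.
#'
#' @param n_taxa taxa per community (default 40).
#' @param n_functions gene families (default 200).
#' @param redundancy shared-core fraction in [0, 1] (default 0.5).
#' @param n_communities number of community profiles (default 1).
#' @param sigma lognormal abundance shape (default 1).
#' @param seed integer RNG seed.
#' @return list with \code{tree}, \code{content}, \code{communities} (list
#'   of taxonomic profiles), \code{config}.
#' @export
generate_scenario <- function(n_taxa = 40, n_functions = 200,
                              redundancy = 0.5, n_communities = 1,
                              sigma = 1, seed = 1L) {
  base <- as.integer(seed) %% 100000L
  tree <- generate_tree(n_taxa, seed = base + 1L)
  content <- generate_genome_content(n_taxa, n_functions, redundancy,
                                     seed = base + 2L)
  communities <- lapply(seq_len(n_communities), function(i)
    generate_community(n_taxa, sigma = sigma, seed = base + 100L + i))
  names(communities) <- paste0("community_", seq_len(n_communities))
  list(tree = tree, content = content, communities = communities,
       config = list(n_taxa = n_taxa, n_functions = n_functions,
                     redundancy = redundancy, sigma = sigma, seed = seed))
}
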