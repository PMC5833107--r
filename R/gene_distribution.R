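#' Collapse a genome-content matrix to pathway-level content
#'
#' Applies the even-split rule to the columns of the copy-number matrix:
#' a gene family belonging to k pathways contributes 1/k of its copy number
#' to each, so each taxon's total content is conserved. Gene-distribution
#' features can then be computed at the same functional level as fitted
#' profiles.
#'
#' @param content a \code{\link{genome_content}}.
#' @param hierarchy a \code{\link{pathway_hierarchy}}.
#' @param level \code{"pathway"} or \code{"superpathway"}.
#' @return a \code{genome_content} whose columns are pathways.
#' @export
content_to_pathways <- function(content, hierarchy,
                                level = c("pathway", "superpathway")) {
  level <- match.arg(level)
  stopifnot(inherits(content, "genome_content"),
            inherits(hierarchy, "pathway_hierarchy"))
  cn <- content$copy_numbers
  map <- hierarchy$mapping
  if (level == "superpathway") {
    if (is.null(hierarchy$superpathways))
      stop("hierarchy has no superpathway map")
    sp <- hierarchy$superpathways
    map <- merge(map, sp, by = "pathway_id")
    # even split function -> pathways, then pathway -> superpathways
    k_path <- table(hierarchy$mapping$function_id)
    k_super <- table(sp$pathway_id)
    map$w <- 1 / (as.numeric(k_path[map$function_id]) *
                    as.numeric(k_super[map$pathway_id]))
    map$group <- map$superpathway_id
  } else {
    k_path <- table(map$function_id)
    map$w <- 1 / as.numeric(k_path[map$function_id])
    map$group <- map$pathway_id
  }
  map <- map[map$function_id %in% colnames(cn), , drop = FALSE]
  if (!nrow(map)) stop("no content functions appear in the hierarchy")
  agg <- stats::aggregate(w ~ function_id + group, data = map, FUN = sum)
  groups <- sort(unique(agg$group))
  W <- matrix(0, ncol(cn), length(groups),
              dimnames = list(colnames(cn), groups))
  W[cbind(agg$function_id, agg$group)] <- agg$w
  genome_content(cn %*% W, content$rrna_copies)
}

# internal: restrict content to the present (non-zero) taxa of a profile
present_content <- function(profile, content) {
  profile <- as_taxonomic_profile(profile)
  profile <- profile[profile > 0]
  missing <- setdiff(names(profile), rownames(content$copy_numbers))
  if (length(missing))
    stop("taxa missing from genome-content matrix: ",
         paste(missing, collapse = ", "))
  list(s = profile,
       cn = content$copy_numbers[names(profile), , drop = FALSE])
}

#' Functional redundancy of one function in a community
#'
#' The evenness (Shannon entropy) of per-species contributions to a
#' function's abundance, where species i contributes its abundance times
#' its genomic copy number, \eqn{s_i c_i}. A function carried by a single
#' species scores 0; one to which k species contribute equally scores
#' \eqn{\ln k}. With \code{mode = "evenness"} (default) contributions are
#' normalized to proportions before the entropy; \code{mode = "literal"}
#' evaluates \eqn{-\sum (s_i c_i) \ln(s_i c_i)} on the raw products.
#'
#' @param function_id column name in the content matrix.
#' @param profile taxonomic profile (species abundances \eqn{s_i}).
#' @param content a \code{\link{genome_content}}.
#' @param mode \code{"evenness"} or \code{"literal"}.
#' @return non-negative redundancy (in [0, ln N] for \code{"evenness"},
#'   N = number of encoding species).
#' @export
functional_redundancy <- function(function_id, profile, content,
                                  mode = c("evenness", "literal")) {
  mode <- match.arg(mode)
  pc <- present_content(profile, content)
  if (!function_id %in% colnames(pc$cn))
    stop("unknown function id: ", function_id)
  x <- pc$s * pc$cn[, function_id]
  x <- x[x > 0]
  if (!length(x))
    stop("function ", function_id, " absent from all present genomes")
  if (mode == "evenness") x <- x / sum(x)
  -sum(x * log(x))
}

#' Average functional redundancy of a community
#'
#' The mean of per-function redundancies over all functions present in the
#' community, weighted by each function's relative abundance in the
#' community functional profile (so abundant functions dominate the
#' average).
#'
#' @inheritParams functional_redundancy
#' @return weighted average redundancy.
#' @export
average_functional_redundancy <- function(profile, content,
                                          mode = c("evenness", "literal")) {
  mode <- match.arg(mode)
  pc <- present_content(profile, content)
  contrib <- pc$s * pc$cn                  # species x function contributions
  totals <- colSums(contrib)
  present <- totals > 0
  if (!any(present)) stop("no functions present in the community")
  red <- apply(contrib[, present, drop = FALSE], 2, function(x) {
    x <- x[x > 0]
    if (mode == "evenness") x <- x / sum(x)
    -sum(x * log(x))
  })
  w <- totals[present] / sum(totals[present])
  sum(w * red)
}

#' Functional similarity between two genomes
#'
#' Cosine similarity of two genome-content vectors: how well two species
#' could compensate functionally for each other (1 = identical gene
#' repertoires up to scale, 0 = disjoint).
#'
#' @param genome_a,genome_b numeric copy-number vectors over the same
#'   functions.
#' @return similarity in [0, 1].
#' @export
functional_similarity <- function(genome_a, genome_b) {
  na <- sqrt(sum(genome_a^2)); nb <- sqrt(sum(genome_b^2))
  if (na == 0 || nb == 0) stop("empty genome: no encoded functions")
  sum(genome_a * genome_b) / (na * nb)
}

#' Average pairwise functional similarity of a community
#'
#' Unweighted mean cosine similarity over all unordered pairs of present
#' species (self-pairs excluded).
#'
#' @inheritParams functional_redundancy
#' @return similarity in [0, 1]; NA (with a warning) for a single-species
#'   community.
#' @export
average_functional_similarity <- function(profile, content) {
  pc <- present_content(profile, content)
  n <- nrow(pc$cn)
  if (n < 2) {
    warning("fewer than 2 present species; average similarity undefined")
    return(NA_real_)
  }
  norms <- sqrt(rowSums(pc$cn^2))
  if (any(norms == 0)) stop("present species with empty genome")
  unit <- pc$cn / norms
  S <- tcrossprod(unit)
  mean(S[upper.tri(S)])
}

#' Genome-size features of a community
#'
#' Genome size of a species is the total abundance of the functions it
#' encodes (the sum of its copy numbers). Returns the unweighted average
#' over present species and the variability as the coefficient of
#' variation (population standard deviation over mean).
#'
#' @inheritParams functional_redundancy
#' @return list with \code{average} and \code{variability} (NA, with a
#'   warning, for single-species communities).
#' @export
genome_size_features <- function(profile, content) {
  pc <- present_content(profile, content)
  sizes <- rowSums(pc$cn)
  avg <- mean(sizes)
  if (length(sizes) < 2) {
    warning("fewer than 2 present species; genome-size variability undefined")
    return(list(average = avg, variability = NA_real_))
  }
  pop_sd <- sqrt(mean((sizes - avg)^2))
  list(average = avg, variability = pop_sd / avg)
}

#' Unique-function abundance of a community
#'
#' Total relative abundance, in the community functional profile, of
#' functions encoded by exactly one present species (each such function may
#' come from a different species).
#'
#' @inheritParams functional_redundancy
#' @return value in [0, 1].
#' @export
unique_function_abundance <- function(profile, content) {
  pc <- present_content(profile, content)
  f <- colSums(pc$s * pc$cn)
  if (sum(f) == 0) stop("empty functional profile")
  w <- f / sum(f)
  encoders <- colSums(pc$cn > 0)
  sum(w[encoders == 1])
}

#' The five gene-distribution features of a community
#'
#' @inheritParams functional_redundancy
#' @param hierarchy optional \code{\link{pathway_hierarchy}}; when given,
#'   the content matrix is first collapsed to \code{level} so features are
#'   computed at the same functional level as fitted profiles.
#' @param level functional level used when \code{hierarchy} is given.
#' @return named numeric vector: \code{avg_functional_redundancy},
#'   \code{avg_functional_similarity}, \code{avg_genome_size},
#'   \code{genome_size_variability}, \code{unique_function_abundance}.
#' @export
gdf_vector <- function(profile, content, hierarchy = NULL,
                       level = c("pathway", "superpathway"),
                       mode = c("evenness", "literal")) {
  mode <- match.arg(mode)
  if (!is.null(hierarchy))
    content <- content_to_pathways(content, hierarchy, match.arg(level))
  gs <- suppressWarnings(genome_size_features(profile, content))
  c(avg_functional_redundancy =
      average_functional_redundancy(profile, content, mode),
    avg_functional_similarity =
      suppressWarnings(average_functional_similarity(profile, content)),
    avg_genome_size = gs$average,
    genome_size_variability = gs$variability,
    unique_function_abundance = unique_function_abundance(profile, content))
}

#' PCA of gene-distribution features across communities
#'
#' Standardizes (z-scores) each feature and projects communities onto
#' principal components. Constant features are dropped with a warning.
#'
#' @param gdf_table numeric matrix or data.frame, communities in rows,
#'   features in columns (e.g. rbind of \code{\link{gdf_vector}} outputs).
#' @return list with \code{scores}, \code{loadings},
#'   \code{explained_variance} (fractions summing to 1).
#' @export
gdf_pca <- function(gdf_table) {
  m <- as.matrix(gdf_table)
  if (nrow(m) < 3) stop("need at least 3 communities for a PCA")
  sds <- apply(m, 2, stats::sd)
  const <- sds == 0 | is.na(sds)
  if (any(const)) {
    warning("dropping constant feature(s): ",
            paste(colnames(m)[const], collapse = ", "))
    m <- m[, !const, drop = FALSE]
  }
  p <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  list(scores = p$x, loadings = p$rotation,
       explained_variance = p$sdev^2 / sum(p$sdev^2))
}
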