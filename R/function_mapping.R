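#' Correct a taxonomic profile for 16S copy-number variation
#'
#' Divides each taxon's relative abundance by its 16S rRNA gene copy number
#' and renormalizes, converting read-based abundances into genome-equivalent
#' abundances (the standard first step of genome-content-based functional
#' prediction).
#'
#' @param profile taxonomic profile (named numeric, sum 1).
#' @param content a \code{\link{genome_content}} carrying
#'   \code{rrna_copies} for every profile taxon.
#' @param renormalize renormalize to sum 1 after division (default TRUE).
#'   Downstream shift measures are scale-invariant, so this only affects the
#'   reported scale.
#' @return corrected taxonomic profile.
#' @export
normalize_by_copy_number <- function(profile, content, renormalize = TRUE) {
  profile <- as_taxonomic_profile(profile)
  stopifnot(inherits(content, "genome_content"))
  missing <- setdiff(names(profile), names(content$rrna_copies))
  if (length(missing))
    stop("taxa missing from genome-content matrix: ",
         paste(missing, collapse = ", "))
  out <- profile / content$rrna_copies[names(profile)]
  as_taxonomic_profile(out, renormalize = renormalize)
}

#' Predict a community functional profile from genome content
#'
#' The linear taxa-to-function model: the abundance of gene family j is the
#' abundance-weighted sum of its genomic copy number over community members,
#' \eqn{F_j = \sum_i a_i c_{ij}}. With \code{correct_16S = TRUE} the profile
#' is first passed through \code{\link{normalize_by_copy_number}}.
#'
#' @param profile taxonomic profile.
#' @param content a \code{\link{genome_content}} whose taxa cover the
#'   profile.
#' @param correct_16S apply 16S copy-number correction first (default TRUE).
#' @param post_normalization \code{"sum"} scales the result to sum 1,
#'   \code{"none"} returns raw average copy numbers, \code{"median_set"}
#'   divides by the median abundance of the gene families in
#'   \code{reference_functions} (e.g. universal single-copy families).
#' @param reference_functions function ids used by \code{"median_set"}.
#' @return named numeric vector of gene-family abundances (a functional
#'   profile).
#' @examples
#' cn <- matrix(c(2, 0, 0, 2), 2, 2,
#'              dimnames = list(c("A", "B"), c("F1", "F2")))
#' gc <- genome_content(cn)
#' predict_functional_profile(c(A = 0.5, B = 0.5), gc,
#'                            post_normalization = "none")
#' @export
predict_functional_profile <- function(profile, content, correct_16S = TRUE,
                                       post_normalization = c("sum", "none",
                                                              "median_set"),
                                       reference_functions = NULL) {
  post_normalization <- match.arg(post_normalization)
  profile <- as_taxonomic_profile(profile)
  stopifnot(inherits(content, "genome_content"))
  missing <- setdiff(names(profile), rownames(content$copy_numbers))
  if (length(missing))
    stop("taxa missing from genome-content matrix: ",
         paste(missing, collapse = ", "))
  if (correct_16S) profile <- normalize_by_copy_number(profile, content)
  f <- drop(crossprod(content$copy_numbers[names(profile), , drop = FALSE],
                      profile))
  if (all(f == 0)) stop("functional profile is identically zero")
  switch(post_normalization,
         none = f,
         sum = f / sum(f),
         median_set = {
           if (is.null(reference_functions))
             stop("median_set normalization needs reference_functions")
           ref <- f[intersect(reference_functions, names(f))]
           if (!length(ref) || stats::median(ref) <= 0)
             stop("reference gene families absent or zero in the profile")
           f / stats::median(ref)
         })
}

#' Summarize a gene-family profile to pathway level
#'
#' Each gene family's abundance is split evenly across all pathways that
#' contain it (a family in k pathways contributes abundance/k to each), so
#' total mapped abundance is conserved. Families absent from the hierarchy
#' are dropped or collected into an \code{"unmapped"} bin.
#'
#' @param profile functional profile (named numeric over gene families).
#' @param hierarchy a \code{\link{pathway_hierarchy}}.
#' @param level \code{"pathway"} or \code{"superpathway"} (the latter
#'   re-applies the even split along the pathway-to-superpathway map).
#' @param unmapped \code{"drop"} or \code{"bin"}.
#' @return functional profile over pathways.
#' @export
summarize_to_pathways <- function(profile, hierarchy,
                                  level = c("pathway", "superpathway"),
                                  unmapped = c("drop", "bin")) {
  level <- match.arg(level)
  unmapped <- match.arg(unmapped)
  stopifnot(inherits(hierarchy, "pathway_hierarchy"))
  map <- hierarchy$mapping
  out <- even_split(profile, map$function_id, map$pathway_id, unmapped)
  if (level == "superpathway") {
    if (is.null(hierarchy$superpathways))
      stop("hierarchy has no superpathway map")
    sp <- hierarchy$superpathways
    keep <- names(out) != "unmapped"
    binned <- out[!keep]
    out <- even_split(out[keep], sp$pathway_id, sp$superpathway_id, unmapped)
    if (length(binned))
      out["unmapped"] <- sum(binned, out["unmapped"], na.rm = TRUE)
  }
  out
}

# internal: split each element of x evenly over its groups
even_split <- function(x, from, to, unmapped) {
  k <- table(from)[names(x)]            # memberships per id, NA if unmapped
  hit <- !is.na(k)
  idx <- from %in% names(x)
  contrib <- x[from[idx]] / as.numeric(k[from[idx]])
  out <- tapply(contrib, to[idx], sum)
  out <- stats::setNames(as.numeric(out), names(out))
  if (unmapped == "bin" && any(!hit))
    out["unmapped"] <- sum(x[!hit])
  out[sort(names(out))]
}
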