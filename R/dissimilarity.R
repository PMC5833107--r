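#' Precompute the branch structure used by weighted UniFrac
#'
#' Builds, once per tree, the sparse branch-by-leaf incidence matrix (which
#' leaves descend from each branch), the branch lengths, and the
#' root-to-leaf path lengths. Perturbation sweeps evaluate UniFrac against
#' thousands of perturbed profiles of the same community, so this
#' precomputation turns each evaluation into one sparse matrix product.
#'
#' @param tree rooted \code{phylo} tree with non-negative branch lengths.
#' @return object of class \code{unifrac_engine}.
#' @export
unifrac_engine <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  ntip <- length(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", ntip + tree$Nnode)
  desc[seq_len(ntip)] <- as.list(seq_len(ntip))
  for (e in seq_len(nrow(post$edge))) {
    par <- post$edge[e, 1]; chi <- post$edge[e, 2]
    desc[[par]] <- c(desc[[par]], desc[[chi]])
  }
  tips_per_edge <- desc[post$edge[, 2]]
  lens <- lengths(tips_per_edge)
  inc <- Matrix::sparseMatrix(i = rep(seq_along(tips_per_edge), lens),
                              j = unlist(tips_per_edge), x = 1,
                              dims = c(nrow(post$edge), ntip))
  depths <- ape::node.depth.edgelength(tree)[seq_len(ntip)]
  names(depths) <- tree$tip.label
  structure(list(incidence = inc, branch_lengths = post$edge.length,
                 leaf_depths = depths, tip_labels = tree$tip.label),
            class = "unifrac_engine")
}

# internal: place a profile (or taxa x K matrix) onto the engine's leaves
place_on_leaves <- function(x, engine) {
  if (is.matrix(x)) {
    check_taxa_on_tree(rownames(x), structure(
      list(tip.label = engine$tip_labels), class = "phylo"))
    out <- matrix(0, length(engine$tip_labels), ncol(x),
                  dimnames = list(engine$tip_labels, colnames(x)))
    out[rownames(x), ] <- x
  } else {
    check_taxa_on_tree(names(x), structure(
      list(tip.label = engine$tip_labels), class = "phylo"))
    out <- stats::setNames(numeric(length(engine$tip_labels)),
                           engine$tip_labels)
    out[names(x)] <- x
  }
  out
}

#' Weighted UniFrac dissimilarity between two communities
#'
#' The phylogeny-aware perturbation-magnitude metric: for each branch, the
#' absolute difference between the fractions of the two communities
#' descending from it, weighted by branch length and summed. The normalized
#' variant divides by the abundance-weighted root-to-leaf path lengths,
#' \eqn{\sum_j d_j (p_j + q_j)}, bounding the value in [0, 1].
#'
#' @param p,q taxonomic profiles (named numeric, sum 1) whose taxa are
#'   leaves of the tree.
#' @param tree rooted \code{phylo} tree, or a prebuilt
#'   \code{\link{unifrac_engine}}.
#' @param normalized return the normalized variant (default TRUE).
#' @return non-negative dissimilarity; 0 iff the two profiles place
#'   identical abundance on every leaf.
#' @export
weighted_unifrac <- function(p, q, tree, normalized = TRUE) {
  engine <- if (inherits(tree, "unifrac_engine")) tree else unifrac_engine(tree)
  p <- place_on_leaves(as_taxonomic_profile(p), engine)
  q <- place_on_leaves(as_taxonomic_profile(q), engine)
  a <- as.numeric(engine$incidence %*% p)
  b <- as.numeric(engine$incidence %*% q)
  raw <- sum(engine$branch_lengths * abs(a - b))
  if (!normalized) return(raw)
  denom <- sum(engine$leaf_depths * (p + q))
  if (denom == 0) return(0)
  raw / denom
}

#' Weighted UniFrac of many profiles against one reference
#'
#' Vectorized form used on perturbation sets: one sparse product gives the
#' per-branch mass of every profile at once.
#'
#' @param P taxa x K matrix of relative-abundance columns (each sums to 1).
#' @param q reference taxonomic profile.
#' @param tree rooted \code{phylo} or \code{\link{unifrac_engine}}.
#' @param normalized as in \code{\link{weighted_unifrac}}.
#' @return numeric vector of K dissimilarities.
#' @export
weighted_unifrac_many <- function(P, q, tree, normalized = TRUE) {
  engine <- if (inherits(tree, "unifrac_engine")) tree else unifrac_engine(tree)
  P <- place_on_leaves(P, engine)
  q <- place_on_leaves(as_taxonomic_profile(q), engine)
  A <- engine$incidence %*% P
  b <- as.numeric(engine$incidence %*% q)
  raw <- as.numeric(engine$branch_lengths %*% abs(A - b))
  if (!normalized) return(raw)
  denom <- as.numeric(engine$leaf_depths %*% P) +
    sum(engine$leaf_depths * q)
  ifelse(denom == 0, 0, raw / denom)
}

#' Cosine dissimilarity between two functional profiles
#'
#' \eqn{1 - \sum_j a_j b_j / (\|a\| \|b\|)}; 0 for parallel profiles, 1 for
#' orthogonal ones, invariant to positive rescaling of either profile.
#' Named profiles are aligned on the union of their identifiers with
#' implicit zeros.
#'
#' @param f1,f2 functional profiles (numeric vectors; if named, aligned by
#'   name).
#' @return dissimilarity in [0, 1] for non-negative profiles.
#' @export
cosine_dissimilarity <- function(f1, f2) {
  if (!is.null(names(f1)) && !is.null(names(f2))) {
    ids <- union(names(f1), names(f2))
    a <- stats::setNames(numeric(length(ids)), ids); a[names(f1)] <- f1
    b <- stats::setNames(numeric(length(ids)), ids); b[names(f2)] <- f2
  } else {
    if (length(f1) != length(f2))
      stop("unnamed profiles must have equal length")
    a <- f1; b <- f2
  }
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine dissimilarity undefined for a zero profile")
  max(0, 1 - sum(a * b) / (na * nb))
}

# internal: cosine dissimilarity of each column of F against f0 (aligned)
cosine_dissimilarity_many <- function(F_mat, f0) {
  n0 <- sqrt(sum(f0^2))
  if (n0 == 0) stop("zero reference profile")
  dots <- as.numeric(f0 %*% F_mat)
  norms <- sqrt(colSums(F_mat^2))
  if (any(norms == 0)) stop("zero profile column")
  pmax(0, 1 - dots / (n0 * norms))
}

#' Relative change in the abundance of a single function
#'
#' \eqn{|f_{pert} - f_{orig}| / f_{orig}}, the direction-free functional
#' shift used for function-specific response curves. Entries with zero
#' original abundance are returned as NA with a warning (such records are
#' excluded from fitting).
#'
#' @param f_orig,f_pert original and perturbed abundances (vectorized).
#' @return non-negative relative shifts, NA where \code{f_orig} is 0.
#' @export
relative_function_shift <- function(f_orig, f_pert) {
  out <- abs(f_pert - f_orig) / f_orig
  zero <- f_orig == 0
  if (any(zero)) {
    warning(sum(zero), " record(s) with zero original abundance excluded")
    out[zero] <- NA_real_
  }
  out
}

#' Log ratio of functional to taxonomic dissimilarity
#'
#' For a pair of communities observed with both taxonomic and functional
#' profiles: \eqn{\ln(\mathrm{cosine~dissimilarity} / \mathrm{weighted~UniFrac})}.
#' Low values indicate the functional profiles differ less than the
#' taxonomic profiles do — the empirical signature of taxa-function
#' robustness in paired real communities.
#'
#' @param tax1,tax2 taxonomic profiles of the pair.
#' @param fun1,fun2 functional profiles of the pair (e.g.
#'   metagenome-derived).
#' @param tree rooted \code{phylo} or \code{\link{unifrac_engine}}.
#' @param normalized UniFrac variant flag.
#' @return list with \code{t} (weighted UniFrac), \code{f} (cosine
#'   dissimilarity) and \code{log_ratio} (\code{NA}, with a warning, when
#'   the functional dissimilarity is zero).
#' @export
dissimilarity_ratio <- function(tax1, tax2, fun1, fun2, tree,
                                normalized = TRUE) {
  t_val <- weighted_unifrac(tax1, tax2, tree, normalized = normalized)
  if (t_val == 0) stop("zero taxonomic dissimilarity; ratio undefined")
  f_val <- cosine_dissimilarity(fun1, fun2)
  if (f_val == 0) {
    warning("zero functional dissimilarity; pair flagged, log ratio NA")
    return(list(t = t_val, f = f_val, log_ratio = NA_real_))
  }
  list(t = t_val, f = f_val, log_ratio = log(f_val / t_val))
}
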