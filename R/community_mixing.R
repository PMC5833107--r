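#' Mix two communities at a given fraction
#'
#' Constructs the convex combination of two communities' taxonomic and
#' functional profiles: at mixing fraction m, taxon i has abundance
#' \eqn{a_i (1 - m) + b_i m} and function j has abundance
#' \eqn{c_j (1 - m) + d_j m}. Profiles are aligned on the union of their
#' identifiers with implicit zeros; no renormalization is applied (a convex
#' combination of profiles summing to 1 sums to 1).
#'
#' @param original,mixin lists with elements \code{tax} (taxonomic profile)
#'   and optionally \code{fun} (functional profile); bare vectors are
#'   treated as taxonomic profiles.
#' @param m mixing fraction in [0, 1]; 0 reproduces the original, 1 the
#'   mixin.
#' @return list with \code{m}, \code{tax}, and \code{fun} (NULL when either
#'   input lacks a functional profile).
#' @export
mix_communities <- function(original, mixin, m) {
  if (m < 0 || m > 1) stop("mixing fraction must lie in [0, 1]")
  orig <- if (is.list(original)) original else list(tax = original)
  mixi <- if (is.list(mixin)) mixin else list(tax = mixin)
  blend <- function(a, b) {
    ids <- union(names(a), names(b))
    av <- stats::setNames(numeric(length(ids)), ids); av[names(a)] <- a
    bv <- stats::setNames(numeric(length(ids)), ids); bv[names(b)] <- b
    av * (1 - m) + bv * m
  }
  tax <- blend(as_taxonomic_profile(orig$tax), as_taxonomic_profile(mixi$tax))
  fun <- if (!is.null(orig$fun) && !is.null(mixi$fun))
    blend(orig$fun, mixi$fun) else NULL
  list(m = m, tax = tax, fun = fun)
}

#' Find the mixing fraction achieving a target taxonomic distance
#'
#' Binary search on m in [0, 1] for the fraction at which the mixed
#' community sits at weighted UniFrac distance \code{target_t} from the
#' original, to within \code{tol}. The distance is non-decreasing in m
#' (verified empirically as a package property); if a bracket violation is
#' nevertheless detected, the search falls back to a fine grid scan with a
#' warning.
#'
#' @param original,mixin taxonomic profiles (or lists as in
#'   \code{\link{mix_communities}}).
#' @param tree rooted \code{phylo} or \code{\link{unifrac_engine}}.
#' @param target_t desired weighted UniFrac distance; must not exceed the
#'   m = 1 distance.
#' @param tol distance tolerance (default 1e-9).
#' @param max_iter maximum bisection steps (default 200).
#' @param normalized UniFrac variant flag.
#' @return mixing fraction m with
#'   \code{|unifrac(original, mix(m)) - target_t| <= tol}.
#' @export
find_mixing_fraction <- function(original, mixin, tree, target_t,
                                 tol = 1e-9, max_iter = 200,
                                 normalized = TRUE) {
  engine <- if (inherits(tree, "unifrac_engine")) tree else unifrac_engine(tree)
  orig_tax <- if (is.list(original)) original$tax else original
  dist_at <- function(m)
    weighted_unifrac(mix_communities(original, mixin, m)$tax, orig_tax,
                     engine, normalized = normalized)
  if (target_t < 0) stop("target_t must be non-negative")
  if (target_t <= tol) return(0)
  d_max <- dist_at(1)
  if (target_t > d_max + tol)
    stop("unreachable target: maximum attainable weighted UniFrac is ",
         signif(d_max, 6))
  lo <- 0; hi <- 1
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    d <- dist_at(mid)
    if (abs(d - target_t) <= tol) return(mid)
    if (d < target_t) lo <- mid else hi <- mid
  }
  # bisection exhausted without convergence: monotonicity assumption failed
  warning("binary search did not converge; falling back to grid scan")
  grid <- seq(0, 1, by = 1e-6)
  d <- vapply(grid, dist_at, numeric(1))
  grid[which.min(abs(d - target_t))]
}

#' Fit a response curve from mixed-community perturbations
#'
#' For each target taxonomic distance on the grid, finds the mixing
#' fraction achieving it, forms the mixed community, and records the cosine
#' dissimilarity between the mixed and original functional profiles; the
#' resulting (t, f) records are fitted with the standard log-log response
#' curve. Grid points beyond the pair's maximum attainable distance are
#' dropped with a warning. Functional profiles are taken from the supplied
#' pair members when present (e.g. metagenome-derived) and otherwise
#' predicted from genome content.
#'
#' @param original,mixin lists with \code{tax} and optionally \code{fun}.
#' @param tree rooted \code{phylo} or \code{\link{unifrac_engine}}.
#' @param t_grid target weighted UniFrac distances (default 0.01 to 0.10 by
#'   0.01).
#' @param content optional \code{\link{genome_content}} used to predict
#'   functional profiles when the pair carries none.
#' @param tol binary-search tolerance.
#' @param normalized UniFrac variant flag.
#' @return list with \code{records} (data.frame of m, t, f) and
#'   \code{curve} (a \code{response_curve}).
#' @export
mixing_based_curve <- function(original, mixin, tree,
                               t_grid = seq(0.01, 0.10, by = 0.01),
                               content = NULL, tol = 1e-9,
                               normalized = TRUE) {
  engine <- if (inherits(tree, "unifrac_engine")) tree else unifrac_engine(tree)
  orig <- if (is.list(original)) original else list(tax = original)
  mixi <- if (is.list(mixin)) mixin else list(tax = mixin)
  if (is.null(orig$fun) || is.null(mixi$fun)) {
    if (is.null(content))
      stop("pair carries no functional profiles and no genome content given")
    orig$fun <- predict_functional_profile(orig$tax, content)
    mixi$fun <- predict_functional_profile(mixi$tax, content)
  }
  d_max <- weighted_unifrac(orig$tax, mixi$tax, engine,
                            normalized = normalized)
  if (d_max <= tol) {
    warning("pair members are phylogenetically identical; curve unfittable")
    return(list(records = data.frame(m = numeric(0), t = numeric(0),
                                     f = numeric(0)),
                curve = NULL))
  }
  reachable <- t_grid <= d_max + tol
  if (!all(reachable))
    warning(sum(!reachable), " grid point(s) beyond the attainable distance ",
            signif(d_max, 6), " dropped")
  t_grid <- t_grid[reachable]
  if (length(t_grid) < 2)
    stop("fewer than 2 reachable grid points; cannot fit a curve")
  recs <- lapply(t_grid, function(tt) {
    m <- find_mixing_fraction(orig, mixi, engine, tt, tol = tol,
                              normalized = normalized)
    mixed <- mix_communities(orig, mixi, m)
    data.frame(m = m,
               t = weighted_unifrac(mixed$tax, orig$tax, engine,
                                    normalized = normalized),
               f = cosine_dissimilarity(mixed$fun, orig$fun))
  })
  records <- do.call(rbind, recs)
  ok <- records$t > 0 & records$f > 0
  curve <- if (sum(ok) >= 2)
    fit_response_curve(records[ok, , drop = FALSE], scope = "mixing") else NULL
  if (is.null(curve)) warning("too few positive records; curve unfittable")
  list(records = records, curve = curve)
}

#' Assign random same-subsite community pairs
#'
#' Utility for pairing communities ahead of mixing-based robustness
#' estimation: within each subsite, samples are shuffled and paired off
#' (one left over when odd). The first member of each pair is the original,
#' the second the mixin.
#'
#' @param sample_ids character vector of community ids.
#' @param subsites character vector of subsite labels, parallel to
#'   \code{sample_ids}.
#' @param seed integer RNG seed.
#' @return data.frame with columns \code{original_id}, \code{mixin_id},
#'   \code{subsite}.
#' @export
pair_communities <- function(sample_ids, subsites, seed = 1L) {
  stopifnot(length(sample_ids) == length(subsites))
  set.seed(seed)
  out <- lapply(split(sample_ids, subsites), function(ids) {
    ids <- sample(ids)
    n_pairs <- length(ids) %/% 2
    if (n_pairs == 0) return(NULL)
    data.frame(original_id = ids[seq_len(n_pairs) * 2 - 1],
               mixin_id = ids[seq_len(n_pairs) * 2])
  })
  keep <- !vapply(out, is.null, logical(1))
  res <- do.call(rbind, c(Map(function(d, s) cbind(d, subsite = s),
                              out[keep], names(out)[keep]),
                          list(make.row.names = FALSE)))
  res
}
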