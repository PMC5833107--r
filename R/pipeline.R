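#' Taxonomic and functional shift records for a perturbation set
#'
#' For every perturbed composition, computes the taxonomic perturbation
#' magnitude t (weighted UniFrac to the original) and the functional shift
#' f (cosine dissimilarity between the predicted functional profiles),
#' fully vectorized over the set. When a hierarchy is given, profiles are
#' compared at pathway level (the even-split summarization is linear, so it
#' is applied to the content matrix once).
#'
#' @param pset a \code{\link{generate_perturbation_set}} result.
#' @param content a \code{\link{genome_content}}.
#' @param tree rooted \code{phylo} or \code{\link{unifrac_engine}}.
#' @param hierarchy optional \code{\link{pathway_hierarchy}}.
#' @param level functional level when \code{hierarchy} is given.
#' @param correct_16S apply 16S copy-number correction (default TRUE).
#' @param normalized UniFrac variant flag.
#' @return data.frame with columns \code{M}, \code{t}, \code{f}.
#' @export
compute_shift_records <- function(pset, content, tree, hierarchy = NULL,
                                  level = c("pathway", "superpathway"),
                                  correct_16S = TRUE, normalized = TRUE) {
  stopifnot(inherits(pset, "perturbation_set"),
            inherits(content, "genome_content"))
  engine <- if (inherits(tree, "unifrac_engine")) tree else unifrac_engine(tree)
  if (!is.null(hierarchy))
    content <- content_to_pathways(content, hierarchy, match.arg(level))
  taxa <- rownames(pset$profiles)
  missing <- setdiff(taxa, rownames(content$copy_numbers))
  if (length(missing))
    stop("taxa missing from genome-content matrix: ",
         paste(missing, collapse = ", "))
  t_val <- weighted_unifrac_many(pset$profiles, pset$original, engine,
                                 normalized = normalized)
  P <- pset$profiles
  orig <- pset$original
  if (correct_16S) {
    rr <- content$rrna_copies[taxa]
    P <- P / rr
    P <- sweep(P, 2, colSums(P), "/")
    orig <- orig / rr
    orig <- orig / sum(orig)
  }
  cn <- content$copy_numbers[taxa, , drop = FALSE]
  F_mat <- crossprod(cn, P)                  # functions x perturbations
  f0 <- drop(crossprod(cn, orig))
  f_val <- cosine_dissimilarity_many(F_mat, f0)
  data.frame(M = pset$magnitudes, t = t_val, f = f_val)
}

#' Simulate, measure, and fit one community's response curve
#'
#' Runs the standard per-community chain: perturbation sweep, shift
#' records, log-window subsampling, log-log least-squares fit. Communities
#' whose functional profile barely moves under any perturbation (all
#' cosine shifts below \code{unfittable_tol}, as happens when all genomes
#' are functionally identical) are flagged unfittable instead of fitted.
#'
#' @param profile taxonomic profile.
#' @param content a \code{\link{genome_content}}.
#' @param tree rooted \code{phylo} or \code{\link{unifrac_engine}}.
#' @param hierarchy optional \code{\link{pathway_hierarchy}}.
#' @param n_magnitudes,M_min,M_max,n_per_magnitude perturbation grid, see
#'   \code{\link{generate_perturbation_set}}.
#' @param n_windows,cap subsampling controls, see
#'   \code{\link{window_subsample}}.
#' @param seed integer RNG seed for the sweep and the subsample.
#' @param unfittable_tol shift level below which records are considered
#'   numerically zero (default 1e-12).
#' @param ... further arguments to \code{\link{compute_shift_records}}.
#' @return list with \code{curve} (a \code{response_curve} or NULL),
#'   \code{records}, \code{retained}, \code{n_dropped},
#'   \code{unfittable}.
#' @export
community_response <- function(profile, content, tree, hierarchy = NULL,
                               n_magnitudes = 45, M_min = 1.2, M_max = 10,
                               n_per_magnitude = 100, n_windows = 50,
                               cap = 50, seed = 1L,
                               unfittable_tol = 1e-12, ...) {
  pset <- generate_perturbation_set(profile, n_magnitudes = n_magnitudes,
                                    M_min = M_min, M_max = M_max,
                                    n_per_magnitude = n_per_magnitude,
                                    seed = seed)
  records <- compute_shift_records(pset, content, tree,
                                   hierarchy = hierarchy, ...)
  usable <- records$t > 0 & records$f > unfittable_tol
  if (sum(usable) < 2 || length(unique(records$t[usable])) < 2) {
    return(list(curve = NULL, records = records, retained = NULL,
                n_dropped = sum(!usable), unfittable = TRUE))
  }
  retained <- window_subsample(records[usable, , drop = FALSE],
                               n_windows = n_windows, cap = cap,
                               seed = seed)
  list(curve = fit_response_curve(retained),
       records = records, retained = retained,
       n_dropped = sum(!usable) + attr(retained, "n_dropped"),
       unfittable = FALSE)
}

#' Function-specific response curves
#'
#' Fits one response curve per function, replacing the whole-profile cosine
#' shift by the per-function relative abundance change
#' \eqn{|b_j - a_j| / a_j}. Functions with zero original abundance, or
#' whose abundance never moves (e.g. encoded identically in every genome),
#' are skipped and reported.
#'
#' @inheritParams community_response
#' @param level functional level when \code{hierarchy} is given.
#' @param correct_16S apply 16S copy-number correction.
#' @param normalized UniFrac variant flag.
#' @return list with \code{curves} (named list of \code{response_curve}),
#'   \code{skipped} (named character vector of reasons).
#' @export
function_specific_curves <- function(profile, content, tree,
                                     hierarchy = NULL,
                                     level = c("pathway", "superpathway"),
                                     n_magnitudes = 45, M_min = 1.2,
                                     M_max = 10, n_per_magnitude = 100,
                                     n_windows = 50, cap = 50, seed = 1L,
                                     correct_16S = TRUE, normalized = TRUE) {
  engine <- if (inherits(tree, "unifrac_engine")) tree else unifrac_engine(tree)
  if (!is.null(hierarchy))
    content <- content_to_pathways(content, hierarchy, match.arg(level))
  pset <- generate_perturbation_set(profile, n_magnitudes = n_magnitudes,
                                    M_min = M_min, M_max = M_max,
                                    n_per_magnitude = n_per_magnitude,
                                    seed = seed)
  taxa <- rownames(pset$profiles)
  t_val <- weighted_unifrac_many(pset$profiles, pset$original, engine,
                                 normalized = normalized)
  P <- pset$profiles
  orig <- pset$original
  if (correct_16S) {
    rr <- content$rrna_copies[taxa]
    P <- sweep(P / rr, 2, colSums(P / rr), "/")
    orig <- (orig / rr) / sum(orig / rr)
  }
  cn <- content$copy_numbers[taxa, , drop = FALSE]
  F_mat <- crossprod(cn, P)
  f0 <- drop(crossprod(cn, orig))
  curves <- list()
  skipped <- character(0)
  for (j in seq_along(f0)) {
    id <- names(f0)[j]
    if (f0[j] <= 0) { skipped[id] <- "zero original abundance"; next }
    shift <- abs(F_mat[j, ] - f0[j]) / f0[j]
    rec <- data.frame(t = t_val, f = shift)
    rec <- rec[rec$t > 0 & rec$f > 1e-15, , drop = FALSE]
    if (nrow(rec) < 2 || length(unique(rec$t)) < 2) {
      skipped[id] <- "no abundance change under perturbation"; next
    }
    retained <- window_subsample(rec, n_windows = n_windows, cap = cap,
                                 seed = seed)
    curves[[id]] <- fit_response_curve(retained, scope = id)
  }
  list(curves = curves, skipped = skipped)
}

#' Run the full robustness workflow over a set of communities
#'
#' Per community: perturbation sweep, shift records, window subsampling,
#' response-curve fit, and the five gene-distribution features. When
#' environment labels are supplied, per-environment pseudomedian
#' attenuation and buffering (with 95% CIs) are summarized and, for >= 2
#' environments, pairwise Wilcoxon rank-sum comparisons of attenuation
#' with Benjamini-Hochberg correction are reported.
#'
#' @param communities named list of taxonomic profiles.
#' @param content a \code{\link{genome_content}}.
#' @param tree rooted \code{phylo} tree covering all taxa.
#' @param hierarchy optional \code{\link{pathway_hierarchy}}.
#' @param environments optional named character vector mapping community
#'   ids to environment labels.
#' @param seed master integer seed; per-community seeds are derived from it.
#' @param gdf_mode redundancy mode passed to \code{\link{gdf_vector}}.
#' @param ... perturbation and fitting controls passed to
#'   \code{\link{community_response}}.
#' @return list with \code{results} (per-community list: \code{curve},
#'   \code{gdf}, \code{n_dropped}, \code{unfittable}), \code{table}
#'   (data.frame of attenuation, buffering, GDFs per fitted community),
#'   \code{environment_summary}, \code{environment_tests}.
#' @export
run_pipeline <- function(communities, content, tree, hierarchy = NULL,
                         environments = NULL, seed = 1L,
                         gdf_mode = "evenness", ...) {
  stopifnot(is.list(communities), !is.null(names(communities)))
  engine <- unifrac_engine(tree)
  results <- list()
  for (i in seq_along(communities)) {
    id <- names(communities)[i]
    prof <- communities[[i]]
    if (n_nonzero_taxa(prof) < 2) {
      warning("community ", id, " has < 2 non-zero taxa; skipped")
      next
    }
    resp <- community_response(prof, content, engine, hierarchy = hierarchy,
                               seed = seed + i, ...)
    gdf <- gdf_vector(prof, content, hierarchy = hierarchy, mode = gdf_mode)
    results[[id]] <- list(community_id = id, curve = resp$curve, gdf = gdf,
                          n_dropped = resp$n_dropped,
                          unfittable = resp$unfittable,
                          environment = if (!is.null(environments))
                            unname(environments[id]) else NA_character_)
  }
  fitted <- Filter(function(r) !r$unfittable, results)
  table <- if (length(fitted)) {
    do.call(rbind, lapply(fitted, function(r) {
      data.frame(community_id = r$community_id,
                 environment = r$environment,
                 attenuation = r$curve$attenuation,
                 buffering = r$curve$buffering,
                 n_points = r$curve$n_points,
                 t(r$gdf), check.names = FALSE)
    }))
  } else data.frame()
  env_summary <- NULL
  env_tests <- NULL
  if (!is.null(environments) && nrow(table) > 0) {
    groups <- split(table, table$environment)
    env_summary <- do.call(rbind, lapply(names(groups), function(e) {
      a <- pseudomedian_with_ci(groups[[e]]$attenuation)
      b <- pseudomedian_with_ci(groups[[e]]$buffering)
      data.frame(environment = e, n = a$n,
                 attenuation = a$pseudomedian,
                 attenuation_lo = a$ci_low, attenuation_hi = a$ci_high,
                 buffering = b$pseudomedian,
                 buffering_lo = b$ci_low, buffering_hi = b$ci_high)
    }))
    if (length(groups) >= 2) {
      pairs <- utils::combn(names(groups), 2)
      env_tests <- data.frame(
        env1 = pairs[1, ], env2 = pairs[2, ],
        p_value = apply(pairs, 2, function(p)
          stats::wilcox.test(groups[[p[1]]]$attenuation,
                             groups[[p[2]]]$attenuation)$p.value))
      env_tests$p_adjusted <- stats::p.adjust(env_tests$p_value, "BH")
    }
  }
  list(results = results, table = table,
       environment_summary = env_summary, environment_tests = env_tests)
}
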