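#' Sample a perturbation specification
#'
#' Draws one multiplicative perturbation: multipliers \eqn{m_i} i.i.d.
#' uniform on (0, M] (realized as \eqn{M (1 - U)} with U uniform on [0, 1))
#' and directions \eqn{d_i} i.i.d. fair-coin on \{-1, +1\}. Note that a
#' "shrinking" direction \eqn{d_i = -1} paired with \eqn{m_i < 1} inflates
#' the abundance, since \eqn{m_i^{-1} > 1}; the formula is applied literally.
#'
#' @param N number of taxa.
#' @param M maximum perturbation magnitude (> 0).
#' @param seed integer RNG seed; same seed, same spec.
#' @return list with \code{multipliers}, \code{directions}, \code{M},
#'   \code{seed}.
#' @export
sample_spec <- function(N, M, seed = 1L) {
  stopifnot(N >= 1, M > 0)
  set.seed(seed)
  m <- M * (1 - stats::runif(N))
  d <- sample(c(-1, 1), N, replace = TRUE)
  list(multipliers = m, directions = d, M = M, seed = seed)
}

#' Apply a multiplicative perturbation to a taxonomic profile
#'
#' Perturbed abundances are \eqn{p_i \propto a_i m_i^{d_i}}, renormalized to
#' sum 1. The expected magnitude of change of each taxon is proportional to
#' its original abundance, and no taxon is created or destroyed.
#'
#' @param profile taxonomic profile (named numeric, sum 1).
#' @param spec a specification from \code{\link{sample_spec}} (or a list
#'   with \code{multipliers} and \code{directions} of the profile's length).
#' @return perturbed taxonomic profile (named numeric, sum 1, same support).
#' @examples
#' apply_perturbation(c(A = 0.5, B = 0.5),
#'                    list(multipliers = c(2, 4), directions = c(1, -1)))
#' @export
apply_perturbation <- function(profile, spec) {
  profile <- as_taxonomic_profile(profile)
  m <- spec$multipliers
  d <- spec$directions
  if (length(m) != length(profile) || length(d) != length(profile))
    stop("spec length does not match the number of profile taxa")
  if (any(m <= 0)) stop("multipliers must be > 0")
  if (!all(d %in% c(-1, 1))) stop("directions must be -1 or +1")
  as_taxonomic_profile(profile * m^d)
}

#' Generate the full perturbation set of a community
#'
#' Perturbs a community at \code{n_magnitudes} maximum perturbation
#' magnitudes M evenly spaced between \code{M_min} and \code{M_max}
#' inclusive, with \code{n_per_magnitude} independent perturbations at each,
#' 4500 in total under the defaults. Per-perturbation sub-seeds are derived
#' from the master seed so the set is reproducible regardless of iteration
#' order.
#'
#' @param profile taxonomic profile with >= 2 non-zero taxa.
#' @param n_magnitudes number of grid points (default 45).
#' @param M_min,M_max grid endpoints (defaults 1.2 and 10); \code{M_min}
#'   must exceed 1.
#' @param n_per_magnitude perturbations per magnitude (default 100).
#' @param seed master integer seed.
#' @return object of class \code{perturbation_set}: list with
#'   \code{profiles} (taxa x perturbations matrix, columns sum to 1),
#'   \code{magnitudes} (M per column), \code{original}, \code{seed}.
#' @export
generate_perturbation_set <- function(profile, n_magnitudes = 45,
                                      M_min = 1.2, M_max = 10,
                                      n_per_magnitude = 100, seed = 1L) {
  profile <- as_taxonomic_profile(profile)
  profile <- profile[profile > 0]
  if (M_min <= 1)
    stop("M_min must exceed 1 so multipliers can alter the composition")
  if (M_max < M_min) stop("M_max must be >= M_min")
  if (length(profile) < 2)
    warning("profile has < 2 non-zero taxa; all perturbations are identity")
  grid <- seq(M_min, M_max, length.out = n_magnitudes)
  N <- length(profile)
  n_tot <- n_magnitudes * n_per_magnitude
  set.seed(seed)
  # one uniform and one sign per (taxon, perturbation), drawn in a fixed
  # column-major order so the set depends only on (profile, seed, grid)
  U <- matrix(stats::runif(N * n_tot), nrow = N)
  D <- matrix(sample(c(-1, 1), N * n_tot, replace = TRUE), nrow = N)
  M_col <- rep(grid, each = n_per_magnitude)
  Mmat <- matrix(M_col, nrow = N, ncol = n_tot, byrow = TRUE)
  mult <- (Mmat * (1 - U))^D
  raw <- profile * mult
  P <- sweep(raw, 2, colSums(raw), "/")
  rownames(P) <- names(profile)
  structure(list(profiles = P, magnitudes = M_col, original = profile,
                 seed = seed),
            class = "perturbation_set")
}

#' @export
print.perturbation_set <- function(x, ...) {
  cat("Perturbation set:", ncol(x$profiles), "perturbations of",
      nrow(x$profiles), "taxa; M in [", min(x$magnitudes), ",",
      max(x$magnitudes), "]\n")
  invisible(x)
}

#' Write a perturbation set as TSV
#'
#' One row per perturbation with provenance columns (perturbation index,
#' maximum magnitude M, master seed) followed by the perturbed relative
#' abundances.
#'
#' @param pset a \code{perturbation_set}.
#' @param path output path.
#' @export
write_perturbation_set <- function(pset, path) {
  stopifnot(inherits(pset, "perturbation_set"))
  df <- data.frame(perturbation = seq_len(ncol(pset$profiles)),
                   M = pset$magnitudes, seed = pset$seed,
                   t(pset$profiles), check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# perturbation set; seed=", pset$seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
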