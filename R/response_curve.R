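#' Uniformly subsample perturbation records across log-spaced windows
#'
#' Perturbation sweeps oversample large taxonomic distances; before fitting,
#' records are thinned by splitting the observed range of the taxonomic
#' distance t into \code{n_windows} non-overlapping windows evenly spaced on
#' the natural-log scale and keeping at most \code{cap} records per window
#' (all records where fewer are present). Records with non-positive t or f
#' are dropped first (they cannot enter the log-log fit); their count is
#' attached as attribute \code{n_dropped}.
#'
#' @param records data.frame with numeric columns \code{t} and \code{f}.
#' @param n_windows number of windows (default 50).
#' @param cap per-window retention cap (default 50).
#' @param seed integer RNG seed for the within-window subsample.
#' @return subsampled data.frame (same columns), attribute
#'   \code{n_dropped}.
#' @export
window_subsample <- function(records, n_windows = 50, cap = 50, seed = 1L) {
  stopifnot(is.data.frame(records), all(c("t", "f") %in% names(records)))
  ok <- is.finite(records$t) & is.finite(records$f) &
    records$t > 0 & records$f > 0
  dropped <- sum(!ok)
  records <- records[ok, , drop = FALSE]
  if (length(unique(records$t)) < 2)
    stop("fewer than 2 distinct taxonomic distances after filtering")
  lt <- log(records$t)
  edges <- seq(min(lt), max(lt), length.out = n_windows + 1)
  win <- findInterval(lt, edges, rightmost.closed = TRUE)
  set.seed(seed)
  keep <- unlist(lapply(split(seq_len(nrow(records)), win), function(idx) {
    if (length(idx) <= cap) idx else sample(idx, cap)
  }), use.names = FALSE)
  out <- records[sort(keep), , drop = FALSE]
  attr(out, "n_dropped") <- dropped
  out
}

#' Fit the taxa-function response curve
#'
#' Fits the power-law response \eqn{f = t^b / e^a} by ordinary least
#' squares on the log-log scale, \eqn{\ln f = -a + b \ln t}: the intercept
#' is the negated attenuation a, the slope the buffering b. Higher
#' attenuation means smaller functional shifts per unit taxonomic
#' perturbation (more robust); higher buffering means stronger suppression
#' of shifts at small perturbations.
#'
#' @param records data.frame with columns \code{t} and \code{f}, all
#'   positive, at least 2 distinct t values (typically the output of
#'   \code{\link{window_subsample}}).
#' @param scope label recording what was fitted (\code{"profile"} or a
#'   function id).
#' @return object of class \code{response_curve}: list with
#'   \code{attenuation}, \code{buffering}, \code{n_points},
#'   \code{residual_sum} (residual sum of squares on the log scale),
#'   \code{scope}.
#' @examples
#' t <- exp(seq(-4, -1, length.out = 20))
#' fit_response_curve(data.frame(t = t, f = t^1.5 * exp(-2)))
#' @export
fit_response_curve <- function(records, scope = "profile") {
  stopifnot(is.data.frame(records), all(c("t", "f") %in% names(records)))
  if (any(records$t <= 0) || any(records$f <= 0))
    stop("all records must have t > 0 and f > 0")
  if (length(unique(records$t)) < 2)
    stop("degenerate design: need >= 2 distinct t values")
  fit <- stats::lm.fit(cbind(1, log(records$t)), log(records$f))
  structure(list(attenuation = unname(-fit$coefficients[1]),
                 buffering = unname(fit$coefficients[2]),
                 n_points = nrow(records),
                 residual_sum = sum(fit$residuals^2),
                 scope = scope),
            class = "response_curve")
}

#' @export
print.response_curve <- function(x, ...) {
  cat(sprintf("Taxa-function response curve (%s): attenuation a = %.4g, buffering b = %.4g (n = %d)\n",
              x$scope, x$attenuation, x$buffering, x$n_points))
  invisible(x)
}

#' Expected functional shift at a given taxonomic distance
#'
#' Evaluates the fitted response curve, \eqn{f = t^b e^{-a}}; used e.g. to
#' predict the functional shift between two longitudinal samples from their
#' weighted UniFrac distance.
#'
#' @param curve a \code{response_curve}.
#' @param t taxonomic dissimilarity (> 0, vectorized).
#' @return expected functional shift(s).
#' @export
predict_expected_shift <- function(curve, t) {
  stopifnot(inherits(curve, "response_curve"))
  if (any(t <= 0)) stop("t must be > 0")
  t^curve$buffering * exp(-curve$attenuation)
}

#' Hodges-Lehmann pseudomedian with a Wilcoxon-inversion CI
#'
#' The pseudomedian is the median of all Walsh averages
#' \eqn{(x_i + x_j)/2, i \le j}, a location estimator suited to the
#' asymmetric distributions of attenuation and buffering. The confidence
#' interval is obtained by inverting the one-sample Wilcoxon signed-rank
#' statistic with its normal approximation: the interval spans the Walsh
#' averages whose rank lies between the \eqn{\alpha/2} and
#' \eqn{1 - \alpha/2} normal quantiles of the statistic's null
#' distribution.
#'
#' @param values numeric vector (n >= 1).
#' @param alpha two-sided significance level (default 0.05).
#' @return list with \code{pseudomedian}, \code{ci_low}, \code{ci_high},
#'   \code{n}. For n = 1 the interval degenerates to the single value.
#' @examples
#' pseudomedian_with_ci(c(1, 2, 6))
#' @export
pseudomedian_with_ci <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0) stop("empty input")
  w <- outer(values, values, "+")[upper.tri(diag(n), diag = TRUE)] / 2
  w <- sort(w)
  pm <- stats::median(w)
  n_w <- length(w)                      # n(n+1)/2 Walsh averages
  z <- stats::qnorm(1 - alpha / 2)
  k <- floor(n_w / 2 - z * sqrt(n * (n + 1) * (2 * n + 1) / 24))
  lo <- w[max(1L, k + 1L)]
  hi <- w[min(n_w, n_w - k)]
  list(pseudomedian = pm, ci_low = min(lo, pm), ci_high = max(hi, pm), n = n)
}

#' Mood's median test across groups
#'
#' Counts, per group, values above versus not above the pooled grand median
#' (ties count as "not above") and applies a chi-square test to the
#' resulting 2 x k contingency table. Rank-based, hence invariant to
#' monotone transforms of the pooled values.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 1).
#' @return list with \code{p_value}, \code{statistic}, \code{table},
#'   \code{degenerate} (TRUE, with p = 1, when all pooled values are
#'   identical and the test is undefined).
#' @export
mood_median_test <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) == 0)) stop("each group needs at least one value")
  pooled <- unlist(groups, use.names = FALSE)
  gm <- stats::median(pooled)
  above <- vapply(groups, function(g) sum(g > gm), numeric(1))
  below <- lengths(groups) - above
  tab <- rbind(above = above, not_above = below)
  if (all(above == 0) || all(below == 0))
    return(list(p_value = 1, statistic = 0, table = tab, degenerate = TRUE))
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(p_value = res$p.value, statistic = unname(res$statistic),
       table = tab, degenerate = FALSE)
}

#' Determine the most robust environment set for a function
#'
#' A function is most robust in a set of environments when its median
#' attenuation in each member is significantly higher (Mood's median test)
#' than in every non-member, and not significantly different from any other
#' member. Candidate sets are the prefixes of the environments sorted by
#' decreasing median attenuation; the smallest qualifying prefix is
#' returned, or an empty set when none qualifies.
#'
#' @param per_env_attenuations named list: environment -> numeric
#'   attenuation values.
#' @param alpha significance threshold for the pairwise tests (default
#'   0.05).
#' @return character vector of environment names (possibly empty).
#' @export
most_robust_environments <- function(per_env_attenuations, alpha = 0.05) {
  stopifnot(is.list(per_env_attenuations),
            length(per_env_attenuations) >= 2,
            !is.null(names(per_env_attenuations)))
  envs <- names(per_env_attenuations)
  meds <- vapply(per_env_attenuations, stats::median, numeric(1))
  ord <- envs[order(meds, decreasing = TRUE)]
  K <- length(ord)
  sig_higher <- function(e1, e2) {
    p <- mood_median_test(per_env_attenuations[c(e1, e2)])$p_value
    p < alpha && meds[e1] > meds[e2]
  }
  differs <- function(e1, e2)
    mood_median_test(per_env_attenuations[c(e1, e2)])$p_value < alpha
  for (k in seq_len(K)) {
    set <- ord[seq_len(k)]
    rest <- setdiff(ord, set)
    cond_out <- all(outer(set, rest, Vectorize(sig_higher)))
    cond_in <- TRUE
    if (k > 1) {
      pairs <- utils::combn(set, 2)
      cond_in <- !any(apply(pairs, 2, function(p) differs(p[1], p[2])))
    }
    if (cond_out && cond_in) return(set)
  }
  character(0)
}
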