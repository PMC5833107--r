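# Shared fixture builders and independent oracles used across the suite.

# a tiny fully hand-checkable genome-content matrix
toy_content <- function() {
  cn <- matrix(c(2, 0, 1,
                 0, 2, 1,
                 1, 1, 1), nrow = 3, byrow = TRUE,
               dimnames = list(c("A", "B", "C"), c("F1", "F2", "F3")))
  genome_content(cn, c(A = 1, B = 2, C = 1))
}

toy_tree <- function() ape::read.tree(text = "((A:1,B:1):0.5,C:2);")

toy_profile <- function() as_taxonomic_profile(c(A = 0.5, B = 0.3, C = 0.2))

random_profile <- function(tree, allow_zero = FALSE) {
  x <- stats::runif(length(tree$tip.label))
  if (allow_zero && length(x) > 2) x[sample(length(x), 1)] <- 0
  as_taxonomic_profile(stats::setNames(x + 1e-9, tree$tip.label))
}

# independent weighted UniFrac oracle: per-branch descendant sets from
# phangorn, root-to-tip depths from the full node distance matrix
oracle_weighted_unifrac <- function(p, q, tree, normalized = TRUE) {
  ntip <- length(tree$tip.label)
  pv <- stats::setNames(numeric(ntip), tree$tip.label); pv[names(p)] <- p
  qv <- stats::setNames(numeric(ntip), tree$tip.label); qv[names(q)] <- q
  raw <- 0
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    tips <- unlist(phangorn::Descendants(tree, child, type = "tips"))
    raw <- raw + tree$edge.length[e] * abs(sum(pv[tips]) - sum(qv[tips]))
  }
  if (!normalized) return(raw)
  dn <- ape::dist.nodes(tree)
  root <- ntip + 1
  denom <- sum(dn[root, seq_len(ntip)] * (pv + qv))
  raw / denom
}

# two-stage grid-search oracle for the mixing fraction: coarse 1e-3 scan,
# then exhaustive 1e-6 scan around the coarse minimizer (equivalent to the
# full 1e-6 grid because the distance is monotone in m)
oracle_mixing_fraction <- function(original, mixin, tree, target_t,
                                   normalized = TRUE) {
  dist_at <- function(m)
    weighted_unifrac(mix_communities(original, mixin, m)$tax, original,
                     tree, normalized = normalized)
  coarse <- seq(0, 1, by = 1e-3)
  d <- vapply(coarse, dist_at, numeric(1))
  m0 <- coarse[which.min(abs(d - target_t))]
  fine <- seq(max(0, m0 - 1e-3), min(1, m0 + 1e-3), by = 1e-6)
  df <- vapply(fine, dist_at, numeric(1))
  fine[which.min(abs(df - target_t))]
}
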