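test_that("functional redundancy is the entropy of weighted contributions", {
  cn <- matrix(c(1, 3,
                 1, 1,
                 0, 2), nrow = 3, byrow = TRUE,
               dimnames = list(c("A", "B", "C"), c("F1", "F2")))
  gc <- genome_content(cn)
  # F1: only A and B encode; equal abundances and copies -> ln 2
  expect_equal(functional_redundancy("F1", c(A = 0.5, B = 0.5), gc), log(2))
  # single encoder -> 0
  expect_equal(functional_redundancy("F1", c(A = 0.8, C = 0.2), gc), 0)
  # contributions (0.75, 0.25)
  prof <- c(A = 0.75, B = 0.25)
  expect_equal(functional_redundancy("F1", prof, gc),
               -(0.75 * log(0.75) + 0.25 * log(0.25)))
  # literal mode evaluates the unnormalized products
  expect_equal(functional_redundancy("F1", prof, gc, mode = "literal"),
               -(0.75 * log(0.75) + 0.25 * log(0.25)))
  expect_error(functional_redundancy("F2", c(A = 1), gc, mode = "literal"),
               NA)  # single encoder, fine
  expect_error(functional_redundancy("F9", prof, gc), "unknown")
})

test_that("redundancy is bounded by ln(number of encoders)", {
  set.seed(18)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    cn <- matrix(rpois(n * 3, 2), n,
                 dimnames = list(paste0("t", 1:n), paste0("F", 1:3)))
    cn[, 1] <- pmax(cn[, 1], 1)
    gc <- genome_content(cn)
    prof <- as_taxonomic_profile(setNames(runif(n) + 0.01, rownames(cn)))
    red <- functional_redundancy("F1", prof, gc)
    expect_gte(red, 0)
    expect_lte(red, log(sum(cn[, 1] > 0)) + 1e-12)
  }
})

test_that("average redundancy weights functions by their profile share", {
  # identical genomes, k equal taxa: every function scores ln k
  k <- 4
  cn <- matrix(rep(c(2, 1, 3), each = k), k,
               dimnames = list(paste0("t", 1:k), paste0("F", 1:3)))
  gc <- genome_content(cn)
  prof <- as_taxonomic_profile(setNames(rep(1, k), rownames(cn)))
  expect_equal(average_functional_redundancy(prof, gc), log(k))
  # all single-encoder functions -> 0
  gc2 <- genome_content(matrix(c(1, 0, 0, 1), 2,
                               dimnames = list(c("A", "B"),
                                               c("F1", "F2"))))
  expect_equal(average_functional_redundancy(c(A = 0.5, B = 0.5), gc2), 0)
  # weighting: recompute the weighted mean by hand on a 2-function toy
  cn3 <- matrix(c(1, 4,
                  1, 0), nrow = 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("F1", "F2")))
  gc3 <- genome_content(cn3)
  prof3 <- c(A = 0.5, B = 0.5)
  r1 <- functional_redundancy("F1", prof3, gc3)  # both encode -> ln 2
  # F1 total 1.0, F2 total 2.0 -> weights 1/3, 2/3; F2 redundancy 0
  expect_equal(average_functional_redundancy(prof3, gc3),
               (1 / 3) * r1 + (2 / 3) * 0)
})

test_that("functional similarity is pairwise cosine, averaged unweighted", {
  expect_equal(functional_similarity(c(1, 1, 0), c(1, 0, 0)), 1 / sqrt(2))
  expect_equal(functional_similarity(c(2, 4), c(1, 2)), 1)
  expect_equal(functional_similarity(c(1, 0), c(0, 3)), 0)
  expect_error(functional_similarity(c(0, 0), c(1, 1)), "empty")
  cn <- matrix(c(1, 1, 0,
                 1, 0, 0,
                 0, 0, 2), nrow = 3, byrow = TRUE,
               dimnames = list(c("A", "B", "C"), paste0("F", 1:3)))
  gc <- genome_content(cn)
  prof <- c(A = 1 / 3, B = 1 / 3, C = 1 / 3)
  expect_equal(average_functional_similarity(prof, gc),
               mean(c(1 / sqrt(2), 0, 0)))
  expect_warning(one <- average_functional_similarity(c(A = 1), gc))
  expect_true(is.na(one))
})

test_that("genome-size features use unweighted means and population CV", {
  cn <- matrix(c(1, 1, 2,
                 3, 1, 2), nrow = 2, byrow = TRUE,
               dimnames = list(c("A", "B"), paste0("F", 1:3)))
  gc <- genome_content(cn)
  gs <- genome_size_features(c(A = 0.9, B = 0.1), gc)
  expect_equal(gs$average, 5)       # sizes 4 and 6
  expect_equal(gs$variability, 1 / 5)  # pop SD 1 over mean 5
  # abundance-invariant
  gs2 <- genome_size_features(c(A = 0.1, B = 0.9), gc)
  expect_equal(gs2, gs)
  # sizes {2, 6}: average 4, variability 0.5
  cn2 <- matrix(c(2, 0, 6, 0), 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("F1", "F2")))
  gs3 <- genome_size_features(c(A = 0.5, B = 0.5), genome_content(cn2))
  expect_equal(gs3$average, 4)
  expect_equal(gs3$variability, 0.5)
  expect_warning(single <- genome_size_features(c(A = 1), gc))
  expect_true(is.na(single$variability))
})

test_that("unique-function abundance sums single-encoder profile shares", {
  cn <- matrix(c(3, 1,
                 0, 1), nrow = 2, byrow = TRUE,
               dimnames = list(c("A", "B"), c("F1", "F2")))
  gc <- genome_content(cn)
  prof <- c(A = 0.4, B = 0.6)
  # F1 encoded only by A: profile share 1.2 / (1.2 + 1.0) = 0.545...
  expect_equal(unique_function_abundance(prof, gc), 1.2 / 2.2)
  # everything multi-encoded -> 0
  all2 <- genome_content(matrix(1, 2, 2, dimnames = dimnames(cn)))
  expect_equal(unique_function_abundance(prof, all2), 0)
})

test_that("GDF vector and its PCA behave across a redundancy sweep", {
  rhos <- seq(0.1, 0.9, by = 0.2)
  gdfs <- t(vapply(rhos, function(rho) {
    sc <- generate_scenario(n_taxa = 20, n_functions = 80, redundancy = rho,
                            seed = 50)
    gdf_vector(sc$communities[[1]], sc$content)
  }, numeric(5)))
  expect_true(all(diff(gdfs[, "avg_functional_redundancy"]) > 0))
  # unique-function load drops as redundancy rises
  expect_lt(cor(gdfs[, "avg_functional_redundancy"],
                gdfs[, "unique_function_abundance"], method = "spearman"), 0)
  expect_true(all(gdfs[, "avg_functional_similarity"] >= 0 &
                    gdfs[, "avg_functional_similarity"] <= 1))
  pca <- gdf_pca(gdfs)
  expect_equal(sum(pca$explained_variance), 1)
  expect_equal(unname(colMeans(pca$scores)), rep(0, ncol(pca$scores)),
               tolerance = 1e-12)
  # constant columns are dropped with a warning
  degen <- cbind(gdfs, const = 1)
  expect_warning(gdf_pca(degen), "constant")
})

test_that("pathway-level content collapse conserves per-taxon totals", {
  gc <- toy_content()
  hier <- pathway_hierarchy(data.frame(
    function_id = c("F1", "F1", "F2", "F3"),
    pathway_id = c("P1", "P2", "P2", "P3")))
  pw <- content_to_pathways(gc, hier)
  expect_equal(rowSums(pw$copy_numbers), rowSums(gc$copy_numbers))
  expect_equal(pw$copy_numbers["A", "P1"], 1)  # F1 copy 2 split over 2
})
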