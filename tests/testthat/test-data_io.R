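test_that("OTU table TSV round trip is lossless", {
  counts <- matrix(c(10L, 0L, 3L, 5L,
                     2L, 8L, 0L, 1L,
                     7L, 7L, 7L, 7L), nrow = 4,
                   dimnames = list(paste0("otu", 1:4), paste0("s", 1:3)))
  tab <- count_table(counts,
                     taxonomy = setNames(paste0("k__Bacteria; otu", 1:4),
                                         rownames(counts)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(tab, path, comment = "seed=1")
  back <- read_otu_table(path)
  expect_equal(back$counts, tab$counts)
  expect_equal(back$taxonomy, tab$taxonomy)
})

test_that("BIOM-style input parses into the same counts as TSV", {
  counts <- matrix(c(5, 1, 0, 9, 2, 4), nrow = 3,
                   dimnames = list(paste0("otu", 1:3), c("s1", "s2")))
  path <- withr::local_tempfile(fileext = ".biom")
  biomformat::write_biom(biomformat::make_biom(counts), path)
  back <- read_otu_table(path)
  expect_equal(back$counts[rownames(counts), colnames(counts)], counts)
})

test_that("validation rejects malformed tables and missing taxa are named", {
  counts <- matrix(-1L, 1, 1, dimnames = list("otu1", "s1"))
  expect_error(count_table(counts), "non-negative")
  expect_error(count_table(matrix(1.5, 1, 1,
                                  dimnames = list("otu1", "s1"))),
               "integer")
  # a profile taxon absent from the tree leaves is reported by name
  tr <- toy_tree()
  expect_error(weighted_unifrac(c(A = 0.5, X = 0.5), c(A = 1), tr), "X")
})

test_that("chloroplast filtering removes matching lineages only", {
  counts <- matrix(1L, 5, 2,
                   dimnames = list(paste0("otu", 1:5), c("s1", "s2")))
  tax <- setNames(c("k__Bacteria", "c__Chloroplast; f__x", "k__Bacteria",
                    "k__Bacteria; c__CHLOROPLAST", "k__Bacteria"),
                  rownames(counts))
  tab <- count_table(counts, taxonomy = tax)
  out <- filter_chloroplast(tab)
  expect_setequal(rownames(out$counts), c("otu1", "otu3", "otu5"))
  # no matches: unchanged
  clean <- count_table(counts, taxonomy = setNames(rep("k__Bacteria", 5),
                                                   rownames(counts)))
  expect_equal(filter_chloroplast(clean)$counts, clean$counts)
  # all matches: warning
  allc <- count_table(counts, taxonomy = setNames(rep("chloroplast", 5),
                                                  rownames(counts)))
  expect_warning(filter_chloroplast(allc), "all taxa")
  expect_error(filter_chloroplast(count_table(counts)), "taxonomy")
})

test_that("QC filtering drops shallow or species-poor samples and rarefies exactly", {
  set.seed(99)
  deep <- rmultinom(1, 6000, prob = runif(20))[, 1]
  shallow <- rmultinom(1, 4000, prob = runif(20))[, 1]
  poor <- c(rep(0L, 11), rmultinom(1, 6000, prob = runif(9))[, 1])
  counts <- cbind(deep = deep, shallow = shallow, poor = poor)
  rownames(counts) <- paste0("otu", 1:20)
  tab <- count_table(counts)
  out <- qc_filter_and_rarefy(tab, seed = 11)
  expect_identical(colnames(out$counts), "deep")
  expect_setequal(attr(out, "removed_samples"), c("shallow", "poor"))
  expect_equal(sum(out$counts), 5000)
  # rarefaction never increases a count, and is seed-reproducible
  expect_true(all(out$counts <= counts[, "deep"]))
  out2 <- qc_filter_and_rarefy(tab, seed = 11)
  expect_identical(out$counts, out2$counts)
  expect_error(qc_filter_and_rarefy(tab, depth = 6000), "depth")
})

test_that("OTU subsampling keeps k taxa, renormalizes, favors abundant taxa", {
  set.seed(3)
  prof <- as_taxonomic_profile(setNames(rlnorm(50), paste0("t", 1:50)))
  sub <- subsample_otus(prof, k = 10, seed = 4)
  expect_length(sub, 10)
  expect_equal(sum(sub), 1)
  expect_true(all(names(sub) %in% names(prof)))
  # 10-taxon profile: support unchanged
  ten <- as_taxonomic_profile(setNames(runif(10), paste0("t", 1:10)))
  expect_setequal(names(subsample_otus(ten, k = 10, seed = 1)), names(ten))
  expect_error(subsample_otus(ten, k = 11), "non-zero taxa")
  # retention frequency tracks abundance (weighted sampling)
  skew <- as_taxonomic_profile(c(big = 60, mid = 30, s1 = 1, s2 = 1, s3 = 1,
                                 s4 = 1, s5 = 1, s6 = 1, s7 = 1, s8 = 1,
                                 s9 = 1, s10 = 1))
  hits <- vapply(1:400, function(s)
    c("big", "s1") %in% names(subsample_otus(skew, k = 3, seed = s)),
    logical(2))
  expect_gt(sum(hits[1, ]), sum(hits[2, ]))
})

test_that("subsite pooling relabels metadata via the mapping", {
  counts <- matrix(1L, 2, 4, dimnames = list(c("o1", "o2"),
                                             paste0("s", 1:4)))
  md <- data.frame(subsite = c("L_fossa", "R_fossa", "gut", "gut"),
                   row.names = paste0("s", 1:4))
  tab <- count_table(counts, metadata = md)
  out <- pool_subsites(tab, c(L_fossa = "fossa", R_fossa = "fossa"))
  expect_equal(out$metadata$subsite, c("fossa", "fossa", "gut", "gut"))
})
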