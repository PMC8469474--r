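test_that("rarefaction preserves depth and sampling is hypergeometric", {
  tab <- matrix(c(10L, 0L, 0L,
                  4L, 3L, 5L), 2, 3, byrow = TRUE,
                dimnames = list(c("s1", "s2"), c("A", "B", "C")))
  r <- rarefy(tab, 5, seed = 1)
  expect_equal(unname(r["s1", ]), c(5L, 0L, 0L))  # single-OTU sample
  expect_equal(rowSums(r), c(s1 = 5, s2 = 5))
  # depth equal to the row sum leaves counts unchanged
  r2 <- rarefy(tab[2, , drop = FALSE], 12, seed = 1)
  expect_equal(r2, tab[2, , drop = FALSE])
  expect_error(rarefy(tab, 11), "depth exceeds")

  # (500, 500) at depth 100: mean first-OTU count is the hypergeometric
  # mean 50; with 1000 replicates the MC error of the mean is ~0.15
  tab2 <- matrix(c(500L, 500L), 1, 2, dimnames = list("s1", c("A", "B")))
  draws <- vapply(seq_len(1000), function(s) rarefy(tab2, 100, seed = s)[1, 1],
                  integer(1))
  expect_lt(abs(mean(draws) - 50), 0.8)
})

test_that("abundance partition follows the pooled thresholds", {
  # 3 OTUs over 1000 pooled reads: 0.2% (abundant), 0.05% in spirit via
  # a 100000-read table for the rare/intermediate boundary cases
  counts <- matrix(c(2L, 500L, 498L), 1, 3,
                   dimnames = list("s1", c("A", "B", "C")))
  p <- partition_by_abundance(counts)
  expect_true("A" %in% p$abundant_ids)  # 2/1000 = 0.2% >= 0.1%

  big <- matrix(c(1L, 50L, 99949L), 1, 3,
                dimnames = list("s1", c("A", "B", "C")))
  p2 <- partition_by_abundance(big)
  expect_true("A" %in% p2$rare_ids)          # 0.001% <= 0.01%
  expect_true("B" %in% p2$intermediate_ids)  # 0.05% between thresholds
  expect_true("C" %in% p2$abundant_ids)
  expect_error(partition_by_abundance(big, abundant_min = 1e-5, rare_max = 1e-4),
               "must exceed")
})

test_that("abundance partition is a partition for random tables, both modes", {
  for (seed in 1:5) {
    tab <- rand_table(6, 40, seed = seed, lambda = 2)
    for (mode in c("pooled", "every_sample")) {
      p <- partition_by_abundance(tab, abundant_min = 0.02, rare_max = 0.005,
                                  mode = mode)
      ids <- c(p$abundant_ids, p$rare_ids, p$intermediate_ids)
      expect_setequal(ids, colnames(tab))
      expect_equal(anyDuplicated(ids), 0L)
    }
  }
  # every_sample is stricter than pooled for the abundant class
  tab <- rand_table(6, 40, seed = 9, lambda = 2)
  pe <- partition_by_abundance(tab, 0.02, 0.005, mode = "every_sample")
  pp <- partition_by_abundance(tab, 0.02, 0.005, mode = "pooled")
  expect_true(all(pe$abundant_ids %in%
                  c(pp$abundant_ids, pp$intermediate_ids)))
})

test_that("Bray-Curtis matches the direct formula and its bounds", {
  tab <- matrix(c(1L, 2L, 3L,
                  3L, 2L, 1L,
                  1L, 2L, 3L,
                  0L, 0L, 7L), 4, 3, byrow = TRUE,
                dimnames = list(paste0("s", 1:4), c("A", "B", "C")))
  bc <- bray_curtis(tab)
  expect_equal(bc["s1", "s3"], 0)                    # identical rows
  expect_equal(bc["s1", "s2"], bc_brute(tab[1, ], tab[2, ]))  # (2+0+2)/12
  expect_equal(bc["s1", "s2"], 1 / 3)
  disjoint <- matrix(c(5L, 0L, 0L, 6L), 2, 2,
                     dimnames = list(c("a", "b"), c("X", "Y")))
  expect_equal(unclass(bray_curtis(disjoint))["a", "b"], 1)
  expect_error(bray_curtis(rbind(tab, s5 = c(0L, 0L, 0L))), "zero total")
})

test_that("weighted UniFrac hits its boundary cases", {
  tree <- ape::read.tree(text = "(A:1,B:1);")
  tab <- matrix(c(10L, 0L, 0L, 10L, 10L, 0L), 3, 2, byrow = TRUE,
                dimnames = list(c("s1", "s2", "s3"), c("A", "B")))
  wu <- weighted_unifrac(tab, tree)
  expect_equal(wu["s1", "s3"], 0)   # identical samples
  expect_equal(wu["s1", "s2"], 1)   # complete turnover on an equal cherry
})

test_that("weighted UniFrac equals the brute-force branch enumeration", {
  for (seed in 1:6) {
    tree <- rand_tree(8, seed = seed)
    tab <- rand_table(4, 8, seed = seed + 100, lambda = 3)
    wu <- weighted_unifrac(tab, tree)
    wu_raw <- weighted_unifrac(tab, tree, normalized = FALSE)
    for (i in 1:3) for (j in (i + 1):4) {
      expect_equal(wu[i, j], wunifrac_brute(tree, tab[i, ], tab[j, ]),
                   tolerance = 1e-10)
      expect_equal(wu_raw[i, j],
                   wunifrac_brute(tree, tab[i, ], tab[j, ], normalized = FALSE),
                   tolerance = 1e-10)
    }
  }
})

test_that("weighted UniFrac agrees with phyloseq and ignores tip order", {
  tree <- rand_tree(10, seed = 21)
  tab <- rand_table(5, 10, seed = 22, lambda = 3)
  wu <- weighted_unifrac(tab, tree)
  ps <- phyloseq::phyloseq(phyloseq::otu_table(t(tab), taxa_are_rows = TRUE),
                           phyloseq::phy_tree(tree))
  ref <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE, normalized = TRUE))
  expect_equal(unclass(wu), ref[rownames(wu), colnames(wu)],
               tolerance = 1e-10, ignore_attr = TRUE)
  # permuting table columns changes nothing
  perm <- sample(ncol(tab))
  expect_equal(unclass(weighted_unifrac(tab[, perm], tree)), unclass(wu),
               tolerance = 1e-12)
})

test_that("zero-length internal edges do not change weighted UniFrac", {
  poly <- ape::read.tree(text = "((A:1,B:1,C:1.5):1,D:2);")
  resolved <- ape::multi2di(poly)  # inserts a zero-length internal edge
  expect_gt(nrow(resolved$edge), nrow(poly$edge))
  tab <- matrix(c(3L, 2L, 5L, 1L,
                  1L, 4L, 5L, 2L), 2, 4, byrow = TRUE,
                dimnames = list(c("s1", "s2"), c("A", "B", "C", "D")))
  a <- weighted_unifrac(tab, poly)["s1", "s2"]
  b <- weighted_unifrac(tab, resolved)["s1", "s2"]
  expect_equal(a, b, tolerance = 1e-12)
  expect_equal(a, wunifrac_brute(poly, tab[1, ], tab[2, ]), tolerance = 1e-10)
})
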