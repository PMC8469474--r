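test_that("betaMNTD boundary cases follow the definition", {
  # identical samples: every taxon's nearest neighbour is its conspecific
  tree <- rand_tree(6, seed = 1)
  tab <- rand_table(2, 6, seed = 2, lambda = 3)
  tab[2, ] <- tab[1, ]
  bm <- beta_mntd(tab, tree)
  expect_equal(bm[1, 2], 0)
  # two single-OTU samples: betaMNTD is their patristic distance
  cherry <- ape::read.tree(text = "(A:2,B:2);")
  tab2 <- matrix(c(5L, 0L, 0L, 9L), 2, 2,
                 dimnames = list(c("s1", "s2"), c("A", "B")))
  expect_equal(unclass(beta_mntd(tab2, cherry))["s1", "s2"], 4)
})

test_that("betaMNTD equals the brute-force nearest-taxon search", {
  for (seed in 1:6) {
    tree <- rand_tree(8, seed = seed + 40)
    tab <- rand_table(4, 8, seed = seed + 50, lambda = 2)
    for (w in c(TRUE, FALSE)) for (ex in c(FALSE, TRUE)) {
      bm <- beta_mntd(tab, tree, abundance_weighted = w,
                      exclude_conspecifics = ex)
      for (i in 1:3) for (j in (i + 1):4) {
        expect_equal(bm[i, j],
                     bmntd_brute(tree, tab[i, ], tab[j, ],
                                 weighted = w, exclude_conspecifics = ex),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("betaMNTD agrees with picante's comdistnt", {
  tree <- rand_tree(12, seed = 61)
  tab <- rand_table(5, 12, seed = 62, lambda = 2)
  bm <- beta_mntd(tab, tree)
  ref <- as.matrix(picante::comdistnt(tab, ape::cophenetic.phylo(tree),
                                      abundance.weighted = TRUE))
  expect_equal(unclass(bm), ref[rownames(bm), colnames(bm)],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("betaNTI is deterministic and flags degenerate nulls", {
  tree <- rand_tree(20, seed = 71)
  tab <- rand_table(5, 20, seed = 72, lambda = 2)
  a <- bnti(tab, tree, n_rand = 49, seed = 3)
  b <- bnti(tab, tree, n_rand = 49, seed = 3)
  expect_identical(unclass(a$score), unclass(b$score))
  expect_s3_class(a$score, "pairwise_matrix")

  # a 2-tip pool admits no variation under tip shuffling: null sd is zero
  cherry <- ape::read.tree(text = "(A:2,B:2);")
  tab2 <- matrix(c(5L, 1L, 2L, 9L), 2, 2,
                 dimnames = list(c("s1", "s2"), c("A", "B")))
  z <- bnti(tab2, cherry, n_rand = 19, seed = 1)
  expect_true(z$degenerate["s1", "s2"])
  expect_true(is.na(unclass(z$score)["s1", "s2"]))
})

test_that("tip-shuffling leaves abundances and occupancies untouched", {
  # betaNTI's null distribution must depend on the tree only: the observed
  # betaMNTD recomputed with the identity shuffle equals beta_mntd()
  tree <- rand_tree(10, seed = 81)
  tab <- rand_table(4, 10, seed = 82, lambda = 2)
  res <- bnti(tab, tree, n_rand = 29, seed = 5)
  expect_equal(res$obs, unclass(beta_mntd(tab, tree)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(res$null_sd[upper.tri(res$null_sd)] >= 0))
})

test_that("RC_Bray is bounded, deterministic and ranks extremes correctly", {
  tab <- rand_table(6, 30, seed = 91, lambda = 1)
  tab <- rarefy(tab, min(rowSums(tab)), seed = 1)
  a <- raup_crick_bray(tab, n_rand = 99, seed = 7)
  b <- raup_crick_bray(tab, n_rand = 99, seed = 7)
  expect_identical(unclass(a$score), unclass(b$score))
  v <- pair_values(a$score)
  expect_true(all(v >= -1 & v <= 1))

  # identical samples: observed BC = 0 sits below every non-tied null
  tab2 <- rand_table(1, 20, seed = 92, lambda = 3)
  tab2 <- rbind(s1 = tab2[1, ], s2 = tab2[1, ])
  colnames(tab2) <- sprintf("OTU%03d", 1:20)
  rc <- raup_crick_bray(tab2, n_rand = 49, seed = 2)
  expect_equal(unclass(rc$score)["s1", "s2"], -1)

  expect_error(raup_crick_bray(rand_table(3, 10, seed = 93)), "equal depth")
})

test_that("process classification follows the thresholds, boundaries stochastic-side", {
  lab <- c("s1", "s2", "s3")
  mk <- function(vals, role) {
    m <- matrix(0, 3, 3, dimnames = list(lab, lab))
    m[upper.tri(m)] <- vals
    m <- m + t(m)
    pairwise_matrix(m, role)
  }
  # pairs (1,2), (1,3), (2,3)
  z <- mk(c(2.5, 0.3, 0.0), "bnti")
  r <- mk(c(0.1, 0.99, 0.0), "rc")
  ps <- classify_processes(z, r)
  got <- setNames(as.character(ps$pairs$process),
                  paste(ps$pairs$sample_a, ps$pairs$sample_b))
  expect_equal(unname(got["s1 s2"]), "variable_selection")
  expect_equal(unname(got["s1 s3"]), "dispersal_limitation")
  expect_equal(unname(got["s2 s3"]), "undominated")
  expect_equal(sum(ps$fractions), 1)

  # exact boundary values are never assigned to the extreme classes
  zb <- mk(c(2, -2, 1), "bnti")
  rb <- mk(c(0.95, -0.95, -0.99), "rc")
  psb <- classify_processes(zb, rb)
  gotb <- as.character(psb$pairs$process)
  expect_equal(gotb, c("undominated", "undominated", "homogenizing_dispersal"))

  # mismatched pair sets fail
  z2 <- mk(c(1, 1, 1), "bnti")
  rownames(z2) <- colnames(z2) <- c("x", "y", "z")
  expect_error(classify_processes(z2, r), "same sample labels")
})

test_that("process fractions sum to one and exclude undefined pairs", {
  set.seed(99)
  for (rep in 1:5) {
    n <- 6
    lab <- sprintf("s%02d", 1:n)
    z <- matrix(0, n, n, dimnames = list(lab, lab))
    z[upper.tri(z)] <- rnorm(n * (n - 1) / 2, sd = 2)
    z <- z + t(z)
    z[1, 2] <- z[2, 1] <- NA  # a degenerate pair
    r <- matrix(0, n, n, dimnames = list(lab, lab))
    r[upper.tri(r)] <- runif(n * (n - 1) / 2, -1, 1)
    r <- r + t(r)
    ps <- classify_processes(pairwise_matrix(z, "bnti"),
                             pairwise_matrix(r, "rc"))
    expect_equal(sum(ps$fractions), 1)
    expect_equal(ps$n_excluded, 1)
    expect_equal(ps$n_pairs, n * (n - 1) / 2 - 1)
  }
})
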