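md_fixture <- function(n = 8, seed = 1) {
  md <- simulate_metadata(simulation_config(n_sites = n, n_otus = 10,
                                            seed = seed))
  top <- md[md$layer == "topsoil", ]
  attr(top, "group_map") <- attr(md, "group_map")
  top
}

test_that("haversine distances match the spherical closed form", {
  md <- data.frame(sample_id = c("a", "b", "c"),
                   longitude = c(0, 0, 10), latitude = c(0, 1, 0))
  d <- spatial_distance(md)
  expect_equal(d["a", "a"], 0)
  # one degree of latitude = 2 pi R / 360 on the sphere
  expect_equal(d["a", "b"], 2 * pi * 6371.0088 / 360, tolerance = 1e-4)
  expect_equal(unclass(d), t(unclass(d)), ignore_attr = TRUE)
  md$latitude[1] <- 95
  expect_error(spatial_distance(md), "out of range")
})

test_that("environmental distance is a z-scored group-composite Euclidean", {
  md <- md_fixture()
  en <- environmental_distance(md)
  expect_equal(diag(unclass(en)), setNames(rep(0, nrow(md)), md$sample_id))

  # two sites differing only in pH: distance equals the z-score difference
  md2 <- md
  for (v in names(attr(md, "group_map"))) md2[[v]] <- mean(md[[v]])
  md2$ph <- md$ph
  en2 <- suppressWarnings(environmental_distance(md2, groups = "soil_ph"))
  z <- (md2$ph - mean(md2$ph)) / sd(md2$ph)
  expect_equal(unclass(en2)[1, 2], abs(z[1] - z[2]), tolerance = 1e-10)

  # adding a constant to one variable changes nothing
  md3 <- md; md3$mat <- md3$mat + 100
  expect_equal(unclass(environmental_distance(md3)),
               unclass(environmental_distance(md)), tolerance = 1e-10)

  # constant variables are dropped with a warning
  md4 <- md; md4$npp <- 5
  expect_warning(environmental_distance(md4), "constant")
  # unknown group errors
  expect_error(environmental_distance(md, groups = "soil_magic"), "unknown group")
})

test_that("distance-decay recovers a perfectly linear surface exactly", {
  md <- md_fixture(n = 10, seed = 3)
  d <- spatial_distance(md)
  x <- pair_values(d)
  xs <- (x - mean(x)) / sd(x)
  sim_v <- 0.6 - 0.1 * xs  # exact line on standardized distance
  n <- nrow(d)
  S <- matrix(0, n, n, dimnames = dimnames(d))
  S[upper.tri(S)] <- sim_v
  S <- S + t(S); diag(S) <- 1
  sim <- pairwise_matrix(S, "similarity")
  fit <- fit_distance_decay(sim, d, n_perm = 99, seed = 1)
  expect_equal(fit$slope, -0.1, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.6, tolerance = 1e-10)
  expect_equal(fit$pearson_r, -1, tolerance = 1e-10)
  expect_equal(fit$n_pairs, n * (n - 1) / 2)
  # doubling raw distances leaves the standardized slope unchanged
  d2 <- pairwise_matrix(unclass(d) * 2, "spatial_km")
  fit2 <- fit_distance_decay(sim, d2, n_perm = 99, seed = 1)
  expect_equal(fit2$slope, fit$slope, tolerance = 1e-10)
})

test_that("the Mantel test is exact on self-comparison and reproducible", {
  md <- md_fixture(n = 8, seed = 5)
  d <- spatial_distance(md)
  mt <- mantel_test(d, d, n_perm = 199, seed = 2)
  expect_equal(mt$r, 1)
  expect_equal(mt$p, 1 / 200)
  mt2 <- mantel_test(d, d, n_perm = 199, seed = 2)
  expect_identical(mt, mt2)
  cst <- unclass(d); cst[] <- 1; diag(cst) <- 0
  dimnames(cst) <- dimnames(unclass(d))
  expect_error(mantel_test(d, pairwise_matrix(cst, "spatial_km")), "constant")
})

test_that("Mantel permutes rows and columns jointly, not pairs", {
  # on a structured (Euclidean) matrix the joint permutation preserves the
  # triangle-inequality structure; naive pair shuffling destroys it and
  # yields a visibly narrower null for r. The two nulls must differ.
  set.seed(11)
  xy <- cbind(runif(12), runif(12))
  m1 <- points_beta(xy)
  m2 <- points_beta(xy + matrix(rnorm(24, sd = 0.05), 12, 2))
  n <- nrow(m1); idx <- which(upper.tri(unclass(m1)), arr.ind = TRUE)
  v1 <- pair_values(m1); M2 <- unclass(m2)
  joint <- replicate(400, {
    p <- sample.int(n)
    cor(v1, M2[cbind(p[idx[, 1]], p[idx[, 2]])])
  })
  naive <- replicate(400, cor(v1, sample(pair_values(m2))))
  # equality of the two nulls would put this ratio within ~1 +/- 0.1
  expect_gt(sd(joint) / sd(naive), 1.2)
})

test_that("slope comparison detects real differences and respects symmetry", {
  # two groups with within-group slopes -0.1 vs -0.4 plus small pair noise
  set.seed(21)
  n <- 30
  pos <- c(runif(n, 0, 10), runif(n, 0, 10))
  lab <- sprintf("s%02d", seq_len(2 * n))
  D <- as.matrix(dist(pos)); dimnames(D) <- list(lab, lab)
  Ds <- (D - mean(D[upper.tri(D)])) / sd(D[upper.tri(D)])
  grp <- rep(c(0, 1), each = n)
  S <- matrix(0, 2 * n, 2 * n, dimnames = list(lab, lab))
  for (i in seq_len(2 * n - 1)) for (j in (i + 1):(2 * n)) {
    slope <- if (grp[i] == grp[j] && grp[i] == 1) -0.4 else -0.1
    S[i, j] <- S[j, i] <- 0.5 + slope * Ds[i, j] / 4 + rnorm(1, sd = 0.02)
  }
  S <- pmin(pmax(S, 0), 1); diag(S) <- 1
  sim <- pairwise_matrix(S, "similarity")
  dist_pm <- pairwise_matrix(D, "spatial_km")
  grouping <- factor(rep(c("top", "sub"), each = n), levels = c("top", "sub"))
  cmp <- compare_slopes(sim, dist_pm, grouping, n_perm = 199, seed = 3)
  expect_lt(cmp$p_perm, 0.05)
  expect_lt(cmp$slopes["sub"], cmp$slopes["top"])

  # swapping group labels flips the interaction sign, p unchanged
  flipped <- factor(grouping, levels = rev(levels(grouping)))
  cmp2 <- compare_slopes(sim, dist_pm, flipped, n_perm = 199, seed = 3)
  expect_equal(cmp2$interaction, -cmp$interaction, tolerance = 1e-10)
  expect_equal(cmp2$p_perm, cmp$p_perm)

  # identical structure in both groups: interaction near zero, p large
  set.seed(31)
  S0 <- matrix(0, 2 * n, 2 * n, dimnames = list(lab, lab))
  for (i in seq_len(2 * n - 1)) for (j in (i + 1):(2 * n)) {
    S0[i, j] <- S0[j, i] <- 0.5 - 0.1 * Ds[i, j] / 4 + rnorm(1, sd = 0.02)
  }
  S0 <- pmin(pmax(S0, 0), 1); diag(S0) <- 1
  cmp0 <- compare_slopes(pairwise_matrix(S0, "similarity"), dist_pm,
                         grouping, n_perm = 199, seed = 4)
  expect_gt(cmp0$p_perm, 0.1)
})
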