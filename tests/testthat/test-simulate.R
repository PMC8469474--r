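test_that("simulated phylogenies have the requested tips and are reproducible", {
  for (n in c(2, 10, 100)) {
    tree <- simulate_phylogeny(n, seed = 7)
    expect_equal(ape::Ntip(tree), n)
    expect_true(all(tree$edge.length >= 0))
  }
  expect_error(simulate_phylogeny(1), ">= 2")
  a <- simulate_phylogeny(50, seed = 9)
  b <- simulate_phylogeny(50, seed = 9)
  expect_identical(ape::write.tree(a), ape::write.tree(b))
})

test_that("metadata tracks the latent gradient with the generating slopes", {
  cfg <- simulation_config(n_sites = 32, n_otus = 10, seed = 2)
  md <- simulate_metadata(cfg)
  expect_equal(nrow(md), 64)
  g <- attr(md, "gradient")
  top <- md[md$layer == "topsoil", ]
  gt <- g[top$sample_id]
  # oracle = the generating linear equations; noise sd is 20% of the range,
  # so the fitted slope must sit within a few standard errors of the truth
  for (vdef in list(c("map", 165, 246.5), c("mat", 6.4, -8.7),
                    c("ph", 9.9, -2.2), c("npp", 80, 320))) {
    v <- top[[vdef[1]]]
    fit <- lm(v ~ gt)
    slope <- as.numeric(vdef[3])
    se <- summary(fit)$coefficients[2, 2]
    expect_lt(abs(coef(fit)[2] - slope), 4 * se + 1e-9)
  }
  # gradient endpoints map to environmental extremes within noise
  expect_gt(mean(top$map[gt > 0.8]), mean(top$map[gt < 0.2]))
  expect_lt(mean(top$ph[gt > 0.8]), mean(top$ph[gt < 0.2]))
})

test_that("the transect spans its nominal length on the sphere", {
  cfg <- simulation_config(n_sites = 16, n_otus = 10, transect_length_km = 1500,
                           seed = 4)
  md <- simulate_metadata(cfg)
  d <- spatial_distance(md[md$layer == "topsoil", ])
  expect_equal(unclass(d)[1, 16], 1500, tolerance = 0.01)
})

test_that("community tables have exact row sums and a skewed abundance structure", {
  cfg <- simulation_config(n_sites = 8, n_otus = 200, reads_per_sample = 2000,
                           seed = 11)
  dat <- simulate_dataset(cfg)
  expect_true(all(rowSums(dat$table) == 2000))
  pooled <- sort(colSums(dat$table), decreasing = TRUE)
  top_decile <- sum(pooled[seq_len(ceiling(length(pooled) / 10))])
  expect_gt(top_decile / sum(pooled), 0.5)
})

test_that("Brownian optima carry phylogenetic signal", {
  cfg <- simulation_config(n_sites = 6, n_otus = 150, seed = 13)
  dat <- simulate_dataset(cfg)
  opt <- attr(dat$table, "optima")
  D <- ape::cophenetic.phylo(dat$tree)
  dopt <- abs(outer(opt, opt, "-"))
  ut <- upper.tri(D)
  expect_gt(cor(D[ut], dopt[ut]), 0.1)
})

test_that("selection regimes produce gradient-driven turnover, neutral ones do not", {
  # strong selection, well mixed: Bray-Curtis rises with gradient separation
  cfg <- simulation_config(n_sites = 8, n_otus = 150, niche_strength = 30,
                           dispersal_km = Inf, layer_effect = FALSE, seed = 17)
  dat <- simulate_dataset(cfg)
  bc <- bray_curtis(dat$table)
  g <- attr(dat$metadata, "gradient")[rownames(bc)]
  dg <- abs(outer(g, g, "-"))
  dimnames(dg) <- dimnames(bc)
  mt <- mantel_test(bc, pairwise_matrix(dg, "env_distance"),
                    n_perm = 199, seed = 1)
  expect_gt(mt$r, 0.3)
  expect_lt(mt$p, 0.05)

  # neutral well-mixed: no gradient signal
  cfg0 <- simulation_config(n_sites = 8, n_otus = 150, niche_strength = 0,
                            dispersal_km = Inf, layer_effect = FALSE, seed = 18)
  dat0 <- simulate_dataset(cfg0)
  bc0 <- bray_curtis(dat0$table)
  g0 <- attr(dat0$metadata, "gradient")[rownames(bc0)]
  dg0 <- abs(outer(g0, g0, "-")); dimnames(dg0) <- dimnames(bc0)
  mt0 <- mantel_test(bc0, pairwise_matrix(dg0, "env_distance"),
                     n_perm = 199, seed = 1)
  expect_lt(abs(mt0$r), 0.3)

  # dispersal-limited neutral: similarity decays with space, not with the
  # environment once space is controlled for
  cfgd <- simulation_config(n_sites = 10, n_otus = 150, niche_strength = 0,
                            dispersal_km = 100, layer_effect = FALSE, seed = 19)
  datd <- simulate_dataset(cfgd)
  md_t <- datd$metadata[datd$metadata$layer == "topsoil", ]
  attr(md_t, "group_map") <- attr(datd$metadata, "group_map")
  bcd <- bray_curtis(datd$table[md_t$sample_id, ])
  sp <- spatial_distance(md_t)
  en <- environmental_distance(md_t)
  mts <- mantel_test(bcd, sp, n_perm = 199, seed = 2)
  expect_gt(mts$r, 0.3)
  expect_lt(mts$p, 0.05)
  # partial: residualize both on space; env adds nothing
  y <- pair_values(bcd); s <- pair_values(sp); e <- pair_values(en)
  r_partial <- cor(resid(lm(y ~ s)), resid(lm(e ~ s)))
  expect_lt(abs(r_partial), 0.25)
})
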