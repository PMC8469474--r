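#' Great-circle spatial distance between samples
#'
#' Haversine distance on a sphere of radius 6371.0088 km, in kilometres.
#'
#' @param metadata data.frame with `sample_id`, `longitude`, `latitude`.
#' @return [pairwise_matrix()] with role `spatial_km`.
#' @export
spatial_distance <- function(metadata) {
  if (any(abs(metadata$latitude) > 90) || any(abs(metadata$longitude) > 180)) {
    stop("coordinates out of range")
  }
  p <- cbind(metadata$longitude, metadata$latitude)
  d <- geosphere::distm(p, fun = function(a, b) {
    geosphere::distHaversine(a, b, r = 6371008.8)
  }) / 1000
  dimnames(d) <- list(metadata$sample_id, metadata$sample_id)
  pairwise_matrix(d, "spatial_km")
}

# z-score the environmental variables of a metadata set; constant variables
# are dropped with a warning. Returns samples x variables matrix.
env_zscores <- function(metadata) {
  gm <- attr(metadata, "group_map")
  if (is.null(gm)) stop("metadata lacks a group_map attribute; use read_metadata()/validate_metadata()")
  X <- as.matrix(metadata[, names(gm), drop = FALSE])
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    warning("dropping constant variable(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  scale(X)
}

#' Composite environmental distance
#'
#' Each variable is z-scored across the supplied samples; each group is
#' reduced to one composite (the mean of its members' z-scores, or the first
#' principal component with `composite = "pca"`); the distance is Euclidean
#' over the selected group composites. Single-group calls give the per-driver
#' distances used in the random-forest stage.
#'
#' @param metadata metadata data.frame with `group_map` attribute.
#' @param groups `"all"` (default) or a subset of [env_group_names()].
#' @param composite `"mean"` (default) or `"pca"`.
#' @return [pairwise_matrix()] with role `env_distance`.
#' @export
environmental_distance <- function(metadata, groups = "all",
                                   composite = c("mean", "pca")) {
  composite <- match.arg(composite)
  gm <- attr(metadata, "group_map")
  Z <- env_zscores(metadata)
  gm <- gm[colnames(Z)]
  if (identical(groups, "all")) groups <- intersect(env_group_names(), unique(gm))
  unknown <- setdiff(groups, env_group_names())
  if (length(unknown)) stop("unknown group(s): ", paste(unknown, collapse = ", "))
  absent <- setdiff(groups, gm)
  if (length(absent)) stop("no variables mapped to group(s): ", paste(absent, collapse = ", "))
  comp <- vapply(groups, function(g) {
    zg <- Z[, names(gm)[gm == g], drop = FALSE]
    if (composite == "mean" || ncol(zg) == 1L) {
      rowMeans(zg)
    } else {
      as.numeric(prcomp(zg, center = FALSE, scale. = FALSE)$x[, 1L])
    }
  }, numeric(nrow(Z)))
  d <- as.matrix(stats::dist(comp))
  dimnames(d) <- list(metadata$sample_id, metadata$sample_id)
  pairwise_matrix(d, "env_distance")
}

#' Fit a distance-decay relationship
#'
#' Ordinary least-squares regression of pairwise community similarity on
#' pairwise distance over the upper triangle; the distance is standardized to
#' zero mean and unit sd over pairs by default so spatial and environmental
#' slopes are comparable. The slope is the community turnover rate; its
#' significance is attached via [mantel_test()].
#'
#' @param similarity [pairwise_matrix()] with role `similarity`.
#' @param distance [pairwise_matrix()] with a distance role.
#' @param standardize standardize distances over pairs (default `TRUE`).
#' @param n_perm Mantel permutations (default 999).
#' @param seed integer seed for the Mantel test.
#' @return object of class `ddr_fit`: `slope`, `intercept`, `pearson_r`,
#'   `mantel_r`, `mantel_p`, `n_pairs`, `n_perm`, `seed`.
#' @export
fit_distance_decay <- function(similarity, distance, standardize = TRUE,
                               n_perm = 999, seed = 1L) {
  if (!identical(attr(similarity, "role"), "similarity")) {
    stop("`similarity` must carry role = similarity (see to_similarity())")
  }
  check_same_labels(similarity, distance)
  y <- pair_values(similarity)
  x <- pair_values(distance)
  if (length(y) < 3) stop("need at least 3 pairs")
  if (standardize) x <- (x - mean(x)) / sd(x)
  fit <- lm(y ~ x)
  mt <- mantel_test(similarity, distance, n_perm = n_perm, seed = seed)
  out <- list(slope = unname(coef(fit)[2L]),
              intercept = unname(coef(fit)[1L]),
              pearson_r = cor(x, y),
              mantel_r = mt$r, mantel_p = mt$p,
              n_pairs = length(y), n_perm = n_perm, seed = seed)
  class(out) <- "ddr_fit"
  out
}

#' @export
print.ddr_fit <- function(x, ...) {
  cat(sprintf("distance-decay fit: slope %.4g, r %.3f, Mantel p %.4g (%d pairs)\n",
              x$slope, x$pearson_r, x$mantel_p, x$n_pairs))
  invisible(x)
}

#' Mantel test between two pairwise matrices
#'
#' Pearson correlation of the upper triangles; significance by simultaneous
#' row/column permutation of the second matrix (pairs are never shuffled
#' independently). The p-value is two-sided:
#' `p = (1 + #{|r_perm| >= |r_obs|}) / (1 + n_perm)`.
#'
#' @param m1,m2 square symmetric matrices with matching labels.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return list with `r`, `p`, `n_perm`, `seed`.
#' @export
mantel_test <- function(m1, m2, n_perm = 999, seed = 1L) {
  check_same_labels(m1, m2)
  n <- nrow(m1)
  idx <- pair_index(n)
  v1 <- unclass(m1)[idx]
  if (sd(v1) == 0) stop("constant upper triangle in m1")
  M2 <- unclass(m2)
  v2 <- M2[idx]
  if (sd(v2) == 0) stop("constant upper triangle in m2")
  r_obs <- cor(v1, v2)
  set.seed(seed)
  hits <- 0L
  for (k in seq_len(n_perm)) {
    p <- sample.int(n)
    v2p <- M2[cbind(p[idx[, 1]], p[idx[, 2]])]
    if (abs(cor(v1, v2p)) >= abs(r_obs) - 1e-12) hits <- hits + 1L
  }
  list(r = r_obs, p = (1 + hits) / (1 + n_perm), n_perm = n_perm, seed = seed)
}

# Within-group upper-triangle pair rows (i, j) for a logical sample mask.
group_pairs <- function(mask) {
  s <- which(mask)
  if (length(s) < 2) return(matrix(integer(), 0, 2))
  t(utils::combn(s, 2))
}

#' Compare distance-decay slopes between two sample groups
#'
#' Pooled linear model `similarity ~ distance * group` over within-group
#' pairs. Because pairwise similarities sharing a sample are not independent,
#' the observed interaction coefficient is tested against a permutation null
#' that shuffles group labels at the level of whole samples (never of pairs);
#' the classical ANOVA-style p-value for the interaction is also reported for
#' reference. Distances are standardized over the pooled within-group pairs.
#'
#' @param similarity [pairwise_matrix()], role `similarity`.
#' @param distance [pairwise_matrix()] with a distance role.
#' @param grouping factor (2 levels) over the samples of `similarity`.
#' @param n_perm sample-label permutations (default 999).
#' @param seed integer seed.
#' @return list of class `slope_comparison`: `interaction` (slope
#'   difference, group 2 minus group 1), `slopes` (per group), `p_perm`,
#'   `p_classical`, `n_perm`, `seed`.
#' @export
compare_slopes <- function(similarity, distance, grouping, n_perm = 999,
                           seed = 1L) {
  check_same_labels(similarity, distance)
  grouping <- factor(grouping)
  if (nlevels(grouping) != 2L) stop("grouping must have exactly 2 levels")
  if (length(grouping) != nrow(similarity)) stop("grouping length mismatch")
  if (min(table(grouping)) < 3L) stop("each group needs >= 3 samples")
  S <- unclass(similarity); D <- unclass(distance)
  mu_d <- mean(pair_values(distance)); sd_d <- sd(pair_values(distance))

  stat_for <- function(g) {
    rows <- rbind(cbind(group_pairs(g == levels(g)[1L]), 0),
                  cbind(group_pairs(g == levels(g)[2L]), 1))
    y <- S[rows[, 1:2, drop = FALSE]]
    x <- (D[rows[, 1:2, drop = FALSE]] - mu_d) / sd_d
    grp <- rows[, 3L]
    X <- cbind(1, x, grp, x * grp)
    fit <- lm.fit(X, y)
    fit$coefficients[4L]
  }
  b_obs <- stat_for(grouping)
  set.seed(seed)
  hits <- 0L
  for (k in seq_len(n_perm)) {
    if (abs(stat_for(sample(grouping))) >= abs(b_obs) - 1e-12) hits <- hits + 1L
  }
  # classical (pair-level) reference p for the interaction term
  rows <- rbind(cbind(group_pairs(grouping == levels(grouping)[1L]), 0),
                cbind(group_pairs(grouping == levels(grouping)[2L]), 1))
  y <- S[rows[, 1:2, drop = FALSE]]
  x <- (D[rows[, 1:2, drop = FALSE]] - mu_d) / sd_d
  grp <- rows[, 3L]
  cls <- summary(lm(y ~ x * grp))$coefficients
  slopes <- c(cls["x", "Estimate"], cls["x", "Estimate"] + cls["x:grp", "Estimate"])
  names(slopes) <- levels(grouping)
  out <- list(interaction = unname(b_obs), slopes = slopes,
              p_perm = (1 + hits) / (1 + n_perm),
              p_classical = unname(cls["x:grp", "Pr(>|t|)"]),
              n_perm = n_perm, seed = seed)
  class(out) <- "slope_comparison"
  out
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat(sprintf("slope difference %.4g (slopes: %s); permutation p %.4g, classical p %.4g\n",
              x$interaction,
              paste(sprintf("%s %.4g", names(x$slopes), x$slopes), collapse = ", "),
              x$p_perm, x$p_classical))
  invisible(x)
}
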