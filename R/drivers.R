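#' Variation partitioning of beta-diversity on distance matrices
#'
#' Multiple regression on distance matrices over the vectorized upper
#' triangles: `r2_full = R2(beta ~ env + spa)`, unique environmental fraction
#' `a = r2_full - R2(beta ~ spa)`, unique spatial fraction
#' `c = r2_full - R2(beta ~ env)`, shared `b = r2_full - a - c`, residual
#' `d = 1 - r2_full`. The four fractions sum to 1 exactly (no flooring is
#' applied to them); tiny negative unique fractions are floored at zero only
#' when computing the deterministic/stochastic percentages
#' `deterministic_pct = 100 a / (a + c)` and
#' `stochastic_pct = 100 c / (a + c)`, which read the unique environmental
#' vs spatial effects as the footprint of selection vs dispersal/drift.
#' Adjusted-R2 analogues are reported alongside.
#'
#' @param beta [pairwise_matrix()], role `dissimilarity` (or any numeric
#'   pairwise matrix).
#' @param env_dist,spatial_dist predictor distance matrices, same labels.
#' @return object of class `varpart_fractions`: `a`, `b`, `c`, `d`,
#'   `r2_full`, `deterministic_pct`, `stochastic_pct`, `adjusted` (same
#'   fractions from adjusted R2), `floored`, `collinear`, `n_pairs`.
#' @export
variation_partition <- function(beta, env_dist, spatial_dist) {
  check_same_labels(beta, env_dist)
  check_same_labels(beta, spatial_dist)
  y <- pair_values(beta)
  e <- pair_values(env_dist)
  s <- pair_values(spatial_dist)
  if (sd(e) == 0 || sd(s) == 0) stop("constant predictor distances")
  collinear <- abs(cor(e, s)) > 1 - 1e-12
  if (collinear) warning("env and spatial distances are collinear; shared fraction b is unstable")

  r2 <- function(fit) summary(fit)$r.squared
  r2a <- function(fit) summary(fit)$adj.r.squared
  f_full <- lm(y ~ e + s); f_e <- lm(y ~ e); f_s <- lm(y ~ s)

  frac <- function(R2full, R2e, R2s) {
    a <- R2full - R2s
    c <- R2full - R2e
    b <- R2full - a - c
    d <- 1 - R2full
    af <- max(a, 0); cf <- max(c, 0)
    det <- if (af + cf > 0) 100 * af / (af + cf) else NA_real_
    list(a = a, b = b, c = c, d = d, r2_full = R2full,
         deterministic_pct = det,
         stochastic_pct = if (is.na(det)) NA_real_ else 100 - det,
         floored = (a < 0) || (c < 0))
  }
  raw <- frac(r2(f_full), r2(f_e), r2(f_s))
  adj <- frac(r2a(f_full), r2a(f_e), r2a(f_s))
  out <- c(raw, list(adjusted = adj, collinear = collinear,
                     n_pairs = length(y)))
  class(out) <- "varpart_fractions"
  out
}

#' @export
print.varpart_fractions <- function(x, ...) {
  cat(sprintf("varpart: env unique a=%.3f, shared b=%.3f, spatial unique c=%.3f, residual d=%.3f\n",
              x$a, x$b, x$c, x$d))
  cat(sprintf("deterministic %.1f%% vs stochastic %.1f%% (of unique effects)\n",
              x$deterministic_pct, x$stochastic_pct))
  invisible(x)
}

#' Random-forest importance of individual beta-diversity drivers
#'
#' Regression forest of the vectorized beta-diversity on the vectorized
#' predictor distances (spatial distance plus the six single-group
#' environmental distances, typically). Importance is the mean percent
#' increase in out-of-bag MSE when the predictor is permuted
#' (`%IncMSE` of [randomForest::randomForest()]).
#'
#' @param beta [pairwise_matrix()] response.
#' @param predictors named list of pairwise matrices with the same labels.
#' @param n_trees trees in the forest (default 500).
#' @param seed integer seed (forests are deterministic given the seed).
#' @return data.frame of class `importance_table`: `predictor`,
#'   `importance` (%IncMSE), `rank`.
#' @export
rf_importance <- function(beta, predictors, n_trees = 500, seed = 1L) {
  if (length(predictors) < 2L || is.null(names(predictors))) {
    stop("need a named list of >= 2 predictor matrices")
  }
  for (p in predictors) check_same_labels(beta, p)
  y <- pair_values(beta)
  X <- as.data.frame(lapply(predictors, pair_values))
  if (length(y) < 10L) stop("too few pairs for a regression forest")
  set.seed(seed)
  rf <- randomForest::randomForest(X, y, ntree = n_trees, importance = TRUE)
  imp <- randomForest::importance(rf, type = 1L)[, 1L]
  out <- data.frame(predictor = names(predictors),
                    importance = unname(imp[names(predictors)]),
                    row.names = NULL)
  out$rank <- rank(-out$importance, ties.method = "first")
  class(out) <- c("importance_table", "data.frame")
  out
}
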