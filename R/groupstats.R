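# Shared validation for the dissimilarity-matrix group tests.
check_grouping <- function(beta, grouping) {
  grouping <- factor(grouping)
  if (length(grouping) != nrow(beta)) stop("grouping length mismatch")
  if (nlevels(grouping) < 2L) stop("need at least 2 groups")
  if (min(table(grouping)) < 2L) stop("singleton group")
  grouping
}

group_test_result <- function(test, statistic, p, n_perm, seed) {
  out <- data.frame(test = test, statistic = statistic, p = p,
                    n_perm = n_perm, seed = seed)
  class(out) <- c("group_test_result", "data.frame")
  out
}

#' PERMANOVA (Adonis) on a dissimilarity matrix
#'
#' Pseudo-F from Gower-centred within/between sums of squared
#' dissimilarities, significance by label permutation
#' (via [vegan::adonis2()]).
#'
#' @param beta [pairwise_matrix()] dissimilarity.
#' @param grouping factor over samples, >= 2 groups of >= 2 samples.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return one-row data.frame: `test`, `statistic` (F), `p`, `n_perm`, `seed`.
#' @export
permanova <- function(beta, grouping, n_perm = 999, seed = 1L) {
  grouping <- check_grouping(beta, grouping)
  set.seed(seed)
  fit <- vegan::adonis2(as.dist(unclass(beta)) ~ grouping,
                        permutations = n_perm)
  group_test_result("permanova", fit$F[1L], fit$`Pr(>F)`[1L], n_perm, seed)
}

#' Analysis of similarity (ANOSIM)
#'
#' `R = (mean between-group rank - mean within-group rank) / (n_pairs / 2)`
#' on dissimilarity ranks, via [vegan::anosim()].
#'
#' @inheritParams permanova
#' @return one-row data.frame: `test`, `statistic` (R), `p`, `n_perm`, `seed`.
#' @export
anosim <- function(beta, grouping, n_perm = 999, seed = 1L) {
  grouping <- check_grouping(beta, grouping)
  set.seed(seed)
  fit <- vegan::anosim(as.dist(unclass(beta)), grouping,
                       permutations = n_perm)
  group_test_result("anosim", fit$statistic, fit$signif, n_perm, seed)
}

#' Multiresponse permutation procedure (MRPP)
#'
#' Group-size-weighted mean within-group dissimilarity delta; chance-corrected
#' effect `A = 1 - delta / E[delta_perm]`, via [vegan::mrpp()].
#'
#' @inheritParams permanova
#' @return one-row data.frame: `test`, `statistic` (A), `p`, plus
#'   attribute `delta`.
#' @export
mrpp <- function(beta, grouping, n_perm = 999, seed = 1L) {
  grouping <- check_grouping(beta, grouping)
  set.seed(seed)
  fit <- vegan::mrpp(as.dist(unclass(beta)), grouping,
                     permutations = n_perm)
  out <- group_test_result("mrpp", fit$A, fit$Pvalue, n_perm, seed)
  attr(out, "delta") <- fit$delta
  out
}

#' Multivariate homogeneity of group dispersions (PERMDISP)
#'
#' Principal-coordinate embedding of the dissimilarity (negative eigenvalues
#' handled by vegan's standard correction), per-sample distance to the group
#' centroid (or spatial median), ANOVA F on those distances, permutation p.
#' Targets spread only: translating a group rigidly leaves it unaffected.
#'
#' @inheritParams permanova
#' @param type `"centroid"` (default) or `"median"`.
#' @return one-row data.frame: `test`, `statistic` (dispersion F), `p`.
#' @export
permdisp <- function(beta, grouping, n_perm = 999, seed = 1L,
                     type = c("centroid", "median")) {
  type <- match.arg(type)
  grouping <- check_grouping(beta, grouping)
  set.seed(seed)
  mod <- vegan::betadisper(as.dist(unclass(beta)), grouping, type = type)
  pt <- vegan::permutest(mod, permutations = n_perm)
  group_test_result("permdisp", pt$tab$F[1L], pt$tab$`Pr(>F)`[1L],
                    n_perm, seed)
}

#' Paired topsoil-minus-subsoil abundance contrast per taxon group
#'
#' For each taxon group, the per-site difference in summed relative abundance
#' between the two layers (topsoil minus subsoil) is averaged, and a
#' two-sided paired sign-flip permutation test gives the p-value; groups
#' significant at alpha = 0.05 are starred.
#'
#' @param table samples x OTUs count matrix covering both layers.
#' @param taxon_groups named character vector, OTU id -> group label.
#' @param metadata data.frame with `sample_id`, `site_id`, `layer`; every
#'   site must have both layers.
#' @param n_perm sign-flip permutations (default 999).
#' @param seed integer seed.
#' @return data.frame: `group`, `delta` (mean topsoil - subsoil relative
#'   abundance), `p`, `sig` (`"*"` at p < 0.05).
#' @export
taxon_abundance_contrast <- function(table, taxon_groups, metadata,
                                     n_perm = 999, seed = 1L) {
  md <- metadata[match(rownames(table), metadata$sample_id), ]
  if (anyNA(md$sample_id)) stop("samples missing from metadata")
  sites <- unique(md$site_id)
  top <- md$sample_id[md$layer == "topsoil"][match(sites, md$site_id[md$layer == "topsoil"])]
  sub <- md$sample_id[md$layer == "subsoil"][match(sites, md$site_id[md$layer == "subsoil"])]
  if (anyNA(top) || anyNA(sub)) stop("unpaired site(s): every site needs both layers")
  unknown <- setdiff(names(taxon_groups), colnames(table))
  if (length(unknown)) stop("taxon_groups names not in table: ", paste(head(unknown), collapse = ", "))
  rel <- relative_abundance(table)
  groups <- sort(unique(taxon_groups))
  G <- vapply(groups, function(g) {
    rowSums(rel[, names(taxon_groups)[taxon_groups == g], drop = FALSE])
  }, numeric(nrow(rel)))
  diffs <- G[top, , drop = FALSE] - G[sub, , drop = FALSE]
  set.seed(seed)
  res <- lapply(groups, function(g) {
    d <- diffs[, g]
    obs <- mean(d)
    if (all(d == 0)) return(data.frame(group = g, delta = 0, p = 1))
    hits <- 0L
    for (k in seq_len(n_perm)) {
      flip <- sample(c(-1, 1), length(d), replace = TRUE)
      if (abs(mean(flip * d)) >= abs(obs) - 1e-15) hits <- hits + 1L
    }
    data.frame(group = g, delta = obs, p = (1 + hits) / (1 + n_perm))
  })
  out <- do.call(rbind, res)
  out$sig <- ifelse(out$p < 0.05, "*", "")
  out
}
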