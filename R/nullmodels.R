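# Internal state shared by beta_mntd() and bnti(): patristic distances over
# the full tree (the regional pool), relative-abundance weights, and the
# per-sample membership lists handed to the C++ nearest-taxon kernel.
mntd_setup <- function(table, tree, abundance_weighted) {
  tree <- validate_phylogeny(tree)
  table <- match_table_tree(table, tree)
  if (nrow(table) < 2) stop("need at least 2 samples")
  if (any(rowSums(table) == 0)) stop("empty sample")
  D <- ape::cophenetic.phylo(tree)
  tip_of_otu <- match(colnames(table), tree$tip.label)
  Fm <- if (abundance_weighted) {
    relative_abundance(table)
  } else {
    pres <- (table > 0) * 1
    sweep(pres, 1, rowSums(pres), "/")
  }
  members <- lapply(seq_len(nrow(table)),
                    function(s) which(table[s, ] > 0) - 1L)
  list(D = D, tip_of_otu = tip_of_otu, Fm = Fm, members = members,
       n_tip = length(tree$tip.label), labels = rownames(table))
}

# betaMNTD matrix for one tip assignment (0-based indices into D).
bmntd_from_setup <- function(st, tip0, exclude_conspecifics) {
  M <- min_taxon_dist(st$D, st$members, tip0, exclude_conspecifics)
  X <- st$Fm %*% M
  (X + t(X)) / 2
}

#' Abundance-weighted beta mean nearest-taxon distance (betaMNTD)
#'
#' For samples A and B,
#' `betaMNTD = 1/2 [ sum_{i in A} f_iA min_{j in B} d(i, j)
#'                 + sum_{j in B} f_jB min_{i in A} d(j, i) ]`,
#' with `f` the relative abundance (or `1/richness` when
#' `abundance_weighted = FALSE`) and `d` the patristic distance on the tree.
#'
#' @param table samples x OTUs count matrix.
#' @param tree rooted `phylo` tree; tips a superset of the table's OTUs.
#' @param abundance_weighted weight by relative abundance (default `TRUE`).
#' @param exclude_conspecifics drop the conspecific (same-OTU) match in the
#'   other community from the nearest-taxon minimum. Needed when cosmopolitan
#'   taxa occur in every community, where self-matches force betaMNTD towards
#'   zero and the null variance collapses.
#' @return [pairwise_matrix()] with role `bmntd`.
#' @export
beta_mntd <- function(table, tree, abundance_weighted = TRUE,
                      exclude_conspecifics = FALSE) {
  st <- mntd_setup(table, tree, abundance_weighted)
  B <- bmntd_from_setup(st, st$tip_of_otu - 1L, exclude_conspecifics)
  diag(B) <- 0  # the self-pair is not a community pair
  dimnames(B) <- list(st$labels, st$labels)
  pairwise_matrix(B, "bmntd")
}

#' Phylogenetic beta nearest-taxon index (betaNTI)
#'
#' Null model for betaMNTD: tip labels are shuffled across the full supplied
#' tree (the regional pool), randomizing phylogenetic relationships while
#' holding abundances and occupancies fixed. Per pair,
#' `betaNTI = (betaMNTD_obs - mean(betaMNTD_null)) / sd(betaMNTD_null)`.
#' `|betaNTI| > 2` signals selection: variable selection if `> 2`
#' (more phylogenetic turnover than expected), homogeneous selection if
#' `< -2`.
#'
#' @inheritParams beta_mntd
#' @param n_rand number of randomizations (default 999).
#' @param seed integer seed; results are bit-identical on rerun.
#' @return object of class `null_model_result` with elements `statistic`
#'   (`"bnti"`), `obs` (betaMNTD), `null_mean`, `null_sd`, `score`
#'   ([pairwise_matrix()] role `bnti`, `NA` where the null sd is zero),
#'   `degenerate` (logical matrix flagging those pairs), `n_rand`, `seed`.
#' @export
bnti <- function(table, tree, n_rand = 999, seed = 1L,
                 abundance_weighted = TRUE, exclude_conspecifics = FALSE) {
  if (n_rand < 1) stop("n_rand must be >= 1")
  st <- mntd_setup(table, tree, abundance_weighted)
  obs <- bmntd_from_setup(st, st$tip_of_otu - 1L, exclude_conspecifics)
  set.seed(seed)
  n_s <- length(st$labels)
  sum1 <- matrix(0, n_s, n_s)
  sum2 <- matrix(0, n_s, n_s)
  n_otu <- ncol(st$Fm)
  for (r in seq_len(n_rand)) {
    tip0 <- sample.int(st$n_tip, n_otu) - 1L
    B <- bmntd_from_setup(st, tip0, exclude_conspecifics)
    sum1 <- sum1 + B
    sum2 <- sum2 + B * B
  }
  mu <- sum1 / n_rand
  sdv <- sqrt(pmax(sum2 - n_rand * mu^2, 0) / max(n_rand - 1, 1))
  degenerate <- sdv <= 1e-12
  z <- (obs - mu) / sdv
  z[degenerate] <- NA_real_
  # enforce exact symmetry against float accumulation order
  z <- (z + t(z)) / 2
  dimnames(z) <- dimnames(mu) <- dimnames(sdv) <-
    dimnames(degenerate) <- list(st$labels, st$labels)
  diag(z) <- NA_real_
  out <- list(statistic = "bnti", obs = obs, null_mean = mu, null_sd = sdv,
              score = pairwise_matrix(z, "bnti"),
              degenerate = degenerate, n_rand = n_rand, seed = seed)
  class(out) <- "null_model_result"
  out
}

#' Bray-Curtis-based Raup-Crick index (RC_Bray)
#'
#' Null communities preserve each sample's observed richness and total reads:
#' OTUs are drawn from the regional pool with probability proportional to
#' occupancy frequency; each drawn OTU receives one read (so null richness
#' equals observed richness exactly) and the remaining reads are allocated
#' among the drawn OTUs multinomially with probability proportional to
#' regional relative abundance. Each randomization builds one null assemblage per sample and
#' Bray-Curtis is taken across all pairs. Per pair,
#' `RC = 2 [ #(null < obs) + 0.5 #(null = obs) ] / n_rand - 1`, in \[-1, 1\].
#' `RC > 0.95` with `|betaNTI| <= 2` indicates dispersal limitation,
#' `RC < -0.95` homogenizing dispersal.
#'
#' @param table samples x OTUs count matrix, rarefied to equal depth.
#' @param n_rand number of randomizations (default 999).
#' @param seed integer seed.
#' @return `null_model_result` with `statistic = "rc_bray"`, `obs` (observed
#'   Bray-Curtis) and `score` ([pairwise_matrix()] role `rc`).
#' @export
raup_crick_bray <- function(table, n_rand = 999, seed = 1L) {
  table <- validate_otu_table(table)
  if (nrow(table) < 2) stop("need at least 2 samples")
  depth <- rowSums(table)
  if (length(unique(depth)) != 1L) {
    stop("samples must be rarefied to equal depth before RC_Bray")
  }
  pool <- which(colSums(table) > 0)
  occ <- colSums(table[, pool, drop = FALSE] > 0)
  reg <- colSums(table[, pool, drop = FALSE])
  rich <- rowSums(table > 0)
  if (any(rich > length(pool))) stop("sample richness exceeds regional pool size")
  obs <- as.matrix(vegan::vegdist(table, method = "bray"))
  set.seed(seed)
  n_s <- nrow(table)
  n_pool <- length(pool)
  less <- matrix(0, n_s, n_s)
  ties <- matrix(0, n_s, n_s)
  for (r in seq_len(n_rand)) {
    null_tab <- matrix(0L, n_s, n_pool)
    for (s in seq_len(n_s)) {
      draw <- sample.int(n_pool, rich[s], prob = occ)
      # each drawn OTU gets one read (observed richness is preserved
      # exactly), the remaining reads follow regional relative abundance
      null_tab[s, draw] <- 1L +
        rmultinom(1, depth[s] - rich[s], reg[draw])[, 1]
    }
    bc <- as.matrix(vegan::vegdist(null_tab, method = "bray"))
    less <- less + (bc < obs)
    ties <- ties + (bc == obs)
  }
  rc <- 2 * (less + 0.5 * ties) / n_rand - 1
  dimnames(rc) <- dimnames(obs)
  diag(rc) <- NA_real_
  out <- list(statistic = "rc_bray", obs = pairwise_matrix(obs, "dissimilarity"),
              score = pairwise_matrix(rc, "rc"),
              n_rand = n_rand, seed = seed)
  class(out) <- "null_model_result"
  out
}

#' Five-way ecological process classification
#'
#' Combines betaNTI and RC_Bray per pair: `betaNTI > bnti_cut` = variable
#' selection; `betaNTI < -bnti_cut` = homogeneous selection; otherwise
#' `RC < -rc_cut` = homogenizing dispersal, `RC > rc_cut` = dispersal
#' limitation, and anything else (weak selection/dispersal, diversification,
#' drift) = undominated. Boundary values (exactly +/-2 or +/-0.95) fall on
#' the stochastic/undominated side (strict inequalities for the extreme
#' classes). Pairs with an undefined betaNTI (zero null sd) are excluded
#' from the fractions and counted separately.
#'
#' @param bnti_result `null_model_result` from [bnti()] or a `bnti`-role
#'   [pairwise_matrix()].
#' @param rc_result `null_model_result` from [raup_crick_bray()] or an
#'   `rc`-role [pairwise_matrix()].
#' @param bnti_cut selection threshold (default 2).
#' @param rc_cut dispersal threshold (default 0.95).
#' @return object of class `process_summary`: `pairs` data.frame
#'   (sample_a, sample_b, bnti, rc, process), integer `counts` per process
#'   (sum exactly to `n_pairs`), `fractions` (counts / n_pairs), `n_pairs`,
#'   `n_excluded`, `thresholds`.
#' @export
classify_processes <- function(bnti_result, rc_result, bnti_cut = 2,
                               rc_cut = 0.95) {
  z <- if (inherits(bnti_result, "null_model_result")) bnti_result$score else bnti_result
  rc <- if (inherits(rc_result, "null_model_result")) rc_result$score else rc_result
  check_same_labels(z, rc)
  idx <- pair_index(nrow(z))
  zz <- unclass(z)[idx]
  rr <- unclass(rc)[idx]
  if (anyNA(rr)) stop("RC values missing for some pairs")
  lvl <- c("variable_selection", "homogeneous_selection",
           "homogenizing_dispersal", "dispersal_limitation", "undominated")
  lab <- rep(NA_character_, length(zz))
  ok <- !is.na(zz)
  lab[ok & zz > bnti_cut] <- "variable_selection"
  lab[ok & zz < -bnti_cut] <- "homogeneous_selection"
  stoch <- ok & abs(zz) <= bnti_cut
  lab[stoch & rr < -rc_cut] <- "homogenizing_dispersal"
  lab[stoch & rr > rc_cut] <- "dispersal_limitation"
  lab[stoch & abs(rr) <= rc_cut] <- "undominated"
  pairs <- data.frame(sample_a = rownames(z)[idx[, 1]],
                      sample_b = rownames(z)[idx[, 2]],
                      bnti = zz, rc = rr,
                      process = factor(lab, levels = lvl))
  counted <- pairs[!is.na(pairs$process), , drop = FALSE]
  if (nrow(counted) == 0L) stop("no classifiable pairs (all betaNTI undefined)")
  cnt <- table(counted$process)
  out <- list(pairs = pairs,
              counts = setNames(as.integer(cnt), names(cnt)),
              fractions = setNames(as.numeric(cnt) / nrow(counted), names(cnt)),
              n_pairs = nrow(counted),
              n_excluded = sum(is.na(pairs$process)),
              thresholds = c(bnti_cut = bnti_cut, rc_cut = rc_cut))
  class(out) <- "process_summary"
  out
}

#' @export
print.process_summary <- function(x, ...) {
  cat("Ecological process classification over", x$n_pairs, "pairs")
  if (x$n_excluded > 0) cat(" (", x$n_excluded, " excluded: undefined betaNTI)", sep = "")
  cat("\n")
  print(round(x$fractions, 3))
  invisible(x)
}
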