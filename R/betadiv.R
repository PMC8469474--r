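#' Rarefy an OTU table to a common depth
#'
#' Subsamples each sample without replacement to exactly `depth` reads
#' (via [vegan::rrarefy()]), so all row sums are equal afterwards.
#'
#' @param table samples x OTUs count matrix.
#' @param depth target reads per sample; must not exceed the smallest row sum.
#' @param seed integer seed.
#' @return rarefied integer count matrix.
#' @export
rarefy <- function(table, depth, seed = 1L) {
  table <- validate_otu_table(table)
  if (depth > min(rowSums(table))) {
    stop("depth exceeds the smallest sample total (",
         min(rowSums(table)), ")")
  }
  set.seed(seed)
  out <- withCallingHandlers(
    vegan::rrarefy(table, depth),
    # vegan warns when the smallest positive count exceeds 1 (a heuristic
    # for transformed data); validated integer tables trip it spuriously
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  validate_otu_table(out)
}

#' Per-sample relative abundances
#'
#' @param table samples x OTUs count matrix.
#' @return numeric matrix; rows sum to 1.
#' @export
relative_abundance <- function(table) {
  rs <- rowSums(table)
  if (any(rs == 0)) stop("sample(s) with zero total reads")
  sweep(table, 1, rs, "/")
}

#' Partition OTUs into abundant, rare and intermediate classes
#'
#' With `mode = "pooled"` (default) the classification uses pooled relative
#' abundance: OTU i is abundant iff `total_i / grand_total >= abundant_min`
#' and rare iff `<= rare_max`. `mode = "every_sample"` instead requires the
#' condition in each individual sample (the literal reading of an
#' "in all samples" threshold). Everything else is intermediate.
#'
#' @param table samples x OTUs count matrix.
#' @param abundant_min abundant threshold as a fraction; default 0.001 (0.1%).
#' @param rare_max rare threshold as a fraction; default 0.0001 (0.01%).
#' @param mode `"pooled"` or `"every_sample"`.
#' @return list of class `abundance_partition` with `abundant_ids`,
#'   `rare_ids`, `intermediate_ids`, `thresholds`, `mode`.
#' @export
partition_by_abundance <- function(table, abundant_min = 0.001,
                                   rare_max = 0.0001,
                                   mode = c("pooled", "every_sample")) {
  mode <- match.arg(mode)
  table <- validate_otu_table(table)
  if (abundant_min <= rare_max) stop("abundant_min must exceed rare_max")
  otus <- colnames(table)
  if (mode == "pooled") {
    p <- colSums(table) / sum(table)
    abundant <- p >= abundant_min
    rare <- p <= rare_max
  } else {
    rel <- relative_abundance(table)
    abundant <- apply(rel, 2, function(x) all(x >= abundant_min))
    rare <- apply(rel, 2, function(x) all(x <= rare_max))
  }
  out <- list(abundant_ids = otus[abundant & !rare],
              rare_ids = otus[rare],
              intermediate_ids = otus[!abundant & !rare],
              thresholds = c(abundant_min = abundant_min, rare_max = rare_max),
              mode = mode)
  class(out) <- "abundance_partition"
  out
}

#' Bray-Curtis dissimilarity
#'
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)`, computed on counts
#' (intended for equal-depth, rarefied tables) via [vegan::vegdist()].
#'
#' @param table samples x OTUs count matrix (>= 2 samples, no empty sample).
#' @return [pairwise_matrix()] with role `dissimilarity`.
#' @export
bray_curtis <- function(table) {
  if (nrow(table) < 2) stop("need at least 2 samples")
  if (any(rowSums(table) == 0)) stop("sample(s) with zero total reads")
  d <- as.matrix(vegan::vegdist(table, method = "bray"))
  pairwise_matrix(d, "dissimilarity")
}

#' Weighted UniFrac dissimilarity
#'
#' For each branch `b` with length `l_b`, let `A_b`, `B_b` be the summed
#' relative abundances of the tips descending `b` in samples A and B. Raw
#' weighted UniFrac is `sum_b l_b |A_b - B_b|`; the normalized variant
#' (default) divides by `sum_b l_b (A_b + B_b)` so values lie in \[0, 1\].
#' Tree tips must be a superset of the table's OTUs.
#'
#' @param table samples x OTUs count matrix.
#' @param tree rooted `phylo` tree with branch lengths.
#' @param normalized return the \[0, 1\]-bounded variant (default `TRUE`).
#' @return [pairwise_matrix()] with role `dissimilarity` (normalized) or
#'   `bmntd`-style unbounded matrix when `normalized = FALSE`.
#' @export
weighted_unifrac <- function(table, tree, normalized = TRUE) {
  if (nrow(table) < 2) stop("need at least 2 samples")
  tree <- validate_phylogeny(tree)
  table <- match_table_tree(table, tree)
  rel <- relative_abundance(table)

  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  n_s <- nrow(rel)
  # branch abundances by postorder accumulation: children before parents
  V <- matrix(0, n_node, n_s)
  V[match(colnames(rel), tree$tip.label), ] <- t(rel)
  po <- ape::postorder(tree)
  for (e in po) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    V[p, ] <- V[p, ] + V[ch, ]
  }
  A <- V[tree$edge[, 2L], , drop = FALSE]  # edges x samples
  len <- tree$edge.length

  d <- matrix(0, n_s, n_s, dimnames = list(rownames(rel), rownames(rel)))
  for (i in seq_len(n_s - 1)) {
    for (j in (i + 1):n_s) {
      num <- sum(len * abs(A[, i] - A[, j]))
      val <- if (normalized) num / sum(len * (A[, i] + A[, j])) else num
      d[i, j] <- d[j, i] <- val
    }
  }
  pairwise_matrix(d, if (normalized) "dissimilarity" else "bmntd")
}

#' Subset an OTU table to a set of OTUs, keeping the original counts
#'
#' Used for abundant/rare sub-communities: counts are not re-rarefied or
#' re-normalized.
#'
#' @param table samples x OTUs count matrix.
#' @param otu_ids OTU ids to keep.
#' @param drop_empty_samples drop samples left with zero reads.
#' @return subset count matrix.
#' @export
subset_otus <- function(table, otu_ids, drop_empty_samples = FALSE) {
  missing <- setdiff(otu_ids, colnames(table))
  if (length(missing)) stop("unknown OTU id(s): ", paste(head(missing), collapse = ", "))
  out <- table[, otu_ids, drop = FALSE]
  if (drop_empty_samples) out <- out[rowSums(out) > 0, , drop = FALSE]
  out
}
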