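# Random fixtures and independent brute-force oracles. The oracles are kept
# deliberately naive (explicit loops, path enumeration) so they share no code
# path with the implementations they check.

rand_tree <- function(n_tips, seed) {
  set.seed(seed)
  tree <- ape::rtree(n_tips, br = function(n) rexp(n, 1))
  tree$tip.label <- sprintf("OTU%03d", seq_len(n_tips))
  tree
}

rand_table <- function(n_samples, n_otus, seed, lambda = 4) {
  set.seed(seed)
  repeat {
    m <- matrix(rpois(n_samples * n_otus, lambda), n_samples, n_otus,
                dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                                sprintf("OTU%03d", seq_len(n_otus))))
    if (all(rowSums(m) > 0)) break
  }
  storage.mode(m) <- "integer"
  m
}

bc_brute <- function(x, y) sum(abs(x - y)) / sum(x + y)

# tips descending an edge, by root-path enumeration
edge_tips <- function(tree, edge_row) {
  node <- tree$edge[edge_row, 2L]
  root <- length(tree$tip.label) + 1L
  keep <- vapply(seq_along(tree$tip.label), function(t) {
    node %in% ape::nodepath(tree, root, t)
  }, logical(1))
  tree$tip.label[keep]
}

wunifrac_brute <- function(tree, xa, xb, normalized = TRUE) {
  pa <- xa / sum(xa)
  pb <- xb / sum(xb)
  num <- 0; den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- edge_tips(tree, e)
    A <- sum(pa[intersect(tips, names(pa))])
    B <- sum(pb[intersect(tips, names(pb))])
    num <- num + tree$edge.length[e] * abs(A - B)
    den <- den + tree$edge.length[e] * (A + B)
  }
  if (normalized) num / den else num
}

bmntd_brute <- function(tree, xa, xb, weighted = TRUE,
                        exclude_conspecifics = FALSE) {
  D <- ape::cophenetic.phylo(tree)
  A <- names(xa)[xa > 0]; B <- names(xb)[xb > 0]
  fa <- if (weighted) xa[A] / sum(xa) else setNames(rep(1 / length(A), length(A)), A)
  fb <- if (weighted) xb[B] / sum(xb) else setNames(rep(1 / length(B), length(B)), B)
  nearest <- function(i, other) {
    cand <- if (exclude_conspecifics) setdiff(other, i) else other
    if (length(cand) == 0L) return(0)
    min(D[i, cand])
  }
  tA <- sum(vapply(A, function(i) fa[i] * nearest(i, B), numeric(1)))
  tB <- sum(vapply(B, function(j) fb[j] * nearest(j, A), numeric(1)))
  (tA + tB) / 2
}

# simple 2D point-cloud dissimilarity fixture for the group tests
points_beta <- function(xy) {
  d <- as.matrix(dist(xy))
  d <- d / max(d)
  dimnames(d) <- list(sprintf("s%02d", seq_len(nrow(xy))),
                      sprintf("s%02d", seq_len(nrow(xy))))
  pairwise_matrix(d, "dissimilarity")
}
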