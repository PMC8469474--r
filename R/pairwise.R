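#' Pairwise sample-by-sample matrices
#'
#' All pairwise quantities in the package (dissimilarity, similarity, spatial
#' and environmental distance, betaMNTD, betaNTI, RC_Bray) travel as a square
#' symmetric numeric matrix with sample labels and a `role` attribute that
#' records what the values mean and fixes the admissible range:
#'
#' * `dissimilarity`, `similarity`: values in \[0, 1\]; diagonal 0 (resp. 1).
#' * `spatial_km`, `env_distance`, `bmntd`: non-negative, zero diagonal.
#' * `bnti`: standardized effect sizes, unbounded; diagonal masked as `NA`.
#' * `rc`: values in \[-1, 1\]; diagonal masked as `NA`.
#'
#' @param values square numeric matrix with identical row/column labels.
#' @param role one of the roles above.
#' @return the validated matrix with attribute `role` and class
#'   `pairwise_matrix`.
#' @export
pairwise_matrix <- function(values, role) {
  role <- match.arg(role, pairwise_roles())
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (nrow(values) != ncol(values)) stop("pairwise matrix must be square")
  labels <- rownames(values)
  if (is.null(labels) || is.null(colnames(values)) ||
      !identical(labels, colnames(values))) {
    stop("pairwise matrix needs identical row and column labels")
  }
  if (anyDuplicated(labels)) stop("duplicate sample labels")
  if (role %in% c("bnti", "rc")) diag(values) <- NA_real_
  attr(values, "role") <- role
  class(values) <- c("pairwise_matrix", "matrix", "array")
  validate_pairwise(values)
  values
}

pairwise_roles <- function() {
  c("dissimilarity", "similarity", "spatial_km", "env_distance",
    "bmntd", "bnti", "rc")
}

#' Validate a pairwise matrix against its role contract
#'
#' @param m a [pairwise_matrix()].
#' @param tol numerical tolerance for symmetry and range checks.
#' @return `m`, invisibly; errors on violation.
#' @export
validate_pairwise <- function(m, tol = 1e-8) {
  role <- attr(m, "role")
  if (is.null(role)) stop("not a pairwise_matrix: missing role")
  v <- unclass(m)
  off <- v[row(v) != col(v)]
  if (anyNA(off)) {
    # betaNTI is undefined where the null sd collapses; other roles are total
    if (role != "bnti") stop("off-diagonal NA values in pairwise matrix")
    if (!identical(is.na(v), is.na(t(v)))) stop("asymmetric NA pattern")
    off <- off[!is.na(off)]
    if (!length(off)) off <- 0
  }
  sym_diff <- abs(v - t(v))
  if (any(!is.na(sym_diff)) && max(sym_diff, na.rm = TRUE) > tol) {
    stop("matrix not symmetric")
  }
  d <- diag(v)
  if (role == "similarity") {
    if (max(abs(d - 1)) > tol) stop("similarity diagonal must be 1")
  } else if (role %in% c("bnti", "rc")) {
    if (!all(is.na(d))) stop("diagonal must be masked NA for role ", role)
  } else {
    if (max(abs(d)) > tol) stop("diagonal must be 0 for role ", role)
  }
  rng <- switch(role,
    dissimilarity = c(0 - tol, 1 + tol),
    similarity = c(0 - tol, 1 + tol),
    rc = c(-1 - tol, 1 + tol),
    spatial_km = c(0 - tol, Inf),
    env_distance = c(0 - tol, Inf),
    bmntd = c(0 - tol, Inf),
    bnti = c(-Inf, Inf)
  )
  if (min(off) < rng[1] || max(off) > rng[2]) {
    stop("values out of range for role ", role)
  }
  invisible(m)
}

#' Convert a bounded dissimilarity to the companion similarity view
#'
#' @param m a `pairwise_matrix` with role `dissimilarity`.
#' @return a `pairwise_matrix` with role `similarity` (1 - dissimilarity).
#' @export
to_similarity <- function(m) {
  if (!identical(attr(m, "role"), "dissimilarity")) {
    stop("to_similarity() expects role = dissimilarity")
  }
  pairwise_matrix(1 - unclass(m), "similarity")
}

# Upper-triangle (i < j) pair index matrix for n labels.
pair_index <- function(n) {
  which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
}

#' Extract the vector of upper-triangle pair values
#'
#' @param m square matrix.
#' @return numeric vector, pairs ordered column-wise (i < j).
#' @export
pair_values <- function(m) {
  v <- unclass(m)
  v[upper.tri(v)]
}

# Check two pairwise matrices share the same labels (order included).
check_same_labels <- function(a, b) {
  if (!identical(rownames(a), rownames(b))) {
    stop("pairwise matrices must share the same sample labels")
  }
  invisible(TRUE)
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("pairwise_matrix [%s], %d samples\n",
              attr(x, "role"), nrow(x)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))])
  invisible(x)
}
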