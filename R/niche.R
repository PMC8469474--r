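#' Levins' habitat niche breadth per OTU
#'
#' `B_i = 1 / sum_j p_ij^2` with `p_ij` the fraction of OTU i's reads found
#' in sample j. B is the effective number of habitats the OTU occupies:
#' 1 for an OTU confined to a single sample, `n_samples` for a perfectly
#' even OTU. Invariant to scaling an OTU's counts by a constant. OTUs with
#' zero total reads are excluded (with a message).
#'
#' @param table samples x OTUs count matrix (rarefied counts recommended for
#'   comparability across samples).
#' @return named numeric vector of breadths for the OTUs with reads.
#' @export
levins_breadth <- function(table) {
  tot <- colSums(table)
  if (any(tot == 0)) {
    message("excluding ", sum(tot == 0), " OTU(s) with zero total reads")
    table <- table[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  p <- sweep(table, 2, tot, "/")
  1 / colSums(p^2)
}

#' Community-level habitat niche breadth
#'
#' Aggregates per-OTU Levins' breadths over a community subset: the
#' unweighted mean by default, or the abundance-weighted mean with
#' `weighted = TRUE`.
#'
#' @param table samples x OTUs count matrix.
#' @param otu_subset OTU ids to aggregate over (default: all OTUs with reads).
#' @param weighted weight by total OTU abundance.
#' @return single numeric community breadth.
#' @export
community_breadth <- function(table, otu_subset = NULL, weighted = FALSE) {
  B <- levins_breadth(table)
  if (is.null(otu_subset)) otu_subset <- names(B)
  if (length(otu_subset) == 0L) stop("empty OTU subset")
  otu_subset <- intersect(otu_subset, names(B))
  if (length(otu_subset) == 0L) stop("no subset OTU has reads in this table")
  if (!weighted) return(mean(B[otu_subset]))
  w <- colSums(table)[otu_subset]
  sum(B[otu_subset] * w) / sum(w)
}

#' Per-sample community niche breadth
#'
#' The community breadth realized in each sample: the mean Levins' breadth of
#' the subset OTUs present in that sample (abundance-weighted within the
#' sample if `weighted = TRUE`). This gives the per-site replication used by
#' the layer and class comparisons of [compare_breadths()].
#'
#' @inheritParams community_breadth
#' @return named numeric vector, one breadth per sample.
#' @export
sample_breadths <- function(table, otu_subset = NULL, weighted = FALSE) {
  B <- levins_breadth(table)
  if (is.null(otu_subset)) otu_subset <- names(B)
  otu_subset <- intersect(otu_subset, names(B))
  if (length(otu_subset) == 0L) stop("no subset OTU has reads in this table")
  sub <- table[, otu_subset, drop = FALSE]
  vapply(rownames(table), function(s) {
    present <- otu_subset[sub[s, ] > 0]
    if (length(present) == 0L) return(NA_real_)
    if (!weighted) return(mean(B[present]))
    w <- sub[s, present]
    sum(B[present] * w) / sum(w)
  }, numeric(1))
}

# Compact letter display by insert-absorb from a pairwise p-value matrix.
letters_from_p <- function(pmat, alpha = 0.05) {
  g <- rownames(pmat)
  cols <- list(g)  # start with one letter covering everything
  for (i in seq_along(g)) {
    for (j in seq_along(g)) {
      if (j <= i || pmat[i, j] >= alpha) next
      # i and j differ: split every letter containing both
      for (k in seq_along(cols)) {
        if (all(c(g[i], g[j]) %in% cols[[k]])) {
          cols <- c(cols, list(setdiff(cols[[k]], g[i])),
                    list(setdiff(cols[[k]], g[j])))
          cols[[k]] <- NULL
          break
        }
      }
      # absorb letters contained in another
      keep <- rep(TRUE, length(cols))
      for (k in seq_along(cols)) {
        for (l in seq_along(cols)) {
          if (k != l && keep[l] && all(cols[[k]] %in% cols[[l]]) &&
              length(cols[[k]]) < length(cols[[l]])) keep[k] <- FALSE
        }
      }
      cols <- cols[keep]
    }
  }
  out <- vapply(g, function(x) {
    paste(letters[which(vapply(cols, function(cl) x %in% cl, logical(1)))],
          collapse = "")
  }, character(1))
  out
}

#' Compare community niche breadths across layers and community classes
#'
#' Paired t-tests contrast topsoil vs subsoil within each community class
#' (sites pair the observations); a one-way ANOVA with Tukey HSD across the
#' classes (e.g. overall / abundant / rare) yields a compact letter display
#' at `alpha = 0.05` - classes sharing a letter are not distinguishable.
#'
#' @param breadths data.frame with columns `site`, `layer` (topsoil/subsoil),
#'   `class`, `value` (community breadth).
#' @param alpha significance level for the letters (default 0.05).
#' @return list of class `breadth_comparison`: `paired` (per-class t, p),
#'   `classes` (per-class mean and letter), `anova_p`.
#' @export
compare_breadths <- function(breadths, alpha = 0.05) {
  stopifnot(all(c("site", "layer", "class", "value") %in% names(breadths)))
  classes <- sort(unique(breadths$class))
  paired <- lapply(classes, function(cl) {
    d <- breadths[breadths$class == cl & !is.na(breadths$value), ]
    sites <- intersect(d$site[d$layer == "topsoil"],
                       d$site[d$layer == "subsoil"])
    dropped <- setdiff(unique(d$site), sites)
    if (length(dropped)) {
      message("class ", cl, ": dropping ", length(dropped),
              " site(s) without both layers")
    }
    if (length(sites) < 2L) stop("fewer than 2 complete layer pairs in class ", cl)
    top <- d$value[d$layer == "topsoil"][match(sites, d$site[d$layer == "topsoil"])]
    sub <- d$value[d$layer == "subsoil"][match(sites, d$site[d$layer == "subsoil"])]
    dif <- top - sub
    if (sd(dif) < 1e-12) {
      # degenerate paired differences: identical layers or an exact offset
      if (abs(mean(dif)) < 1e-12) {
        data.frame(class = cl, t = 0, p = 1, mean_diff = 0)
      } else {
        data.frame(class = cl, t = sign(mean(dif)) * Inf, p = 0,
                   mean_diff = mean(dif))
      }
    } else {
      tt <- t.test(top, sub, paired = TRUE)
      data.frame(class = cl, t = unname(tt$statistic), p = tt$p.value,
                 mean_diff = unname(tt$estimate))
    }
  })
  paired <- do.call(rbind, paired)

  if (length(classes) >= 2L) {
    fit <- aov(value ~ class, data = transform(breadths, class = factor(class)))
    anova_p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
    tk <- TukeyHSD(fit, conf.level = 1 - alpha)$class
    pmat <- matrix(1, length(classes), length(classes),
                   dimnames = list(classes, classes))
    for (rn in rownames(tk)) {
      ab <- strsplit(rn, "-", fixed = TRUE)[[1L]]
      pmat[ab[1L], ab[2L]] <- pmat[ab[2L], ab[1L]] <- tk[rn, "p adj"]
    }
    lets <- letters_from_p(pmat, alpha)
  } else {
    anova_p <- NA_real_
    lets <- setNames("a", classes)
  }
  cls <- data.frame(class = classes,
                    mean = vapply(classes, function(cl)
                      mean(breadths$value[breadths$class == cl]), numeric(1)),
                    letter = unname(lets[classes]))
  out <- list(paired = paired, classes = cls, anova_p = anova_p)
  class(out) <- "breadth_comparison"
  out
}

#' @export
print.breadth_comparison <- function(x, ...) {
  cat("niche breadth, topsoil vs subsoil (paired t):\n")
  print(x$paired, row.names = FALSE)
  cat("across classes (Tukey letters):\n")
  print(x$classes, row.names = FALSE)
  invisible(x)
}
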