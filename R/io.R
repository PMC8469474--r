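#' The six environmental variable groups
#'
#' Canonical group names for the composite environmental distance: historical
#' temperature anomaly, contemporary climate, aboveground vegetation, soil
#' fertility, soil pH, and soil mineral content.
#'
#' @return character vector of the six group names.
#' @export
env_group_names <- function() {
  c("historical_temperature_anomaly", "contemporary_climate",
    "aboveground_vegetation", "soil_fertility", "soil_ph", "soil_mineral")
}

#' Read an OTU count table
#'
#' Tab-separated file; by amplicon convention OTUs are rows and samples are
#' columns (`otus_as_rows = TRUE`). In memory the table is always samples x
#' OTUs of non-negative integer counts.
#'
#' @param path TSV path. First column holds OTU (or sample) ids.
#' @param otus_as_rows file orientation; default `TRUE`.
#' @return integer matrix, samples x OTUs, with dimnames.
#' @export
read_otu_table <- function(path, otus_as_rows = TRUE) {
  df <- read.delim(path, check.names = FALSE, row.names = NULL)
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty or malformed OTU table: ", path)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cells in OTU table: ", path)
  rownames(m) <- ids
  if (otus_as_rows) m <- t(m)
  validate_otu_table(m)
}

#' Validate an in-memory OTU table
#'
#' @param table numeric matrix, samples x OTUs.
#' @return the table as integer storage, invisibly usable downstream.
#' @export
validate_otu_table <- function(table) {
  if (!is.matrix(table) || !is.numeric(table)) stop("OTU table must be a numeric matrix")
  if (nrow(table) == 0L || ncol(table) == 0L) stop("empty OTU table")
  if (is.null(rownames(table)) || is.null(colnames(table))) {
    stop("OTU table needs sample and OTU ids as dimnames")
  }
  if (anyDuplicated(rownames(table))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(table))) stop("duplicate OTU ids")
  if (anyNA(table)) stop("missing values in OTU table")
  if (any(table < 0)) stop("negative counts in OTU table")
  if (max(abs(table - round(table))) > 1e-8) stop("non-integer counts in OTU table")
  storage.mode(table) <- "integer"
  table
}

#' Write an OTU count table
#'
#' @param table samples x OTUs matrix.
#' @param path output TSV path.
#' @param otus_as_rows write OTUs as rows (default, round-trips with
#'   [read_otu_table()]).
#' @export
write_otu_table <- function(table, path, otus_as_rows = TRUE) {
  table <- validate_otu_table(table)
  out <- if (otus_as_rows) t(table) else table
  df <- data.frame(id = rownames(out), out, check.names = FALSE)
  names(df)[1L] <- if (otus_as_rows) "otu_id" else "sample_id"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a rooted Newick phylogeny
#'
#' Tips are OTU ids; every edge must carry a non-negative branch length.
#'
#' @param path Newick file path.
#' @return an `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("unparsable Newick file: ", path)
  validate_phylogeny(tree)
}

#' Validate a phylogeny for use in phylogenetic beta-diversity
#'
#' @param tree an `ape::phylo` object.
#' @return the tree, on success.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels in tree")
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge)) {
    stop("tree is missing branch lengths")
  }
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("negative or missing branch lengths")
  }
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  tree
}

#' Read per-sample site metadata with its variable-to-group map
#'
#' The metadata TSV must carry `sample_id`, `site_id`, `longitude`,
#' `latitude`, `layer` (one of `topsoil`/`subsoil`) plus the environmental
#' variables. The group map (TSV with columns `variable`, `group`, or a named
#' character vector) must assign every environmental variable to exactly one
#' of the six groups of [env_group_names()].
#'
#' @param path metadata TSV path.
#' @param group_map group-map TSV path or named character vector
#'   (names = variables, values = groups).
#' @return data.frame with one row per sample and attribute `group_map`.
#' @export
read_metadata <- function(path, group_map) {
  md <- read.delim(path, check.names = FALSE)
  if (is.character(group_map) && length(group_map) == 1L && file.exists(group_map)) {
    gm <- read.delim(group_map)
    group_map <- setNames(as.character(gm$group), gm$variable)
  }
  validate_metadata(md, group_map)
}

#' Validate site metadata
#'
#' @param md metadata data.frame.
#' @param group_map named character vector, variable -> group.
#' @return `md` with attribute `group_map` set.
#' @export
validate_metadata <- function(md, group_map) {
  required <- c("sample_id", "site_id", "longitude", "latitude", "layer")
  missing_cols <- setdiff(required, names(md))
  if (length(missing_cols)) stop("metadata lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(md$sample_id)) stop("duplicate sample_id in metadata")
  if (any(md$latitude < -90 | md$latitude > 90)) stop("latitude out of [-90, 90]")
  if (any(md$longitude < -180 | md$longitude > 180)) stop("longitude out of [-180, 180]")
  bad_layer <- setdiff(unique(md$layer), c("topsoil", "subsoil"))
  if (length(bad_layer)) stop("unknown layer label: ", paste(bad_layer, collapse = ", "))
  env_vars <- setdiff(names(md), required)
  unmapped <- setdiff(env_vars, names(group_map))
  if (length(unmapped)) stop("variables absent from group map: ", paste(unmapped, collapse = ", "))
  bad_groups <- setdiff(unique(group_map[env_vars]), env_group_names())
  if (length(bad_groups)) stop("unknown environment group: ", paste(bad_groups, collapse = ", "))
  for (v in env_vars) {
    if (!is.numeric(md[[v]]) || anyNA(md[[v]]) || any(!is.finite(md[[v]]))) {
      stop("environmental variable not finite numeric: ", v)
    }
  }
  rownames(md) <- md$sample_id
  attr(md, "group_map") <- group_map[env_vars]
  md
}

#' Write metadata and its group map
#'
#' @param md metadata data.frame with attribute `group_map`.
#' @param path metadata TSV path.
#' @param group_map_path optional TSV path for the variable->group map.
#' @export
write_metadata <- function(md, path, group_map_path = NULL) {
  write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(group_map_path)) {
    gm <- attr(md, "group_map")
    write.table(data.frame(variable = names(gm), group = unname(gm)),
                group_map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Enforce id consistency between an OTU table and a phylogeny
#'
#' The tree's tips must be a superset of the table's OTUs. A mismatch is a
#' hard error unless `prune = TRUE`, in which case table OTUs missing from
#' the tree are dropped with a message reporting the counts (silent dropping
#' corrupts UniFrac/betaMNTD).
#'
#' @param table samples x OTUs count matrix.
#' @param tree `phylo` tree.
#' @param prune drop table OTUs absent from the tree instead of erroring.
#' @return the (possibly pruned) table.
#' @export
match_table_tree <- function(table, tree, prune = FALSE) {
  missing_otus <- setdiff(colnames(table), tree$tip.label)
  if (length(missing_otus) == 0L) return(table)
  if (!prune) {
    stop(length(missing_otus), " OTU(s) absent from the tree (e.g. ",
         missing_otus[1L], "); pass prune = TRUE to drop them explicitly")
  }
  message("pruning ", length(missing_otus), " of ", ncol(table),
          " OTUs absent from the tree")
  table[, setdiff(colnames(table), missing_otus), drop = FALSE]
}
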