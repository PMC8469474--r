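#' Configuration for the synthetic transect generator
#'
#' Defaults emulate the post-processing output of a ~1500-km arid-to-mesic
#' grassland transect: 32 sites sampled in two depth layers, equal-depth
#' (rarefied-like) counts, a strongly skewed lognormal regional abundance
#' distribution (few abundant, many rare OTUs), phylogenetic signal in the
#' OTUs' environmental optima, and spatially structured environmental
#' gradients.
#'
#' @param n_sites number of sites along the transect (two samples each:
#'   topsoil and subsoil). Default 32.
#' @param n_otus regional pool size. Default 500.
#' @param reads_per_sample fixed sequencing depth per sample (multinomial
#'   draw). Default 5000.
#' @param transect_length_km transect length. Default 1500.
#' @param niche_strength selection intensity `w >= 0`; 0 switches selection
#'   off entirely. Default 5.
#' @param niche_width niche breadth `sigma > 0` on the \[0, 1\] gradient
#'   scale. Default 0.25.
#' @param dispersal_km e-folding range of the exponential dispersal kernel
#'   from each OTU's source site; `Inf` = well-mixed (no dispersal
#'   limitation). Default `Inf`.
#' @param brownian_rate Brownian-motion rate for the evolution of niche
#'   optima on the tree; larger values are still rescaled to the gradient,
#'   the rate matters only relative to tree depth. Default 1.
#' @param lognormal_meanlog,lognormal_sdlog regional abundance distribution;
#'   `sdlog = 2` gives the few-abundant/many-rare structure typical of soil
#'   16S surveys. Defaults 0 and 2.
#' @param layer_effect if `TRUE` (default) the habitat driver differs by
#'   layer: topsoil communities track the contemporary-climate composite,
#'   subsoil communities track soil pH. If `FALSE` both layers track the
#'   latent transect gradient directly.
#' @param seed integer seed; sub-stages use `seed`, `seed + 1`, `seed + 2`.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_sites = 32, n_otus = 500,
                              reads_per_sample = 5000,
                              transect_length_km = 1500,
                              niche_strength = 5, niche_width = 0.25,
                              dispersal_km = Inf, brownian_rate = 1,
                              lognormal_meanlog = 0, lognormal_sdlog = 2,
                              layer_effect = TRUE, seed = 1L) {
  cfg <- list(n_sites = as.integer(n_sites), n_otus = as.integer(n_otus),
              reads_per_sample = as.integer(reads_per_sample),
              transect_length_km = transect_length_km,
              niche_strength = niche_strength, niche_width = niche_width,
              dispersal_km = dispersal_km, brownian_rate = brownian_rate,
              lognormal_meanlog = lognormal_meanlog,
              lognormal_sdlog = lognormal_sdlog,
              layer_effect = isTRUE(layer_effect), seed = as.integer(seed))
  stopifnot(cfg$n_sites >= 4, cfg$n_otus >= 2, cfg$reads_per_sample >= 100,
            cfg$transect_length_km > 0, cfg$niche_strength >= 0,
            cfg$niche_width > 0, cfg$dispersal_km > 0,
            cfg$brownian_rate > 0, cfg$lognormal_sdlog > 0)
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate a regional-pool phylogeny
#'
#' Random topology with exponential branch lengths (not constrained to be
#' ultrametric); tips are labelled `OTU0001`, `OTU0002`, ...
#'
#' @param n_otus number of tips (>= 2).
#' @param seed integer seed.
#' @return an `ape::phylo` tree.
#' @export
simulate_phylogeny <- function(n_otus, seed = 1L) {
  if (n_otus < 2) stop("n_otus must be >= 2")
  set.seed(seed)
  tree <- ape::rtree(n_otus, br = function(n) rexp(n, rate = 1))
  tree$tip.label <- sprintf("OTU%04d", seq_len(n_otus))
  validate_phylogeny(tree)
}

# Transect layout: site positions (km) along the line, jittered except the
# endpoints, plus lon/lat placed so the haversine span of the transect equals
# transect_length_km.
transect_layout <- function(n_sites, length_km) {
  pos <- seq(0, length_km, length.out = n_sites)
  if (n_sites > 2) {
    jit <- length_km / (4 * (n_sites - 1))
    pos[2:(n_sites - 1)] <- pos[2:(n_sites - 1)] +
      runif(n_sites - 2, -jit, jit)
  }
  pos <- sort(pos)
  # direction roughly SW -> NE across the Inner Mongolian steppe
  lon0 <- 107.93; lat0 <- 39.15; dlon <- 12.04; dlat <- 10.46
  span <- function(f) {
    geosphere::distHaversine(c(lon0, lat0),
                             c(lon0 + f * dlon, lat0 + f * dlat),
                             r = 6371008.8) / 1000
  }
  f <- stats::uniroot(function(x) span(x) - length_km,
                      interval = c(1e-6, 4.8))$root
  t <- pos / length_km
  data.frame(site_id = sprintf("S%02d", seq_len(n_sites)),
             position_km = pos,
             longitude = lon0 + t * f * dlon,
             latitude = lat0 + t * f * dlat)
}

#' Simulate per-sample site metadata along the transect
#'
#' Sites are spread over a line of `transect_length_km` with jitter; a latent
#' gradient `g` in \[0, 1\] runs along it. The 17 environmental variables are
#' linear functions of `g` plus independent Gaussian noise (sd = 20% of each
#' variable's gradient range), grouped into the six groups of
#' [env_group_names()]. Climate, vegetation and temperature-anomaly variables
#' are site-level (identical in both layers); soil variables are drawn per
#' layer, with subsoil fertility halved and subsoil pH offset upwards, as in
#' grassland soil profiles. MAP rises and MAT and pH fall towards the mesic
#' end, mirroring the arid-to-mesic direction of real steppe transects.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed; defaults to `config$seed + 1`.
#' @return metadata data.frame (two rows per site) with attributes
#'   `group_map`, `gradient` (named latent g per sample) and `position_km`.
#' @export
simulate_metadata <- function(config, seed = config$seed + 1L) {
  set.seed(seed)
  n <- config$n_sites
  lay <- transect_layout(n, config$transect_length_km)
  g <- lay$position_km / config$transect_length_km

  lin <- function(a, b, t = g) a + b * t + rnorm(length(t), 0, 0.2 * abs(b))
  site_env <- data.frame(
    map = lin(165, 246.5), mat = lin(6.4, -8.7),
    aridity_index = lin(0.15, 0.25), swc = lin(15, 35),
    temp_anomaly = lin(3.5, 2.5),
    vegetation_biomass = lin(40, 220), plant_richness = lin(4, 22),
    npp = lin(80, 320))

  soil_env <- function(layer) {
    f <- if (layer == "subsoil") 0.5 else 1
    ph0 <- if (layer == "subsoil") 10.2 else 9.9
    data.frame(
      total_n = f * lin(0.5, 1.5), total_c = f * lin(1, 5),
      organic_c = f * lin(0.4, 4.3), total_p = f * lin(0.3, 0.5),
      ph = lin(ph0, -2.2),
      extractable_fe = lin(10, 15), extractable_al = lin(8, 10),
      clay_pct = lin(10, 15), silt_pct = lin(20, 20))
  }

  rows <- lapply(c("topsoil", "subsoil"), function(layer) {
    data.frame(sample_id = paste(lay$site_id, layer, sep = "_"),
               site_id = lay$site_id, longitude = lay$longitude,
               latitude = lay$latitude, layer = layer,
               site_env, soil_env(layer))
  })
  md <- do.call(rbind, rows)
  group_map <- c(
    temp_anomaly = "historical_temperature_anomaly",
    map = "contemporary_climate", mat = "contemporary_climate",
    aridity_index = "contemporary_climate", swc = "contemporary_climate",
    vegetation_biomass = "aboveground_vegetation",
    plant_richness = "aboveground_vegetation", npp = "aboveground_vegetation",
    total_n = "soil_fertility", total_c = "soil_fertility",
    organic_c = "soil_fertility", total_p = "soil_fertility",
    ph = "soil_ph",
    extractable_fe = "soil_mineral", extractable_al = "soil_mineral",
    clay_pct = "soil_mineral", silt_pct = "soil_mineral")
  md <- validate_metadata(md, group_map)
  attr(md, "gradient") <- setNames(rep(g, 2), md$sample_id)
  attr(md, "position_km") <- setNames(rep(lay$position_km, 2), md$sample_id)
  md
}

minmax <- function(x) {
  r <- range(x)
  if (diff(r) == 0) return(rep(0.5, length(x)))
  (x - r[1]) / diff(r)
}

# Habitat value in [0, 1] per sample: the layer-specific driver. Topsoil
# tracks the unsigned mean-of-z-scores contemporary-climate composite (the
# same composite environmental_distance() uses), subsoil tracks pH.
habitat_values <- function(md, layer_effect) {
  pos <- attr(md, "position_km")
  if (is.null(pos)) {
    d <- spatial_distance(md)
    pos <- unclass(d)[, which.min(md$longitude)]
  }
  g <- pos / max(pos)
  h <- setNames(rep(NA_real_, nrow(md)), md$sample_id)
  if (!layer_effect) return(setNames(g, md$sample_id))
  for (layer in unique(md$layer)) {
    i <- md$layer == layer
    if (layer == "topsoil") {
      z <- scale(as.matrix(md[i, c("map", "mat", "aridity_index", "swc")]))
      h[i] <- minmax(rowMeans(z))
    } else {
      h[i] <- minmax(as.numeric(scale(md$ph[i])))
    }
  }
  h
}

#' Simulate community count tables with a known assembly regime
#'
#' Per-OTU niche optima evolve on the tree by Brownian motion and are
#' rescaled to the \[0, 1\] gradient; regional abundances are lognormal.
#' The expected abundance of OTU i in sample s is
#' `lambda_i * exp(-w (h_s - opt_i)^2 / (2 sigma^2)) * exp(-d(s, src_i)/d_km)`
#' where `h_s` is the sample's habitat value, `src_i` the OTU's randomly
#' placed source site and `d` the along-transect distance. Reads are drawn
#' multinomially at `reads_per_sample` per sample, so row sums are exact.
#'
#' @param tree phylogeny whose tips define the OTU pool.
#' @param metadata output of [simulate_metadata()].
#' @param config a [simulation_config()].
#' @param seed integer seed; defaults to `config$seed + 2`.
#' @return samples x OTUs integer count matrix with attributes `optima`,
#'   `habitat` and `sources` recording the generating state.
#' @export
simulate_communities <- function(tree, metadata, config,
                                 seed = config$seed + 2L) {
  if (length(tree$tip.label) != config$n_otus) {
    stop("tree tip count does not match config$n_otus")
  }
  set.seed(seed)
  otus <- tree$tip.label
  opt <- minmax(ape::rTraitCont(tree, model = "BM",
                                sigma = sqrt(config$brownian_rate)))[otus]
  lambda <- rlnorm(length(otus), config$lognormal_meanlog,
                   config$lognormal_sdlog)
  h <- habitat_values(metadata, config$layer_effect)
  pos <- attr(metadata, "position_km")
  site_pos <- pos[!duplicated(metadata$site_id)]
  src <- sample(seq_along(site_pos), length(otus), replace = TRUE)

  w <- config$niche_strength; sig <- config$niche_width
  n_s <- nrow(metadata)
  E <- matrix(0, n_s, length(otus),
              dimnames = list(metadata$sample_id, otus))
  for (s in seq_len(n_s)) {
    fit <- exp(-w * (h[s] - opt)^2 / (2 * sig^2))
    K <- if (is.finite(config$dispersal_km)) {
      exp(-abs(pos[s] - site_pos[src]) / config$dispersal_km)
    } else 1
    E[s, ] <- lambda * fit * K
  }
  counts <- t(vapply(seq_len(n_s), function(s) {
    rmultinom(1, config$reads_per_sample, E[s, ])[, 1]
  }, integer(length(otus))))
  dimnames(counts) <- dimnames(E)
  counts <- validate_otu_table(counts)
  attr(counts, "optima") <- opt
  attr(counts, "habitat") <- h
  attr(counts, "sources") <- setNames(names(site_pos)[src], otus)
  counts
}

#' Simulate a full transect dataset (table + tree + metadata)
#'
#' @param config a [simulation_config()].
#' @return list with elements `table`, `tree`, `metadata`, `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  tree <- simulate_phylogeny(config$n_otus, seed = config$seed)
  metadata <- simulate_metadata(config)
  table <- simulate_communities(tree, metadata, config)
  list(table = table, tree = tree, metadata = metadata, config = config)
}
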