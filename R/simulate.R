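#' @keywords internal
#' @noRd
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1   # guard against all-zero draws
  g / sum(g)
}

sample_ids_for <- function(n) sprintf("s%03d", seq_len(n))
taxon_ids_for <- function(n) sprintf("t%04d", seq_len(n))

#' Simulate a Yule phylogeny of ASVs
#'
#' Pure-birth tree with unit birth rate, branch lengths in time units, tips
#' labeled `t0001`, `t0002`, ...  Deterministic under `seed`.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param seed Integer seed.
#' @return An [ape::phylo] tree.
#' @export
simulate_tree <- function(n_taxa, seed = 1L) {
  if (n_taxa < 2) stop("n_taxa must be at least 2")
  tree <- withr::with_seed(seed, ape::rphylo(n_taxa, birth = 1, death = 0))
  tree$tip.label <- taxon_ids_for(n_taxa)
  tree
}

#' Simulate an enterotype mixture
#'
#' Draws samples from `n_clusters` Dirichlet-multinomial components with
#' distinct mean compositions.  Cluster 1 is "dominance-type" (a single
#' heavily boosted taxon, emulating a Lactobacillus-dominated enterotype);
#' the remaining clusters boost an even block of taxa (a diverse
#' Muribaculaceae-like enterotype), so cluster 1 has lower expected Shannon
#' diversity than cluster 2.  `effect_size = 0` makes all cluster means
#' identical (the null case).
#'
#' @param n_samples,n_taxa,depth Table dimensions and reads per sample.
#' @param n_clusters Number of mixture components (>= 2).
#' @param concentration Dirichlet concentration: larger = less overdispersion
#'   around the cluster mean.
#' @param effect_size Mass of the cluster-specific block relative to the
#'   shared background composition (which has mass 1); 0 = no separation.
#' @param seed Integer seed.
#' @return List with `table` (samples x taxa count tibble) and `truth`
#'   (tibble `sample_id`, `cluster`).
#' @export
simulate_enterotype_mixture <- function(n_samples, n_taxa, depth,
                                        n_clusters = 2, concentration = 40,
                                        effect_size = 4, seed = 1L) {
  if (n_clusters < 2) stop("n_clusters must be >= 2")
  if (effect_size < 0) stop("effect_size must be >= 0")
  n_block <- max(1L, floor(n_taxa / (n_clusters + 1)))
  base <- 0.98^(seq_len(n_taxa) - 1)
  base <- base / sum(base)
  means <- vapply(seq_len(n_clusters), function(c) {
    block <- ((c - 1L) * n_block + 1L):(c * n_block)
    u <- numeric(n_taxa)
    if (c == 1L) {
      u[block] <- 0.25^(seq_along(block) - 1)   # dominance: mass on one taxon
    } else {
      u[block] <- 1                             # evenness: flat over the block
    }
    u <- u / sum(u)
    w <- base + effect_size * u
    w / sum(w)
  }, numeric(n_taxa))
  withr::with_seed(seed, {
    cluster <- sample(rep_len(seq_len(n_clusters), n_samples))
    counts <- t(vapply(seq_len(n_samples), function(s) {
      x <- rdirichlet1(concentration * means[, cluster[s]])
      rmultinom(1, depth, x)[, 1]
    }, numeric(n_taxa)))
  })
  dimnames(counts) <- list(sample_ids_for(n_samples), taxon_ids_for(n_taxa))
  list(table = as_asv_table(counts),
       truth = tibble::tibble(sample_id = rownames(counts), cluster = cluster))
}

#' Simulate a Sloan-neutral community table
#'
#' Metacommunity proportions `p` follow a normalized geometric series
#' (log-series-like skew, ratio `shape`).  Each sample's composition is
#' drawn from `Dirichlet(Nm * p)`, so a taxon's local relative abundance has
#' the `Beta(Nm p_i, Nm (1 - p_i))` marginal the Sloan neutral model
#' assumes; counts are then multinomial at `depth` reads.
#'
#' @inheritParams simulate_enterotype_mixture
#' @param Nm Product of metacommunity size and migration rate (the Sloan
#'   dispersal parameter); larger values pin samples to `p`.
#' @param shape Geometric ratio of the metacommunity abundance distribution.
#' @return List with `table` and `truth` (tibble `taxon_id`, `p`, plus the
#'   scalar `Nm` as an attribute-free list element).
#' @export
simulate_neutral <- function(n_samples, n_taxa, depth, Nm,
                             shape = 0.99, seed = 1L) {
  if (Nm <= 0) stop("Nm must be positive")
  p <- shape^(seq_len(n_taxa) - 1)
  p <- p / sum(p)
  withr::with_seed(seed, {
    counts <- t(vapply(seq_len(n_samples), function(s) {
      x <- rdirichlet1(Nm * p)
      rmultinom(1, depth, x)[, 1]
    }, numeric(n_taxa)))
  })
  dimnames(counts) <- list(sample_ids_for(n_samples), taxon_ids_for(n_taxa))
  list(table = as_asv_table(counts),
       truth = list(p = tibble::tibble(taxon_id = colnames(counts), p = p),
                    Nm = Nm))
}

#' Simulate habitat filtering on a phylogeny
#'
#' Evolves a continuous trait along `tree` by Brownian motion (rate
#' `trait_sigma`), then samples each community multinomially with weight of
#' taxon i in sample s proportional to
#' `base_i * exp(-selection_strength * (trait_i - env_s)^2)`.
#' Identical `env_values` across samples yield phylogenetically clustered
#' communities (betaNTI below -2 under strong selection); divergent
#' environment blocks yield over-dispersed between-block pairs (betaNTI
#' above +2).  `selection_strength = 0` collapses to a neutral multinomial
#' draw from the base abundances.
#'
#' @param tree [ape::phylo] tree whose tips are the taxa.
#' @param n_samples,depth Table dimensions.
#' @param env_values Numeric environment value per sample (length
#'   `n_samples`), on the trait scale.
#' @param trait_sigma Brownian-motion rate of the trait.
#' @param selection_strength Gaussian niche-filter strength (per squared
#'   trait unit); 0 = neutral.
#' @param base_shape Geometric ratio of the base (no-selection) abundances.
#' @param concentration Dirichlet concentration for sample-level
#'   overdispersion around the filtered weights (drift within the selected
#'   pool, the overdispersion real 16S tables show); `Inf` (default) gives
#'   a pure multinomial draw from the weights.
#' @param traits Optional named per-tip trait vector (e.g. from
#'   [simulate_traits()]); when supplied, the Brownian draw is skipped.
#'   Useful when the environment optimum should be placed relative to the
#'   realized trait distribution (e.g. at the niche of an extreme clade).
#' @param seed Integer seed.
#' @return List with `table` and `truth` (`env` per sample, `trait` per taxon).
#' @export
simulate_selected <- function(tree, n_samples, depth, env_values,
                              trait_sigma = 1, selection_strength = 2,
                              base_shape = 0.98, concentration = Inf,
                              traits = NULL, seed = 1L) {
  if (length(env_values) != n_samples) {
    stop("env_values must have one entry per sample")
  }
  taxa <- tree$tip.label
  n_taxa <- length(taxa)
  base <- base_shape^(seq_len(n_taxa) - 1)
  base <- base / sum(base)
  withr::with_seed(seed, {
    trait <- if (is.null(traits)) {
      ape::rTraitCont(tree, model = "BM", sigma = trait_sigma)
    } else {
      if (!all(taxa %in% names(traits))) stop("traits must cover every tip")
      traits
    }
    trait <- trait[taxa]
    counts <- t(vapply(seq_len(n_samples), function(s) {
      w <- base * exp(-selection_strength * (trait - env_values[s])^2)
      w <- w / sum(w)
      if (is.finite(concentration)) w <- rdirichlet1(concentration * w)
      rmultinom(1, depth, w)[, 1]
    }, numeric(n_taxa)))
  })
  dimnames(counts) <- list(sample_ids_for(n_samples), taxa)
  list(table = as_asv_table(counts),
       truth = list(env = tibble::tibble(sample_id = rownames(counts),
                                         env = env_values),
                    trait = tibble::tibble(taxon_id = taxa,
                                           trait = unname(trait))))
}

#' Simulate a Brownian trait on a phylogeny
#'
#' Draws one continuous trait per tip by Brownian motion along `tree`
#' (rate `sigma`), the trait [simulate_selected()] filters on.  Exposed
#' separately so the environmental optimum can be positioned relative to
#' the realized trait distribution.
#'
#' @param tree [ape::phylo] tree.
#' @param sigma Brownian-motion rate.
#' @param seed Integer seed.
#' @return Named numeric vector over `tree$tip.label`.
#' @export
simulate_traits <- function(tree, sigma = 1, seed = 1L) {
  tr <- withr::with_seed(seed, ape::rTraitCont(tree, model = "BM", sigma = sigma))
  tr[tree$tip.label]
}

#' Simulate per-sample host metadata
#'
#' Assigns samples to `n_sites` sites, draws one altitude per site uniformly
#' within `altitude_range`, and generates body length (mm), BMI and body
#' weight (g) with `bmi = body_weight / body_length^2` holding exactly.
#'
#' @param sample_ids Character vector of sample ids.
#' @param n_sites Number of geographic sites.
#' @param altitude_range Numeric length-2: min and max site elevation (m).
#' @param length_mean,length_sd Body length distribution (mm).
#' @param bmi_mean,bmi_sd BMI distribution (g/mm^2).
#' @param seed Integer seed.
#' @return Tibble `sample_id`, `site`, `altitude`, `body_length`,
#'   `body_weight`, `bmi`.
#' @export
simulate_metadata <- function(sample_ids, n_sites = 7,
                              altitude_range = c(120, 838),
                              length_mean = 95, length_sd = 8,
                              bmi_mean = 0.0030, bmi_sd = 4e-4, seed = 1L) {
  if (n_sites < 1) stop("n_sites must be >= 1")
  n <- length(sample_ids)
  withr::with_seed(seed, {
    site_idx <- sample(rep_len(seq_len(n_sites), n))
    alt_site <- runif(n_sites, altitude_range[1], altitude_range[2])
    len <- abs(rnorm(n, length_mean, length_sd)) + 1e-6
    bmi_v <- abs(rnorm(n, bmi_mean, bmi_sd)) + 1e-9
  })
  tibble::tibble(sample_id = sample_ids,
                 site = sprintf("site%02d", site_idx),
                 altitude = alt_site[site_idx],
                 body_length = len,
                 body_weight = bmi_v * len^2,
                 bmi = bmi_v)
}

#' Simulate a flat taxonomy (genus map) for synthetic taxa
#'
#' Randomly assigns taxa to genera (and genera to phyla), producing the
#' minimal ranked lineage the genus-aggregation and per-taxon contrast steps
#' need.  A configurable fraction of taxa get an unassigned genus.
#'
#' @param taxon_ids Character vector of taxon ids.
#' @param n_genera Number of genera (default: one per 4 taxa, at least 2).
#' @param frac_unassigned Fraction of taxa with unassigned genus.
#' @param seed Integer seed.
#' @return Tibble `taxon_id`, `phylum`, `genus`.
#' @export
simulate_taxonomy <- function(taxon_ids, n_genera = NULL,
                              frac_unassigned = 0, seed = 1L) {
  n <- length(taxon_ids)
  if (is.null(n_genera)) n_genera <- max(2L, n %/% 4L)
  n_phyla <- max(2L, ceiling(n_genera / 10))
  withr::with_seed(seed, {
    genus_phylum <- sample(rep_len(seq_len(n_phyla), n_genera))
    g <- sample(rep_len(seq_len(n_genera), n))
    genus <- sprintf("genus_%03d", g)
    phylum <- sprintf("phylum_%02d", genus_phylum[g])
    if (frac_unassigned > 0) {
      drop <- seq_len(n) %in% sample.int(n, round(frac_unassigned * n))
      genus[drop] <- NA_character_
    }
  })
  tibble::tibble(taxon_id = taxon_ids, phylum = phylum, genus = genus)
}
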