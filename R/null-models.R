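# Fast helpers for nearest-taxon phylogenetic turnover.  The engine works on
# a precomputed patristic distance matrix so the betaNTI null (a tip-label
# shuffle) reduces to permuting the rows/columns of that matrix.

rowmins <- function(x) {
  # row minima via max.col (C-level); x must have >= 1 column
  x[cbind(seq_len(nrow(x)), max.col(-x, ties.method = "first"))]
}

# F: samples x taxa relative abundances; D: taxa x taxa patristic distances
# (same taxon order).  Returns the abundance-weighted betaMNTD matrix.
beta_mntd_engine <- function(F, D, presence = F > 0) {
  S <- nrow(F)
  # M[t, k] = distance from taxon t to its nearest taxon present in sample k
  M <- vapply(seq_len(S), function(k) {
    rowmins(D[, presence[k, ], drop = FALSE])
  }, numeric(ncol(F)))
  B <- F %*% M                      # B[j, k] = sum_i f_ij * M[i, k]
  out <- 0.5 * (B + t(B))
  diag(out) <- 0
  dimnames(out) <- list(rownames(F), rownames(F))
  out
}

#' Abundance-weighted beta mean nearest taxon distance
#'
#' For each sample pair (j, k):
#' `betaMNTD(j, k) = 0.5 * [ sum_{i in j} f_ij min_{i' in k} d(i, i') +
#'                           sum_{i in k} f_ik min_{i' in j} d(i, i') ]`
#' with `f` relative abundances and `d` the patristic distance on `tree`.
#' A taxon present in both communities has nearest-taxon distance 0 (itself).
#'
#' @param table_rel Relative-abundance samples x taxa table; all taxa must
#'   be tips of `tree` (use [reconcile_tree_table()] first).
#' @param tree Rooted [ape::phylo] tree with branch lengths.
#' @return Symmetric hollow matrix labeled by sample id.
#' @export
beta_mntd <- function(table_rel, tree) {
  F <- asv_matrix(table_rel)
  missing <- setdiff(colnames(F), tree$tip.label)
  if (length(missing)) {
    stop("taxa missing from tree: ", paste(head(missing, 5), collapse = ", "))
  }
  D <- ape::cophenetic.phylo(tree)[colnames(F), colnames(F)]
  beta_mntd_engine(F, D)
}

#' Beta nearest taxon index (betaNTI)
#'
#' Standardized effect size of [beta_mntd()] against a null distribution
#' obtained by shuffling taxon labels across the tree tips (equivalently,
#' permuting the rows/columns of the patristic distance matrix over the
#' taxa occurring in the table), recomputed `n_rand` times:
#' `betaNTI = (observed - mean_null) / sd_null` per sample pair.
#' Pairs with a degenerate null (`sd_null = 0`) are set to 0 and flagged in
#' the `degenerate` attribute.  `|betaNTI| > 2` is conventionally read as
#' deterministic selection (sign: -2 homogeneous, +2 variable).
#'
#' @inheritParams beta_mntd
#' @param n_rand Number of tip-shuffle randomizations (default 999).
#' @param seed Integer seed; same seed gives a bitwise-identical matrix.
#' @return Symmetric matrix of betaNTI values with attributes `n_rand` and
#'   `degenerate` (logical matrix).
#' @export
beta_nti <- function(table_rel, tree, n_rand = 999, seed = 1L) {
  F <- asv_matrix(table_rel)
  missing <- setdiff(colnames(F), tree$tip.label)
  if (length(missing)) {
    stop("taxa missing from tree: ", paste(head(missing, 5), collapse = ", "))
  }
  D <- ape::cophenetic.phylo(tree)[colnames(F), colnames(F)]
  presence <- F > 0
  obs <- beta_mntd_engine(F, D, presence)
  n_taxa <- ncol(F)
  S <- nrow(F)
  sum_null <- matrix(0, S, S)
  sumsq_null <- matrix(0, S, S)
  withr::with_seed(seed, {
    for (r in seq_len(n_rand)) {
      perm <- sample.int(n_taxa)
      nul <- beta_mntd_engine(F, D[perm, perm, drop = FALSE], presence)
      sum_null <- sum_null + nul
      sumsq_null <- sumsq_null + nul^2
    }
  })
  mean_null <- sum_null / n_rand
  var_null <- pmax(sumsq_null / n_rand - mean_null^2, 0) * n_rand / (n_rand - 1)
  sd_null <- sqrt(var_null)
  degenerate <- sd_null < 1e-12
  z <- (obs - mean_null) / ifelse(degenerate, 1, sd_null)
  z[degenerate] <- 0
  diag(z) <- 0
  dimnames(z) <- dimnames(obs)
  attr(z, "n_rand") <- n_rand
  attr(z, "degenerate") <- degenerate & upper.tri(degenerate)
  z
}

# one null community preserving richness and total abundance; species drawn
# by occupancy weight, remaining individuals by metacommunity abundance
rc_null_pair <- function(rich, total, occ_w, ab_w) {
  n_taxa <- length(occ_w)
  x <- numeric(n_taxa)
  sp <- sample.int(n_taxa, rich, prob = occ_w)
  x[sp] <- 1
  extra <- total - rich
  if (extra > 0) x[sp] <- x[sp] + rmultinom(1, extra, ab_w[sp])[, 1]
  x
}

#' Raup-Crick index on Bray-Curtis (RCbray)
#'
#' For each sample pair, compares the observed Bray-Curtis dissimilarity
#' with `n_rand` null pairs in which each community keeps its observed
#' richness and total abundance while species identities are drawn with
#' probability proportional to metacommunity occupancy and individuals are
#' allocated with probability proportional to metacommunity relative
#' abundance.  The quantile `[(#null < obs) + 0.5 (#null = obs)] / n_rand`
#' is rescaled to `[-1, 1]` as `(q - 0.5) * 2`; values beyond +/-0.95 mark
#' dispersal-driven departures from stochastic expectation.
#'
#' @param table Samples x taxa count table.
#' @param n_rand Number of null draws per pair (default 999).
#' @param seed Integer seed.
#' @return Symmetric matrix of RCbray values in `[-1, 1]`, zero diagonal.
#' @export
raup_crick_bray <- function(table, n_rand = 999, seed = 1L) {
  m <- asv_matrix(table)
  S <- nrow(m)
  rich <- rowSums(m > 0)
  if (any(rich == 0)) {
    stop("sample(s) with zero richness: ",
         paste(rownames(m)[rich == 0], collapse = ", "))
  }
  totals <- rowSums(m)
  occ_w <- colMeans(m > 0)
  ab_w <- colSums(m) / sum(m)
  obs <- as.matrix(vegan::vegdist(m, method = "bray"))
  rc <- matrix(0, S, S, dimnames = dimnames(obs))
  withr::with_seed(seed, {
    for (j in seq_len(S - 1)) {
      for (k in (j + 1):S) {
        nulls <- vapply(seq_len(n_rand), function(r) {
          a <- rc_null_pair(rich[j], totals[j], occ_w, ab_w)
          b <- rc_null_pair(rich[k], totals[k], occ_w, ab_w)
          sum(abs(a - b)) / sum(a + b)
        }, numeric(1))
        q <- (sum(nulls < obs[j, k]) + 0.5 * sum(nulls == obs[j, k])) / n_rand
        rc[j, k] <- rc[k, j] <- (q - 0.5) * 2
      }
    }
  })
  attr(rc, "n_rand") <- n_rand
  rc
}

#' Partition community assembly into five processes
#'
#' Applies the Stegen-framework decision rules to paired betaNTI and RCbray
#' matrices: `betaNTI > +2` variable selection; `betaNTI < -2` homogeneous
#' selection; otherwise (`|betaNTI| <= 2`, stochastic band) `RC > +0.95`
#' dispersal limitation, `RC < -0.95` homogenizing dispersal, and
#' `|RC| <= 0.95` undominated drift.  Rules are exhaustive and mutually
#' exclusive, so the five fractions sum to 1.
#'
#' @param beta_nti_dm betaNTI matrix from [beta_nti()].
#' @param rc_dm RCbray matrix from [raup_crick_bray()] (same labels).
#' @param group Optional group id recorded in the summary (e.g. enterotype).
#' @return List with `pairs` (tibble `sample_a`, `sample_b`, `beta_nti`,
#'   `rc_bray`, `process`) and `summary` (tibble `process`, `n_pairs`,
#'   `fraction`, with zero-count processes included).
#' @export
partition_processes <- function(beta_nti_dm, rc_dm, group = NULL) {
  b <- check_dist(beta_nti_dm, tol = 1e-6)
  r <- check_dist(rc_dm, tol = 1e-6)
  if (!identical(rownames(b), rownames(r))) {
    stop("betaNTI and RC matrices must share sample labels in the same order")
  }
  pairs <- dplyr::rename(tidy_dist(b), beta_nti = "value")
  pairs$rc_bray <- tidy_dist(r)$value
  pairs$process <- dplyr::case_when(
    pairs$beta_nti > 2 ~ "variable_selection",
    pairs$beta_nti < -2 ~ "homogeneous_selection",
    pairs$rc_bray > 0.95 ~ "dispersal_limitation",
    pairs$rc_bray < -0.95 ~ "homogenizing_dispersal",
    TRUE ~ "drift")
  processes <- c("variable_selection", "homogeneous_selection",
                 "dispersal_limitation", "homogenizing_dispersal", "drift")
  counts <- table(factor(pairs$process, levels = processes))
  summary <- tibble::tibble(process = processes,
                            n_pairs = as.integer(counts),
                            fraction = as.numeric(counts) / nrow(pairs))
  if (!is.null(group)) summary <- dplyr::mutate(summary, group = group, .before = 1)
  list(pairs = pairs, summary = summary)
}

#' Mantel test between two distance matrices
#'
#' Correlates the upper-triangle entries of two distance matrices and
#' assesses significance by jointly permuting the rows and columns of the
#' first matrix: `p = (1 + #{perm |r| >= |r_obs|}) / (1 + n_perm)`
#' (two-sided).  Also reports `r^2`.
#'
#' @param dm_a,dm_b Symmetric labeled matrices over the same samples.
#' @param method `"pearson"` or `"spearman"`.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return Tibble `method`, `statistic` (r), `r_squared`, `p_value`,
#'   `n_perm`, `n_samples`.
#' @export
mantel_test <- function(dm_a, dm_b, method = c("pearson", "spearman"),
                        n_perm = 999, seed = 1L) {
  method <- match.arg(method)
  a <- check_dist(dm_a, tol = 1e-6)
  b <- check_dist(dm_b, tol = 1e-6)
  n <- nrow(a)
  if (n < 4) stop("need at least 4 samples for a Mantel test")
  if (!identical(rownames(a), rownames(b))) {
    if (is.null(rownames(b)) || !setequal(rownames(a), rownames(b))) {
      stop("distance matrices must share sample labels")
    }
    b <- b[rownames(a), rownames(a)]
  }
  ut <- upper.tri(a)
  vb <- b[ut]
  r_obs <- cor(a[ut], vb, method = method)
  hits <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      abs(cor(a[p, p][ut], vb, method = method)) >= abs(r_obs) - 1e-12
    }, logical(1)))
  })
  tibble::tibble(method = paste0("Mantel (", method, ")"),
                 statistic = r_obs, r_squared = r_obs^2,
                 p_value = (1 + hits) / (1 + n_perm),
                 n_perm = n_perm, n_samples = n)
}

#' Pairwise distance matrix of a metadata variable
#'
#' Absolute differences `|v_j - v_k|` of a numeric per-sample variable,
#' for use as the environmental side of a Mantel test.
#'
#' @param metadata Tibble with a `sample_id` column.
#' @param column Name of a numeric column (e.g. `"altitude"`, `"bmi"`).
#' @return Symmetric hollow matrix labeled by sample id.
#' @export
env_distance <- function(metadata, column) {
  v <- metadata[[column]]
  if (is.null(v)) stop("no metadata column named '", column, "'")
  if (!is.numeric(v)) stop("metadata column '", column, "' is not numeric")
  if (anyNA(v)) {
    stop("missing ", column, " for sample(s): ",
         paste(metadata$sample_id[is.na(v)], collapse = ", "))
  }
  out <- abs(outer(v, v, "-"))
  dimnames(out) <- list(metadata$sample_id, metadata$sample_id)
  out
}
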