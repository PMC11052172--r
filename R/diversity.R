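#' Shannon and Gini-Simpson diversity of a count vector
#'
#' `shannon()` returns `H = -sum(p_i log p_i)` over non-zero proportions
#' (natural log by default; `base = 2` for bits).  `simpson()` returns the
#' Gini-Simpson index `1 - sum(p_i^2)` (the convention of common amplicon
#' pipelines); set `inverse = TRUE` for inverse Simpson `1 / sum(p_i^2)`.
#'
#' @param counts Non-negative numeric vector with positive total.
#' @param base Logarithm base for `shannon()`.
#' @param inverse Return inverse Simpson instead of Gini-Simpson.
#' @return A single numeric value.
#' @examples
#' shannon(rep(1, 10))   # log(10)
#' simpson(c(1, 1))      # 0.5
#' @export
shannon <- function(counts, base = exp(1)) {
  if (any(counts < 0)) stop("negative counts")
  total <- sum(counts)
  if (total <= 0) stop("zero total count")
  p <- counts[counts > 0] / total
  -sum(p * log(p, base = base))
}

#' @rdname shannon
#' @export
simpson <- function(counts, inverse = FALSE) {
  if (any(counts < 0)) stop("negative counts")
  total <- sum(counts)
  if (total <= 0) stop("zero total count")
  p <- counts / total
  s2 <- sum(p^2)
  if (inverse) 1 / s2 else 1 - s2
}

#' Per-sample alpha diversity table
#'
#' @param table Samples x taxa count table (see [asv_matrix()]).
#' @return Tibble `sample_id`, `richness`, `shannon` (nats), `simpson`
#'   (Gini-Simpson).
#' @export
alpha_diversity <- function(table) {
  m <- asv_matrix(table)
  tibble::tibble(sample_id = rownames(m),
                 richness = rowSums(m > 0),
                 shannon = apply(m, 1, shannon),
                 simpson = apply(m, 1, simpson))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(j, k) = sum_i |x_ij - x_ik| / sum_i (x_ij + x_ik)`, computed with
#' [vegan::vegdist()].
#'
#' @inheritParams alpha_diversity
#' @return Symmetric hollow matrix labeled by sample id, values in `[0, 1]`.
#' @export
bray_curtis <- function(table) {
  m <- asv_matrix(table)
  if (any(rowSums(m) == 0)) {
    stop("all-zero sample(s): ", paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  }
  as.matrix(vegan::vegdist(m, method = "bray"))
}

#' Principal coordinate analysis (classical MDS)
#'
#' Double-centered Gower eigendecomposition of a distance matrix via
#' [stats::cmdscale()].  Proportion explained is computed over positive
#' eigenvalues only; negative eigenvalues (non-Euclidean input) are retained
#' in `eigenvalues` for inspection.
#'
#' @param dm Symmetric labeled distance matrix.
#' @param n_axes Number of axes to return (truncated with a warning if the
#'   positive-eigenvalue rank is smaller).
#' @return Object of class `pcoa_result`: list with `coordinates` (tibble
#'   `sample_id`, `Axis1`, ...), `eigenvalues`, `proportion_explained`.
#' @export
pcoa <- function(dm, n_axes = 2) {
  dm <- check_dist(dm)
  n <- nrow(dm)
  fit <- suppressWarnings(cmdscale(as.dist(dm), k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > max(eig) * 1e-9)
  rank_pos <- length(pos)
  if (n_axes > rank_pos) {
    warning("requested ", n_axes, " axes but positive rank is ", rank_pos,
            "; truncating")
    n_axes <- rank_pos
  }
  coords <- fit$points[, seq_len(n_axes), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_len(n_axes))
  structure(list(
    coordinates = dplyr::bind_cols(tibble::tibble(sample_id = rownames(dm)),
                                   tibble::as_tibble(coords)),
    eigenvalues = eig,
    proportion_explained = eig[pos] / sum(eig[pos])
  ), class = "pcoa_result")
}

#' @method tidy pcoa_result
#' @export
tidy.pcoa_result <- function(x, ...) x$coordinates

#' @method autoplot pcoa_result
#' @export
autoplot.pcoa_result <- function(object, labels = NULL, ...) {
  df <- object$coordinates
  pe <- object$proportion_explained
  if (!is.null(labels)) df$group <- factor(labels)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$Axis1, .data$Axis2)) +
    ggplot2::labs(x = sprintf("PCoA1 (%.1f%%)", 100 * pe[1]),
                  y = sprintf("PCoA2 (%.1f%%)", 100 * pe[2]))
  if (is.null(labels)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of group separation in a distance matrix
#' ([vegan::anosim()]).  `R = (mean between-group rank - mean within-group
#' rank) / (M / 2)` with `M = n (n - 1) / 2`; the p value uses the
#' `(1 + hits) / (1 + n_perm)` estimator and so is never 0.
#'
#' @param dm Symmetric labeled distance matrix.
#' @param labels Group label per sample (>= 2 groups, each of size >= 2).
#' @param n_perm Number of permutations.
#' @param seed Integer seed for the permutations.
#' @return Tibble `method`, `statistic` (R), `p_value`, `n_perm`, `n_groups`.
#' @export
anosim <- function(dm, labels, n_perm = 999, seed = 1L) {
  dm <- check_dist(dm)
  labels <- as.factor(labels)
  if (length(labels) != nrow(dm)) stop("labels must match distance matrix rows")
  sizes <- table(labels)
  if (length(sizes) < 2) stop("need at least two groups")
  if (any(sizes < 2)) {
    stop("singleton group(s): ", paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  fit <- withr::with_seed(seed,
    vegan::anosim(as.dist(dm), grouping = labels, permutations = n_perm))
  tibble::tibble(method = "ANOSIM", statistic = unname(fit$statistic),
                 p_value = fit$signif, n_perm = n_perm,
                 n_groups = length(sizes))
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney test via [stats::wilcox.test()]: exact enumeration
#' when both samples have at most 8 untied observations, tie-corrected
#' normal approximation otherwise.
#'
#' @param x,y Numeric samples (each non-empty).
#' @return Tibble `method`, `statistic` (U for the first sample), `p_value`,
#'   `n_x`, `n_y`.
#' @export
rank_sum_test <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 8 && length(y) <= 8 && !ties
  fit <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = !exact, alternative = "two.sided"))
  tibble::tibble(method = "Wilcoxon rank-sum", statistic = unname(fit$statistic),
                 p_value = fit$p.value, n_x = length(x), n_y = length(y))
}

#' Per-taxon two-group abundance contrasts
#'
#' Runs [rank_sum_test()] on every taxon of a relative-abundance table
#' between two groups and applies Benjamini-Hochberg correction across the
#' whole taxon family.  `enriched_in` records the group with the higher mean
#' relative abundance.
#'
#' @param table_rel Relative-abundance samples x taxa table (typically
#'   aggregated at phylum or genus level).
#' @param labels Two-level group label per sample.
#' @param fdr_alpha Significance threshold applied to the adjusted p values
#'   when flagging `significant`.
#' @return Tibble `taxon_id`, `statistic`, `p_value`, `q_value`,
#'   `enriched_in`, `significant`, sorted by `q_value`.
#' @export
compare_taxa <- function(table_rel, labels, fdr_alpha = 0.05) {
  m <- asv_matrix(table_rel)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("compare_taxa requires exactly two groups")
  g1 <- labels == levels(labels)[1]
  res <- purrr::map_dfr(colnames(m), function(tx) {
    r <- rank_sum_test(m[g1, tx], m[!g1, tx])
    tibble::tibble(taxon_id = tx, statistic = r$statistic, p_value = r$p_value,
                   enriched_in = levels(labels)[if (mean(m[g1, tx]) >= mean(m[!g1, tx])) 1 else 2])
  })
  res$q_value <- p.adjust(res$p_value, method = "BH")
  res$significant <- res$q_value < fdr_alpha
  dplyr::arrange(res, .data$q_value, .data$p_value)
}
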