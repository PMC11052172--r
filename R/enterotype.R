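#' k-medoids (PAM) clustering of a distance matrix
#'
#' BUILD + SWAP partitioning around medoids ([cluster::pam()]) minimizing
#' total within-cluster distance to the medoid.  PAM's BUILD initialization
#' is deterministic, so the result depends only on `dm` and `k`.
#'
#' @param dm Symmetric labeled distance matrix.
#' @param k Number of clusters (`2 <= k < n`).
#' @return List with `labels` (named integer vector), `medoids` (sample
#'   ids) and `total_cost`.
#' @export
pam_cluster <- function(dm, k) {
  dm <- check_dist(dm)
  n <- nrow(dm)
  if (k < 2 || k > n) stop("k must satisfy 2 <= k <= n (n = ", n, ")")
  if (k == n) {
    # degenerate: every sample its own medoid, zero cost
    return(list(labels = setNames(seq_len(n), rownames(dm)),
                medoids = rownames(dm), total_cost = 0))
  }
  fit <- cluster::pam(as.dist(dm), k = k, diss = TRUE)
  labels <- fit$clustering
  names(labels) <- rownames(dm)
  list(labels = labels, medoids = fit$medoids,
       total_cost = sum(dm[cbind(seq_len(n), match(fit$medoids, rownames(dm))[labels])]))
}

#' Calinski-Harabasz index of a clustering
#'
#' Pseudo-F ratio `[B / (k - 1)] / [W / (n - k)]` of between- to
#' within-cluster sums of squared Euclidean deviations, computed in the
#' full principal-coordinate space of `dm` (all positive-eigenvalue axes) —
#' the standard practice for enterotype model selection on Bray-Curtis
#' distances.  A perfectly tight clustering (`W = 0`) returns `Inf`.
#'
#' @param dm Symmetric labeled distance matrix.
#' @param labels Cluster assignment per sample (>= 2 non-empty clusters,
#'   fewer than n).
#' @return A single numeric value (possibly `Inf`).
#' @export
calinski_harabasz <- function(dm, labels) {
  dm <- check_dist(dm)
  labels <- as.factor(labels)
  n <- nrow(dm)
  k <- nlevels(droplevels(labels))
  if (k < 2 || k >= n) stop("need 2 <= k < n clusters")
  fit <- suppressWarnings(cmdscale(as.dist(dm), k = n - 1, eig = TRUE))
  pos <- fit$eig > max(fit$eig) * 1e-9
  coords <- fit$points[, pos[seq_len(ncol(fit$points))], drop = FALSE]
  grand <- colMeans(coords)
  W <- 0; B <- 0
  for (lv in levels(labels)) {
    rows <- coords[labels == lv, , drop = FALSE]
    ctr <- colMeans(rows)
    W <- W + sum(sweep(rows, 2, ctr)^2)
    B <- B + nrow(rows) * sum((ctr - grand)^2)
  }
  if (W <= 1e-12 * max(B, 1)) return(Inf)   # perfectly tight clusters
  (B / (k - 1)) / (W / (n - k))
}

#' Mean silhouette width of a clustering
#'
#' Mean over samples of `(b - a) / max(a, b)` ([cluster::silhouette()]);
#' samples in singleton clusters score 0.
#'
#' @inheritParams calinski_harabasz
#' @return A single numeric value in `[-1, 1]`.
#' @export
silhouette_mean <- function(dm, labels) {
  dm <- check_dist(dm)
  labels <- as.integer(as.factor(labels))
  if (length(unique(labels)) < 2) stop("need at least two clusters")
  sil <- cluster::silhouette(labels, dmatrix = dm)
  mean(sil[, "sil_width"])
}

#' Enterotype discovery: PAM + Calinski-Harabasz scan over k
#'
#' Runs [pam_cluster()] for each `k` in `[k_min, k_max]`, scores each
#' partition with [calinski_harabasz()] and [silhouette_mean()], and selects
#' the `k` with the highest CH value (ties broken toward smaller `k`).
#'
#' @param dm Symmetric labeled distance matrix (typically genus-level
#'   Bray-Curtis).
#' @param k_min,k_max Range of cluster counts to scan.
#' @return Object of class `enterotype_fit`: list with `k_best`, `labels`
#'   (tibble `sample_id`, `cluster`), `medoids`, `profile` (tibble `k`,
#'   `ch`, `silhouette`), `dm`.
#' @export
select_k <- function(dm, k_min = 2, k_max = 6) {
  dm <- check_dist(dm)
  n <- nrow(dm)
  if (!(2 <= k_min && k_min <= k_max && k_max < n)) {
    stop("need 2 <= k_min <= k_max < n")
  }
  ks <- k_min:k_max
  fits <- purrr::map(ks, function(k) pam_cluster(dm, k))
  profile <- tibble::tibble(
    k = ks,
    ch = purrr::map_dbl(fits, function(f) calinski_harabasz(dm, f$labels)),
    silhouette = purrr::map_dbl(fits, function(f) silhouette_mean(dm, f$labels)))
  best <- which(profile$ch == max(profile$ch))[1]   # ties -> smallest k
  fit <- fits[[best]]
  structure(list(
    k_best = ks[best],
    labels = tibble::tibble(sample_id = rownames(dm),
                            cluster = unname(fit$labels)),
    medoids = fit$medoids,
    profile = profile,
    dm = dm
  ), class = "enterotype_fit")
}

#' @export
print.enterotype_fit <- function(x, ...) {
  cat("Enterotype fit: k_best =", x$k_best, "\n")
  cat("cluster sizes:", paste(table(x$labels$cluster), collapse = "/"), "\n")
  cat("CH profile:\n")
  print(as.data.frame(x$profile), row.names = FALSE)
  invisible(x)
}

#' @method tidy enterotype_fit
#' @export
tidy.enterotype_fit <- function(x, ...) x$labels

#' @method glance enterotype_fit
#' @export
glance.enterotype_fit <- function(x, ...) {
  i <- match(x$k_best, x$profile$k)
  tibble::tibble(k_best = x$k_best, ch_best = x$profile$ch[i],
                 silhouette_best = x$profile$silhouette[i],
                 n_samples = nrow(x$labels))
}

#' @method autoplot enterotype_fit
#' @export
autoplot.enterotype_fit <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(.data$k, .data$ch)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k_best, linetype = "dashed") +
    ggplot2::labs(x = "number of clusters k", y = "Calinski-Harabasz index")
}
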