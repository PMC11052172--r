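#' ASV tables as tibbles
#'
#' Throughout the package a community table is an ordinary tibble whose first
#' column, `sample_id`, holds unique sample identifiers and whose remaining
#' columns are numeric abundances, one column per taxon (ASV or genus).  This
#' keeps every stage pipeable; [asv_matrix()] and [as_asv_table()] convert to
#' and from the base matrix form the underlying numerics use.
#'
#' @param table A samples x taxa tibble (first column `sample_id`) or a
#'   numeric matrix with sample ids as row names.
#' @return `asv_matrix()` returns a numeric matrix with row names (samples)
#'   and column names (taxa); `as_asv_table()` returns the tibble form.
#' @examples
#' m <- matrix(c(3, 1, 0, 2), 2, 2, dimnames = list(c("s1", "s2"), c("t1", "t2")))
#' as_asv_table(m)
#' @export
asv_matrix <- function(table) {
  if (is.matrix(table)) {
    m <- table
    if (is.null(rownames(m))) stop("matrix input must carry sample ids as row names")
  } else {
    table <- tibble::as_tibble(table)
    if (!identical(names(table)[1], "sample_id")) {
      stop("the first column of a community table must be `sample_id`")
    }
    ids <- as.character(table$sample_id)
    m <- as.matrix(table[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- names(table)[-1][!vapply(table[-1], is.numeric, logical(1))]
      stop("non-numeric abundance column(s): ", paste(bad, collapse = ", "))
    }
    rownames(m) <- ids
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicated sample id: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(m))) {
    stop("duplicated taxon id: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  }
  if (anyNA(m)) stop("missing values in abundance table")
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at sample '%s', taxon '%s'",
                 rownames(m)[idx[1]], colnames(m)[idx[2]]))
  }
  m
}

#' @rdname asv_matrix
#' @export
as_asv_table <- function(table) {
  m <- asv_matrix(table)
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)), out)
}

check_integer_counts <- function(m, what) {
  if (any(abs(m - round(m)) > 1e-8)) {
    stop(what, " is defined on raw integer counts; found non-integer values")
  }
}

#' Drop low-count ASVs
#'
#' Removes taxa whose total count pooled across all samples falls below a
#' minimum, the standard "fewer than `min_total` reads" denoising follow-up.
#' The bound is strict: a taxon with total exactly `min_total` is retained.
#'
#' @param table Samples x taxa count table (see [asv_matrix()]).
#' @param min_total Minimum pooled count a taxon must reach to be kept
#'   (default 5, i.e. taxa with fewer than 5 reads overall are discarded).
#' @return The filtered table as a tibble; the sample set is unchanged.
#' @export
filter_low_abundance_asvs <- function(table, min_total = 5) {
  m <- asv_matrix(table)
  check_integer_counts(m, "low-abundance filtering")
  keep <- colSums(m) >= min_total
  as_asv_table(m[, keep, drop = FALSE])
}

#' Rarefy counts to an even depth
#'
#' Subsamples each sample's reads without replacement down to a common depth
#' (default: the smallest sample total), via [vegan::rrarefy()].  A single
#' seeded draw is taken; the seed is recorded in the `rarefy_seed` attribute.
#'
#' @inheritParams filter_low_abundance_asvs
#' @param depth Target reads per sample; defaults to the minimum sample total.
#' @param seed Integer seed for the subsampling draw.
#' @return Tibble with every row sum equal to `depth`.
#' @export
rarefy <- function(table, depth = NULL, seed = 1L) {
  m <- asv_matrix(table)
  check_integer_counts(m, "rarefaction")
  totals <- rowSums(m)
  if (is.null(depth)) depth <- min(totals)
  short <- totals < depth
  if (any(short)) {
    stop("depth ", depth, " exceeds the total of sample(s): ",
         paste(rownames(m)[short], collapse = ", "))
  }
  out <- withr::with_seed(seed, vegan::rrarefy(round(m), depth))
  res <- as_asv_table(out)
  attr(res, "rarefy_seed") <- seed
  attr(res, "rarefy_depth") <- depth
  res
}

#' Merge ASVs by genus
#'
#' Sums counts over ASVs sharing a genus label.  ASVs whose genus is
#' unassigned are pooled under the sentinel label `"g__unassigned"`.  The
#' grand total is conserved exactly.
#'
#' @inheritParams filter_low_abundance_asvs
#' @param taxonomy Tibble with columns `taxon_id` and `genus` (unassigned
#'   genera as `NA` or `""`), e.g. from [read_taxonomy()].
#' @return Samples x genera tibble.
#' @export
aggregate_by_genus <- function(table, taxonomy) {
  m <- asv_matrix(table)
  genus <- setNames(as.character(taxonomy$genus), taxonomy$taxon_id)
  missing <- setdiff(colnames(m), names(genus))
  if (length(missing)) {
    stop("taxa absent from taxonomy: ", paste(head(missing, 5), collapse = ", "))
  }
  g <- genus[colnames(m)]
  g[is.na(g) | g == ""] <- "g__unassigned"
  agg <- t(rowsum(t(m), group = g))
  as_asv_table(agg[, order(colnames(agg)), drop = FALSE])
}

#' Convert counts to relative abundances
#'
#' @inheritParams filter_low_abundance_asvs
#' @return Tibble whose rows each sum to 1.  Samples with zero total are an
#'   error rather than being silently normalized.
#' @export
relative_abundance <- function(table) {
  m <- asv_matrix(table)
  totals <- rowSums(m)
  if (any(totals == 0)) {
    stop("all-zero sample(s): ", paste(rownames(m)[totals == 0], collapse = ", "))
  }
  as_asv_table(m / totals)
}

#' Reconcile a community table with a phylogeny
#'
#' Prunes the tree to the taxa present in the table and drops table taxa
#' absent from the tree, reporting both counts.  Downstream phylogenetic
#' functions require exact agreement, so the reconciliation is an explicit,
#' logged step rather than a silent default.
#'
#' @inheritParams filter_low_abundance_asvs
#' @param tree An [ape::phylo] tree whose tips are taxon ids.
#' @return A list with elements `table` (tibble) and `tree` (phylo).
#' @export
reconcile_tree_table <- function(table, tree) {
  m <- asv_matrix(table)
  shared <- intersect(colnames(m), tree$tip.label)
  if (length(shared) < 2) stop("fewer than two taxa shared between table and tree")
  drop_tab <- setdiff(colnames(m), shared)
  drop_tip <- setdiff(tree$tip.label, shared)
  if (length(drop_tab)) {
    message("dropping ", length(drop_tab), " table taxa absent from tree")
  }
  if (length(drop_tip)) {
    message("pruning ", length(drop_tip), " tree tips absent from table")
    tree <- ape::drop.tip(tree, drop_tip)
  }
  list(table = as_asv_table(m[, shared, drop = FALSE]), tree = tree)
}
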