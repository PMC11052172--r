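#' Read a tab-separated ASV count table
#'
#' @param path Path to a TSV file.  Lines starting with `#` are treated as
#'   comment/provenance headers and skipped.
#' @param taxa_as_rows If `TRUE` the file stores taxa as rows and samples as
#'   columns (the common QIIME orientation); the result is transposed to the
#'   package's samples x taxa convention.
#' @return Samples x taxa tibble (see [asv_matrix()]).
#' @export
read_asv_table <- function(path, taxa_as_rows = FALSE) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))), arr.ind = TRUE)
    if (length(bad)) {
      stop(sprintf("non-numeric cell at row '%s', column '%s' of %s",
                   ids[bad[1, 1]], colnames(m)[bad[1, 2]], path))
    }
    m <- apply(m, 2, as.numeric)
  }
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (taxa_as_rows) m <- t(m)
  as_asv_table(m)
}

#' Read a rooted newick tree
#'
#' Wraps [ape::read.tree()].  Missing branch lengths are set to 0 with a
#' warning; negative branch lengths are a hard error.
#'
#' @param path Path to a newick file.
#' @return An [ape::phylo] object.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick file: ", path)
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; setting all to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("missing branch lengths set to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths in ", path)
  if (anyDuplicated(tree$tip.label)) stop("duplicated tip labels in ", path)
  tree
}

#' Read a taxonomy table
#'
#' Expects tab-separated columns `taxon_id` then ranked lineage labels
#' (`kingdom` ... `genus`).  Empty rank labels are kept as explicit `NA`.
#'
#' @param path Path to a TSV file.
#' @return Tibble with at least `taxon_id` and `genus` columns.
#' @export
read_taxonomy <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = c("", "NA"))
  names(df)[1] <- "taxon_id"
  if (!"genus" %in% names(df)) stop("taxonomy file lacks a 'genus' column")
  if (anyDuplicated(df$taxon_id)) stop("duplicated taxon_id in taxonomy")
  tibble::as_tibble(df)
}

#' Read per-sample metadata
#'
#' Expects tab-separated columns `sample_id`, `site`, `altitude` (m),
#' `body_length` (mm), `body_weight` (g) and `bmi` (g/mm^2).  Missing values
#' stay explicit (`NA`); strictly positive fields are validated where present.
#'
#' @param path Path to a TSV file.
#' @return Tibble keyed by `sample_id`.
#' @export
read_metadata <- function(path) {
  df <- tibble::as_tibble(
    read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
               check.names = FALSE, stringsAsFactors = FALSE,
               na.strings = c("", "NA")))
  names(df)[1] <- "sample_id"
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in metadata")
  for (col in intersect(c("altitude", "body_length", "body_weight", "bmi"), names(df))) {
    v <- df[[col]]
    if (any(v <= 0, na.rm = TRUE)) stop("non-positive values in metadata column ", col)
  }
  df
}

#' Write a TSV with a provenance header
#'
#' All pipeline outputs carry a single `#`-prefixed header recording the
#' producing call, parameters and seed, so a results directory is
#' self-describing.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @param provenance Named list appended to the header line.
#' @return `path`, invisibly.
#' @export
write_tsv_provenance <- function(x, path, provenance = list()) {
  prov <- c(list(package = "gutassembly", written = format(Sys.time(), "%Y-%m-%d")),
            provenance)
  header <- paste0("# ", paste(names(prov), unname(vapply(prov, function(v)
    paste(format(v), collapse = ","), character(1))), sep = "=", collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  suppressWarnings(write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' Long-form view of a distance matrix
#'
#' @param dm Symmetric labeled matrix.
#' @return Tibble with one row per unordered sample pair (`sample_a`,
#'   `sample_b`, `value`), upper triangle only.
#' @export
tidy_dist <- function(dm) {
  dm <- as.matrix(dm)
  idx <- which(upper.tri(dm), arr.ind = TRUE)
  tibble::tibble(sample_a = rownames(dm)[idx[, 1]],
                 sample_b = colnames(dm)[idx[, 2]],
                 value = dm[idx])
}

check_dist <- function(dm, tol = 1e-8) {
  dm <- as.matrix(dm)
  stopifnot(nrow(dm) == ncol(dm))
  if (is.null(rownames(dm))) stop("distance matrix must be labeled")
  if (max(abs(dm - t(dm))) > tol) stop("distance matrix is not symmetric")
  dm
}
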