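# small fixtures built in code, shared across test files

tiny_counts <- function() {
  m <- matrix(c(3, 0, 1, 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("t1", "t2")))
  as_asv_table(m)
}

# the 3-taxon caterpillar used for hand-computed phylogenetic examples
tiny_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

write_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# adjusted Rand index between two label vectors (closed form on the
# contingency table); independent of any clustering package
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# exhaustive k=2 medoid-pair oracle: best partition over all medoid pairs
pam_oracle_k2 <- function(dm) {
  n <- nrow(dm)
  best <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    assign <- ifelse(dm[, i] <= dm[, j], i, j)
    cost <- sum(dm[cbind(1:n, assign)])
    if (is.null(best) || cost < best$cost) {
      best <- list(cost = cost, medoids = c(i, j), assign = assign)
    }
  }
  best
}

# two well-separated blobs as a distance matrix: within-distance ~u, between ~u+gap
blob_dm <- function(n_per = 5, gap = 10, seed = 1) {
  withr::with_seed(seed, {
    x <- c(runif(n_per), runif(n_per) + gap)
  })
  dm <- abs(outer(x, x, "-"))
  dimnames(dm) <- list(sprintf("s%02d", seq_along(x)), sprintf("s%02d", seq_along(x)))
  dm
}
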