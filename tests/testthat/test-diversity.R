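test_that("alpha diversity matches closed forms", {
  expect_equal(shannon(rep(1, 10)), log(10))
  expect_equal(shannon(c(7, 0, 0)), 0)
  expect_equal(shannon(c(1, 1, 2)), 1.5 * log(2))
  expect_equal(shannon(c(1, 1, 1, 1), base = 2), 2)
  expect_equal(simpson(c(5, 0)), 0)
  expect_equal(simpson(c(1, 1)), 0.5)
  expect_equal(simpson(c(1, 1, 2)), 0.625)
  expect_equal(simpson(c(1, 1), inverse = TRUE), 2)
  expect_error(shannon(c(0, 0)), "zero total")
  expect_error(simpson(numeric(0)), "zero total")
})

test_that("shannon is bounded by log richness with equality iff uniform", {
  withr::with_seed(1, {
    for (i in 1:20) {
      v <- rpois(12, 5) + 1
      expect_lte(shannon(v), log(length(v)) + 1e-12)
    }
  })
  expect_equal(shannon(rep(3, 7)), log(7))
  expect_lt(shannon(c(10, 1, 1)), log(3))
})

test_that("Bray-Curtis matches closed forms and metric axioms on random tables", {
  m <- matrix(c(6, 2, 2, 2, 1, 3), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("t1", "t2")))
  dm <- bray_curtis(as_asv_table(m))
  expect_equal(dm["a", "b"], 1 / 3)
  expect_equal(dm["a", "a"], 0)
  disj <- matrix(c(5, 0, 0, 4), 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), c("t1", "t2")))
  expect_equal(bray_curtis(as_asv_table(disj))["a", "b"], 1)
  withr::with_seed(2, {
    r <- matrix(rpois(8 * 15, 4), 8, 15,
                dimnames = list(sprintf("s%d", 1:8), sprintf("t%d", 1:15)))
    r[1, ] <- r[1, ] + 1
  })
  dmr <- bray_curtis(as_asv_table(r))
  expect_true(all(dmr >= 0 & dmr <= 1))
  expect_equal(dmr, t(dmr))
  expect_true(all(diag(dmr) == 0))
})

test_that("PCoA reproduces Euclidean configurations", {
  # collinear points: one axis explains all positive inertia
  x <- c(0, 1, 2)
  dm <- abs(outer(x, x, "-"))
  dimnames(dm) <- list(c("a", "b", "c"), c("a", "b", "c"))
  fit <- pcoa(dm, n_axes = 1)
  expect_equal(fit$proportion_explained[1], 1)
  # round-trip: distances among random Euclidean points recovered
  withr::with_seed(5, pts <- matrix(rnorm(10 * 3), 10, 3))
  dm2 <- as.matrix(dist(pts))
  dimnames(dm2) <- list(sprintf("s%d", 1:10), sprintf("s%d", 1:10))
  # 3-D points have positive rank 3: requesting more axes warns and truncates
  expect_warning(fit2 <- pcoa(dm2, n_axes = 9), "truncating")
  rec <- as.matrix(dist(as.matrix(fit2$coordinates[, -1])))
  expect_lt(max(abs(rec - unname(dm2))), 1e-9)
  # duplicate samples land on identical coordinates
  dm3 <- dm2
  dm3[2, ] <- dm3[1, ]; dm3[, 2] <- dm3[, 1]; dm3[2, 2] <- 0
  fit3 <- pcoa(dm3, n_axes = 2)
  expect_equal(unlist(fit3$coordinates[1, -1]), unlist(fit3$coordinates[2, -1]))
})

test_that("ANOSIM gives R = 1 under perfect separation and is seed-stable", {
  dm <- blob_dm(n_per = 5, gap = 10)
  labels <- rep(c("g1", "g2"), each = 5)
  res <- anosim(dm, labels, n_perm = 199, seed = 3)
  expect_equal(res$statistic, 1)
  expect_lte(res$p_value, 0.05)
  expect_identical(res, anosim(dm, labels, n_perm = 199, seed = 3))
  expect_error(anosim(dm, c("a", rep("b", 9))), "singleton")
})

test_that("rank-sum test agrees with exhaustive label enumeration", {
  # oracle: enumerate all C(6,3) assignments of {1..6} into two triples
  vals <- 1:6
  splits <- utils::combn(6, 3)
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  obs_u <- u_stat(1:3, 4:6)
  us <- apply(splits, 2, function(ix) u_stat(vals[ix], vals[-ix]))
  p_exact <- mean(abs(us - 4.5) >= abs(obs_u - 4.5))
  res <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(p_exact, 0.1)
  expect_equal(res$p_value, p_exact)
  expect_equal(res$statistic, 0)
  # symmetry and identical-sample null
  expect_equal(rank_sum_test(c(4, 5, 6), c(1, 2, 3))$p_value, res$p_value)
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(rank_sum_test(numeric(0), 1), "empty")
})

test_that("per-taxon contrasts apply BH within the family", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  withr::with_seed(8, {
    m <- matrix(rpois(20 * 6, 20), 20, 6,
                dimnames = list(sprintf("s%d", 1:20), sprintf("t%d", 1:6)))
    m[1:10, 1] <- m[1:10, 1] + 60    # enriched taxon in group 1
  })
  rel <- relative_abundance(as_asv_table(m))
  labels <- rep(c("A", "B"), each = 10)
  res <- compare_taxa(rel, labels)
  expect_equal(res$q_value, p.adjust(res$p_value, "BH"))
  expect_true(res$significant[res$taxon_id == "t1"])
  expect_equal(res$enriched_in[res$taxon_id == "t1"], "A")
  expect_true(all(res$q_value >= res$p_value))
  # taxon distributed identically across groups: p = q = 1
  same <- matrix(rep(c(5, 7), each = 10), ncol = 1,
                 dimnames = list(sprintf("s%d", 1:20), "tx"))
  same <- cbind(same, tot = 20 - same[, 1])
  res2 <- compare_taxa(relative_abundance(as_asv_table(same)),
                       rep(c("A", "B"), 10))
  expect_true(all(res2$p_value == 1 & res2$q_value == 1))
})
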