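test_that("betaMNTD matches the hand-computed 3-taxon example", {
  tree <- tiny_tree()
  m <- matrix(c(0.5, 0.5, 0,
                0,   0,   1), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("A", "B", "C")))
  bm <- beta_mntd(as_asv_table(m), tree)
  expect_equal(bm["s1", "s2"], 4)
  expect_equal(bm["s1", "s1"], 0)
  # identical communities: nearest taxon is itself
  m2 <- rbind(s1 = c(A = 0.3, B = 0.3, C = 0.4), s2 = c(A = 0.3, B = 0.3, C = 0.4))
  expect_equal(beta_mntd(as_asv_table(m2), tree)["s1", "s2"], 0)
  # linearity in branch lengths
  tree2 <- tree
  tree2$edge.length <- tree2$edge.length * 3
  expect_equal(beta_mntd(as_asv_table(m), tree2)["s1", "s2"], 12)
})

test_that("betaMNTD agrees with picante::comdistnt on random communities", {
  skip_if_not_installed("picante")
  tree <- simulate_tree(30, seed = 5)
  withr::with_seed(6, {
    m <- matrix(rpois(8 * 30, 1.2), 8, 30,
                dimnames = list(sprintf("s%d", 1:8), tree$tip.label))
    m[rowSums(m) == 0, 1] <- 1
  })
  rel <- relative_abundance(as_asv_table(m))
  ours <- beta_mntd(rel, tree)
  ref <- as.matrix(picante::comdistnt(asv_matrix(rel),
                                      ape::cophenetic.phylo(tree),
                                      abundance.weighted = TRUE))
  expect_equal(ours[rownames(ref), colnames(ref)], ref, tolerance = 1e-10)
})

test_that("betaNTI is deterministic under seed and scale-invariant with shared seed", {
  sim <- simulate_neutral(10, 60, 800, Nm = 300, shape = 0.95, seed = 3)
  tree <- simulate_tree(60, seed = 8)
  rel <- relative_abundance(sim$table)
  z1 <- beta_nti(rel, tree, n_rand = 99, seed = 42)
  z2 <- beta_nti(rel, tree, n_rand = 99, seed = 42)
  expect_identical(z1, z2)
  expect_equal(z1, t(z1))
  # uniform branch-length scaling cancels exactly in the z-score
  tree3 <- tree
  tree3$edge.length <- tree3$edge.length * 7
  z3 <- beta_nti(rel, tree3, n_rand = 99, seed = 42)
  expect_equal(unclass(z3), unclass(z1), tolerance = 1e-10)
})

test_that("betaNTI null is approximately standard normal on signal-free data", {
  vals <- unlist(lapply(1:2, function(s) {
    sim <- simulate_neutral(20, 200, 2000, Nm = 2000, shape = 0.97, seed = s)
    tree <- simulate_tree(200, seed = 50 + s)
    z <- beta_nti(relative_abundance(sim$table), tree, n_rand = 99, seed = s)
    z[upper.tri(z)]
  }))
  expect_lt(abs(mean(vals)), 0.5)
  expect_gt(sd(vals), 0.6)
  expect_lt(sd(vals), 1.4)
  expect_lt(mean(abs(vals) > 2), 0.15)
})

test_that("Raup-Crick hits the bounds in the extreme cases and respects seeds", {
  # identical samples: observed BC = 0 sits below every null draw
  m <- matrix(c(20, 10, 5, 20, 10, 5, 3, 30, 8), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("t1", "t2", "t3")))
  rc <- raup_crick_bray(as_asv_table(m), n_rand = 99, seed = 1)
  expect_lte(rc["s1", "s2"], -0.9)   # below essentially all null draws
  expect_true(all(abs(rc) <= 1))
  expect_equal(rc, t(rc))
  expect_identical(rc, raup_crick_bray(as_asv_table(m), n_rand = 99, seed = 1))
  zero_m <- m; zero_m[1, ] <- 0
  expect_error(raup_crick_bray(as_asv_table(zero_m), n_rand = 9), "richness")
})

test_that("Raup-Crick centers near zero when data match the null's assembly scheme", {
  # communities built by the null's own two-step draw (species by occupancy,
  # individuals by pool abundance) must sit in the middle of the null
  two_step <- function(rich, total, occ_w, ab_w) {
    n_taxa <- length(occ_w)
    x <- numeric(n_taxa)
    sp <- sample.int(n_taxa, rich, prob = occ_w)
    x[sp] <- 1
    x[sp] <- x[sp] + rmultinom(1, total - rich, ab_w[sp])[, 1]
    x
  }
  rcvals <- unlist(lapply(1:2, function(s) {
    withr::with_seed(s, {
      pool <- 0.95^(1:80); pool <- pool / sum(pool)
      occ <- pmin(1, pool * 60)
      m <- t(vapply(1:10, function(i) two_step(30, 500, occ, pool), numeric(80)))
      dimnames(m) <- list(sprintf("s%d", 1:10), sprintf("t%d", 1:80))
    })
    rc <- raup_crick_bray(as_asv_table(m), n_rand = 99, seed = s)
    rc[upper.tri(rc)]
  }))
  expect_lt(abs(mean(rcvals)), 0.4)
})

test_that("multinomial draws from one pool read as more-similar-than-null", {
  # compositionally pinned samples: the homogenizing-dispersal signature
  withr::with_seed(1, {
    pool <- 0.95^(1:80); pool <- pool / sum(pool)
    m <- t(vapply(1:8, function(i) rmultinom(1, 500, pool)[, 1], numeric(80)))
    dimnames(m) <- list(sprintf("s%d", 1:8), sprintf("t%d", 1:80))
  })
  rc <- raup_crick_bray(as_asv_table(m), n_rand = 99, seed = 1)
  expect_lt(mean(rc[upper.tri(rc)]), -0.5)
})

test_that("Raup-Crick approaches +1 for maximally divergent samples", {
  # disjoint supports: observed BC = 1, at or above every null draw
  m <- matrix(c(5, 5, 0, 0, 0, 0, 5, 5), 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), sprintf("t%d", 1:4)))
  rc <- raup_crick_bray(as_asv_table(m), n_rand = 99, seed = 2)
  expect_gt(rc["s1", "s2"], 0.5)
  expect_lte(rc["s1", "s2"], 1)
})

test_that("process partition follows the Stegen rule set exhaustively", {
  lab <- c("x", "y", "z")
  mk <- function(v12, v13, v23) {
    m <- matrix(0, 3, 3, dimnames = list(lab, lab))
    m[1, 2] <- m[2, 1] <- v12; m[1, 3] <- m[3, 1] <- v13
    m[2, 3] <- m[3, 2] <- v23
    m
  }
  b <- mk(-2.5, 0.5, 2.5)
  r <- mk(0.1, -0.99, 0.2)
  part <- partition_processes(b, r)
  expect_equal(part$pairs$process,
               c("homogeneous_selection", "homogenizing_dispersal",
                 "variable_selection"))
  expect_equal(sum(part$summary$fraction), 1)
  expect_equal(sum(part$summary$n_pairs), 3)
  # drift case and dispersal limitation case
  part2 <- partition_processes(mk(0.5, 1.2, -0.3), mk(0.2, 0.1, 0.99))
  expect_equal(part2$pairs$process[1], "drift")
  expect_equal(part2$pairs$process[3], "dispersal_limitation")
  # boundary: |betaNTI| = 2 belongs to the stochastic band
  part3 <- partition_processes(mk(2, -2, 0), mk(0, 0, 0))
  expect_true(all(part3$pairs$process == "drift"))
  expect_error(partition_processes(b, r[c(2, 1, 3), c(2, 1, 3)]), "labels")
})

test_that("Mantel statistic and p behave on identity, affine and independent input", {
  dm <- blob_dm(n_per = 5, gap = 2, seed = 3)
  res <- mantel_test(dm, dm, n_perm = 99, seed = 1)
  expect_equal(res$statistic, 1)
  expect_equal(res$p_value, 1 / 100)
  aff <- 2 * dm + 3
  diag(aff) <- 0
  expect_equal(mantel_test(dm, aff, n_perm = 99, seed = 1)$statistic, 1)
  # r agrees with vegan's Mantel r (cross-check of the statistic only)
  withr::with_seed(4, {
    a <- as.matrix(dist(rnorm(12))); b <- as.matrix(dist(rnorm(12)))
    ids <- sprintf("s%d", 1:12)
    dimnames(a) <- dimnames(b) <- list(ids, ids)
  })
  expect_equal(mantel_test(a, b, n_perm = 9, seed = 1)$statistic,
               unname(vegan::mantel(as.dist(a), as.dist(b), permutations = 0)$statistic))
})

test_that("environmental distances are absolute differences with sane errors", {
  md <- tibble::tibble(sample_id = c("a", "b", "c"),
                       altitude = c(120, 120, 838), bmi = c(NA, 1, 2))
  dm <- env_distance(md, "altitude")
  expect_equal(dm["a", "c"], 718)
  expect_equal(dm["a", "b"], 0)
  expect_equal(env_distance(dplyr::mutate(md, altitude = altitude * 2), "altitude"),
               dm * 2)
  expect_error(env_distance(md, "bmi"), "a")
  expect_error(env_distance(md, "nope"), "nope")
})
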