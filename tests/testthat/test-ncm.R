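test_that("occurrence statistics follow their closed forms", {
  m <- matrix(c(10, 90, 0, 100), 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("t1", "t2")))
  st <- occurrence_stats(as_asv_table(m))
  expect_equal(st$p[st$taxon_id == "t1"], 0.05)
  expect_equal(st$freq[st$taxon_id == "t1"], 0.5)
  expect_equal(st$freq[st$taxon_id == "t2"], 1)
  mz <- cbind(m, gone = c(0, 0))
  expect_warning(st2 <- occurrence_stats(as_asv_table(mz)), "absent")
  expect_false("gone" %in% st2$taxon_id)
})

test_that("ncm_predict matches quadrature of the beta density and its limits", {
  # independent oracle: numerical integration of the Beta(Nm p, Nm (1-p)) density
  quad <- function(p, Nm, d) {
    stats::integrate(function(x) stats::dbeta(x, Nm * p, Nm * (1 - p)),
                     lower = d, upper = 1, rel.tol = 1e-10)$value
  }
  for (case in list(c(0.01, 1000, 1e-4), c(0.001, 500, 5e-4), c(0.2, 50, 0.01))) {
    expect_equal(ncm_predict(case[1], case[2], N = 1 / case[3], d = case[3]),
                 quad(case[1], case[2], case[3]), tolerance = 1e-7)
  }
  expect_gt(ncm_predict(1 - 1e-9, 100, N = 1000), 1 - 1e-6)
  # Nm -> inf concentrates at p: step at the detection limit
  expect_equal(ncm_predict(0.01, 1e7, N = 1000), 1, tolerance = 1e-6)
  expect_equal(ncm_predict(1e-4, 1e7, N = 1000), 0, tolerance = 1e-6)
  expect_error(ncm_predict(0, 100, N = 100), "strictly")
})

test_that("predicted frequency is monotone in p and in Nm beyond the limit", {
  p <- seq(2e-4, 5e-3, length.out = 30)   # below saturation at this Nm
  f <- ncm_predict(p, 500, N = 1000)
  expect_true(all(diff(f) > 0))
  f_nm <- sapply(c(50, 200, 800), function(nm) ncm_predict(2e-3, nm, N = 1000))
  expect_true(all(diff(f_nm) > 0))
})

test_that("frequencies set exactly to the prediction give R^2 = 1 and exact Nm", {
  p <- exp(seq(log(1e-4), log(0.05), length.out = 80))
  N <- 5000
  freq <- ncm_predict(p, Nm = 700, N = N, d = 1 / N)
  curve <- ncm_fit_curve(p, freq, N = N, d = 1 / N)
  expect_equal(curve$Nm, 700, tolerance = 1e-4)
  expect_equal(curve$r_squared, 1, tolerance = 1e-9)
})

test_that("fit invariants: band ordering, m = Nm/N, exhaustive partition", {
  sim <- simulate_neutral(30, 300, 3000, Nm = 800, shape = 0.97, seed = 2)
  fit0 <- suppressWarnings(ncm_fit(sim$table))
  st <- fit0$asv
  expect_true(all(st$lower <= st$predicted & st$predicted <= st$upper))
  expect_equal(fit0$m, fit0$Nm / fit0$N)
  expect_equal(mean(st$partition == "within"), fit0$fraction_within)
  expect_true(all(st$partition %in% c("above", "within", "below")))
})

test_that("Nm estimates recover the truth and rank a ladder of true values", {
  est <- sapply(1:3, function(s) {
    sim <- simulate_neutral(40, 600, 10000, Nm = 1500, seed = s)
    suppressWarnings(ncm_fit(sim$table))$Nm
  })
  expect_lt(abs(median(est) / 1500 - 1), 0.15)
  ladder <- sapply(c(100, 400, 1600, 6400), function(nm) {
    sim <- simulate_neutral(30, 400, 5000, Nm = nm, shape = 0.97, seed = 11)
    suppressWarnings(ncm_fit(sim$table))$Nm
  })
  expect_true(all(diff(ladder) > 0))
})

test_that("Wilson and beta bands are both honored and R^2 is not clamped", {
  sim <- simulate_neutral(25, 200, 2000, Nm = 300, shape = 0.96, seed = 4)
  fw <- suppressWarnings(ncm_fit(sim$table, ci_method = "wilson"))
  fb <- suppressWarnings(ncm_fit(sim$table, ci_method = "beta"))
  expect_equal(fw$Nm, fb$Nm)   # band choice cannot move the estimate
  expect_true(all(fb$asv$lower <= fb$asv$upper))
  expect_lte(fw$r_squared, 1)
  # an anti-neutral occupancy pattern must yield a poor (possibly negative) R^2
  m <- asv_matrix(sim$table)
  shuffled <- apply(m, 2, function(col) {
    out <- numeric(length(col))
    nz <- sum(col > 0)
    out[seq_len(nz)] <- sort(col[col > 0], decreasing = TRUE)
    out
  })
  rownames(shuffled) <- rownames(m)
  fit_bad <- suppressWarnings(ncm_fit(as_asv_table(shuffled)))
  expect_lt(fit_bad$r_squared, fw$r_squared)
})
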