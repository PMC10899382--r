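test_that("the Poisson partition estimator matches its closed form", {
  expect_equal(estimate_lambda(0, 20000)$lambda, 0)
  est <- estimate_lambda(2000, 20000)
  expect_equal(est$lambda, -log(1 - 0.1), tolerance = 1e-12)
  expect_equal(est$se, sqrt(0.1 / (0.9 * 20000)), tolerance = 1e-12)
  expect_error(estimate_lambda(20000, 20000), "saturated")
  expect_error(estimate_lambda(5, 0), "n_droplets")
})

test_that("lambda-hat is increasing in the positive count and inflates p-hat", {
  n <- 1000
  lams <- vapply(seq(0, 990, by = 30),
                 function(k) estimate_lambda(k, n)$lambda, numeric(1))
  expect_true(all(diff(lams) > 0))
  for (k in c(1, 100, 500, 950)) {
    expect_gte(estimate_lambda(k, n)$lambda, k / n)
  }
})

test_that("channel ratios behave at the symmetric and null limits", {
  r <- ratio_with_ci(c(3000, 20000), c(3000, 20000))
  expect_equal(r$ratio, 1.0)
  r0 <- ratio_with_ci(c(0, 20000), c(3000, 20000))
  expect_equal(r0$ratio, 0.0)
  expect_error(ratio_with_ci(c(100, 1000), c(0, 1000)), "undefined ratio")
  # droplet_assay objects are accepted directly
  a <- simulate_droplets(0.2, 0.05, 50000, seed = 3)
  expect_equal(ratio_with_ci(a)$ratio,
               ratio_with_ci(c(a$n_positive_target, a$n_droplets),
                             c(a$n_positive_reference, a$n_droplets))$ratio)
})

test_that("simulated assays recover the true concentration ratio", {
  # consistency across droplet counts: bias shrinks as n grows
  true_ratio <- 5
  bias <- vapply(c(1e3, 1e4, 1e5), function(n) {
    est <- vapply(1:20, function(s) {
      ratio_with_ci(simulate_droplets(0.5, 0.1, n, seed = 1000 + s))$ratio
    }, numeric(1))
    abs(mean(est) - true_ratio)
  }, numeric(1))
  expect_lt(bias[3], 0.05)
  expect_lt(bias[3], bias[1] + 0.05)
  # the reported SE covers the truth for a single large assay
  r <- ratio_with_ci(simulate_droplets(0.5, 0.1, 1e5, seed = 77))
  expect_lt(abs(r$ratio - true_ratio), 3 * r$ratio_se)
})

test_that("ploidy estimation recovers the simulated copy-number range", {
  std <- simulate_fcm(1, n_cells = 10000, cv = 0.1, standard = TRUE, seed = 8)
  # sample identical to the standard -> one copy
  p1 <- ploidy_from_histogram(std, std)
  expect_equal(p1$copies_min, 1L)
  expect_equal(p1$copies_max, 1L)
  # uniform 2..6 copies: the lower bound is recovered exactly; the exact
  # 95% quantile of the mixture sits at ~6.50 unit signals (overlap with
  # the 5-copy component inflates it above 6.39), so the rounded upper
  # bound lands on 6 or 7 depending on sampling noise
  smp <- simulate_fcm(2:6, n_cells = 10000, cv = 0.1, seed = 9)
  p26 <- ploidy_from_histogram(smp, std)
  expect_equal(p26$copies_min, 2L)
  expect_true(p26$copies_max %in% c(6L, 7L))
  # at lower noise the component overlap vanishes and (2, 6) is exact
  smp_lo <- simulate_fcm(2:6, n_cells = 10000, cv = 0.03, seed = 9)
  std_lo <- simulate_fcm(1, n_cells = 10000, cv = 0.03, standard = TRUE,
                         seed = 8)
  p_lo <- ploidy_from_histogram(smp_lo, std_lo)
  expect_equal(p_lo$copies_min, 2L)
  expect_equal(p_lo$copies_max, 6L)
  # constant 4 copies with tiny noise -> (4, 4)
  smp4 <- simulate_fcm(4, n_cells = 5000, cv = 0.01, seed = 10)
  std4 <- simulate_fcm(1, n_cells = 5000, cv = 0.01, standard = TRUE,
                       seed = 11)
  p4 <- ploidy_from_histogram(smp4, std4)
  expect_equal(p4$copies_min, 4L)
  expect_equal(p4$copies_max, 4L)
})

test_that("degenerate fluorescence samples are rejected", {
  std <- simulate_fcm(1, n_cells = 5000, cv = 0.05, standard = TRUE,
                      seed = 12, unit_signal = 100)
  dim_smp <- simulate_fcm(1, n_cells = 5000, cv = 0.05, seed = 13,
                          unit_signal = 30)  # signal far below the standard
  expect_error(ploidy_from_histogram(dim_smp, std), "degenerate sample")
})

test_that("per-cell copy ranges floor the ratio-ploidy products", {
  expect_identical(unname(per_cell_copy_range(34.1, ploidy_asserted(2, 6))),
                   c(68L, 204L))
  expect_identical(unname(per_cell_copy_range(0.8, ploidy_asserted(3, 10))),
                   c(2L, 8L))
  expect_identical(unname(per_cell_copy_range(0, ploidy_asserted(2, 6))),
                   c(0L, 0L))
  # decimal ratios floor as exact decimal arithmetic, not binary artifacts
  expect_identical(unname(per_cell_copy_range(8.7, ploidy_asserted(3, 10))),
                   c(26L, 87L))
  # monotone in both arguments
  r <- seq(0, 10, by = 0.5)
  lo <- vapply(r, function(x) per_cell_copy_range(x, ploidy_asserted(2, 6))[1],
               integer(1))
  expect_true(all(diff(lo) >= 0))
  p <- vapply(2:8, function(k) per_cell_copy_range(3.3,
                                                   ploidy_asserted(k, k))[1],
              integer(1))
  expect_true(all(diff(p) >= 0))
})

test_that("the copy-number report assembles ratios and ploidies per row", {
  rep <- copy_number_report(
    labels = c("host1 plasmidA", "host2 plasmidB"),
    ratios = c(34.1, 0.8),
    ploidies = list(ploidy_asserted(2, 6), ploidy_asserted(3, 10)),
    ratio_ses = c(1.6, 0.04))
  expect_equal(rep$plasmid_copies_min, c(68L, 2L))
  expect_equal(rep$plasmid_copies_max, c(204L, 8L))
  expect_equal(rep$chromosome_copies, c("2-6", "3-10"))
})
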