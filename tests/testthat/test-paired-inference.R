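test_that("pair graph applies the 90-day window and records exclusions", {
  meta <- make_meta(
    c("p1", "r1a", "p2", "r2a", "p3", "r3a", "r3b"),
    c("F1", "F1", "F2", "F2", "F3", "F3", "F3"),
    c("patient", "relative", "patient", "relative", "patient", "relative", "relative"),
    c("2019-01-01", "2019-01-11",    # 10 days: eligible
      "2019-01-01", "2019-04-02",    # 91 days: excluded
      "2019-01-01", "2019-01-06", "2019-03-22"))  # 5 and 80 days: both eligible
  g <- build_pair_graph(meta, window_days = 90)
  expect_identical(g$patients, c("p1", "p3"))
  expect_identical(g$excluded_patients, "p2")
  expect_identical(g$eligible[["p3"]]$relative_sample, c("r3a", "r3b"))
  expect_identical(g$eligible[["p1"]]$gap_days, 10L)
  # boundary: exactly 90 days is eligible
  g90 <- build_pair_graph(make_meta(c("p", "r"), c("F", "F"),
                                    c("patient", "relative"),
                                    c("2019-01-01", "2019-04-01")))
  expect_identical(g90$patients, "p")
})

test_that("paired t matches hand closed forms and degenerate conventions", {
  r <- paired_t(c(1, -1))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  # d = (1,2,3,4): dbar = 2.5, s_d = 1.29099, t = 2.5/(1.29099/2)
  r2 <- paired_t(c(1, 2, 3, 4))
  expect_equal(r2$t, 2.5 / (1.290994 / 2), tolerance = 1e-6)
  expect_equal(r2$df, 3)
  r3 <- paired_t(rep(2, 5))
  expect_true(r3$zero_variance)
  expect_identical(r3$t, Inf)
  expect_equal(r3$p, 0)
  expect_error(paired_t(3), ">= 2")
})

test_that("Welch t matches an independent hand computation", {
  # a=(1,2,3), b=(2,4,6): means 2,4; vars 1,4
  # se = sqrt(1/3 + 4/3); t = -2/se; df = (5/3)^2 / ((1/3)^2/2 + (4/3)^2/2)
  se <- sqrt(5 / 3)
  r <- welch_t(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r$t, -2 / se, tolerance = 1e-12)
  expect_equal(r$df, (5 / 3)^2 / ((1 / 3)^2 / 2 + (4 / 3)^2 / 2), tolerance = 1e-12)
  expect_equal(r$diff, -2)
  ident <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  both_const <- welch_t(c(0, 0), c(1, 1))
  expect_true(both_const$zero_variance)
  expect_identical(both_const$t, -Inf)
})

test_that("BH q-values match hand arithmetic and are well behaved", {
  expect_equal(fdr_bh(0.031), 0.031)
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  for (s in 1:10) {
    p <- withr::with_seed(s, stats::runif(20)^2)
    q <- fdr_bh(p)
    expect_gte(min(q), min(p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p-rank
  }
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("unambiguous graphs reduce the permutation test to the exact paired t", {
  meta <- make_meta(sprintf(c("p%d", "r%d"), rep(1:4, each = 2)),
                    rep(sprintf("F%d", 1:4), each = 2),
                    rep(c("patient", "relative"), 4),
                    rep("2020-01-01", 8))
  vals <- c(p1 = 10, r1 = 8, p2 = 11, r2 = 10.5, p3 = 9, r3 = 9.5, p4 = 14, r4 = 10)
  g <- build_pair_graph(meta)
  exact <- paired_t(vals[c("p1", "p2", "p3", "p4")] - vals[c("r1", "r2", "r3", "r4")])
  for (np in c(1, 7, 50)) {
    r <- permutation_paired_test(vals, g, n_perm = np, seed = 5)
    expect_equal(r$mean_t, exact$t)
    expect_equal(r$mean_p, exact$p)
    expect_equal(r$mean_diff, exact$diff)
    expect_equal(r$mean_ci_low, exact$ci_low)
    expect_equal(r$df, 3L)
  }
})

test_that("the permutation test converges to the exhaustive pairing average", {
  meta <- make_meta(
    c("p1", "r1a", "r1b", "p2", "r2", "p3", "r3", "p4", "r4"),
    c("F1", "F1", "F1", "F2", "F2", "F3", "F3", "F4", "F4"),
    c("patient", "relative", "relative", "patient", "relative",
      "patient", "relative", "patient", "relative"),
    rep("2020-06-01", 9))
  vals <- c(p1 = 20, r1a = 15, r1b = 22, p2 = 18, r2 = 14,
            p3 = 25, r3 = 19, p4 = 16, r4 = 17)
  g <- build_pair_graph(meta)
  oracle <- enumerate_pairing(vals, g)
  expect_equal(oracle$n_assignments, 2)
  r <- permutation_paired_test(vals, g, n_perm = 10000, seed = 11)
  expect_lt(abs(r$mean_t - oracle$mean_t), 3 * oracle$sd_t / sqrt(10000))
  expect_lt(abs(r$mean_p - oracle$mean_p), 3 * oracle$sd_p / sqrt(10000))
  expect_lt(abs(r$mean_diff - oracle$mean_diff), 3 * oracle$sd_diff / sqrt(10000))
})

test_that("results are invariant to metadata row order", {
  coh <- null_cohort(401)
  rich <- apply(coh$counts$counts, 1, richness)
  g1 <- build_pair_graph(coh$metadata)
  shuf <- withr::with_seed(1, coh$metadata[sample.int(nrow(coh$metadata)), ])
  g2 <- build_pair_graph(cohort_metadata(shuf))
  r1 <- permutation_paired_test(rich, g1, 200, seed = 3)
  r2 <- permutation_paired_test(rich, g2, 200, seed = 3)
  expect_identical(unclass(r1), unclass(r2))
})

test_that("patients without measurable endpoints are dropped with a warning", {
  meta <- make_meta(
    c("p1", "r1", "p2", "r2", "p3", "r3"),
    c("F1", "F1", "F2", "F2", "F3", "F3"),
    c("patient", "relative", "patient", "relative", "patient", "relative"),
    rep("2020-01-01", 6))
  g <- build_pair_graph(meta)
  vals <- c(p1 = 3, r1 = 1, p2 = 5, r2 = NA, p3 = 2, r3 = 4)
  expect_warning(r <- permutation_paired_test(vals, g, 10, seed = 1),
                 "no measured eligible relative")
  expect_equal(r$n_pairs, 2)
  expect_equal(r$df, 1L)
  expect_identical(r$dropped_patients, "p2")
  expect_error(permutation_paired_test(vals, g, 0, seed = 1), "n_perm")
})

test_that("endpoint tables get BH correction over mean p-values", {
  coh <- null_cohort(77)
  g <- build_pair_graph(coh$metadata)
  logc <- log(coh$metabolites$values)
  tab <- paired_test_table(logc[, 1:5], g, n_perm = 50, seed = 2)
  expect_equal(nrow(tab), 5)
  expect_equal(tab$q, fdr_bh(tab$mean_p))
  expect_true(all(tab$df == tab$n_pairs - 1))
  expect_true(all(tab$mean_ci_low <= tab$mean_diff & tab$mean_diff <= tab$mean_ci_high))
})
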