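test_that("PAM recovers well-separated blobs and agrees with cluster::pam", {
  withr::local_seed(5)
  x <- rbind(matrix(stats::rnorm(20, 0), ncol = 2),
             matrix(stats::rnorm(20, 8), ncol = 2))
  rownames(x) <- sprintf("s%02d", 1:20)
  d <- euclidean_dist(x)
  res <- pam_cluster(d, 2)
  truth <- rep(1:2, each = 10)
  expect_true(all(res$labels == truth) || all(res$labels == 3 - truth))
  ref <- cluster::pam(stats::as.dist(d$d), k = 2)
  expect_true(all((res$labels == res$labels[1]) == (ref$clustering == ref$clustering[1])))
  expect_true(all(diff(res$cost_trace) <= 1e-12))  # SWAP cost nonincreasing
})

test_that("PAM SWAP reaches the exhaustive medoid-subset optimum at small n", {
  for (s in 1:8) {
    cfg <- random_euclidean_config(7, p = 2, seed = 100 + s)
    for (k in 2:3) {
      res <- pam_cluster(cfg$d, k)
      expect_equal(res$cost, pam_exhaustive_cost(cfg$d$d, k), tolerance = 1e-12)
    }
    # k = n-1: clusters of <= 2 members; optimum cost is the best single pair
    res_max <- pam_cluster(cfg$d, 6)
    expect_equal(res_max$cost, pam_exhaustive_cost(cfg$d$d, 6), tolerance = 1e-12)
  }
})

test_that("silhouette-based k selection finds planted cluster counts", {
  withr::local_seed(8)
  make_blobs <- function(centers) {
    x <- do.call(rbind, lapply(centers, function(c0) {
      matrix(stats::rnorm(16, c0), ncol = 2)
    }))
    rownames(x) <- sprintf("s%02d", seq_len(nrow(x)))
    euclidean_dist(x)
  }
  k2 <- select_k(make_blobs(c(0, 10)), 2:5)
  expect_identical(as.integer(k2), 2L)
  expect_false(attr(k2, "low_silhouette"))
  k3 <- select_k(make_blobs(c(0, 10, 20)), 2:5)
  expect_identical(as.integer(k3), 3L)
  noise <- euclidean_dist(
    matrix(stats::rnorm(320), 40, dimnames = list(sprintf("n%02d", 1:40), NULL)))
  expect_true(attr(select_k(noise, 2:4), "low_silhouette"))
  expect_error(select_k(noise, integer(0)), "empty")
})

test_that("exact 2x2 test matches the hypergeometric enumeration oracle", {
  sym <- fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p, 1)
  sep <- fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2))
  expect_identical(sep$odds_ratio, Inf)
  expect_identical(sep$ci_high, Inf)
  expect_equal(sep$p, fisher_p_enum(matrix(c(10, 0, 0, 10), 2)), tolerance = 1e-12)
  tab <- matrix(c(8, 1, 2, 9), 2)  # [[8,2],[1,9]] in row-major writing
  expect_equal(fisher_exact_2x2(tab)$p, fisher_p_enum(tab), tolerance = 1e-12)
  # sweep of random tables with n <= 40
  for (s in 1:30) {
    tab <- withr::with_seed(s, matrix(stats::rmultinom(1, sample(8:40, 1), rep(0.25, 4)), 2))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab)$p, fisher_p_enum(tab), tolerance = 1e-12)
  }
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("random-forest feature ranking finds planted discriminative taxa", {
  withr::local_seed(21)
  n_per <- 15
  # compositions identical outside the 7 markers: the marker block keeps its
  # total mass but redistributes it, so features 8-20 are genuinely
  # non-discriminative under closure
  p1 <- rep(1 / 20, 20)
  p2 <- p1
  p2[1:3] <- 2 / 20
  p2[4:7] <- 0.25 / 20
  mk <- function(p) t(stats::rmultinom(n_per, 800, p))
  m <- rbind(mk(p1), mk(p2))
  rownames(m) <- sprintf("s%02d", seq_len(nrow(m)))
  colnames(m) <- sprintf("f%02d", 1:20)
  labels <- stats::setNames(rep(1:2, each = n_per), rownames(m))
  rk <- rank_cluster_features(count_table(m), labels, seed = 4)
  expect_gte(sum(rk$feature[1:7] %in% sprintf("f%02d", 1:7)), 6)
  expect_identical(unique(rk$marks_cluster[rk$feature %in% c("f01", "f02", "f03")]), "2")
  expect_identical(unique(rk$marks_cluster[rk$feature %in% sprintf("f%02d", 4:7)]), "1")
  # a pair of mass-compensated, perfectly separating features ranks on top
  # (compensation keeps library totals equal so no other feature moves)
  m2 <- cbind(matrix(50L, 10, 3), rep(c(200L, 0L), each = 5),
              rep(c(0L, 200L), each = 5))
  dimnames(m2) <- list(sprintf("t%02d", 1:10), sprintf("g%d", 1:5))
  lab2 <- stats::setNames(rep(1:2, each = 5), rownames(m2))
  rk2 <- rank_cluster_features(count_table(m2), lab2, seed = 4)
  expect_setequal(rk2$feature[1:2], c("g4", "g5"))
  expect_gt(rk2$importance[1], 0)
  expect_error(rank_cluster_features(count_table(m), rep(1, nrow(m))), "2 clusters")
})

test_that("shuffled labels leave importances centered at zero", {
  t <- random_count_table(20, 12, seed = 31, lambda = 40)
  pos <- 0L
  n_seed <- 20
  for (s in seq_len(n_seed)) {
    lab <- withr::with_seed(1000 + s, sample(rep(1:2, 10)))
    names(lab) <- ct_samples(t)
    rk <- rank_cluster_features(t, lab, seed = s, n_trees = 200)
    pos <- pos + sum(rk$importance > 0)
  }
  frac_pos <- pos / (n_seed * 12)
  expect_gt(frac_pos, 0.2)  # sign-test band around 1/2
  expect_lt(frac_pos, 0.8)
})

test_that("PERMANOVA matches vegan and the exhaustive enumeration oracle", {
  t <- random_count_table(12, 15, seed = 6)
  d <- bray_curtis(t)
  g <- stats::setNames(rep(c("A", "B"), each = 6), d$ids)
  res <- permanova(d, g, n_perm = 499, seed = 9)
  ref <- vegan::adonis2(stats::as.dist(d$d) ~ grp,
                        data = data.frame(grp = g[d$ids]), permutations = 499)
  expect_equal(res$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_equal(res$R2, ref$R2[1], tolerance = 1e-10)
  expect_equal(res$df_between, ref$Df[1])
  # scaling the distances leaves F, R2 untouched
  d2 <- distance_matrix(d$d * 3.7)
  res2 <- permanova(d2, g, n_perm = 99, seed = 9)
  expect_equal(res2$pseudo_F, res$pseudo_F)
  expect_equal(res2$R2, res$R2)
  # n = 6 exhaustive: equality with an adonis2-based enumeration
  cfg <- random_euclidean_config(6, p = 2, seed = 13)
  g6 <- stats::setNames(rep(c("A", "B"), each = 3), cfg$d$ids)
  ex <- permanova(cfg$d, g6, exhaustive = TRUE)
  combos <- utils::combn(6, 3)
  fs <- apply(combos, 2, function(idx) {
    gg <- ifelse(seq_len(6) %in% idx, "A", "B")
    vegan::adonis2(stats::as.dist(cfg$d$d) ~ gg, permutations = 2)$F[1]
  })
  expect_equal(ex$p, sum(fs >= ex$pseudo_F - 1e-12) / length(fs), tolerance = 1e-12)
  expect_equal(ex$n_perm, 20L)
})

test_that("maximal separation gives R2 near 1 and near-minimal p", {
  m <- rbind(matrix(rep(c(100L, 0L), each = 5), 5),
             matrix(rep(c(0L, 100L), each = 7), 7))
  dimnames(m) <- list(sprintf("s%02d", 1:12), c("f1", "f2"))
  d <- bray_curtis(count_table(m))
  g <- stats::setNames(rep(c("A", "B"), c(5, 7)), d$ids)
  res <- permanova(d, g, n_perm = 199, seed = 1)
  expect_gt(res$R2, 0.999)
  # only label permutations recreating the planted partition tie with the
  # observed F, so p sits at (1 + #recreations) / (1 + n_perm)
  expect_lte(res$p, 3 / 200)
  expect_error(permanova(d, stats::setNames(rep("A", 12), d$ids), 99), "2 groups")
})

test_that("PERMANOVA p-values are uniform under an exchangeable null", {
  cfg <- random_euclidean_config(10, p = 4, seed = 99)
  ps <- vapply(1:120, function(s) {
    g <- withr::with_seed(3000 + s,
                          stats::setNames(sample(rep(c("A", "B"), 5)), cfg$d$ids))
    permanova(cfg$d, g, n_perm = 99, seed = s)$p
  }, 0)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_lt(abs(mean(ps <= 0.5) - 0.5), 0.15)
})
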