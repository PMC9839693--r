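test_that("rare-feature filtering uses the dataset-wide 100-read rule", {
  m <- matrix(c(50L, 49L, 60L, 40L, 90L, 11L), 2,
              dimnames = list(c("s1", "s2"), c("f1", "f2", "f3")))
  t <- count_table(m)
  # f1 totals 99 -> dropped at the default threshold; f2 exactly 100 kept
  filt <- filter_rare_features(t, 100)
  expect_identical(ct_features(filt), c("f2", "f3"))
  expect_identical(filter_rare_features(t, 0)$counts, t$counts)
  expect_warning(filter_rare_features(t, 1000), "all features")
})

test_that("rarefaction keeps at-depth samples, forces determined outcomes, drops shallow samples", {
  m <- matrix(c(6L, 4L, 1000L, 0L, 3L, 2L), 3, byrow = TRUE,
              dimnames = list(c("atDepth", "deep", "shallow"), c("f1", "f2")))
  expect_warning(r <- rarefy(count_table(m), 10, seed = 7), "shallow")
  expect_identical(attr(r, "dropped_samples"), "shallow")
  expect_identical(unname(r$counts["atDepth", ]), c(6L, 4L))  # total == depth
  expect_identical(unname(r$counts["deep", ]), c(10L, 0L))    # forced outcome
  r2 <- suppressWarnings(rarefy(count_table(m), 10, seed = 7))
  expect_identical(r$counts, r2$counts)                       # seeded
})

test_that("rarefaction draws follow the multivariate hypergeometric law", {
  # counts (5,5) at depth 4: first-taxon count is Hypergeometric(5,5,4)
  t <- count_table(matrix(c(5L, 5L), 1, dimnames = list("s", c("f1", "f2"))))
  n_draw <- 20000
  x <- vapply(seq_len(n_draw), function(s) rarefy(t, 4, seed = s)$counts[1, 1], 0L)
  pmf <- stats::dhyper(0:4, 5, 5, 4)
  obs <- tabulate(x + 1L, nbins = 5) / n_draw
  se <- sqrt(pmf * (1 - pmf) / n_draw)
  expect_true(all(abs(obs - pmf) <= 3.5 * se))
})

test_that("rarefaction preserves expected composition", {
  counts <- c(f1 = 700L, f2 = 200L, f3 = 100L)
  t <- count_table(matrix(counts, 1, dimnames = list("s", names(counts))))
  depth <- 50
  draws <- vapply(1:2000, function(s) rarefy(t, depth, seed = s)$counts[1, ],
                  counts)
  p <- counts / sum(counts)
  se <- sqrt(depth * p * (1 - p) / 2000)
  expect_true(all(abs(rowMeans(draws) - depth * p) <= 4 * se))
})

test_that("inverse Simpson matches closed forms and is scale invariant", {
  expect_equal(inverse_simpson(rep(7, 12)), 12)   # S equally abundant taxa -> S
  expect_equal(inverse_simpson(c(0, 5, 0)), 1)    # single taxon -> 1
  expect_equal(inverse_simpson(c(3, 1)), 1 / (0.75^2 + 0.25^2))
  expect_error(inverse_simpson(c(0, 0)), "all-zero")
  for (s in 1:20) {
    v <- withr::with_seed(s, stats::rpois(15, 5) + (s %% 3 == 0))
    if (sum(v) == 0) v[1] <- 1
    iv <- inverse_simpson(v)
    expect_gte(iv, 1 - 1e-12)
    expect_lte(iv, sum(v > 0) + 1e-12)
    expect_equal(inverse_simpson(v * 17), iv)
  }
})

test_that("richness and shared fractions follow the asymmetric definition", {
  a <- c(1, 1, 1, 0)  # present {1,2,3}
  b <- c(0, 2, 5, 9)  # present {2,3,4}
  expect_equal(richness(a), 3)
  expect_equal(shared_fraction(a, b), 100 * 2 / 3)
  expect_equal(shared_fraction(c(1, 1, 0, 0), c(3, 2, 1, 0)), 100)  # subset
  expect_equal(shared_fraction(c(1, 0), c(0, 1)), 0)                # disjoint
  expect_error(shared_fraction(c(0, 0, 0, 0), b), "zero richness")
  expect_error(shared_fraction(c(1, 0), b), "universes differ")
  # asymmetry appears exactly when presence-set sizes differ
  expect_gt(shared_fraction(c(1, 1, 0, 0), c(1, 1, 1, 1)),
            shared_fraction(c(1, 1, 1, 1), c(1, 1, 0, 0)))
})

test_that("Bray-Curtis matches hand arithmetic and its invariants", {
  m <- matrix(c(2L, 0L, 1L, 1L, 1L, 1L), 2, byrow = TRUE,
              dimnames = list(c("x", "y"), c("f1", "f2", "f3")))
  d <- bray_curtis(count_table(m))
  expect_equal(d$d["x", "y"], 2 / 6)
  ident <- count_table(matrix(c(3L, 1L, 3L, 1L), 2, byrow = TRUE,
                              dimnames = list(c("a", "b"), c("f1", "f2"))))
  expect_equal(bray_curtis(ident)$d["a", "b"], 0)
  disj <- count_table(matrix(c(3L, 0L, 0L, 5L), 2, byrow = TRUE,
                             dimnames = list(c("a", "b"), c("f1", "f2"))))
  expect_equal(bray_curtis(disj)$d["a", "b"], 1)
  expect_error(bray_curtis(count_table(matrix(c(0L, 0L, 1L, 2L), 2, byrow = TRUE,
                                              dimnames = list(c("z", "b"), c("f1", "f2"))))),
               "zero-total")
  for (s in 1:5) {
    t <- random_count_table(6, 10, seed = s)
    d <- bray_curtis(t)$d
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
  }
})

test_that("centroid distances agree with the coordinate-space oracle on Euclidean data", {
  cfg <- random_euclidean_config(6, p = 3, seed = 42)
  g <- stats::setNames(rep(c("A", "B"), each = 3), rownames(cfg$coords))
  cd <- centroid_distances(cfg$d, g)
  oracle <- vapply(rownames(cfg$coords), function(i) {
    idx <- names(g)[g == g[i]]
    sqrt(sum((cfg$coords[i, ] - colMeans(cfg$coords[idx, , drop = FALSE]))^2))
  }, 0)
  expect_equal(as.numeric(cd), unname(oracle), tolerance = 1e-9)
})

test_that("centroid distances handle degenerate groups and match betadisper", {
  # all samples identical -> all distances 0
  t <- count_table(matrix(rep(c(3L, 2L), each = 4), 4,
                          dimnames = list(paste0("s", 1:4), c("f1", "f2"))))
  d0 <- bray_curtis(t)
  cd0 <- centroid_distances(d0, stats::setNames(rep("g", 4), d0$ids))
  expect_equal(as.numeric(cd0), rep(0, 4))
  # 2-point group: each distance is half the pairwise distance
  cfg <- random_euclidean_config(4, seed = 3)
  g2 <- stats::setNames(c("A", "A", "B", "B"), rownames(cfg$coords))
  cd2 <- centroid_distances(cfg$d, g2)
  expect_equal(unname(cd2[1]), cfg$d$d[1, 2] / 2)
  # singleton group flagged with distance 0
  g3 <- stats::setNames(c("A", "A", "A", "B"), rownames(cfg$coords))
  cd3 <- centroid_distances(cfg$d, g3)
  expect_equal(unname(cd3[4]), 0)
  expect_identical(attr(cd3, "singleton_groups"), "B")
  # non-Euclidean Bray-Curtis matrix: cross-check against vegan::betadisper
  t2 <- random_count_table(10, 12, seed = 9)
  db <- bray_curtis(t2)
  gb <- stats::setNames(rep(c("A", "B"), 5), db$ids)
  cdb <- centroid_distances(db, gb)
  bd <- vegan::betadisper(stats::as.dist(db$d), gb[db$ids], type = "centroid")
  expect_equal(as.numeric(cdb), unname(bd$distances), tolerance = 1e-8)
})
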