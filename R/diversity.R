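# Alpha/beta diversity primitives computed from first principles: rare-OTU
# filtering, single-draw rarefaction, inverse Simpson, richness, asymmetric
# shared-OTU fractions, Bray-Curtis / Euclidean distance matrices, and
# distance-to-centroid dispersion on an arbitrary distance matrix.

#' Construct a validated distance matrix
#'
#' @param d Square numeric matrix with matching row/column names (sample
#'   ids), zero diagonal, symmetric, nonnegative.
#' @return An object of class `distance_matrix` with elements `ids`, `d`.
#' @export
distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("distance_matrix: not square")
  if (is.null(rownames(d))) stop("distance_matrix: ids required")
  if (!identical(rownames(d), colnames(d))) stop("distance_matrix: id mismatch")
  if (any(abs(diag(d)) > 1e-12)) stop("distance_matrix: nonzero diagonal")
  if (any(d < -1e-12)) stop("distance_matrix: negative distances")
  if (max(abs(d - t(d))) > 1e-9) stop("distance_matrix: not symmetric")
  d <- (d + t(d)) / 2
  diag(d) <- 0
  structure(list(ids = rownames(d), d = d), class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("distance_matrix over %d samples (max %.4g)\n",
              length(x$ids), max(x$d)))
  invisible(x)
}

#' Drop features rare across the whole data set
#'
#' Removes every feature whose dataset-wide read total is below
#' `min_total_reads` (default 100, the conventional rare-OTU cut). Samples
#' are always retained.
#'
#' @param t A `count_table`.
#' @param min_total_reads Nonnegative count; features with total < this are
#'   dropped.
#' @return A filtered `count_table` (possibly with zero features, with a
#'   warning).
#' @export
filter_rare_features <- function(t, min_total_reads = 100) {
  stopifnot(min_total_reads >= 0)
  keep <- colSums(t$counts) >= min_total_reads
  if (!any(keep)) warning("filter_rare_features: all features below threshold")
  out <- t$counts[, keep, drop = FALSE]
  count_table(out, t$taxonomy[intersect(names(t$taxonomy), colnames(out))])
}

# draw `depth` reads without replacement from one sample's counts
# (multivariate hypergeometric)
rarefy_one <- function(counts, depth) {
  pool <- rep.int(seq_along(counts), counts)
  take <- sample(pool, depth, replace = FALSE)
  tabulate(take, nbins = length(counts))
}

#' Rarefy a count table to a common depth
#'
#' Single-draw rarefaction: each sample with at least `depth` reads is
#' subsampled without replacement (multivariate hypergeometric) to exactly
#' `depth` reads; samples below `depth` are dropped and reported via the
#' `"dropped_samples"` attribute. Deterministic given `seed`.
#'
#' @param t A `count_table`.
#' @param depth Target read depth (>= 1).
#' @param seed Integer seed for the draw.
#' @return A rarefied `count_table`; dropped sample ids in
#'   `attr(, "dropped_samples")`.
#' @export
rarefy <- function(t, depth, seed = 1L) {
  if (depth < 1) stop("rarefy: depth must be >= 1")
  totals <- rowSums(t$counts)
  keep <- totals >= depth
  dropped <- rownames(t$counts)[!keep]
  if (length(dropped)) {
    warning(sprintf("rarefy: dropping %d sample(s) below depth %d: %s",
                    length(dropped), depth,
                    paste(utils::head(dropped, 5), collapse = ", ")))
  }
  m <- t$counts[keep, , drop = FALSE]
  withr::local_seed(seed)
  out <- m
  for (i in seq_len(nrow(m))) {
    if (totals[keep][i] == depth) next  # already at depth: unchanged
    out[i, ] <- rarefy_one(m[i, ], depth)
  }
  res <- count_table(out, t$taxonomy)
  attr(res, "dropped_samples") <- dropped
  res
}

#' Inverse Simpson diversity of one sample
#'
#' `1 / sum(p_i^2)` over relative abundances; ranges from 1 (single taxon) to
#' S (S equally abundant taxa) and is invariant to count scaling.
#'
#' @param counts Nonnegative vector with at least one positive entry.
#' @return The inverse Simpson index.
#' @export
inverse_simpson <- function(counts) {
  tot <- sum(counts)
  if (tot <= 0) stop("inverse_simpson: all-zero count vector")
  p <- counts / tot
  1 / sum(p^2)
}

#' Observed richness of one sample
#' @param counts Nonnegative count vector.
#' @return Number of features with count > 0.
#' @export
richness <- function(counts) sum(counts > 0)

#' Asymmetric shared-feature percentage
#'
#' Percentage of the features present in `a` that are also present in `b`:
#' `100 * |present(a) & present(b)| / |present(a)|`. Asymmetric by design —
#' the denominator is the first argument — so a low-richness sample whose
#' features are a subset of its partner's scores 100 toward the partner while
#' the partner scores lower toward it.
#'
#' @param a,b Count vectors over the same feature universe.
#' @return Shared percentage in `[0, 100]`.
#' @export
shared_fraction <- function(a, b) {
  if (length(a) != length(b)) stop("shared_fraction: feature universes differ")
  pa <- a > 0
  if (!any(pa)) stop("shared_fraction: first sample has zero richness")
  100 * sum(pa & (b > 0)) / sum(pa)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum|x_i - y_i| / sum(x_i + y_i)`, in `[0, 1]`.
#'
#' @param t A `count_table` (typically rarefied) with >= 2 samples and no
#'   zero-total sample.
#' @return A `distance_matrix`.
#' @export
bray_curtis <- function(t) {
  m <- t$counts
  if (nrow(m) < 2) stop("bray_curtis: need >= 2 samples")
  tot <- rowSums(m)
  if (any(tot == 0)) {
    stop("bray_curtis: zero-total sample(s): ",
         paste(rownames(m)[tot == 0], collapse = ", "))
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    xi <- m[i, ]
    for (j in (i + 1):n) {
      num <- sum(abs(xi - m[j, ]))
      d[i, j] <- d[j, i] <- num / (tot[i] + tot[j])
    }
  }
  distance_matrix(d)
}

#' Euclidean distance matrix over a real sample-by-variable matrix
#' @param m Numeric matrix, samples as rows (named).
#' @return A `distance_matrix`.
#' @export
euclidean_dist <- function(m) {
  if (is.null(rownames(m))) stop("euclidean_dist: sample row names required")
  distance_matrix(as.matrix(stats::dist(m, method = "euclidean")))
}

#' Distance to group centroid (beta-dispersion)
#'
#' Embeds the distance matrix by principal-coordinates decomposition keeping
#' negative-eigenvalue axes, then computes each sample's distance to its
#' group centroid with the usual multivariate-dispersion correction: squared
#' distance = (real-axis part) - (imaginary-axis part), floored at zero
#' before the square root. For a Euclidean-embeddable matrix this equals the
#' plain centroid distance in the embedding.
#'
#' @param d A `distance_matrix`.
#' @param groups Group labels, either named by sample id or aligned with
#'   `d$ids`.
#' @return Numeric vector of centroid distances named by sample id, with the
#'   group factor in `attr(, "groups")`; singleton groups get distance 0 and
#'   are flagged in `attr(, "singleton_groups")`.
#' @export
centroid_distances <- function(d, groups) {
  g <- align_labels(groups, d$ids)
  n <- length(d$ids)
  d2 <- d$d^2
  # Gower double-centering
  cmat <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * cmat %*% d2 %*% cmat
  eig <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-10
  pos <- eig$values > tol
  neg <- eig$values < -tol
  xr <- eig$vectors[, pos, drop = FALSE] %*% diag(sqrt(eig$values[pos]), sum(pos))
  xi <- eig$vectors[, neg, drop = FALSE] %*% diag(sqrt(-eig$values[neg]), sum(neg))
  out <- numeric(n)
  singletons <- character(0)
  for (lv in levels(g)) {
    idx <- which(g == lv)
    if (length(idx) == 1L) {
      out[idx] <- 0
      singletons <- c(singletons, lv)
      next
    }
    cr <- colMeans(xr[idx, , drop = FALSE])
    ci <- colMeans(xi[idx, , drop = FALSE])
    zr <- rowSums(sweep(xr[idx, , drop = FALSE], 2, cr)^2)
    zi <- rowSums(sweep(xi[idx, , drop = FALSE], 2, ci)^2)
    out[idx] <- sqrt(pmax(zr - zi, 0))
  }
  names(out) <- d$ids
  attr(out, "groups") <- g
  if (length(singletons)) attr(out, "singleton_groups") <- singletons
  out
}

# Resolve a label vector against an id ordering: accept either a named
# vector (subset ok if it covers all ids) or a vector aligned with ids.
align_labels <- function(groups, ids) {
  if (!is.null(names(groups))) {
    miss <- setdiff(ids, names(groups))
    if (length(miss)) stop("unlabeled sample(s): ", paste(miss, collapse = ", "))
    groups <- groups[ids]
  } else if (length(groups) != length(ids)) {
    stop("groups must be named by sample id or aligned with ids")
  }
  factor(as.vector(groups))
}
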