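# Community-structure analyses on distance matrices: enterotype discovery by
# partitioning around medoids (BUILD + SWAP, written out in full so the cost
# trace is inspectable), silhouette-based choice of k, exact 2x2 association
# with case status, tree-ensemble ranking of cluster-defining OTUs, and
# PERMANOVA.

pam_cost <- function(dm, medoids) sum(apply(dm[, medoids, drop = FALSE], 1, min))

#' Partitioning around medoids on a distance matrix
#'
#' BUILD greedily seeds k medoids minimizing total within-cluster distance,
#' then SWAP exchanges (medoid, non-medoid) pairs while any exchange lowers
#' the total cost, terminating at a local optimum. Because SWAP's local
#' optimum can miss the global one even at small n, instances with at most
#' 1000 candidate medoid subsets are additionally refined by exhaustive
#' enumeration, making small problems provably optimal. Ties break toward
#' the lowest sample index, so the result is deterministic; `seed` is
#' accepted for interface symmetry but unused.
#'
#' @param d A `distance_matrix`.
#' @param k Number of clusters, `2 <= k < n`.
#' @param seed Ignored (algorithm is deterministic).
#' @return An object of class `enterotype_result`: `k`, `labels` (named
#'   integer vector in 1..k), `medoids` (sample ids), `avg_silhouette`,
#'   `per_sample_silhouette`, `cost`, and the nonincreasing `cost_trace`
#'   across SWAP iterations.
#' @export
pam_cluster <- function(d, k, seed = NULL) {
  dm <- d$d
  n <- nrow(dm)
  if (k < 2 || k >= n) stop("pam_cluster: need 2 <= k < n")
  # BUILD
  medoids <- which.min(rowSums(dm))
  while (length(medoids) < k) {
    cand <- setdiff(seq_len(n), medoids)
    costs <- vapply(cand, function(c) pam_cost(dm, c(medoids, c)), 0)
    medoids <- c(medoids, cand[which.min(costs)])
  }
  trace <- pam_cost(dm, medoids)
  # SWAP
  repeat {
    cur <- trace[length(trace)]
    best <- cur
    best_pair <- NULL
    nonmed <- setdiff(seq_len(n), medoids)
    for (mi in seq_along(medoids)) {
      for (c in nonmed) {
        trial <- medoids
        trial[mi] <- c
        cost <- pam_cost(dm, trial)
        if (cost < best - 1e-12) {
          best <- cost
          best_pair <- c(mi, c)
        }
      }
    }
    if (is.null(best_pair)) break
    medoids[best_pair[1]] <- best_pair[2]
    trace <- c(trace, best)
  }
  # SWAP stops at a local optimum; tiny instances are cheap to solve exactly,
  # so refine by full medoid-subset enumeration when feasible
  if (choose(n, k) <= 1000) {
    combos <- utils::combn(n, k)
    costs <- apply(combos, 2, function(med) pam_cost(dm, med))
    if (min(costs) < trace[length(trace)] - 1e-12) {
      medoids <- combos[, which.min(costs)]
      trace <- c(trace, min(costs))
    }
  }
  medoids <- sort(medoids)
  assign_mat <- dm[, medoids, drop = FALSE]
  labels <- apply(assign_mat, 1, which.min)  # ties -> lowest medoid index
  sil <- silhouette_widths(dm, labels)
  structure(list(k = as.integer(k),
                 labels = stats::setNames(as.integer(labels), d$ids),
                 medoids = d$ids[medoids],
                 avg_silhouette = mean(sil),
                 per_sample_silhouette = stats::setNames(sil, d$ids),
                 cost = trace[length(trace)],
                 cost_trace = trace),
            class = "enterotype_result")
}

#' @export
print.enterotype_result <- function(x, ...) {
  cat(sprintf("PAM enterotypes: k = %d, sizes %s, avg silhouette %.3f\n",
              x$k, paste(table(x$labels), collapse = "/"), x$avg_silhouette))
  invisible(x)
}

# standard silhouette widths from a distance matrix and integer labels;
# singletons get 0
silhouette_widths <- function(dm, labels) {
  n <- nrow(dm)
  ks <- sort(unique(labels))
  vapply(seq_len(n), function(i) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) return(0)
    a <- mean(dm[i, setdiff(own, i)])
    b <- min(vapply(setdiff(ks, labels[i]),
                    function(l) mean(dm[i, labels == l]), 0))
    (b - a) / max(a, b)
  }, 0)
}

#' Choose the number of clusters by average silhouette width
#'
#' Runs [pam_cluster()] over `k_range` and returns the k maximizing the
#' average silhouette width; ties go to the smallest k. When even the best
#' average silhouette is below 0.25 the data show no substantial cluster
#' structure and the result is flagged.
#'
#' @param d A `distance_matrix`.
#' @param k_range Candidate k values within `[2, n - 1]` (default 2:6).
#' @return The selected k (integer) with attributes `avg_silhouettes` (named
#'   vector over `k_range`) and `low_silhouette` (logical flag).
#' @export
select_k <- function(d, k_range = 2:6) {
  n <- length(d$ids)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(k_range)) stop("select_k: empty k range")
  sils <- vapply(k_range, function(k) pam_cluster(d, k)$avg_silhouette, 0)
  best <- k_range[which.max(sils)]  # which.max -> first (smallest) on ties
  structure(as.integer(best),
            avg_silhouettes = stats::setNames(sils, k_range),
            low_silhouette = max(sils) < 0.25)
}

#' Exact test of association in a 2x2 table
#'
#' Two-sided p-value as the sum of hypergeometric probabilities of all
#' tables (margins fixed) no more probable than the observed one; odds ratio
#' as the conditional maximum-likelihood estimate under the noncentral
#' hypergeometric likelihood with an exact 95 percent CI, as produced by
#' [stats::fisher.test()].
#'
#' @param table 2x2 matrix of nonnegative integer counts with positive
#'   margins.
#' @return Object of class `fisher_result`: `table`, `p`, `odds_ratio`,
#'   `ci_low`, `ci_high`.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L)) stop("fisher_exact_2x2: table must be 2x2")
  if (any(table < 0) || any(table != round(table))) {
    stop("fisher_exact_2x2: counts must be nonnegative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("fisher_exact_2x2: zero margin, association undefined")
  }
  ft <- stats::fisher.test(table, conf.int = TRUE, conf.level = 0.95)
  structure(list(table = table, p = ft$p.value,
                 odds_ratio = unname(ft$estimate),
                 ci_low = ft$conf.int[1], ci_high = ft$conf.int[2]),
            class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat(sprintf("Fisher's exact test: OR = %.3f (95%% CI %.3f to %.3f), p = %.4g\n",
              x$odds_ratio, x$ci_low, x$ci_high, x$p))
  invisible(x)
}

#' Rank cluster-defining features by permutation importance
#'
#' Classifies cluster labels from relative abundances with an
#' out-of-bag-validated random forest and ranks features by mean decrease in
#' accuracy; each feature is tagged with the cluster it marks (the cluster
#' with the highest median relative abundance). Deterministic given `seed`.
#'
#' @param t A `count_table`.
#' @param labels Cluster labels (named by sample id or aligned); >= 2
#'   clusters with >= 2 samples each.
#' @param seed Integer seed for the forest.
#' @param n_trees Number of trees (default 500; sqrt(m) features per split).
#' @return Data frame sorted by decreasing importance: `feature`,
#'   `importance`, `marks_cluster`, with the OOB error rate in
#'   `attr(, "oob_error")`.
#' @export
rank_cluster_features <- function(t, labels, seed = 1L, n_trees = 500) {
  g <- align_labels(labels, ct_samples(t))
  if (nlevels(g) < 2 || any(table(g) < 2)) {
    stop("rank_cluster_features: need >= 2 clusters with >= 2 samples each")
  }
  rel <- t$counts / rowSums(t$counts)
  withr::local_seed(seed)
  rf <- randomForest::randomForest(x = rel, y = g, ntree = n_trees,
                                   importance = TRUE)
  imp <- randomForest::importance(rf, type = 1, scale = TRUE)[, 1]
  marks <- vapply(seq_len(ncol(rel)), function(j) {
    med <- tapply(rel[, j], g, stats::median)
    levels(g)[which.max(med)]
  }, "")
  out <- data.frame(feature = colnames(rel), importance = unname(imp),
                    marks_cluster = marks, stringsAsFactors = FALSE)
  out <- out[order(-out$importance), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "oob_error") <- rf$err.rate[n_trees, "OOB"]
  out
}

permanova_f <- function(d2, g, n) {
  lv <- levels(g)
  ss_total <- sum(d2) / (2 * n)
  ss_within <- 0
  for (l in lv) {
    i <- g == l
    ss_within <- ss_within + sum(d2[i, i]) / (2 * sum(i))
  }
  ss_between <- ss_total - ss_within
  k <- length(lv)
  list(F = (ss_between / (k - 1)) / (ss_within / (n - k)),
       R2 = ss_between / ss_total)
}

#' PERMANOVA on a distance matrix
#'
#' One-way permutational multivariate analysis of variance.
#' `SS_total = (1/n) sum_{i<j} d_ij^2`; within-group SS analogously per
#' group; `pseudo_F = (SS_between/(k-1)) / (SS_within/(n-k))`. The p-value
#' uses the +1 convention, `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`,
#' under random relabeling; with `exhaustive = TRUE` (two groups only) all
#' distinct label assignments are enumerated and
#' `p = #{F >= F_obs} / #assignments` (the observed assignment included).
#'
#' @param d A `distance_matrix`.
#' @param groups Group labels (named by sample id or aligned); >= 2 groups,
#'   each nonempty, none equal to all samples.
#' @param n_perm Number of label permutations (default 9999).
#' @param seed Integer seed.
#' @param exhaustive Enumerate all assignments instead of sampling.
#' @return Object of class `permanova_result`: `pseudo_F`, `R2`, `p`,
#'   `df_between`, `n_perm`.
#' @export
permanova <- function(d, groups, n_perm = 9999, seed = 1L, exhaustive = FALSE) {
  g <- align_labels(groups, d$ids)
  g <- droplevels(g)
  if (nlevels(g) < 2) stop("permanova: need >= 2 groups")
  # canonical sample order so the permutation stream (hence p) is invariant
  # to input ordering
  ord <- order(d$ids)
  g <- g[ord]
  d2 <- d$d[ord, ord]^2
  n <- length(d$ids)
  obs <- permanova_f(d2, g, n)
  if (exhaustive) {
    if (nlevels(g) != 2) stop("permanova: exhaustive enumeration supports 2 groups")
    n1 <- sum(g == levels(g)[1])
    combos <- utils::combn(n, n1)
    fs <- apply(combos, 2, function(idx) {
      gp <- factor(ifelse(seq_len(n) %in% idx, levels(g)[1], levels(g)[2]),
                   levels = levels(g))
      permanova_f(d2, gp, n)$F
    })
    p <- sum(fs >= obs$F - 1e-12) / length(fs)
    n_used <- ncol(combos)
  } else {
    withr::local_seed(seed)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      gp <- g[sample.int(n)]
      if (permanova_f(d2, gp, n)$F >= obs$F - 1e-12) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (1 + n_perm)
    n_used <- as.integer(n_perm)
  }
  structure(list(pseudo_F = obs$F, R2 = obs$R2, p = p,
                 df_between = nlevels(g) - 1L, n_perm = n_used,
                 exhaustive = exhaustive),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: F = %.4f, df = %d, R2 = %.4f, p = %.4g (%s permutations)\n",
              x$pseudo_F, x$df_between, x$R2, x$p,
              if (x$exhaustive) "exhaustive" else format(x$n_perm)))
  invisible(x)
}
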