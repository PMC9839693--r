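# The study design's central statistic: patients may have several eligible
# relative samples (or several samples per relative), so a single paired
# t-test is ill-defined. Instead, each permutation draws one eligible
# relative sample per patient uniformly at random, computes an ordinary
# paired t-test on the patient-minus-relative differences, and the reported
# statistics are the arithmetic means across permutations. Welch tests and
# Benjamini-Hochberg FDR round out the testing machinery used elsewhere.

#' Enumerate eligible patient-relative sample pairs
#'
#' For each patient sample, every relative sample from the same family whose
#' collection date lies within `window_days` (inclusive) is eligible.
#' Patients with no eligible relative are excluded from paired analyses and
#' recorded.
#'
#' @param meta A `cohort_metadata` containing at least one patient sample.
#' @param window_days Maximum |date gap| in days (default 90; a gap of 91
#'   days is excluded).
#' @return An object of class `pair_graph`: list with `patients` (patient
#'   sample ids with >= 1 eligible relative), `eligible` (named list of data
#'   frames `relative_sample`, `gap_days`), and `excluded_patients`.
#' @export
build_pair_graph <- function(meta, window_days = 90) {
  if (!any(meta$role == "patient")) stop("build_pair_graph: no patient samples")
  dates <- collection_dates(meta)
  pats <- meta[meta$role == "patient", , drop = FALSE]
  rels <- meta[meta$role == "relative", , drop = FALSE]
  eligible <- list()
  excluded <- character(0)
  for (i in seq_len(nrow(pats))) {
    pid <- pats$sample_id[i]
    fam <- rels[rels$family_id == pats$family_id[i], , drop = FALSE]
    gaps <- abs(as.integer(dates[fam$sample_id] - dates[pid]))
    ok <- gaps <= window_days
    if (any(ok)) {
      df <- data.frame(relative_sample = fam$sample_id[ok],
                       gap_days = gaps[ok], stringsAsFactors = FALSE)
      eligible[[pid]] <- df[order(df$relative_sample), , drop = FALSE]
    } else {
      excluded <- c(excluded, pid)
    }
  }
  structure(list(patients = sort(names(eligible)),
                 eligible = eligible,
                 window_days = window_days,
                 excluded_patients = sort(excluded)),
            class = "pair_graph")
}

#' @export
print.pair_graph <- function(x, ...) {
  amb <- sum(vapply(x$eligible, nrow, 0L) > 1L)
  cat(sprintf("pair_graph: %d patients (%d with multiple eligible relatives), %d excluded (window %d days)\n",
              length(x$patients), amb, length(x$excluded_patients), x$window_days))
  invisible(x)
}

# Closed-form one-sample t machinery on a matrix of difference draws
# (columns = permutations); returns per-column t, p, ci bounds.
t_stats_by_column <- function(dm) {
  n <- nrow(dm)
  mean_d <- colMeans(dm)
  sd_d <- sqrt(colSums(sweep(dm, 2, mean_d)^2) / (n - 1))
  se <- sd_d / sqrt(n)
  t <- ifelse(se == 0, ifelse(mean_d == 0, 0, sign(mean_d) * Inf), mean_d / se)
  df <- n - 1
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  crit <- stats::qt(0.975, df)
  list(t = t, df = df, p = p, diff = mean_d,
       ci_low = mean_d - crit * se, ci_high = mean_d + crit * se)
}

#' Paired t-test on within-pair differences
#'
#' Thin wrapper over [stats::t.test()] with an explicit convention for the
#' degenerate zero-variance case: identical nonzero differences give
#' `t = +-Inf`, `p = 0` and set the `zero_variance` flag.
#'
#' @param d Numeric vector of within-pair differences (patient - relative),
#'   length >= 2, finite.
#' @return List with `t`, `df`, `p`, `diff`, `ci_low`, `ci_high`,
#'   `zero_variance`.
#' @export
paired_t <- function(d) {
  if (length(d) < 2) stop("paired_t: need >= 2 differences")
  if (any(!is.finite(d))) stop("paired_t: non-finite differences")
  if (stats::sd(d) == 0) {
    m <- mean(d)
    return(list(t = if (m == 0) 0 else sign(m) * Inf,
                df = length(d) - 1L,
                p = if (m == 0) 1 else 0,
                diff = m, ci_low = m, ci_high = m, zero_variance = TRUE))
  }
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, diff = unname(tt$estimate),
       ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
       zero_variance = FALSE)
}

#' Welch two-sample t-test
#'
#' Welch statistic with Welch-Satterthwaite degrees of freedom, two-sided p,
#' and a 95 percent CI on the mean difference `mean(a) - mean(b)`. Both
#' groups constant and equal gives `t = 0`, `p = 1` with the flag set.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List with `t`, `df`, `p`, `diff`, `ci_low`, `ci_high`,
#'   `zero_variance`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("welch_t: both groups need n >= 2")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    m <- mean(a) - mean(b)
    return(list(t = if (m == 0) 0 else sign(m) * Inf,
                df = length(a) + length(b) - 2L,
                p = if (m == 0) 1 else 0,
                diff = m, ci_low = m, ci_high = m, zero_variance = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, diff = unname(diff(rev(tt$estimate))),
       ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
       zero_variance = FALSE)
}

#' Benjamini-Hochberg q-values
#' @param p Vector of p-values in `[0, 1]`.
#' @return Step-up q-values (monotone nondecreasing in p-rank), via
#'   [stats::p.adjust()].
#' @export
fdr_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("fdr_bh: p outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Random-pairing permutation paired t-test
#'
#' Each of `n_perm` permutations independently draws, uniformly at random,
#' one eligible relative sample per patient, forms the patient - relative
#' differences, and computes a paired t-test. Reported statistics are the
#' across-permutation arithmetic means of t, p, the mean difference and the
#' 95 percent CI bounds; `df = n_pairs - 1` is fixed. Patients whose
#' endpoint, or all of whose eligible relatives' endpoints, are missing are
#' dropped with a warning before permuting. Draws run over patients in
#' sorted-id order with sorted relative lists, so results are invariant to
#' input ordering. When every patient has exactly one eligible relative the
#' output equals the single closed-form paired t-test for any `n_perm`.
#'
#' @param values Numeric endpoint named by sample id.
#' @param graph A [build_pair_graph()] result.
#' @param n_perm Number of random pairings (default 1000).
#' @param seed Integer seed.
#' @param endpoint Optional endpoint name carried into the result.
#' @return An object of class `paired_test_result` with fields `endpoint`,
#'   `n_pairs`, `df`, `mean_t`, `mean_p`, `mean_diff`, `mean_ci_low`,
#'   `mean_ci_high`, `n_permutations`, `seed`, plus `sd_t` (across-permutation
#'   spread) and `relative_reuse` (whether any relative sample serves two
#'   patients).
#' @export
permutation_paired_test <- function(values, graph, n_perm = 1000, seed = 1L,
                                    endpoint = "endpoint") {
  if (n_perm < 1) stop("permutation_paired_test: n_perm must be >= 1")
  if (is.null(names(values))) stop("permutation_paired_test: values must be named by sample id")
  pats <- graph$patients
  keep <- character(0)
  rel_values <- list()
  for (pid in pats) {
    if (!pid %in% names(values) || !is.finite(values[pid])) {
      warning("patient sample without endpoint dropped: ", pid)
      next
    }
    rel <- graph$eligible[[pid]]$relative_sample
    v <- values[rel]
    ok <- !is.na(v) & is.finite(v)
    if (!any(ok)) {
      warning("patient with no measured eligible relative dropped: ", pid)
      next
    }
    keep <- c(keep, pid)
    rel_values[[pid]] <- v[ok]
  }
  n_pairs <- length(keep)
  if (n_pairs < 2) stop("permutation_paired_test: fewer than 2 usable pairs")
  all_rel <- unlist(lapply(rel_values, names), use.names = FALSE)
  reuse <- anyDuplicated(all_rel) > 0
  withr::local_seed(seed)
  # draw matrix: n_perm rows, one chosen relative value per patient column;
  # single stream over patients in sorted order => order invariance
  dm <- matrix(0, nrow = n_pairs, ncol = n_perm)
  for (j in seq_len(n_pairs)) {
    rv <- rel_values[[keep[j]]]
    picks <- if (length(rv) == 1L) rep(1L, n_perm) else
      sample.int(length(rv), n_perm, replace = TRUE)
    dm[j, ] <- values[keep[j]] - rv[picks]
  }
  st <- t_stats_by_column(dm)
  structure(list(endpoint = endpoint,
                 n_pairs = n_pairs,
                 df = n_pairs - 1L,
                 mean_t = mean(st$t),
                 mean_p = mean(st$p),
                 mean_diff = mean(st$diff),
                 mean_ci_low = mean(st$ci_low),
                 mean_ci_high = mean(st$ci_high),
                 sd_t = stats::sd(st$t),
                 n_permutations = as.integer(n_perm),
                 seed = seed,
                 relative_reuse = reuse,
                 dropped_patients = setdiff(pats, keep)),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf(
    "permutational paired t-test [%s]: mean t = %.4f, df = %d, mean p = %.4g\n  mean diff = %.4f (mean 95%% CI %.4f to %.4f), %d pairs, %d permutations\n",
    x$endpoint, x$mean_t, x$df, x$mean_p, x$mean_diff,
    x$mean_ci_low, x$mean_ci_high, x$n_pairs, x$n_permutations))
  invisible(x)
}

#' Run the random-pairing test over many endpoints with FDR
#'
#' Applies [permutation_paired_test()] to each column of an endpoint matrix
#' (one table family, e.g. all metabolites of one biofluid) and appends
#' Benjamini-Hochberg q-values over the mean p-values.
#'
#' @param endpoints Numeric matrix, rows = samples (named), columns =
#'   endpoints.
#' @param graph A `pair_graph`.
#' @param n_perm,seed Passed to [permutation_paired_test()]; each endpoint
#'   uses an offset of `seed` so endpoints are independent but reproducible.
#' @return Data frame with one row per endpoint: the aggregated statistics
#'   plus `q`.
#' @export
paired_test_table <- function(endpoints, graph, n_perm = 1000, seed = 1L) {
  res <- lapply(seq_len(ncol(endpoints)), function(j) {
    r <- permutation_paired_test(stats::setNames(endpoints[, j], rownames(endpoints)),
                                 graph, n_perm = n_perm, seed = seed + j - 1L,
                                 endpoint = colnames(endpoints)[j])
    data.frame(endpoint = r$endpoint, n_pairs = r$n_pairs, df = r$df,
               mean_t = r$mean_t, mean_p = r$mean_p, mean_diff = r$mean_diff,
               mean_ci_low = r$mean_ci_low, mean_ci_high = r$mean_ci_high,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- fdr_bh(out$mean_p)
  out
}
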