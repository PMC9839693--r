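# Mouse-arm computations: the eight-factor ordinal pathology score, gut
# transit time on the 10-minute check grid, and the divergence-over-time
# trajectory (per-timepoint PERMANOVA plus a Welch test on beta-dispersion)
# stratified by housing condition.

#' Total pathology score from eight ordinal factor bins
#'
#' Sums the eight factor bins (hind limb clasping, grooming, cataracts,
#' kyphosis, motor function, tremors, jumping, body condition). Bin widths
#' are configuration: the default gives four factors a 0-2 range and four a
#' 0-1 range, so totals span 0 (no disease) to 12 (severe disease).
#'
#' @param bins Named numeric vector (or one-row data frame) of the eight
#'   factor scores.
#' @param bin_max Named vector of per-factor maxima (default
#'   `PATHOLOGY_FACTORS`: clasping/grooming/kyphosis/motor 0-2, the rest
#'   0-1).
#' @return Integer total score.
#' @export
pathology_score <- function(bins, bin_max = PATHOLOGY_FACTORS) {
  if (is.data.frame(bins)) bins <- unlist(bins[1, names(bin_max)])
  miss <- setdiff(names(bin_max), names(bins))
  if (length(miss)) stop("pathology_score: missing factor(s): ",
                         paste(miss, collapse = ", "))
  b <- bins[names(bin_max)]
  if (any(b != round(b)) || any(b < 0) || any(b > bin_max)) {
    bad <- names(bin_max)[b != round(b) | b < 0 | b > bin_max][1]
    stop("pathology_score: bin out of range: ", bad)
  }
  as.integer(sum(b))
}

#' Gut transit time at 10-minute resolution
#'
#' Transit is the time between gavage and first observation of red stool,
#' reported at the check-interval resolution (a detection strictly within
#' the first interval reports as one full interval). Censored observations
#' (no detection by session end) are flagged `NA`, never imputed.
#'
#' @param gavage_time,first_red_stool_time Times in minutes (numeric);
#'   `first_red_stool_time = NA` marks a censored assay.
#' @param check_interval Observation grid in minutes (default 10).
#' @return List with `minutes` (NA when censored) and `censored` flag.
#' @export
transit_time <- function(gavage_time, first_red_stool_time, check_interval = 10) {
  if (is.na(first_red_stool_time)) {
    return(list(minutes = NA_real_, censored = TRUE))
  }
  if (first_red_stool_time < gavage_time) {
    stop("transit_time: red stool before gavage")
  }
  delta <- first_red_stool_time - gavage_time
  ticks <- ceiling(delta / check_interval)
  list(minutes = max(ticks, 1) * check_interval, censored = FALSE)
}

#' Transit times for a whole assay table
#' @param transit Data frame with `gavage_time`, `first_red_stool_time`,
#'   optional `check_interval` and `censored` columns (censored rows keep
#'   `NA`).
#' @return The input with `transit_minutes` appended.
#' @export
transit_table <- function(transit) {
  ci <- if ("check_interval" %in% names(transit)) transit$check_interval else 10
  detect <- transit$first_red_stool_time
  if ("censored" %in% names(transit)) detect[transit$censored] <- NA
  transit$transit_minutes <- vapply(seq_len(nrow(transit)), function(i) {
    transit_time(transit$gavage_time[i], detect[i],
                 if (length(ci) > 1) ci[i] else ci)$minutes
  }, 0)
  transit
}

#' Microbiome divergence trajectory by housing condition
#'
#' For each housing stratum and timepoint with both genotypes present:
#' Bray-Curtis distances, PERMANOVA of FD vs control, and a Welch test on
#' the distance-to-centroid dispersions. Benjamini-Hochberg correction is
#' applied across timepoints within each stratum and test family. Strata
#' missing a genotype at a timepoint are skipped with a warning.
#'
#' @param tables Named list of `count_table`, one per timepoint (names
#'   `dpw_<d>` or any; timepoint read from the metadata `dpw` column).
#' @param meta A `cohort_metadata` with `dpw` and `housing` covariates over
#'   all samples in `tables`.
#' @param n_perm Permutations per PERMANOVA (default 999).
#' @param seed Integer seed.
#' @return Data frame, one row per stratum x timepoint: `housing`, `dpw`,
#'   `n_fd`, `n_control`, `pseudo_F`, `R2`, `p`, `q`, `disp_t`, `disp_df`,
#'   `disp_diff`, `disp_p`, `disp_q`.
#' @export
divergence_trajectory <- function(tables, meta, n_perm = 999, seed = 1L) {
  rows <- list()
  strata <- sort(unique(meta$housing))
  for (tab_i in seq_along(tables)) {
    t <- tables[[tab_i]]
    sm <- meta[match(ct_samples(t), meta$sample_id), , drop = FALSE]
    dpw <- unique(sm$dpw)
    if (length(dpw) != 1) stop("divergence_trajectory: table spans multiple dpw")
    for (h in strata) {
      idx <- sm$housing == h
      roles <- sm$role[idx]
      if (length(unique(roles)) < 2) {
        warning(sprintf("divergence_trajectory: stratum '%s' at dpw %s lacks a genotype; skipped",
                        h, dpw))
        next
      }
      sub <- count_table(t$counts[idx, , drop = FALSE])
      d <- bray_curtis(sub)
      g <- stats::setNames(roles, sm$sample_id[idx])
      pv <- permanova(d, g, n_perm = n_perm, seed = seed + tab_i)
      cd <- centroid_distances(d, g)
      wt <- welch_t(cd[roles == "fd_mouse"], cd[roles == "control_mouse"])
      rows[[length(rows) + 1L]] <- data.frame(
        housing = h, dpw = as.integer(dpw),
        n_fd = sum(roles == "fd_mouse"), n_control = sum(roles == "control_mouse"),
        pseudo_F = pv$pseudo_F, R2 = pv$R2, p = pv$p,
        disp_t = wt$t, disp_df = wt$df, disp_diff = wt$diff, disp_p = wt$p,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("divergence_trajectory: no testable stratum/timepoint")
  out <- do.call(rbind, rows)
  out <- out[order(out$housing, out$dpw), , drop = FALSE]
  out$q <- stats::ave(out$p, out$housing, FUN = fdr_bh)
  out$disp_q <- stats::ave(out$disp_p, out$housing, FUN = fdr_bh)
  rownames(out) <- NULL
  out
}
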