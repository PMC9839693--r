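# End-to-end human-cohort pipeline: one call takes a directory of tables (or
# in-memory objects), runs filtering -> rarefaction -> alpha/beta diversity
# -> random-pairing paired tests -> enterotyping + association -> metabolite
# testing + PLS-DA, and writes a results bundle (TSVs, a JSON summary, and a
# line-oriented JSON log of every decision value).

#' Default run configuration
#'
#' @param rarefy_depth Target depth, or `"min"` to use the smallest library
#'   (the convention that drops no samples).
#' @param min_otu_total Dataset-wide rare-OTU threshold (default 100).
#' @param window_days Pairing date window (default 90).
#' @param n_perm_paired,n_perm_permanova,n_perm_plsda Permutation counts
#'   (defaults 1000 / 9999 / 1000).
#' @param k_range Candidate enterotype counts (default 2:6).
#' @param contrasts_on `"rarefied"` (default) or `"filtered"`: which table
#'   richness/shared-OTU contrasts use.
#' @param seed Master seed; every stochastic step derives its own fixed
#'   offset from it.
#' @return A `run_config` list.
#' @export
run_config <- function(rarefy_depth = "min", min_otu_total = 100,
                       window_days = 90, n_perm_paired = 1000,
                       n_perm_permanova = 9999, n_perm_plsda = 1000,
                       k_range = 2:6, contrasts_on = c("rarefied", "filtered"),
                       seed = 1L) {
  contrasts_on <- match.arg(contrasts_on)
  structure(list(rarefy_depth = rarefy_depth, min_otu_total = min_otu_total,
                 window_days = window_days, n_perm_paired = n_perm_paired,
                 n_perm_permanova = n_perm_permanova,
                 n_perm_plsda = n_perm_plsda, k_range = k_range,
                 contrasts_on = contrasts_on, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys mirror the [run_config()] arguments;
#'   absent keys keep their defaults.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) stop("read_run_config: unknown key(s): ",
                            paste(unknown, collapse = ", "))
  do.call(run_config, y)
}

log_line <- function(con, step, ...) {
  rec <- c(list(step = step), list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = 10), con)
}

#' Run the full human-cohort analysis and write a results bundle
#'
#' Pipeline order: rare-OTU filtering, rarefaction, alpha diversity (inverse
#' Simpson) and richness, random-pairing permutation paired tests for
#' richness / shared-OTU fraction / alpha diversity, Bray-Curtis PERMANOVA
#' of patients vs relatives with centroid-distance dispersion, PAM
#' enterotyping with silhouette-selected k plus the enterotype-by-status
#' exact test and a Welch test of alpha diversity between clusters, and
#' per-metabolite (log concentration) paired tests with FDR plus a PLS-DA
#' validation report on the preprocessed matrix.
#'
#' @param counts A `count_table`.
#' @param metabolites A `concentration_table` (or `NULL` to skip the
#'   metabolome block).
#' @param meta A `cohort_metadata`.
#' @param config A [run_config()].
#' @param out_dir Output directory for the bundle (`NULL` = write nothing).
#' @param metabolome_mode Preprocessing mode for the PLS-DA block.
#' @return The results bundle (named list), invisibly when writing.
#' @export
run_report <- function(counts, metabolites, meta, config = run_config(),
                       out_dir = NULL, metabolome_mode = "human_stool") {
  log_con <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    log_con <- file(file.path(out_dir, "run_log.jsonl"), open = "wb")
    on.exit(close(log_con))
  }
  note <- function(step, ...) if (!is.null(log_con)) log_line(log_con, step, ...)
  note("config", config = unclass(config))

  filt <- filter_rare_features(counts, config$min_otu_total)
  depth <- if (identical(config$rarefy_depth, "min")) {
    min(rowSums(filt$counts))
  } else config$rarefy_depth
  rare <- rarefy(filt, depth, seed = config$seed)
  note("rarefy", depth = depth, n_features = ncol(rare$counts),
       dropped = attr(rare, "dropped_samples"))

  contrast_tab <- if (config$contrasts_on == "rarefied") rare else filt
  alpha <- apply(rare$counts, 1, inverse_simpson)
  rich <- apply(contrast_tab$counts, 1, richness)

  graph <- build_pair_graph(meta, config$window_days)
  note("pair_graph", n_patients = length(graph$patients),
       excluded = graph$excluded_patients)

  paired_rows <- list()
  for (ep in c("richness", "alpha_diversity")) {
    vals <- if (ep == "richness") rich else alpha
    r <- permutation_paired_test(vals, graph, n_perm = config$n_perm_paired,
                                 seed = config$seed, endpoint = ep)
    paired_rows[[ep]] <- r
  }
  shared <- shared_fraction_test(contrast_tab, graph,
                                 n_perm = config$n_perm_paired,
                                 seed = config$seed)
  paired_rows[["shared_otus"]] <- shared

  d_bc <- bray_curtis(rare)
  status <- stats::setNames(meta$role, meta$sample_id)[d_bc$ids]
  pv <- permanova(d_bc, status, n_perm = config$n_perm_permanova,
                  seed = config$seed)
  disp <- centroid_distances(d_bc, status)
  disp_t <- welch_t(disp[status == "patient"], disp[status == "relative"])
  note("permanova", F = pv$pseudo_F, R2 = pv$R2, p = pv$p)

  k <- select_k(d_bc, config$k_range)
  ent <- pam_cluster(d_bc, as.integer(k))
  # field convention: "cluster 1" is the case-associated enterotype, so
  # orient the 2x2 table on the cluster with the highest patient share
  pat_share <- tapply(status == "patient", ent$labels[d_bc$ids], mean)
  assoc <- as.integer(names(pat_share)[which.max(pat_share)])
  tab2 <- table(factor(status, c("patient", "relative")),
                factor(ent$labels[d_bc$ids] == assoc, c(TRUE, FALSE),
                       labels = c("cluster1", "other")))
  fisher <- fisher_exact_2x2(as.matrix(tab2))
  cl_alpha <- welch_t(alpha[ent$labels[d_bc$ids] == assoc],
                      alpha[ent$labels[d_bc$ids] != assoc])
  note("enterotypes", k = as.integer(k), avg_silhouette = ent$avg_silhouette,
       fisher_or = fisher$odds_ratio, fisher_p = fisher$p)

  metab_tests <- NULL
  plsda <- NULL
  if (!is.null(metabolites)) {
    logconc <- log(pmax(metabolites$values, min(metabolites$values[metabolites$values > 0]) / 2))
    metab_tests <- paired_test_table(logconc, graph,
                                     n_perm = config$n_perm_paired,
                                     seed = config$seed)
    Xp <- preprocess_concentrations(metabolites, metabolome_mode)
    y <- factor(stats::setNames(meta$role, meta$sample_id)[rownames(Xp)])
    plsda <- plsda_validate(Xp, y, n_perm = config$n_perm_plsda,
                            seed = config$seed)
    note("metabolome", n_tested = nrow(metab_tests),
         n_significant = sum(metab_tests$q < 0.05),
         plsda_q2 = plsda$Q2, plsda_auroc = plsda$AUROC)
  }

  bundle <- list(
    depth = depth,
    alpha = alpha, richness = rich,
    pair_graph = graph,
    paired_tests = paired_rows,
    permanova = pv,
    dispersion_welch = disp_t,
    enterotypes = ent, selected_k = as.integer(k),
    fisher = fisher,
    cluster_alpha_welch = cl_alpha,
    metabolite_tests = metab_tests,
    plsda = plsda)

  if (!is.null(out_dir)) {
    write_bundle(bundle, out_dir)
    invisible(bundle)
  } else bundle
}

#' Random-pairing permutation test of the shared-OTU asymmetry
#'
#' The shared-OTU endpoint is pair-specific (its value depends on which
#' relative is drawn), so it gets its own permutation loop mirroring
#' [permutation_paired_test()]: each permutation's paired difference is the
#' patient's shared percentage toward the drawn relative minus that
#' relative's shared percentage toward the patient. A positive mean
#' difference means patients' OTU sets sit inside their relatives' more than
#' the reverse.
#'
#' @param t A `count_table` (typically rarefied).
#' @param graph A [build_pair_graph()] result.
#' @param n_perm Number of random pairings (default 1000).
#' @param seed Integer seed.
#' @return A `paired_test_result` for the endpoint `"shared_otus"`.
#' @export
shared_fraction_test <- function(t, graph, n_perm = 1000, seed = 1L) {
  m <- t$counts
  pats <- graph$patients[graph$patients %in% rownames(m)]
  keep <- pats[vapply(pats, function(p) {
    any(graph$eligible[[p]]$relative_sample %in% rownames(m))
  }, TRUE)]
  if (length(keep) < 2) stop("shared_fraction_test: fewer than 2 usable pairs")
  withr::local_seed(seed)
  dm <- matrix(0, nrow = length(keep), ncol = n_perm)
  for (j in seq_along(keep)) {
    rel <- graph$eligible[[keep[j]]]$relative_sample
    rel <- rel[rel %in% rownames(m)]
    picks <- if (length(rel) == 1L) rep(1L, n_perm) else
      sample.int(length(rel), n_perm, replace = TRUE)
    # per-pair difference: share of patient's OTUs found in the relative
    # minus share of the relative's OTUs found in the patient
    sf <- vapply(rel, function(r) {
      shared_fraction(m[keep[j], ], m[r, ]) - shared_fraction(m[r, ], m[keep[j], ])
    }, 0)
    dm[j, ] <- sf[picks]
  }
  st <- t_stats_by_column(dm)
  structure(list(endpoint = "shared_otus", n_pairs = length(keep),
                 df = length(keep) - 1L,
                 mean_t = mean(st$t), mean_p = mean(st$p),
                 mean_diff = mean(st$diff),
                 mean_ci_low = mean(st$ci_low), mean_ci_high = mean(st$ci_high),
                 sd_t = stats::sd(st$t),
                 n_permutations = as.integer(n_perm), seed = seed,
                 relative_reuse = FALSE, dropped_patients = setdiff(pats, keep)),
            class = "paired_test_result")
}

paired_row_df <- function(r) {
  data.frame(endpoint = r$endpoint, n_pairs = r$n_pairs, df = r$df,
             mean_t = r$mean_t, mean_p = r$mean_p, mean_diff = r$mean_diff,
             mean_ci_low = r$mean_ci_low, mean_ci_high = r$mean_ci_high,
             stringsAsFactors = FALSE)
}

write_bundle <- function(bundle, out_dir) {
  pt <- do.call(rbind, lapply(bundle$paired_tests, paired_row_df))
  utils::write.table(pt, file.path(out_dir, "paired_tests.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ent <- data.frame(sample_id = names(bundle$enterotypes$labels),
                    cluster = bundle$enterotypes$labels,
                    silhouette = bundle$enterotypes$per_sample_silhouette,
                    stringsAsFactors = FALSE)
  utils::write.table(ent, file.path(out_dir, "enterotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  av <- data.frame(sample_id = names(bundle$alpha),
                   inverse_simpson = bundle$alpha,
                   richness = bundle$richness[names(bundle$alpha)],
                   stringsAsFactors = FALSE)
  utils::write.table(av, file.path(out_dir, "alpha_diversity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$metabolite_tests)) {
    utils::write.table(bundle$metabolite_tests,
                       file.path(out_dir, "metabolite_tests.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  summary <- list(
    rarefy_depth = bundle$depth,
    n_pairs = bundle$paired_tests$richness$n_pairs,
    paired_tests = lapply(bundle$paired_tests, function(r) {
      r[c("endpoint", "n_pairs", "df", "mean_t", "mean_p", "mean_diff",
          "mean_ci_low", "mean_ci_high")]
    }),
    permanova = unclass(bundle$permanova),
    dispersion_welch = bundle$dispersion_welch,
    selected_k = bundle$selected_k,
    avg_silhouette = bundle$enterotypes$avg_silhouette,
    fisher = list(odds_ratio = bundle$fisher$odds_ratio, p = bundle$fisher$p,
                  ci_low = bundle$fisher$ci_low, ci_high = bundle$fisher$ci_high),
    cluster_alpha_welch = bundle$cluster_alpha_welch,
    plsda = if (!is.null(bundle$plsda)) {
      bundle$plsda[c("n_components", "R2", "Q2", "accuracy", "CER", "AUROC",
                     "permutation_p_separation", "permutation_p_accuracy")]
    })
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(out_dir)
}
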