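# Independent oracles and small fixture builders shared across the suite.
# Oracles deliberately take a different computational path from the package
# (t.test per assignment, dhyper enumeration, brute-force subset search,
# vegan) so agreement is evidence, not tautology.

# Exhaustive enumeration of all pairing assignments for a pair graph:
# the exact distribution the random-pairing permutation test samples from.
enumerate_pairing <- function(values, graph) {
  choices <- lapply(graph$patients, function(p) graph$eligible[[p]]$relative_sample)
  grid <- expand.grid(lapply(choices, seq_along))
  stats <- apply(as.matrix(grid), 1, function(row) {
    d <- vapply(seq_along(graph$patients), function(j) {
      unname(values[graph$patients[j]] - values[choices[[j]][row[j]]])
    }, 0)
    tt <- stats::t.test(d)
    c(t = unname(tt$statistic), p = tt$p.value, diff = mean(d))
  })
  list(mean_t = mean(stats["t", ]), mean_p = mean(stats["p", ]),
       mean_diff = mean(stats["diff", ]),
       sd_t = stats::sd(stats["t", ]), sd_p = stats::sd(stats["p", ]),
       sd_diff = stats::sd(stats["diff", ]),
       n_assignments = ncol(stats))
}

# Two-sided Fisher p by direct hypergeometric enumeration (probabilities no
# more probable than the observed table, with the usual relative-error
# guard).
fisher_p_enum <- function(tab) {
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Brute-force optimal k-medoid cost over all medoid subsets (n <= ~10).
pam_exhaustive_cost <- function(dm, k) {
  combos <- utils::combn(nrow(dm), k)
  min(apply(combos, 2, function(med) {
    sum(apply(dm[, med, drop = FALSE], 1, min))
  }))
}

# A metadata registry with explicit families/roles/dates, for pair-graph
# fixtures.
make_meta <- function(sample_id, family_id, role, collection_date) {
  cohort_metadata(data.frame(sample_id = sample_id, subject_id = sample_id,
                             family_id = family_id, role = role,
                             collection_date = collection_date,
                             stringsAsFactors = FALSE))
}

# Random Euclidean configuration -> distance_matrix, plus the coordinates.
random_euclidean_config <- function(n, p = 3, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(stats::rnorm(n * p), n, p)
    rownames(x) <- sprintf("s%02d", seq_len(n))
    list(coords = x, d = euclidean_dist(x))
  })
}

# Random small count table (all samples nonzero).
random_count_table <- function(n_samples, n_features, seed = 1, lambda = 20) {
  withr::with_seed(seed, {
    m <- matrix(stats::rpois(n_samples * n_features, lambda), n_samples,
                dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                                sprintf("f%02d", seq_len(n_features))))
    m[rowSums(m) == 0, 1] <- 1L
    count_table(m)
  })
}

# The null-cohort conditions used for type-I calibration: one relative per
# family, no planted community or metabolite effect, symmetric enterotype
# odds (full exchangeability of patient/relative labels).
null_cohort <- function(seed, n_families = 15, n_taxa = 100) {
  sp <- cohort_spec(n_families = n_families, n_taxa = n_taxa,
                    patient_taxon_dropout = 0, enterotype_assignment_odds = 1,
                    relatives_per_family_weights = c(0, 1, 0, 0),
                    depth_mean = 3000, depth_dispersion = 10, seed = seed)
  ms <- metabolite_spec(effect_metabolites = c(choline = 1), seed = seed + 1L)
  generate_human_cohort(sp, ms)
}
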