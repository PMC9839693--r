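# Synthetic paired human cohort generator. Families contain one patient and
# 0-3 cohabitating relatives; each subject's gut community is a
# Dirichlet-multinomial draw from one of two enterotype base compositions,
# with patients hosting only a random subset of the taxa (structural zeros
# applied to the composition before sampling) so patient richness and alpha
# diversity sit below their relatives'. Metabolite concentrations are
# log-normal with a family random effect and configurable patient
# fold-changes (by default a 2-fold choline elevation).

#' Default pair of enterotype base compositions
#'
#' Two power-law communities over the same taxon universe whose dominance
#' order differs by a half-cycle rotation mixed back toward the first
#' composition, giving two well-separated but overlapping community types.
#'
#' @param n_taxa Number of taxa.
#' @param shift_mix Weight in `[0, 1]` on the rotated abundance ranking for
#'   the second enterotype (default 0.75; 0 makes the enterotypes identical).
#' @return List of two probability vectors summing to 1.
#' @export
default_enterotype_compositions <- function(n_taxa, shift_mix = 0.75) {
  v <- 1 / seq_len(n_taxa)
  p1 <- v / sum(v)
  rot <- v[((seq_len(n_taxa) - 1 + n_taxa %/% 2) %% n_taxa) + 1]
  p2 <- (1 - shift_mix) * p1 + shift_mix * rot / sum(rot)
  list(enterotype1 = p1, enterotype2 = p2 / sum(p2))
}

#' Specification of a synthetic paired human cohort
#'
#' Defaults describe a realistic paired study: 30 families whose relative
#' counts follow the enrollment mix of a rare-disease cohort (most families
#' contribute one relative), 200 taxa, two enterotypes with assignment odds
#' of 3 (so the planted patient-vs-relative enterotype odds ratio is 9), 25
#' percent per-taxon patient dropout, overdispersed negative-binomial
#' library sizes, and relative collection dates jittered up to 100 days so
#' the >90-day pair-exclusion rule is exercised.
#'
#' @param n_families Number of families (each with exactly one patient).
#' @param relatives_per_family_weights Probability weights over 0-3 enrolled
#'   relatives per family.
#' @param n_taxa Number of taxa.
#' @param enterotype_base_compositions List of two probability vectors over
#'   taxa; `NULL` uses [default_enterotype_compositions()].
#' @param enterotype_assignment_odds Positive odds that a patient's latent
#'   enterotype is 1 (relatives use the inverse odds).
#' @param patient_taxon_dropout Per-taxon probability in `[0, 1]` that a
#'   patient lacks a taxon of the family composition.
#' @param depth_mean,depth_dispersion Negative-binomial library-size model
#'   (mean and size).
#' @param dm_concentration Dirichlet-multinomial concentration of the
#'   within-enterotype community draw.
#' @param date_jitter_days Half-width (days) of the uniform jitter applied
#'   to relative collection dates around the family anchor date.
#' @param seed Integer seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_families = 30,
                        relatives_per_family_weights = c(7, 27, 13, 1) / 48,
                        n_taxa = 200,
                        enterotype_base_compositions = NULL,
                        enterotype_assignment_odds = 3,
                        patient_taxon_dropout = 0.25,
                        depth_mean = 15000,
                        depth_dispersion = 10,
                        dm_concentration = 60,
                        date_jitter_days = 100,
                        seed = 1L) {
  if (n_families < 1) stop("cohort_spec: zero families")
  if (is.null(enterotype_base_compositions)) {
    enterotype_base_compositions <- default_enterotype_compositions(n_taxa)
  }
  w <- relatives_per_family_weights
  if (length(w) != 4 || any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    stop("cohort_spec: weights must be 4 nonnegative values summing to 1")
  }
  for (p in enterotype_base_compositions) {
    if (length(p) != n_taxa || any(p < 0) || abs(sum(p) - 1) > 1e-12) {
      stop("cohort_spec: base compositions must sum to 1 over n_taxa")
    }
  }
  if (patient_taxon_dropout < 0 || patient_taxon_dropout > 1) {
    stop("cohort_spec: dropout must be in [0, 1]")
  }
  if (enterotype_assignment_odds <= 0) stop("cohort_spec: odds must be positive")
  if (depth_mean <= 0 || depth_dispersion <= 0 || dm_concentration <= 0) {
    stop("cohort_spec: depth and concentration parameters must be positive")
  }
  if (date_jitter_days < 0) stop("cohort_spec: date_jitter_days must be >= 0")
  structure(list(n_families = as.integer(n_families),
                 relatives_per_family_weights = w,
                 n_taxa = as.integer(n_taxa),
                 enterotype_base_compositions = enterotype_base_compositions,
                 enterotype_assignment_odds = enterotype_assignment_odds,
                 patient_taxon_dropout = patient_taxon_dropout,
                 depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 dm_concentration = dm_concentration,
                 date_jitter_days = as.integer(date_jitter_days),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Specification of the synthetic metabolite panel
#'
#' Log-normal baselines with a shared family random effect; patient effects
#' are multiplicative fold-changes on named metabolites. The default panel
#' carries 20 stool metabolites including choline (2-fold patient
#' elevation), with per-metabolite log-sd 0.5 and family effect sd 0.3.
#'
#' @param n_metabolites Panel size.
#' @param metabolite_names Names; defaults to choline, xanthine, urea,
#'   methanol then generic ids.
#' @param baseline_log_means,baseline_log_sds Per-metabolite log-scale
#'   baselines.
#' @param effect_metabolites Named positive fold-changes applied to patients
#'   (e.g. `c(choline = 2)`).
#' @param family_random_effect_sd Nonnegative sd of the family-level
#'   log-scale random effect.
#' @param units Concentration unit string.
#' @param seed Integer seed.
#' @return Object of class `metabolite_spec`.
#' @export
metabolite_spec <- function(n_metabolites = 20,
                            metabolite_names = NULL,
                            baseline_log_means = NULL,
                            baseline_log_sds = NULL,
                            effect_metabolites = c(choline = 2.0),
                            family_random_effect_sd = 0.3,
                            units = "nanomoles/gram",
                            seed = 1L) {
  if (is.null(metabolite_names)) {
    base <- c("choline", "xanthine", "urea", "methanol")
    extra <- sprintf("met_%02d", seq_len(max(0, n_metabolites - length(base))))
    metabolite_names <- c(base, extra)[seq_len(n_metabolites)]
  }
  if (length(metabolite_names) != n_metabolites) {
    stop("metabolite_spec: need one name per metabolite")
  }
  if (is.null(baseline_log_means)) {
    baseline_log_means <- seq(2, 6, length.out = n_metabolites)
  }
  if (is.null(baseline_log_sds)) baseline_log_sds <- rep(0.5, n_metabolites)
  if (any(baseline_log_sds < 0)) stop("metabolite_spec: sds must be >= 0")
  if (any(effect_metabolites <= 0)) stop("metabolite_spec: fold-changes must be positive")
  if (length(bad <- setdiff(names(effect_metabolites), metabolite_names))) {
    stop("metabolite_spec: effect metabolite(s) not in panel: ",
         paste(bad, collapse = ", "))
  }
  if (family_random_effect_sd < 0) stop("metabolite_spec: family sd must be >= 0")
  structure(list(n_metabolites = as.integer(n_metabolites),
                 metabolite_names = metabolite_names,
                 baseline_log_means = baseline_log_means,
                 baseline_log_sds = baseline_log_sds,
                 effect_metabolites = effect_metabolites,
                 family_random_effect_sd = family_random_effect_sd,
                 units = units,
                 seed = as.integer(seed)),
            class = "metabolite_spec")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1  # degenerate guard
  g / sum(g)
}

draw_depth <- function(mean, size) {
  max(1L, stats::rnbinom(1, size = size, mu = mean))
}

#' Generate a synthetic paired human cohort
#'
#' One patient per family; 0-3 relatives per the spec weights. Each family
#' draws independent latent enterotypes for the patient (probability
#' `odds/(1+odds)` of enterotype 1) and for its relatives (the inverse
#' odds). Relatives' communities are Dirichlet-multinomial draws from their
#' enterotype composition; the patient's community uses the same machinery
#' after zeroing a dropout-selected taxon subset and renormalizing, so
#' expected patient richness is `(1 - dropout)` times relative richness.
#' Metabolites are log-normal with patient fold-changes. The patient's
#' collection date anchors the family; relative dates are jittered uniformly
#' within `+-date_jitter_days`. Fully deterministic given the spec seeds.
#'
#' @param spec A [cohort_spec()].
#' @param mspec A [metabolite_spec()].
#' @return List with `counts` (a `count_table`), `metabolites` (a
#'   `concentration_table`) and `metadata` (a `cohort_metadata` whose
#'   `enterotype` column records each subject's latent enterotype).
#' @export
generate_human_cohort <- function(spec, mspec = metabolite_spec()) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(mspec, "metabolite_spec"))
  comps <- spec$enterotype_base_compositions
  p_pat1 <- spec$enterotype_assignment_odds / (1 + spec$enterotype_assignment_odds)
  withr::local_seed(spec$seed)
  rows <- list()
  count_rows <- list()
  anchor0 <- as.Date("2019-06-01")
  for (f in seq_len(spec$n_families)) {
    fam_id <- sprintf("F%02d", f)
    n_rel <- sample(0:3, 1, prob = spec$relatives_per_family_weights)
    e_pat <- if (stats::runif(1) < p_pat1) 1L else 2L
    e_rel <- if (stats::runif(1) < 1 - p_pat1) 1L else 2L
    anchor <- anchor0 + sample.int(361, 1) - 181L
    # patient: structural zeros on the composition, then renormalize
    base <- comps[[e_pat]]
    comp_p <- NULL
    for (try in 1:10) {
      drop_mask <- stats::runif(spec$n_taxa) < spec$patient_taxon_dropout
      kept <- base * !drop_mask
      if (sum(kept) > 0) {
        comp_p <- kept / sum(kept)
        break
      }
    }
    if (is.null(comp_p)) stop("generate_human_cohort: dropout left no taxa after retries")
    sid <- paste0(fam_id, ".P")
    alpha <- comp_p * spec$dm_concentration
    p <- rdirichlet1(alpha)
    depth <- draw_depth(spec$depth_mean, spec$depth_dispersion)
    count_rows[[sid]] <- as.integer(stats::rmultinom(1, depth, p))
    rows[[sid]] <- data.frame(
      sample_id = sid, subject_id = sid, family_id = fam_id, role = "patient",
      collection_date = format(anchor, "%Y-%m-%d"),
      enterotype = as.character(e_pat), stringsAsFactors = FALSE)
    for (r in seq_len(n_rel)) {
      rid <- sprintf("%s.R%d", fam_id, r)
      jitter <- if (spec$date_jitter_days > 0) {
        sample.int(2L * spec$date_jitter_days + 1L, 1) - spec$date_jitter_days - 1L
      } else 0L
      p_r <- rdirichlet1(comps[[e_rel]] * spec$dm_concentration)
      depth_r <- draw_depth(spec$depth_mean, spec$depth_dispersion)
      count_rows[[rid]] <- as.integer(stats::rmultinom(1, depth_r, p_r))
      rows[[rid]] <- data.frame(
        sample_id = rid, subject_id = rid, family_id = fam_id, role = "relative",
        collection_date = format(anchor + jitter, "%Y-%m-%d"),
        enterotype = as.character(e_rel), stringsAsFactors = FALSE)
    }
  }
  meta_df <- do.call(rbind, rows)
  counts <- do.call(rbind, count_rows)
  rownames(counts) <- names(count_rows)
  colnames(counts) <- sprintf("Otu%03d", seq_len(spec$n_taxa))
  metab <- generate_metabolites(meta_df, mspec)
  list(counts = count_table(counts),
       metabolites = metab,
       metadata = cohort_metadata(meta_df))
}

# log-normal concentrations with family random effect + patient fold-changes
generate_metabolites <- function(meta_df, mspec) {
  withr::local_seed(mspec$seed)
  fams <- unique(meta_df$family_id)
  u <- stats::setNames(stats::rnorm(length(fams), 0, mspec$family_random_effect_sd),
                       fams)
  fold <- rep(0, mspec$n_metabolites)
  names(fold) <- mspec$metabolite_names
  fold[names(mspec$effect_metabolites)] <- log(mspec$effect_metabolites)
  m <- t(vapply(seq_len(nrow(meta_df)), function(i) {
    is_pat <- meta_df$role[i] == "patient"
    lg <- mspec$baseline_log_means + u[meta_df$family_id[i]] +
      (if (is_pat) fold else 0) +
      stats::rnorm(mspec$n_metabolites, 0, mspec$baseline_log_sds)
    exp(lg)
  }, numeric(mspec$n_metabolites)))
  rownames(m) <- meta_df$sample_id
  colnames(m) <- mspec$metabolite_names
  concentration_table(m, stats::setNames(rep(mspec$units, mspec$n_metabolites),
                                         mspec$metabolite_names))
}
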