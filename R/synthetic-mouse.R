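# Synthetic longitudinal mouse colony. FD-mouse communities drift away from
# the shared control baseline at a per-day rate attenuated by cohousing;
# pathology scores follow an ordinal eight-factor model centered on a
# housing-specific progression; gut transit is slower for separately housed
# FD mice. All draws hang off one explicit seed.

#' Specification of a synthetic mouse colony
#'
#' Cages are given as a data frame with columns `cage_id`, `n_fd`,
#' `n_control`; a cage holding both genotypes is cohoused, otherwise its
#' mice are separately housed. The default colony mirrors a two-arm design:
#' a separate arm (10 FD mice in 3 cages, 6 controls in 2 cages) and a
#' cohoused arm (9 FD + 12 controls mixed over 3 cages).
#'
#' @param cages Data frame `cage_id`, `n_fd`, `n_control` (every mouse lives
#'   in exactly one cage).
#' @param timepoints_dpw Strictly increasing integer days post-weaning at
#'   which stool is sampled (default `c(0, 15, 25, 40, 54)`).
#' @param divergence_rate Per-day drift of the FD community away from the
#'   control baseline (mixing weight accrues as
#'   `min(1, rate * (1 - attenuation) * dpw)`).
#' @param cohousing_attenuation Attenuation factor in `[0, 1]` applied to
#'   the drift of cohoused FD mice (1 = full rescue).
#' @param pathology_progression Named list (`separate`, `cohoused`) of named
#'   numeric vectors mapping DPW to the mean FD pathology score.
#' @param transit_mean_minutes Named vector of mean gut transit times for
#'   `fd_separate`, `fd_cohoused`, `control_separate`, `control_cohoused`.
#' @param n_taxa,dm_concentration,depth_mean,depth_dispersion Community and
#'   library-size model, as in [cohort_spec()].
#' @param seed Integer seed.
#' @return Object of class `mouse_colony_spec`.
#' @export
mouse_colony_spec <- function(cages = NULL,
                              timepoints_dpw = c(0L, 15L, 25L, 40L, 54L),
                              divergence_rate = 0.012,
                              cohousing_attenuation = 0.85,
                              pathology_progression = list(
                                separate = c(`80` = 3.5, `180` = 5.5, `280` = 7.5),
                                cohoused = c(`80` = 1.7, `180` = 3.4, `280` = 5.3)),
                              transit_mean_minutes = c(fd_separate = 240,
                                                       fd_cohoused = 150,
                                                       control_separate = 120,
                                                       control_cohoused = 120),
                              n_taxa = 150,
                              dm_concentration = 60,
                              depth_mean = 8000,
                              depth_dispersion = 10,
                              seed = 1L) {
  if (is.null(cages)) {
    cages <- data.frame(
      cage_id = sprintf("C%02d", 1:8),
      n_fd = c(4, 3, 3, 0, 0, 3, 3, 3),
      n_control = c(0, 0, 0, 3, 3, 4, 4, 4),
      stringsAsFactors = FALSE)
  }
  if (!nrow(cages)) stop("mouse_colony_spec: empty cage list")
  if (anyDuplicated(cages$cage_id)) stop("mouse_colony_spec: duplicate cage ids")
  if (any(cages$n_fd + cages$n_control < 1)) stop("mouse_colony_spec: empty cage")
  if (any(diff(timepoints_dpw) <= 0)) {
    stop("mouse_colony_spec: timepoints must be strictly increasing")
  }
  if (divergence_rate < 0) stop("mouse_colony_spec: divergence_rate must be >= 0")
  if (cohousing_attenuation < 0 || cohousing_attenuation > 1) {
    stop("mouse_colony_spec: attenuation must be in [0, 1]")
  }
  structure(list(cages = cages,
                 timepoints_dpw = as.integer(timepoints_dpw),
                 divergence_rate = divergence_rate,
                 cohousing_attenuation = cohousing_attenuation,
                 pathology_progression = pathology_progression,
                 transit_mean_minutes = transit_mean_minutes,
                 n_taxa = as.integer(n_taxa),
                 dm_concentration = dm_concentration,
                 depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 seed = as.integer(seed)),
            class = "mouse_colony_spec")
}

# eight ordinal pathology factors; four scored 0-2 and four 0-1 (total <= 12)
PATHOLOGY_FACTORS <- c(hind_limb_clasping = 2L, grooming = 2L, kyphosis = 2L,
                       motor_function = 2L, cataracts = 1L, tremors = 1L,
                       jumping = 1L, body_condition = 1L)

#' Generate a synthetic longitudinal mouse colony
#'
#' Control communities are Dirichlet-multinomial draws from a fixed
#' baseline; FD communities at `dpw` days post-weaning are drawn from the
#' mixture `(1 - w) * baseline + w * shifted` with
#' `w = min(1, divergence_rate * (1 - attenuation_if_cohoused) * dpw)`.
#' Pathology observations are ordinal eight-factor draws centered on the
#' housing-specific progression (controls sit near zero); transit times are
#' log-normal around the housing/genotype group means, observed on a
#' 10-minute check grid. Deterministic given the spec seed.
#'
#' @param spec A [mouse_colony_spec()].
#' @return List with `counts` (named list of `count_table`, one per
#'   timepoint), `metadata` (a `cohort_metadata` over all stool samples, with
#'   `cage_id`, `dpw`, `housing` covariates), `pathology` (data frame of
#'   per-factor bins), and `transit` (data frame of gavage/detection times in
#'   minutes, `censored` flag).
#' @export
generate_mouse_colony <- function(spec) {
  stopifnot(inherits(spec, "mouse_colony_spec"))
  withr::local_seed(spec$seed)
  v <- 1 / seq_len(spec$n_taxa)
  base <- v / sum(v)
  rot <- v[((seq_len(spec$n_taxa) - 1 + spec$n_taxa %/% 2) %% spec$n_taxa) + 1]
  shifted <- rot / sum(rot)
  # mouse roster
  mice <- list()
  for (i in seq_len(nrow(spec$cages))) {
    cg <- spec$cages[i, ]
    housing <- if (cg$n_fd > 0 && cg$n_control > 0) "cohoused" else "separate"
    for (j in seq_len(cg$n_fd)) {
      mid <- sprintf("%s.FD%d", cg$cage_id, j)
      mice[[mid]] <- data.frame(mouse_id = mid, role = "fd_mouse",
                                cage_id = cg$cage_id, housing = housing,
                                stringsAsFactors = FALSE)
    }
    for (j in seq_len(cg$n_control)) {
      mid <- sprintf("%s.CT%d", cg$cage_id, j)
      mice[[mid]] <- data.frame(mouse_id = mid, role = "control_mouse",
                                cage_id = cg$cage_id, housing = housing,
                                stringsAsFactors = FALSE)
    }
  }
  roster <- do.call(rbind, mice)
  wean_date <- as.Date("2021-03-01")
  meta_rows <- list()
  counts <- list()
  for (tp in spec$timepoints_dpw) {
    mat <- matrix(0L, nrow(roster), spec$n_taxa,
                  dimnames = list(sprintf("%s.T%03d", roster$mouse_id, tp),
                                  sprintf("Otu%03d", seq_len(spec$n_taxa))))
    for (i in seq_len(nrow(roster))) {
      att <- if (roster$housing[i] == "cohoused") spec$cohousing_attenuation else 0
      w <- if (roster$role[i] == "fd_mouse") {
        min(1, spec$divergence_rate * (1 - att) * tp)
      } else 0
      comp <- (1 - w) * base + w * shifted
      p <- rdirichlet1(comp * spec$dm_concentration)
      depth <- draw_depth(spec$depth_mean, spec$depth_dispersion)
      mat[i, ] <- as.integer(stats::rmultinom(1, depth, p))
      meta_rows[[rownames(mat)[i]]] <- data.frame(
        sample_id = rownames(mat)[i],
        subject_id = roster$mouse_id[i],
        family_id = roster$cage_id[i],
        role = roster$role[i],
        collection_date = format(wean_date + tp, "%Y-%m-%d"),
        cage_id = roster$cage_id[i],
        dpw = as.character(tp),
        housing = roster$housing[i],
        stringsAsFactors = FALSE)
    }
    counts[[sprintf("dpw_%03d", tp)]] <- count_table(mat)
  }
  # pathology: FD mice tracked against the progression; controls near zero
  path_rows <- list()
  for (housing in names(spec$pathology_progression)) {
    prog <- spec$pathology_progression[[housing]]
    idx <- which(roster$housing == housing)
    for (dpw_chr in names(prog)) {
      for (i in idx) {
        target <- if (roster$role[i] == "fd_mouse") prog[[dpw_chr]] else 0.4
        pr <- min(1, target / sum(PATHOLOGY_FACTORS))
        bins <- stats::rbinom(length(PATHOLOGY_FACTORS), PATHOLOGY_FACTORS, pr)
        row <- as.data.frame(as.list(bins))
        names(row) <- names(PATHOLOGY_FACTORS)
        path_rows[[length(path_rows) + 1L]] <- cbind(
          data.frame(mouse_id = roster$mouse_id[i], role = roster$role[i],
                     housing = housing, dpw = as.integer(dpw_chr),
                     stringsAsFactors = FALSE), row)
      }
    }
  }
  pathology <- do.call(rbind, path_rows)
  # transit: one assay per mouse on a 10-minute check grid
  grp <- ifelse(roster$role == "fd_mouse", "fd", "control")
  key <- paste(grp, roster$housing, sep = "_")
  mu <- spec$transit_mean_minutes[key]
  raw <- stats::rlnorm(nrow(roster), log(mu) - 0.25^2 / 2, 0.25)
  transit <- data.frame(mouse_id = roster$mouse_id, role = roster$role,
                        housing = roster$housing,
                        gavage_time = 0,
                        first_red_stool_time = raw,
                        check_interval = 10,
                        censored = FALSE,
                        stringsAsFactors = FALSE)
  list(counts = counts,
       metadata = cohort_metadata(do.call(rbind, meta_rows)),
       pathology = pathology,
       transit = transit)
}
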