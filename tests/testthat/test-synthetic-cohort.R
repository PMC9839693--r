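test_that("cohort generation is deterministic and structurally valid", {
  sp <- cohort_spec(n_families = 8, seed = 42)
  ms <- metabolite_spec(seed = 43)
  a <- generate_human_cohort(sp, ms)
  b <- generate_human_cohort(sp, ms)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$metabolites$values, b$metabolites$values)
  expect_identical(as.data.frame(a$metadata), as.data.frame(b$metadata))
  # one patient per family; roles and enterotype column present
  tab <- table(a$metadata$family_id, a$metadata$role)
  expect_true(all(tab[, "patient"] == 1))
  expect_true(all(a$metadata$enterotype %in% c("1", "2")))
  expect_error(cohort_spec(n_families = 0), "zero families")
  expect_error(cohort_spec(patient_taxon_dropout = 1.2), "dropout")
  expect_error(cohort_spec(relatives_per_family_weights = c(1, 1, 0, 0)), "summing to 1")
})

test_that("no dropout and symmetric odds leave patient and relative richness equal", {
  coh <- generate_human_cohort(
    cohort_spec(n_families = 60, patient_taxon_dropout = 0,
                enterotype_assignment_odds = 1,
                relatives_per_family_weights = c(0, 1, 0, 0),
                depth_mean = 5000, seed = 7),
    metabolite_spec(seed = 8))
  rich <- apply(coh$counts$counts, 1, richness)
  pat <- coh$metadata$sample_id[coh$metadata$role == "patient"]
  rel <- coh$metadata$sample_id[coh$metadata$role == "relative"]
  d <- rich[pat] - rich[sub("P$", "R1", pat)]
  expect_lt(abs(mean(d)), 3 * stats::sd(d) / sqrt(length(d)))
  expect_true(length(rel) == length(pat))
})

test_that("dropout thins expected patient richness by the planted factor", {
  # at saturating depth, support size ratio -> 1 - dropout (Bernoulli thinning)
  coh <- generate_human_cohort(
    cohort_spec(n_families = 30, n_taxa = 100, patient_taxon_dropout = 0.3,
                depth_mean = 1e5, depth_dispersion = 50,
                dm_concentration = 1e4, seed = 21),
    metabolite_spec(seed = 22))
  rich <- apply(coh$counts$counts, 1, richness)
  pat <- coh$metadata$sample_id[coh$metadata$role == "patient"]
  ratio <- mean(rich[pat]) / 100
  expect_lt(abs(ratio - 0.7), 0.035)  # ~3.5 binomial sigma at n = 30
})

test_that("patients share more of their OTUs with relatives than the reverse", {
  coh <- generate_human_cohort(cohort_spec(seed = 3),
                               metabolite_spec(seed = 4))
  m <- coh$counts$counts
  meta <- coh$metadata
  pat <- meta$sample_id[meta$role == "patient"]
  fwd <- bwd <- c()
  for (p in pat) {
    fam <- meta$family_id[meta$sample_id == p]
    rels <- meta$sample_id[meta$family_id == fam & meta$role == "relative"]
    for (r in rels) {
      fwd <- c(fwd, shared_fraction(m[p, ], m[r, ]))
      bwd <- c(bwd, shared_fraction(m[r, ], m[p, ]))
    }
  }
  expect_gt(mean(fwd), mean(bwd))
})

test_that("mouse colony generation is deterministic with a valid roster", {
  sp <- mouse_colony_spec(timepoints_dpw = c(0L, 20L), seed = 17)
  a <- generate_mouse_colony(sp)
  b <- generate_mouse_colony(sp)
  expect_identical(a$counts[[2]]$counts, b$counts[[2]]$counts)
  expect_identical(a$pathology, b$pathology)
  expect_identical(a$transit, b$transit)
  # every mouse in exactly one cage; cohoused cages carry both genotypes
  roster <- unique(a$metadata[, c("subject_id", "cage_id", "housing")])
  expect_false(anyDuplicated(roster$subject_id) > 0)
  coh_cages <- unique(a$metadata$cage_id[a$metadata$housing == "cohoused"])
  for (cg in coh_cages) {
    roles <- unique(a$metadata$role[a$metadata$cage_id == cg])
    expect_setequal(roles, c("fd_mouse", "control_mouse"))
  }
  expect_error(mouse_colony_spec(timepoints_dpw = c(10, 10)), "increasing")
  expect_error(mouse_colony_spec(cages = data.frame(cage_id = character(0),
                                                    n_fd = integer(0),
                                                    n_control = integer(0))),
               "empty cage")
})

test_that("zero divergence makes genotypes exchangeable; attenuation = 1 rescues", {
  # null: mean pseudo-F near 1 at the final timepoint
  fs_null <- vapply(1:20, function(s) {
    col <- generate_mouse_colony(mouse_colony_spec(
      cages = data.frame(cage_id = c("c1", "c2"), n_fd = c(4, 0), n_control = c(0, 4)),
      timepoints_dpw = c(0L, 40L), divergence_rate = 0, n_taxa = 60,
      depth_mean = 2000, seed = 600 + s))
    t <- col$counts[["dpw_040"]]
    d <- bray_curtis(t)
    g <- stats::setNames(col$metadata$role[match(d$ids, col$metadata$sample_id)], d$ids)
    permanova(d, g, n_perm = 99, seed = s)$pseudo_F
  }, 0)
  expect_gt(mean(fs_null), 0.6)
  expect_lt(mean(fs_null), 1.5)
  # full rescue: cohoused FD trajectories match the control distribution
  col <- generate_mouse_colony(mouse_colony_spec(
    cages = data.frame(cage_id = c("c1", "c2"), n_fd = c(5, 5), n_control = c(5, 5)),
    timepoints_dpw = c(0L, 40L), divergence_rate = 0.05,
    cohousing_attenuation = 1, n_taxa = 60, depth_mean = 2000, seed = 9))
  d <- bray_curtis(col$counts[["dpw_040"]])
  g <- stats::setNames(col$metadata$role[match(d$ids, col$metadata$sample_id)], d$ids)
  expect_gt(permanova(d, g, n_perm = 199, seed = 2)$p, 0.05)
})

test_that("divergence grows with days post-weaning when planted", {
  mean_f <- vapply(c("dpw_000", "dpw_020", "dpw_040"), function(tp) {
    mean(vapply(1:25, function(s) {
      col <- generate_mouse_colony(mouse_colony_spec(
        cages = data.frame(cage_id = c("c1", "c2"), n_fd = c(5, 0), n_control = c(0, 5)),
        timepoints_dpw = c(0L, 20L, 40L), divergence_rate = 0.02, n_taxa = 60,
        depth_mean = 2000, seed = 800 + s))
      d <- bray_curtis(col$counts[[tp]])
      g <- stats::setNames(col$metadata$role[match(d$ids, col$metadata$sample_id)], d$ids)
      permanova(d, g, n_perm = 39, seed = s)$pseudo_F
    }, 0))
  }, 0)
  expect_lt(mean_f["dpw_000"], mean_f["dpw_020"])
  expect_lt(mean_f["dpw_020"], mean_f["dpw_040"])
})
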