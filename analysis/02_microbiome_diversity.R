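#!/usr/bin/env Rscript

# Human microbiome diversity: rare-OTU filtering (dataset-wide < 100 reads),
# rarefaction to the smallest library, inverse-Simpson alpha diversity,
# Bray-Curtis beta diversity, PERMANOVA of patients vs relatives, and the
# beta-dispersion (distance-to-centroid) contrast.

library(paircohort)

seed <- 1L
counts <- read_count_table("results/data/human_otu_counts.tsv")
meta <- read_metadata("results/data/human_metadata.tsv")

filt <- filter_rare_features(counts, 100)
depth <- min(rowSums(filt$counts))
rare <- rarefy(filt, depth, seed = seed)
cat(sprintf("filtered %d -> %d OTUs; rarefied to %d reads/sample\n",
            ncol(counts$counts), ncol(filt$counts), depth))

alpha <- apply(rare$counts, 1, inverse_simpson)
rich <- apply(rare$counts, 1, richness)
status <- setNames(meta$role, meta$sample_id)
cat(sprintf("inverse Simpson, patients %.2f vs relatives %.2f (mean)\n",
            mean(alpha[status[names(alpha)] == "patient"]),
            mean(alpha[status[names(alpha)] == "relative"])))

d <- bray_curtis(rare)
pv <- permanova(d, status[d$ids], n_perm = 9999, seed = seed)
print(pv)

disp <- centroid_distances(d, status[d$ids])
dw <- welch_t(disp[status[d$ids] == "patient"],
              disp[status[d$ids] == "relative"])
cat(sprintf("beta-dispersion Welch: t = %.3f, df = %.2f, p = %.4g (patients %s dispersed)\n",
            dw$t, dw$df, dw$p, if (dw$diff > 0) "more" else "less"))

dir.create("results", showWarnings = FALSE)
utils::write.table(
  data.frame(sample_id = names(alpha), role = status[names(alpha)],
             inverse_simpson = alpha, richness = rich[names(alpha)],
             centroid_distance = disp[names(alpha)]),
  "results/human_alpha_diversity.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
utils::write.table(as.data.frame(d$d), "results/human_bray_curtis.tsv",
                   sep = "\t", quote = FALSE)
utils::write.table(
  data.frame(test = c("permanova_patient_vs_relative", "dispersion_welch"),
             statistic = c(pv$pseudo_F, dw$t), df = c(pv$df_between, dw$df),
             R2 = c(pv$R2, NA), p = c(pv$p, dw$p)),
  "results/human_beta_diversity_tests.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
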