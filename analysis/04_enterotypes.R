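#!/usr/bin/env Rscript

# Enterotype discovery on the rarefied OTU table: PAM over the Bray-Curtis
# matrix with silhouette-selected k, association of the case-associated
# cluster with patient status (exact odds ratio), the cluster
# alpha-diversity contrast, and a random-forest ranking of the OTUs that
# define the partition.

library(paircohort)

seed <- 1L
counts <- read_count_table("results/data/human_otu_counts.tsv")
meta <- read_metadata("results/data/human_metadata.tsv")

filt <- filter_rare_features(counts, 100)
rare <- rarefy(filt, min(rowSums(filt$counts)), seed = seed)
d <- bray_curtis(rare)

k <- select_k(d, 2:6)
cat("average silhouette by k:",
    paste(sprintf("k=%s %.3f", names(attr(k, "avg_silhouettes")),
                  attr(k, "avg_silhouettes")), collapse = ", "), "\n")
ent <- pam_cluster(d, as.integer(k))
print(ent)

status <- setNames(meta$role, meta$sample_id)[d$ids]
pat_share <- tapply(status == "patient", ent$labels, mean)
assoc <- as.integer(names(pat_share)[which.max(pat_share)])
tab <- table(factor(status, c("patient", "relative")),
             factor(ent$labels == assoc, c(TRUE, FALSE),
                    labels = c("cluster1", "other")))
print(tab)
fr <- fisher_exact_2x2(as.matrix(tab))
print(fr)

alpha <- apply(rare$counts, 1, inverse_simpson)
ct <- welch_t(alpha[ent$labels == assoc], alpha[ent$labels != assoc])
cat(sprintf("cluster 1 vs cluster 2 inverse Simpson: t = %.3f, df = %.2f, p = %.4g, diff = %.3f\n",
            ct$t, ct$df, ct$p, ct$diff))

imp <- rank_cluster_features(rare, ent$labels, seed = seed)
cat("top cluster-defining OTUs:\n")
print(utils::head(imp, 7), row.names = FALSE)

dir.create("results", showWarnings = FALSE)
utils::write.table(
  data.frame(sample_id = names(ent$labels), cluster = ent$labels,
             silhouette = ent$per_sample_silhouette),
  "results/human_enterotypes.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(imp, "results/human_enterotype_otu_importance.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
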