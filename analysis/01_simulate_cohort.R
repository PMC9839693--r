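#!/usr/bin/env Rscript

# Generate the synthetic study data every later step consumes: a paired
# human cohort (30 families, two enterotypes, patient taxon dropout, 2-fold
# choline elevation) and a two-arm longitudinal mouse colony. Tables are
# written as TSV under results/data/ in the same dialects the readers
# accept, so the whole workflow can also be pointed at real tables.

library(paircohort)

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cohort <- generate_human_cohort(cohort_spec(seed = seed),
                                metabolite_spec(seed = seed + 1L))
write_count_table(cohort$counts, file.path(out, "human_otu_counts.tsv"))
write_count_table(cohort$counts, file.path(out, "human_otu_counts.shared"),
                  dialect = "mothur_shared")
write_metadata(cohort$metadata, file.path(out, "human_metadata.tsv"))
write_concentration_table(cohort$metabolites,
                          file.path(out, "human_stool_metabolites.tsv"))

n_pat <- sum(cohort$metadata$role == "patient")
cat(sprintf("human cohort: %d samples (%d patients, %d relatives), %d OTUs, %d metabolites\n",
            nrow(cohort$counts$counts), n_pat,
            sum(cohort$metadata$role == "relative"),
            ncol(cohort$counts$counts), ncol(cohort$metabolites$values)))

colony <- generate_mouse_colony(mouse_colony_spec(
  timepoints_dpw = c(0L, 25L, 54L), seed = seed + 7L))
for (tp in names(colony$counts)) {
  write_count_table(colony$counts[[tp]],
                    file.path(out, sprintf("mouse_otu_counts_%s.tsv", tp)))
}
write_metadata(colony$metadata, file.path(out, "mouse_metadata.tsv"))
utils::write.table(colony$pathology, file.path(out, "mouse_pathology.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(colony$transit, file.path(out, "mouse_transit.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("mouse colony: %d mice over %d timepoints (%s)\n",
            length(unique(colony$metadata$subject_id)),
            length(colony$counts),
            paste(names(colony$counts), collapse = ", ")))
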