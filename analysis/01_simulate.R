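#!/usr/bin/env Rscript
# Stage 1 — simulate the study: 612 editing sites (576 mitochondrial +
# 36 plastid) over 24 transcripts; a wild-type, two mutant alleles of the
# same factor sharing one effect truth (14% of mitochondrial sites
# increased, 3% decreased, |delta| in [0.15, 0.4]); two fully restoring
# transgenic lines per mutant background; binomial counts at depth 2000,
# two biological replicates per genotype.

suppressMessages(library(orgedit))
seed <- 1L
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sites <- gen_sites(576, 36, n_transcripts = 24, seed = seed)
truth <- gen_truth(sites, frac_increased = 0.14, frac_decreased = 0.03,
                   delta_range = c(0.15, 0.4), seed = seed + 1L,
                   mutants = c("mutA", "mutB"))
for (m in c("mutA", "mutB")) {
  for (k in 1:2) {
    truth <- add_transgenic_truth(truth, paste0("T_", m, "_", k), m,
                                  restore = 1)
  }
}
design <- design_from_truth(truth)
em <- gen_counts(truth, design, depth = 2000, seed = seed + 2L)

write_sites(sites, file.path(out, "sites.tsv"))
write_sites_bed(sites, file.path(out, "sites.bed"))
write.table(design, file.path(out, "design.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_count_table(em, file.path(out, "counts.tsv"))
truth_df <- data.frame(site_id = sites$site_id,
                       effect_class = unname(truth$effect_class),
                       delta_true = unname(truth$delta_true),
                       truth$extents, check.names = FALSE)
write.table(truth_df, file.path(out, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Simulated", nrow(sites), "sites x", nrow(design), "samples\n")
print(table(truth$effect_class))
cat("Wrote sites/design/counts/truth under", out, "\n")
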