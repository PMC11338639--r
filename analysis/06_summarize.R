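#!/usr/bin/env Rscript
# Step 6: assemble the count/proportion tables that summarize the run:
# validated genes by clade, genomes by copy number, contexts by type, WLP
# routes, and transcript aggregates. Also demonstrates the percentage
# arithmetic on reported count ratios.

library(gutcodh)

out <- "results/summary"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

validated <- read.delim("results/screen/validated.tsv",
                        stringsAsFactors = FALSE)
contexts <- read.delim("results/contexts/contexts.tsv",
                       stringsAsFactors = FALSE)
profiles <- read.delim("results/wlp/profiles.tsv", stringsAsFactors = FALSE)

by_clade <- summarize_counts(validated, "clade")
write.table(by_clade, file.path(out, "genes_by_clade.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
copies <- pcodh_copy_histogram(validated)
write.table(copies, file.path(out, "copies_per_genome.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
by_type <- summarize_counts(contexts, "assigned_type")
write.table(by_type, file.path(out, "contexts_by_type.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
routes <- summarize_counts(profiles[profiles$is_pcodh_acs, ],
                           c("fdh_status", "formate_route"))
write.table(routes, file.path(out, "wlp_routes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message("validated pCODH genes by clade:")
print(by_clade)
message("pCODH copies per genome:")
print(copies)

## percentage arithmetic on count ratios (numerators/denominators as inputs)
message("examples of reported-ratio arithmetic:")
message("  1302 / 30691 genomes  -> ", proportion_pct(1302, 30691, 1), " %")
message("  107 / 110 datasets    -> ", proportion_pct(107, 110, 1), " %")
message("  526 / 667 genomes     -> ", proportion_pct(526, 667, 0), " %")
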