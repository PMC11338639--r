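#!/usr/bin/env Rscript
# Step 3: extract the +/-15-gene window around every validated pCODH gene and
# assign one of the eight marker-defined context types, tallying auxiliary
# genes (oxyR, narGHIJK, pflAB, hypAB, cooC, cooF).

library(gutcodh)

syn <- "results/synthetic"
out <- "results/contexts"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

validated <- read.delim("results/screen/validated.tsv",
                        stringsAsFactors = FALSE)
bundles <- lapply(unique(validated$genome_id), function(id) {
  read_genome_bundle(file.path(syn, "genomes", id), id)
})

contexts <- classify_contexts(bundles, validated)
write.table(contexts, file.path(out, "contexts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

tab <- summarize_counts(contexts, "assigned_type")
write.table(tab, file.path(out, "contexts_by_type.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("context type counts:")
print(tab)

truth <- read_truth_table(file.path(syn, "truth.tsv"))
planted_ct <- truth[truth$fact_type == "context", ]
idx <- match(contexts$gene_id, planted_ct$gene_id)
expected <- ifelse(planted_ct$value[idx] == "none", "unclassified",
                   planted_ct$value[idx])
message("agreement with planted context types: ",
        round(100 * mean(contexts$assigned_type == expected), 1), " %")
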