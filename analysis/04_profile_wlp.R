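#!/usr/bin/env Rscript
# Step 4: build the genome x gene-symbol presence matrix over the WLP,
# accessory and formate-acquisition KO lists, define pCODH/ACS-encoding
# genomes, classify Fdh status and formate routes, and compute per-genus
# presence rates.

library(gutcodh)

syn <- "results/synthetic"
out <- "results/wlp"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ids <- readLines(file.path(syn, "genome_ids.txt"))
bundles <- lapply(ids, function(id) {
  read_genome_bundle(file.path(syn, "genomes", id), id)
})
validated <- read.delim("results/screen/validated.tsv",
                        stringsAsFactors = FALSE)

prof <- profile_genomes(bundles, unique(validated$genome_id))
write.table(data.frame(genome_id = rownames(prof$presence),
                       prof$presence, check.names = FALSE),
            file.path(out, "presence_matrix.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(prof$profiles, file.path(out, "profiles.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

taxonomy <- do.call(rbind, lapply(bundles, function(b) {
  data.frame(genome_id = b$genome_id, genus = b$taxonomy[["genus"]],
             stringsAsFactors = FALSE)
}))
gp <- genus_proportions(prof$presence, taxonomy,
                        symbols = c("cooC", "cooF", "acsB", "acsC", "acsD",
                                    "acsE", "fhs", "folD", "metF", "fdhA",
                                    "fdhF", "fdoG", "pfl", "fdhC", "por"))
write.table(gp, file.path(out, "genus_proportions.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

acs <- prof$profiles[prof$profiles$is_pcodh_acs, ]
message(nrow(acs), " pCODH/ACS-encoding genomes (validated pCODH + acsB)")
if (nrow(acs) > 0) {
  message("Fdh-lacking among them: ",
          proportion_pct(sum(acs$fdh_status == "fdh_lacking"), nrow(acs), 0),
          " %")
  message("formate routes: ",
          paste(names(table(acs$formate_route)), table(acs$formate_route),
                collapse = ", "))
}
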