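#!/usr/bin/env Rscript
# Step 1: build the clade-representative reference set and a synthetic cohort
# of annotated genomes with planted ground truth, and write everything to
# disk in the pipeline's on-disk formats.
#
# Cohort design: 24 screening genomes (4 per clade; planted identities
# 50-90 %; half intact motifs, half substituted/deleted), 16 context genomes
# (2 per context type) and 20 WLP-preset genomes (4 per preset).

library(gutcodh)

seed <- 1L
out <- "results/synthetic"
dir.create(file.path(out, "genomes"), showWarnings = FALSE, recursive = TRUE)

rs <- make_reference_set(seed)
write_fasta(rs$proteins, file.path(out, "reference_set.faa"))
write.table(rs$clade_map, file.path(out, "clade_map.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_motif_config(default_motif_config(rs), file.path(out, "motif_config.yaml"))
write_fasta(make_coxl_reference(seed), file.path(out, "coxl_reference.faa"))

genera <- c("Blautia", "Veillonella", "Faecousia", "CAG-170")
truth <- list(); n <- 0L

emit <- function(spec) {
  pg <- plant_genome(spec, rs)
  write_genome_bundle(pg$bundle, file.path(out, "genomes", spec$genome_id))
  pg$truth
}

message("planting 24 screening genomes ...")
states <- c("intact", "substituted", "intact", "deleted")
for (cl in rs$clade_map$clade) {
  for (j in 1:4) {
    n <- n + 1L
    spec <- plant_spec(
      sprintf("SCR_%s_%d", cl, j),
      taxonomy = c(domain = "Bacteria", phylum = "Bacillota", class = "",
                   order = "", family = "", genus = genera[(j %% 4) + 1],
                   species = ""),
      planted_genes = data.frame(
        template_name = paste0("REF_", cl),
        target_identity = seq(0.5, 0.9, length.out = 4)[j],
        motif_state = states[j], contig_id = "c1", rank_slot = 16L,
        strand = "+", stringsAsFactors = FALSE),
      contig_genes = 22L, seed = seed * 1000L + n)
    truth[[spec$genome_id]] <- emit(spec)
  }
}

message("planting 16 context genomes (2 per type) ...")
for (ct in context_types()) {
  for (j in 1:2) {
    n <- n + 1L
    spec <- plant_spec(
      sprintf("CTX_%s_%d", ct, j),
      taxonomy = c(domain = "Bacteria", phylum = "Bacillota", class = "",
                   order = "", family = "", genus = genera[j], species = ""),
      planted_genes = data.frame(
        template_name = "REF_E", target_identity = 0.75,
        motif_state = "intact", contig_id = "c1", rank_slot = 16L,
        strand = "+", stringsAsFactors = FALSE),
      context_type = ct, seed = seed * 1000L + n)
    truth[[spec$genome_id]] <- emit(spec)
  }
}

message("planting 20 WLP-preset genomes (4 per preset) ...")
presets <- c("full_wlp", "fdh_lacking_pfl", "fdh_lacking_transporter",
             "fdh_lacking_neither", "no_wlp")
for (p in presets) {
  for (j in 1:4) {
    n <- n + 1L
    spec <- plant_spec(
      sprintf("WLP_%s_%d", p, j),
      taxonomy = c(domain = "Bacteria", phylum = "Bacillota", class = "",
                   order = "", family = "", genus = genera[j], species = ""),
      planted_genes = data.frame(
        template_name = "REF_B", target_identity = 0.8,
        motif_state = "intact", contig_id = "c1", rank_slot = 16L,
        strand = "+", stringsAsFactors = FALSE),
      wlp_profile = p, contig_genes = 20L, seed = seed * 1000L + n)
    truth[[spec$genome_id]] <- emit(spec)
  }
}

truth <- do.call(rbind, truth)
write_truth_table(truth, file.path(out, "truth.tsv"))
ids <- unique(truth$genome_id)
writeLines(ids, file.path(out, "genome_ids.txt"))
message("wrote ", length(ids), " genomes and ", nrow(truth),
        " truth facts under ", out)
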