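# Shared fixtures, built once per test run and memoised.
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

fx_reference_set <- function() memo("refset", function() make_reference_set(1))

fx_motif_config <- function() {
  memo("motif_config", function() default_motif_config(fx_reference_set()))
}

# One planted genome: clade-E cooS at 70 % identity, intact motifs, WLP
# context, Fdh-lacking-with-PFL gene complement.
fx_wlp_genome <- function() {
  memo("wlp_genome", function() {
    spec <- plant_spec(
      "FIX1",
      taxonomy = c(domain = "Bacteria", phylum = "Bacillota", class = "Clostridia",
                   order = "Lachnospirales", family = "Lachnospiraceae",
                   genus = "Blautia", species = "Blautia sp."),
      planted_genes = data.frame(template_name = "REF_E", target_identity = 0.7,
                                 motif_state = "intact", contig_id = "c1",
                                 rank_slot = 16L, strand = "+",
                                 stringsAsFactors = FALSE),
      context_type = "WLP", wlp_profile = "fdh_lacking_pfl", seed = 2024L)
    plant_genome(spec, fx_reference_set())
  })
}

fx_focal_gene <- function(planted) {
  planted$truth$gene_id[planted$truth$fact_type == "context"][1]
}

# Cohort of genomes for quantification: three genomes, one focal gene each,
# two genera with a 3:1 planted abundance ratio between them.
fx_quant_cohort <- function() {
  memo("quant_cohort", function() {
    genera <- c("Blautia", "Blautia", "Veillonella")
    pgs <- lapply(1:3, function(i) {
      spec <- plant_spec(
        paste0("QG", i),
        taxonomy = c(domain = "Bacteria", phylum = "Bacillota", class = "",
                     order = "", family = "", genus = genera[i], species = ""),
        planted_genes = data.frame(template_name = "REF_E",
                                   target_identity = 0.8,
                                   motif_state = "intact", contig_id = "c1",
                                   rank_slot = 16L,
                                   strand = c("+", "-", "+")[i],
                                   stringsAsFactors = FALSE),
        context_type = c("WLP", "WLP", "PEPCK")[i], seed = 500L + i)
      plant_genome(spec, fx_reference_set())
    })
    bundles <- lapply(pgs, `[[`, "bundle")
    focals <- vapply(pgs, fx_focal_gene, character(1))
    ref_genes <- unlist(lapply(seq_along(bundles), function(i) {
      gene_nt_sequences(bundles[[i]], focals[i])
    }))
    metadata <- data.frame(
      gene_id = focals,
      genus = genera,
      context_type = c("WLP", "WLP", "PEPCK"),
      is_pcodh = TRUE, stringsAsFactors = FALSE)
    list(bundles = bundles, focals = focals, ref_genes = ref_genes,
         metadata = metadata)
  })
}

# The end-to-end screen cohort: 60 genomes, 10 per clade template, planted
# identities 50-90 %, half intact and half substituted/deleted.
fx_screen_cohort <- function() {
  memo("screen_cohort", function() {
    clades <- c("B", "C", "D", "E", "F", "mini")
    states <- rep(c("intact", "substituted", "intact", "deleted", "intact"), 2)
    identities <- seq(0.5, 0.9, length.out = 10)
    pgs <- list()
    for (ci in seq_along(clades)) {
      for (j in 1:10) {
        gid <- sprintf("E2E_%s_%02d", clades[ci], j)
        spec <- plant_spec(
          gid, NULL,
          planted_genes = data.frame(
            template_name = paste0("REF_", clades[ci]),
            target_identity = identities[j], motif_state = states[j],
            contig_id = "c1", rank_slot = 16L, strand = "+",
            stringsAsFactors = FALSE),
          context_type = "none", wlp_profile = "no_wlp", contig_genes = 25L,
          seed = 7000L + ci * 100L + j)
        pgs[[gid]] <- plant_genome(spec, fx_reference_set())
      }
    }
    pgs
  })
}
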