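AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

#' Synthetic motif site layout (stand-in coordinates)
#'
#' Residue coordinates of the five metal clusters (two C-clusters, one
#' B-cluster, one D-cluster) and two acid-base catalysts on the synthetic
#' clade-F anchor. These are synthetic stand-in positions: for real data the
#' config must be re-anchored to an experimentally characterized CooS (e.g.
#' the C. hydrogenoformans CooSII-style reference) with curated coordinates.
#'
#' @return data.frame with columns site, position, required (allowed residues
#'   as a string of one-letter codes).
#' @export
synth_motif_sites <- function() {
  data.frame(
    site = c("D_cluster", "D_cluster",
             "B_cluster", "B_cluster", "B_cluster", "B_cluster",
             "acid_base_1",
             "C_cluster_1", "C_cluster_1", "C_cluster_1",
             "C_cluster_2", "C_cluster_2",
             "acid_base_2"),
    position = c(39L, 47L, 56L, 59L, 64L, 70L, 93L,
                 261L, 295L, 333L, 446L, 481L, 563L),
    required = c("C", "C", "C", "C", "C", "C", "H",
                 "H", "C", "C", "C", "C", "K"),
    stringsAsFactors = FALSE
  )
}

random_protein <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Reverse-complement a DNA string
#' @param x Character vector of DNA sequences.
#' @return Reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## codon table grouped by amino acid (standard code)
codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

reverse_translate <- function(protein, codon_table = codons_by_aa()) {
  aa <- strsplit(protein, "")[[1]]
  codons <- vapply(aa, function(a) {
    opts <- codon_table[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  stop_codon <- codon_table[["*"]][sample.int(3L, 1L)]
  paste(c(codons, stop_codon), collapse = "")
}

#' Mutate a protein to a target global identity
#'
#' Substitution-only mutagenesis: exactly `round((1 - target) * L)` positions
#' are changed to a different residue, so the realized global identity equals
#' the target up to rounding (well within the contract's 2-percentage-point
#' band). Mutated positions are spread evenly along the sequence (one draw
#' per contiguous block of mutable positions) so that local-alignment
#' identity tracks the global identity instead of being inflated by trimming
#' mutation-dense ends. Protected positions are never touched.
#'
#' @param template Protein sequence (string).
#' @param target_identity Target identity in `[0, 1]`.
#' @param protected_positions Integer positions that must stay unchanged.
#' @param seed Integer seed.
#' @return Mutated protein string.
#' @export
mutate_to_identity <- function(template, target_identity,
                               protected_positions = integer(0), seed = 1L) {
  stopifnot(target_identity >= 0, target_identity <= 1)
  len <- nchar(template)
  stopifnot(all(protected_positions >= 1), all(protected_positions <= len))
  n_mut <- round((1 - target_identity) * len)
  mutable <- setdiff(seq_len(len), protected_positions)
  if (n_mut > length(mutable)) {
    stop("target identity ", target_identity, " infeasible: needs ", n_mut,
         " substitutions but only ", length(mutable), " mutable positions")
  }
  if (n_mut == 0) return(template)
  withr::with_seed(seed, {
    mutable <- sort(mutable)
    block <- cut(seq_along(mutable), breaks = n_mut, labels = FALSE)
    picks <- vapply(split(mutable, block), function(p) {
      p[sample.int(length(p), 1L)]
    }, integer(1))
    aa <- strsplit(template, "")[[1]]
    for (p in picks) {
      aa[p] <- sample(setdiff(AA20, aa[p]), 1L)
    }
    paste(aa, collapse = "")
  })
}

#' Global (ungapped-length) identity between two equal-length proteins
#' @param a,b Protein strings of equal length.
#' @return Fraction of identical positions.
#' @export
global_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
}

#' Generate the clade-representative reference set
#'
#' Emits six mutually distinct catalytic-subunit templates (clades B, C, D,
#' E, F and mini), each 630 aa and each carrying the configured active-site
#' motif residues. The clade-F template is the motif anchor; the others are
#' derived from it at ~55 % identity with motif positions protected, keeping
#' all pairwise template identities below 60 % while guaranteeing that any
#' candidate planted at >= 50 % identity to one template still aligns
#' reliably to the anchor for motif mapping.
#'
#' @param seed Integer seed.
#' @param length_aa Template length (default 630).
#' @return List with `proteins` (named character, ids REF_B..REF_mini),
#'   `clade_map` (data.frame reference_id, clade) and `anchor_id`.
#' @export
make_reference_set <- function(seed = 1L, length_aa = 630L) {
  sites <- synth_motif_sites()
  stopifnot(length_aa >= max(sites$position))
  anchor <- withr::with_seed(seed, {
    aa <- strsplit(random_protein(length_aa), "")[[1]]
    aa[sites$position] <- substr(sites$required, 1, 1)
    paste(aa, collapse = "")
  })
  clades <- c("B", "C", "D", "E", "F", "mini")
  proteins <- stats::setNames(character(length(clades)),
                              paste0("REF_", clades))
  proteins[["REF_F"]] <- anchor
  others <- setdiff(clades, "F")
  for (i in seq_along(others)) {
    proteins[[paste0("REF_", others[i])]] <-
      mutate_to_identity(anchor, 0.55, protected_positions = sites$position,
                         seed = seed * 1000L + i)
  }
  list(
    proteins = proteins,
    clade_map = data.frame(reference_id = names(proteins), clade = clades,
                           stringsAsFactors = FALSE),
    anchor_id = "REF_F"
  )
}

#' Synthetic CoxL (Mo-CODH large subunit) reference
#'
#' An 800-aa template carrying the Mo-CODH active-site motif AYRCSFR at a
#' fixed internal position, used to screen for Mo-CODH candidates.
#'
#' @param seed Integer seed.
#' @return Named character vector of length 1 (id `REF_CoxL`).
#' @export
make_coxl_reference <- function(seed = 1L) {
  prot <- withr::with_seed(seed + 777L, {
    aa <- strsplit(random_protein(800L), "")[[1]]
    aa[401:407] <- strsplit("AYRCSFR", "")[[1]]
    paste(aa, collapse = "")
  })
  c(REF_CoxL = prot)
}

#' Synthetic pyruvate formate-lyase (PFL) anchor and Cys-Cys site
#'
#' A deterministic 740-aa stand-in PFL with the adjacent catalytic Cys-Cys
#' pair at positions 418-419, used to validate K00656-annotated genes.
#'
#' @return List with `anchor_sequence` and `positions` (the two Cys sites).
#' @export
default_pfl_config <- function() {
  prot <- withr::with_seed(20401L, {
    aa <- strsplit(random_protein(740L), "")[[1]]
    aa[418:419] <- "C"
    paste(aa, collapse = "")
  })
  list(anchor_sequence = prot, positions = c(418L, 419L))
}

## Per-context marker plan: offsets are rank distances from the focal gene.
context_marker_plan <- function() {
  list(
    WLP = data.frame(offset = c(1L, 2L),
                     ko = c("K07321", "K14138"),
                     cog = c("", "COG1614"),
                     symbol = c("cooC", "acsB"), stringsAsFactors = FALSE),
    PEPCK = data.frame(offset = c(1L, -1L),
                       ko = c("K01610", "K04761"),
                       cog = c("COG1866", "COG0583"),
                       symbol = c("pckA", "oxyR"), stringsAsFactors = FALSE),
    FNOR = data.frame(offset = 1L, ko = "", cog = "COG1251",
                      symbol = "fnor", stringsAsFactors = FALSE),
    ABC_transporter = data.frame(offset = 1:3,
                                 ko = c("K02049", "K02050", "K02051"),
                                 cog = c("COG0715", "COG0600", "COG1116"),
                                 symbol = c("abcA", "abcB", "abcC"),
                                 stringsAsFactors = FALSE),
    Fe_hydrogenase = data.frame(offset = c(1L, 4L, 5L),
                                ko = c("", "K04069", "K00656"),
                                cog = c("COG4624", "", ""),
                                symbol = c("feHyd", "pflA", "pflB"),
                                stringsAsFactors = FALSE),
    MFS_transporter = data.frame(offset = 1L, ko = "K08177", cog = "COG2223",
                                 symbol = "oxlT", stringsAsFactors = FALSE),
    uncharacterized_dehydrogenase = data.frame(
      offset = c(1L, -1L, -2L),
      ko = c("K00004", "K04651", "K04652"),
      cog = c("COG1063", "", ""),
      symbol = c("dehyd", "hypA", "hypB"), stringsAsFactors = FALSE),
    cysteine_synthase = data.frame(offset = 1L, ko = "K01738", cog = "COG0031",
                                   symbol = "cysK", stringsAsFactors = FALSE),
    none = data.frame(offset = integer(0), ko = character(0),
                      cog = character(0), symbol = character(0),
                      stringsAsFactors = FALSE)
  )
}

#' Names of the eight genomic context types
#' @return Character vector in precedence order (WLP first).
#' @export
context_types <- function() {
  c("WLP", "PEPCK", "FNOR", "ABC_transporter", "Fe_hydrogenase",
    "MFS_transporter", "uncharacterized_dehydrogenase", "cysteine_synthase")
}

## WLP gene-complement presets planted on a secondary contig.
wlp_preset_plan <- function() {
  core <- data.frame(
    symbol = c("cooC", "cooF", "acsB", "acsC", "acsD", "acsE",
               "fhs", "folD", "metF", "metV", "por"),
    ko = c("K07321", "K00196", "K14138", "K00197", "K00194", "K15023",
           "K01938", "K01491", "K00297", "K25007", "K03737"),
    stringsAsFactors = FALSE
  )
  list(
    full_wlp = rbind(core, data.frame(symbol = "fdhA", ko = "K05299")),
    fdh_lacking_pfl = rbind(core, data.frame(symbol = c("pflA", "pflB"),
                                             ko = c("K04069", "K00656"))),
    fdh_lacking_transporter = rbind(core, data.frame(symbol = "fdhC",
                                                     ko = "K21993")),
    fdh_lacking_neither = core,
    no_wlp = core[0, ]
  )
}

#' Construct a planting specification for one synthetic genome
#'
#' @param genome_id Genome identifier.
#' @param taxonomy Named 7-rank character vector (or NULL).
#' @param planted_genes data.frame with columns template_name,
#'   target_identity, motif_state (`intact`/`substituted`/`deleted`),
#'   contig_id, rank_slot, strand. May have zero rows.
#' @param context_type One of [context_types()] or `"none"`.
#' @param wlp_profile One of full_wlp, fdh_lacking_pfl,
#'   fdh_lacking_transporter, fdh_lacking_neither, no_wlp.
#' @param contig_genes Number of genes on the focal contig (default 33).
#' @param seed Integer seed.
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(genome_id, taxonomy = NULL, planted_genes,
                       context_type = "none", wlp_profile = "no_wlp",
                       contig_genes = 33L, seed = 1L) {
  stopifnot(context_type %in% c(context_types(), "none"))
  stopifnot(wlp_profile %in% names(wlp_preset_plan()))
  stopifnot(all(planted_genes$target_identity >= 0),
            all(planted_genes$target_identity <= 1))
  stopifnot(all(planted_genes$motif_state %in%
                  c("intact", "substituted", "deleted")))
  structure(list(genome_id = genome_id, taxonomy = taxonomy,
                 planted_genes = planted_genes, context_type = context_type,
                 wlp_profile = wlp_profile,
                 contig_genes = as.integer(contig_genes),
                 seed = as.integer(seed)),
            class = "plant_spec")
}

## Apply a motif damage to a planted protein: one substitution in
## C_cluster_1, or a deletion spanning the whole B-cluster (a single deleted
## residue next to a conserved block is not localizable by pairwise
## alignment, so the planted deletion removes the full site span).
apply_motif_state <- function(protein, motif_state, sites) {
  if (motif_state == "intact") return(protein)
  aa <- strsplit(protein, "")[[1]]
  if (motif_state == "substituted") {
    pos <- sites$position[sites$site == "C_cluster_1"][1]
    allowed <- strsplit(sites$required[sites$site == "C_cluster_1"][1], "")[[1]]
    aa[pos] <- setdiff(AA20, allowed)[1]
    return(paste(aa, collapse = ""))
  }
  span <- range(sites$position[sites$site == "B_cluster"])
  paste(aa[-(span[1]:span[2])], collapse = "")
}

#' Plant a synthetic genome with ground truth
#'
#' Builds one annotated genome: background random-codon ORFs (200-700 aa,
#' no KO/COG annotations), the planted cooS-derived gene(s) at the requested
#' identity and motif state, context marker genes within 15 ranks of the
#' focal gene when a context type is requested, and a secondary contig
#' carrying the requested WLP gene complement. Every planted fact is recorded
#' in a truth table.
#'
#' @param spec A [plant_spec()].
#' @param reference_set Output of [make_reference_set()].
#' @param pfl_config PFL anchor config (default [default_pfl_config()]).
#' @return List with `bundle` (a `genome_bundle`) and `truth` (data.frame
#'   fact_type, genome_id, gene_id, key, value).
#' @export
plant_genome <- function(spec, reference_set, pfl_config = default_pfl_config()) {
  stopifnot(inherits(spec, "plant_spec"))
  sites <- synth_motif_sites()
  plan <- context_marker_plan()[[spec$context_type]]
  presets <- wlp_preset_plan()[[spec$wlp_profile]]
  withr::with_seed(spec$seed, {
    ct <- codons_by_aa()
    n_genes <- spec$contig_genes
    planted <- spec$planted_genes
    if (nrow(planted) > 0 &&
        any(planted$rank_slot < 0 | planted$rank_slot >= n_genes)) {
      stop("rank_slot outside the focal contig (contig too small for window)")
    }
    ## focal contig gene slots
    proteins <- vapply(seq_len(n_genes),
                       function(i) random_protein(sample(200:700, 1L)),
                       character(1))
    ko <- rep("", n_genes)
    cog <- rep("", n_genes)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    role <- rep("background", n_genes)
    truth <- list()
    focal_slots <- integer(0)
    for (i in seq_len(nrow(planted))) {
      pg <- planted[i, ]
      slot <- pg$rank_slot + 1L
      template <- reference_set$proteins[[pg$template_name]]
      if (is.null(template)) stop("unknown template: ", pg$template_name)
      prot <- mutate_to_identity(template, pg$target_identity,
                                 protected_positions = sites$position,
                                 seed = spec$seed * 100L + i)
      prot <- apply_motif_state(prot, pg$motif_state, sites)
      proteins[slot] <- prot
      strand[slot] <- pg$strand
      role[slot] <- "planted_cooS"
      focal_slots <- c(focal_slots, slot)
      clade <- reference_set$clade_map$clade[
        reference_set$clade_map$reference_id == pg$template_name]
      truth[[length(truth) + 1L]] <- data.frame(
        fact_type = "planted_gene", genome_id = spec$genome_id,
        gene_id = slot,  # resolved to ids below
        key = c("template", "clade", "target_identity", "motif_state",
                "expected_pass"),
        value = c(pg$template_name, clade,
                  as.character(pg$target_identity), pg$motif_state,
                  as.character(pg$motif_state == "intact")),
        stringsAsFactors = FALSE)
    }
    ## context markers around the first planted gene(s)
    if (spec$context_type != "none" && length(focal_slots) > 0 &&
        nrow(plan) > 0) {
      for (fs in focal_slots) {
        for (j in seq_len(nrow(plan))) {
          slot <- fs + plan$offset[j]
          if (slot < 1L || slot > n_genes) {
            stop("contig too small for requested context window")
          }
          ko[slot] <- plan$ko[j]
          cog[slot] <- plan$cog[j]
          role[slot] <- paste0("marker_", plan$symbol[j])
          if (plan$symbol[j] == "pflB") {
            proteins[slot] <- pfl_config$anchor_sequence
          }
          truth[[length(truth) + 1L]] <- data.frame(
            fact_type = "context_marker", genome_id = spec$genome_id,
            gene_id = slot, key = plan$symbol[j],
            value = spec$context_type, stringsAsFactors = FALSE)
        }
        truth[[length(truth) + 1L]] <- data.frame(
          fact_type = "context", genome_id = spec$genome_id, gene_id = fs,
          key = "context_type", value = spec$context_type,
          stringsAsFactors = FALSE)
      }
    } else if (length(focal_slots) > 0) {
      for (fs in focal_slots) {
        truth[[length(truth) + 1L]] <- data.frame(
          fact_type = "context", genome_id = spec$genome_id, gene_id = fs,
          key = "context_type", value = "none", stringsAsFactors = FALSE)
      }
    }
    ## secondary contig with the WLP gene complement
    n2 <- nrow(presets)
    proteins2 <- character(0); ko2 <- character(0); role2 <- character(0)
    if (n2 > 0) {
      proteins2 <- vapply(seq_len(n2),
                          function(i) random_protein(sample(250:600, 1L)),
                          character(1))
      proteins2[presets$symbol == "pflB"] <- pfl_config$anchor_sequence
      ko2 <- presets$ko
      role2 <- paste0("wlp_", presets$symbol)
    }
    ## assemble gene ids in contig order, build nucleotide contigs
    all_prot <- c(proteins, proteins2)
    all_ko <- c(ko, ko2)
    all_cog <- c(cog, rep("", n2))
    all_strand <- c(strand, rep("+", n2))
    all_contig <- c(rep("c1", n_genes), rep("c2", n2))
    gene_id <- sprintf("%s_g%03d", spec$genome_id, seq_along(all_prot))
    build_contig <- function(idx) {
      segs <- character(0)
      starts <- integer(length(idx)); ends <- integer(length(idx))
      pos <- 0L
      parts <- list()
      for (k in seq_along(idx)) {
        i <- idx[k]
        spacer <- random_dna(50L)
        cds <- reverse_translate(all_prot[i], ct)
        seg <- if (all_strand[i] == "-") revcomp(cds) else cds
        parts[[length(parts) + 1L]] <- spacer
        pos <- pos + 50L
        starts[k] <- pos
        parts[[length(parts) + 1L]] <- seg
        pos <- pos + nchar(seg)
        ends[k] <- pos
      }
      parts[[length(parts) + 1L]] <- random_dna(50L)
      list(seq = paste(unlist(parts), collapse = ""),
           start = starts, end = ends)
    }
    contigs <- character(0)
    start <- integer(length(all_prot)); end <- integer(length(all_prot))
    for (cid in unique(all_contig)) {
      idx <- which(all_contig == cid)
      built <- build_contig(idx)
      contigs[cid] <- built$seq
      start[idx] <- built$start
      end[idx] <- built$end
    }
    genes <- data.frame(gene_id = gene_id, contig_id = all_contig,
                        start = start, end = end, strand = all_strand,
                        ko = all_ko, cog = all_cog, protein = all_prot,
                        stringsAsFactors = FALSE)
    bundle <- genome_bundle(spec$genome_id, spec$taxonomy, contigs, genes)
    ## resolve slot indices in truth to gene ids (c1 slots map 1:1 to ids)
    truth <- if (length(truth) > 0) do.call(rbind, truth) else
      data.frame(fact_type = character(0), genome_id = character(0),
                 gene_id = character(0), key = character(0),
                 value = character(0), stringsAsFactors = FALSE)
    if (nrow(truth) > 0) truth$gene_id <- gene_id[as.integer(truth$gene_id)]
    ## genome-level expected WLP classification from planted annotations
    kos_present <- unique(unlist(split_ids(genes$ko)))
    has_fdh <- any(c("K05299", "K22015", "K00123") %in% kos_present)
    has_pfl <- "K00656" %in% kos_present  # planted PFLs carry the intact anchor
    has_transporter <- any(c("K03459", "K06212", "K08177", "K21990",
                             "K21993") %in% kos_present)
    route <- if (has_fdh) "fdh" else if (has_pfl) "pfl" else
      if (has_transporter) "transporter" else "none"
    has_valid_pcodh <- nrow(planted) > 0 && any(planted$motif_state == "intact")
    is_pcodh_acs <- has_valid_pcodh && ("K14138" %in% kos_present)
    truth <- rbind(truth, data.frame(
      fact_type = "wlp", genome_id = spec$genome_id, gene_id = "",
      key = c("wlp_profile", "fdh_status", "formate_route", "is_pcodh_acs"),
      value = c(spec$wlp_profile,
                if (has_fdh) "has_any_fdh" else "fdh_lacking",
                route, as.character(is_pcodh_acs)),
      stringsAsFactors = FALSE))
    list(bundle = bundle, truth = truth)
  })
}

#' Extract strand-aware nucleotide sequences for genes
#'
#' @param bundle A `genome_bundle`.
#' @param gene_ids Genes to extract (default all).
#' @return Named character vector of coding-strand nucleotide sequences.
#' @export
gene_nt_sequences <- function(bundle, gene_ids = bundle$genes$gene_id) {
  g <- bundle$genes[match(gene_ids, bundle$genes$gene_id), , drop = FALSE]
  if (anyNA(g$gene_id)) stop("unknown gene_id(s): ",
                             paste(setdiff(gene_ids, bundle$genes$gene_id),
                                   collapse = ", "))
  seg <- substr(bundle$contigs[g$contig_id], g$start + 1L, g$end)
  seg <- unname(seg)
  rev <- g$strand == "-"
  if (any(rev)) seg[rev] <- revcomp(seg[rev])
  stats::setNames(seg, g$gene_id)
}

#' Simulate error-free metatranscriptome reads
#'
#' Reads are drawn from gene coding sequences with probability proportional
#' to `weight * gene length`, at uniform positions, reverse-complemented with
#' probability 0.5. Quality is constant. Truth counts per gene are recorded.
#'
#' @param bundles List of `genome_bundle`s.
#' @param abundance_map Named numeric vector: gene_id -> nonnegative weight.
#' @param read_length Read length in nt.
#' @param n_reads Number of reads.
#' @param seed Integer seed.
#' @return List with `reads` (named character), `truth_counts` (data.frame
#'   gene_id, length_nt, count).
#' @export
simulate_reads <- function(bundles, abundance_map, read_length, n_reads,
                           seed = 1L) {
  if (all(abundance_map <= 0)) stop("all-zero abundance map")
  stopifnot(!is.null(names(abundance_map)))
  gene_seq <- unlist(unname(lapply(bundles, function(b) {
    ids <- intersect(b$genes$gene_id, names(abundance_map))
    if (length(ids) == 0) return(character(0))
    gene_nt_sequences(b, ids)
  })))
  missing <- setdiff(names(abundance_map), names(gene_seq))
  if (length(missing) > 0) stop("abundance map names unknown gene(s): ",
                                paste(missing, collapse = ", "))
  lens <- nchar(gene_seq)[names(abundance_map)]
  active <- abundance_map > 0
  if (any(lens[active] < read_length)) {
    stop("read_length exceeds the length of a weighted gene")
  }
  w <- abundance_map * lens
  withr::with_seed(seed, {
    origin <- sample(names(abundance_map), n_reads, replace = TRUE,
                     prob = w / sum(w))
    pos <- vapply(origin, function(g) {
      sample.int(nchar(gene_seq[[g]]) - read_length + 1L, 1L)
    }, integer(1))
    reads <- unname(substr(gene_seq[origin], pos, pos + read_length - 1L))
    flip <- stats::runif(n_reads) < 0.5
    reads[flip] <- revcomp(reads[flip])
    names(reads) <- sprintf("read%06d", seq_len(n_reads))
    tab <- table(factor(origin, levels = names(abundance_map)))
    truth_counts <- data.frame(gene_id = names(abundance_map),
                               length_nt = unname(lens),
                               count = as.numeric(tab),
                               stringsAsFactors = FALSE)
    list(reads = reads, truth_counts = truth_counts)
  })
}

#' Write a truth table TSV
#' @param truth data.frame fact_type, genome_id, gene_id, key, value.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a truth table TSV
#' @param path Path to the truth TSV.
#' @return data.frame fact_type, genome_id, gene_id, key, value.
#' @export
read_truth_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}
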