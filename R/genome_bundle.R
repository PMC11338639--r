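#' Construct a genome bundle
#'
#' A genome bundle is the unit of analysis: one annotated prokaryotic genome
#' with its contig sequences, protein-coding gene table (0-based half-open
#' coordinates, per-contig ranks), per-gene protein sequences, and a 7-rank
#' taxonomy. KO/COG annotations are carried as ';'-joined strings on the gene
#' table; a gene may carry several KOs and all are retained.
#'
#' @param genome_id Genome identifier.
#' @param taxonomy Named character vector over the seven ranks
#'   domain..species (empty labels allowed), or NULL for all-empty.
#' @param contigs Named character vector of contig nucleotide sequences.
#' @param genes Gene table with columns gene_id, contig_id, start, end,
#'   strand, ko, cog, protein. Ranks are recomputed.
#' @return An object of class `genome_bundle`.
#' @export
genome_bundle <- function(genome_id, taxonomy = NULL, contigs, genes) {
  if (is.null(taxonomy)) {
    taxonomy <- stats::setNames(rep("", length(TAXONOMY_RANKS)), TAXONOMY_RANKS)
  }
  taxonomy <- taxonomy[TAXONOMY_RANKS]
  taxonomy[is.na(taxonomy)] <- ""
  names(taxonomy) <- TAXONOMY_RANKS
  stopifnot(is.character(contigs), !is.null(names(contigs)))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  required <- c("gene_id", "contig_id", "start", "end", "strand", "protein")
  missing <- setdiff(required, names(genes))
  if (length(missing) > 0) stop("gene table lacks column(s): ",
                                paste(missing, collapse = ", "))
  if (is.null(genes$ko)) genes$ko <- ""
  if (is.null(genes$cog)) genes$cog <- ""
  genes <- recompute_ranks(genes)
  bundle <- structure(
    list(genome_id = genome_id, taxonomy = taxonomy,
         contigs = contigs,
         genes = genes[, c(GENE_TABLE_COLS, "protein")]),
    class = "genome_bundle"
  )
  validate_genome_bundle(bundle)
  bundle
}

#' Validate genome-bundle invariants
#'
#' Checks unique gene ids, interval sanity (0 <= start < end, length >= 3 nt,
#' contained in the contig), strand symbols, consecutive per-contig ranks and
#' the protein alphabet (20 standard residues plus X, optional trailing '*').
#'
#' @param bundle A `genome_bundle`.
#' @return `bundle`, invisibly; stops on violation.
#' @export
validate_genome_bundle <- function(bundle) {
  g <- bundle$genes
  dup <- g$gene_id[duplicated(g$gene_id)]
  if (length(dup) > 0) stop("duplicate gene_id(s): ", paste(dup, collapse = ", "))
  if (any(g$start < 0 | g$end <= g$start)) stop("invalid gene interval (need 0 <= start < end)")
  if (any(g$end - g$start < 3)) stop("gene shorter than 3 nt")
  bad <- setdiff(unique(g$strand), c("+", "-"))
  if (length(bad) > 0) stop("unknown strand symbol(s): ", paste(bad, collapse = ", "))
  unknown <- setdiff(unique(g$contig_id), names(bundle$contigs))
  if (length(unknown) > 0) stop("gene on unknown contig(s): ",
                                paste(unknown, collapse = ", "))
  clen <- nchar(bundle$contigs)[g$contig_id]
  if (any(g$end > clen)) stop("gene interval exceeds contig length")
  ok_rank <- vapply(split(g$rank[order(g$contig_id, g$start)],
                          g$contig_id[order(g$contig_id, g$start)]),
                    function(r) identical(as.integer(r), seq_along(r) - 1L),
                    logical(1))
  if (!all(ok_rank)) stop("ranks are not consecutive 0-based per contig")
  prot <- gsub("\\*$", "", g$protein)
  if (any(grepl("[^ACDEFGHIKLMNPQRSTVWYX]", prot))) {
    stop("protein sequence outside the 20 standard residues plus X")
  }
  invisible(bundle)
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat("genome_bundle", x$genome_id, "\n")
  cat("  contigs:", length(x$contigs), " genes:", nrow(x$genes), "\n")
  tx <- x$taxonomy[nzchar(x$taxonomy)]
  if (length(tx) > 0) cat("  taxonomy:", paste(tx, collapse = "; "), "\n")
  invisible(x)
}

#' Write a genome bundle to a directory
#'
#' Emits `<id>.fna` (contigs), `<id>.faa` (proteins), `<id>.gff3` (gene
#' coordinates, 1-based inclusive on disk), `<id>.ann.tsv` (gene_id, ko, cog,
#' product) and `<id>.tax.tsv` (7-rank taxonomy).
#'
#' @param bundle A `genome_bundle`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_genome_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- bundle$genome_id
  write_fasta(bundle$contigs, file.path(dir, paste0(id, ".fna")))
  prot <- stats::setNames(bundle$genes$protein, bundle$genes$gene_id)
  write_fasta(prot, file.path(dir, paste0(id, ".faa")))
  write_gene_table(bundle$genes, file.path(dir, paste0(id, ".gff3")), "gff3")
  write_annotation_table(
    data.frame(gene_id = bundle$genes$gene_id, ko = bundle$genes$ko,
               cog = bundle$genes$cog, product = "",
               stringsAsFactors = FALSE),
    file.path(dir, paste0(id, ".ann.tsv")))
  write_taxonomy_table(
    data.frame(genome_id = id, t(bundle$taxonomy), stringsAsFactors = FALSE),
    file.path(dir, paste0(id, ".tax.tsv")))
  invisible(dir)
}

#' Read a genome bundle from a directory
#'
#' Inverse of [write_genome_bundle()]; coordinates, strands, ranks and
#' annotation sets round-trip exactly.
#'
#' @param dir Directory holding the bundle files.
#' @param genome_id Genome identifier (file prefix).
#' @return A `genome_bundle`.
#' @export
read_genome_bundle <- function(dir, genome_id) {
  contigs <- read_fasta(file.path(dir, paste0(genome_id, ".fna")))
  prot <- read_fasta(file.path(dir, paste0(genome_id, ".faa")))
  genes <- read_gene_table(file.path(dir, paste0(genome_id, ".gff3")), "gff3")
  ann <- read_annotation_table(file.path(dir, paste0(genome_id, ".ann.tsv")))
  idx <- match(genes$gene_id, ann$gene_id)
  genes$ko <- ifelse(is.na(idx), "", ann$ko[idx])
  genes$cog <- ifelse(is.na(idx), "", ann$cog[idx])
  missing <- setdiff(genes$gene_id, names(prot))
  if (length(missing) > 0) stop("protein missing for gene(s): ",
                                paste(missing, collapse = ", "))
  genes$protein <- unname(prot[genes$gene_id])
  tax <- read_taxonomy_table(file.path(dir, paste0(genome_id, ".tax.tsv")))
  taxonomy <- stats::setNames(as.character(tax[1, TAXONOMY_RANKS]), TAXONOMY_RANKS)
  genome_bundle(genome_id, taxonomy, contigs, genes)
}
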