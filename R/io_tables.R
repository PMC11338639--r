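#' @importFrom utils read.delim write.table
NULL

GENE_TABLE_COLS <- c("gene_id", "contig_id", "start", "end", "strand",
                     "rank", "ko", "cog")

#' Recompute gene ranks per contig
#'
#' Rank is the 0-based ordinal of a gene along its contig, ordered by start
#' position. Windows around focal genes are defined in rank space.
#'
#' @param genes Gene table with `contig_id` and `start` columns.
#' @return The table with a recomputed `rank` column, sorted by contig and start.
#' @export
recompute_ranks <- function(genes) {
  genes <- genes[order(genes$contig_id, genes$start), , drop = FALSE]
  genes$rank <- stats::ave(genes$start, genes$contig_id,
                           FUN = function(x) seq_along(x) - 1L)
  genes$rank <- as.integer(genes$rank)
  rownames(genes) <- NULL
  genes
}

#' Read a gene table (GFF3 subset or TSV dialect)
#'
#' Internal coordinates are 0-based half-open; on-disk GFF3 is 1-based
#' inclusive and is converted on read. The TSV dialect already carries
#' 0-based half-open coordinates and optional `ko`/`cog` columns
#' (';'-separated identifier lists). Ranks are always recomputed from start
#' positions per contig.
#'
#' @param path Path to the gene table.
#' @param dialect Either `"gff3"` or `"tsv"`.
#' @return A data.frame with columns gene_id, contig_id, start, end, strand,
#'   rank, ko, cog. `ko`/`cog` are ';'-joined identifier strings (possibly "").
#' @export
read_gene_table <- function(path, dialect = c("gff3", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    strand <- as.character(GenomicRanges::strand(gr))
    bad <- setdiff(unique(strand), c("+", "-"))
    if (length(bad) > 0) stop("unknown strand symbol(s): ", paste(bad, collapse = ", "))
    genes <- data.frame(
      gene_id = as.character(S4Vectors::mcols(gr)$ID),
      contig_id = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,  # 1-based inclusive -> 0-based half-open
      end = GenomicRanges::end(gr),
      strand = strand,
      ko = "", cog = "",
      stringsAsFactors = FALSE
    )
  } else {
    genes <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
    required <- c("gene_id", "contig_id", "start", "end", "strand")
    missing <- setdiff(required, names(genes))
    if (length(missing) > 0) stop("TSV gene table lacks column(s): ",
                                  paste(missing, collapse = ", "))
    genes$start <- as.integer(genes$start)
    genes$end <- as.integer(genes$end)
    if (is.null(genes$ko)) genes$ko <- ""
    if (is.null(genes$cog)) genes$cog <- ""
    bad <- setdiff(unique(genes$strand), c("+", "-"))
    if (length(bad) > 0) stop("unknown strand symbol(s): ", paste(bad, collapse = ", "))
  }
  bad <- genes$gene_id[genes$end <= genes$start]
  if (length(bad) > 0) stop("end <= start for gene(s): ", paste(bad, collapse = ", "))
  genes$ko[is.na(genes$ko)] <- ""
  genes$cog[is.na(genes$cog)] <- ""
  genes <- recompute_ranks(genes)
  genes[, GENE_TABLE_COLS]
}

#' Write a gene table (GFF3 subset or TSV dialect)
#'
#' @param genes Gene table as returned by [read_gene_table()].
#' @param path Output path.
#' @param dialect Either `"gff3"` or `"tsv"`.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path, dialect = c("gff3", "tsv"),
                             source = "gutcodh") {
  dialect <- match.arg(dialect)
  if (dialect == "gff3") {
    gr <- GenomicRanges::GRanges(
      seqnames = genes$contig_id,
      ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
      strand = genes$strand
    )
    S4Vectors::mcols(gr)$source <- source
    S4Vectors::mcols(gr)$type <- "CDS"
    S4Vectors::mcols(gr)$ID <- genes$gene_id
    suppressWarnings(suppressMessages(rtracklayer::export.gff3(gr, path)))
  } else {
    write.table(genes[, GENE_TABLE_COLS], path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Split a ';'-joined annotation string into an identifier set
#'
#' @param x Character vector of ';'-joined identifiers (may be "" or NA).
#' @return A list of character vectors (one set per element of `x`).
#' @export
split_ids <- function(x) {
  x[is.na(x)] <- ""
  lapply(strsplit(x, ";", fixed = TRUE), function(v) v[nzchar(v)])
}

#' Read a KO/COG annotation side table
#'
#' Columns: gene_id, ko, cog, product; ko and cog are ';'-separated lists.
#' Mirrors how functional-annotation output is consumed alongside gene calls.
#'
#' @param path Path to the annotation TSV.
#' @return data.frame with columns gene_id, ko, cog, product.
#' @export
read_annotation_table <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(c("gene_id", "ko", "cog"), names(ann))
  if (length(missing) > 0) stop("annotation table lacks column(s): ",
                                paste(missing, collapse = ", "))
  if (is.null(ann$product)) ann$product <- ""
  for (col in c("ko", "cog", "product")) ann[[col]][is.na(ann[[col]])] <- ""
  ann[, c("gene_id", "ko", "cog", "product")]
}

#' Write a KO/COG annotation side table
#' @param ann data.frame with gene_id, ko, cog (and optionally product).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(ann, path) {
  if (is.null(ann$product)) ann$product <- ""
  write.table(ann[, c("gene_id", "ko", "cog", "product")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

TAXONOMY_RANKS <- c("domain", "phylum", "class", "order", "family",
                    "genus", "species")

#' Read a 7-rank taxonomy table
#' @param path Path to a TSV with columns genome_id + the seven ranks.
#' @return data.frame with genome_id and the seven rank columns (empty labels allowed).
#' @export
read_taxonomy_table <- function(path) {
  tax <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(c("genome_id", TAXONOMY_RANKS), names(tax))
  if (length(missing) > 0) stop("taxonomy table lacks column(s): ",
                                paste(missing, collapse = ", "))
  for (col in TAXONOMY_RANKS) tax[[col]][is.na(tax[[col]])] <- ""
  tax[, c("genome_id", TAXONOMY_RANKS)]
}

#' Write a 7-rank taxonomy table
#' @param tax data.frame with genome_id and the seven rank columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy_table <- function(tax, path) {
  write.table(tax[, c("genome_id", TAXONOMY_RANKS)], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

TABULAR_HIT_COLS <- c("query_id", "subject_id", "pct_identity", "aln_length",
                      "mismatches", "gap_opens", "q_start", "q_end",
                      "s_start", "s_end", "evalue", "bit_score")

#' Read 12-column tabular homology hits
#'
#' The standard headerless 12-column tab-separated dialect of protein
#' homology searches; alignment endpoints are 1-based inclusive on disk.
#'
#' @param path Path to the tabular file.
#' @return data.frame of hits, row order preserved.
#' @export
read_tabular_hits <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    out <- as.data.frame(matrix(nrow = 0, ncol = 12))
    names(out) <- TABULAR_HIT_COLS
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 12L)
  if (length(bad) > 0) {
    stop("expected 12 tab-separated columns, got ", nf[bad[1]],
         " at line ", bad[1])
  }
  m <- do.call(rbind, fields)
  out <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    pct_identity = as.numeric(m[, 3]), aln_length = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]), gap_opens = as.integer(m[, 6]),
    q_start = as.integer(m[, 7]), q_end = as.integer(m[, 8]),
    s_start = as.integer(m[, 9]), s_end = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bit_score = as.numeric(m[, 12]),
    stringsAsFactors = FALSE
  )
  out
}

#' Write 12-column tabular homology hits
#' @param hits data.frame with the 12 hit columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tabular_hits <- function(hits, path) {
  write.table(format(hits[, TABULAR_HIT_COLS], scientific = TRUE, trim = TRUE,
                     digits = 6),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-gene counts table
#' @param path TSV with columns gene_id, length_nt, count.
#' @return data.frame with those columns.
#' @export
read_counts_table <- function(path) {
  cts <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("gene_id", "length_nt", "count"), names(cts))
  if (length(missing) > 0) stop("counts table lacks column(s): ",
                                paste(missing, collapse = ", "))
  cts$length_nt <- as.integer(cts$length_nt)
  cts$count <- as.numeric(cts$count)
  cts[, c("gene_id", "length_nt", "count")]
}

#' Write a per-gene counts table
#' @param cts data.frame with gene_id, length_nt, count.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(cts, path) {
  write.table(cts[, c("gene_id", "length_nt", "count")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
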