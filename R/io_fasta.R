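#' Read a FASTA file into a named character vector
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that enforces the
#' conventions used throughout the pipeline: record order is preserved,
#' sequences are uppercased, ids must be unique and sequences non-empty.
#' The id is the header token up to the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  empty <- ids[nchar(seqs) == 0]
  if (length(empty) > 0) {
    stop("empty sequence for FASTA id(s): ", paste(empty, collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::BStringSet(as.character(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Reads error-free pipeline FASTQ (quality strings are ignored downstream).
#'
#' @param path Path to an (optionally gzipped) FASTQ file.
#' @return Named character vector of uppercase read sequences.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  reads <- toupper(as.character(set))
  names(reads) <- sub("\\s.*$", "", names(set))
  reads
}

#' Write reads to a FASTQ file with constant quality
#'
#' @param reads Named character vector of read sequences.
#' @param path Output path.
#' @param quality_char Single character used for every base quality (default "I").
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  stopifnot(!is.null(names(reads)))
  lines <- character(4L * length(reads))
  lines[seq(1, length(lines), by = 4)] <- paste0("@", names(reads))
  lines[seq(2, length(lines), by = 4)] <- as.character(reads)
  lines[seq(3, length(lines), by = 4)] <- "+"
  lines[seq(4, length(lines), by = 4)] <-
    vapply(nchar(reads), function(n) strrep(quality_char, n), character(1))
  writeLines(lines, path)
  invisible(path)
}
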