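#' Homology-search parameters
#'
#' Defaults mirror a protein homology screen for cooS/cdhA markers: E-value
#' <= 1e-10, alignment identity >= 30 %, alignment length >= 200 columns,
#' BLOSUM62 with affine gap costs 11/1. Because the search runs in-process,
#' the E-value needs an explicit Karlin-Altschul model: gapped BLOSUM62
#' parameters (lambda = 0.267, K = 0.041) and an effective database size in
#' residues (`db_size_aa`, default 1e7).
#'
#' @param evalue_max Maximum E-value.
#' @param identity_min_pct Minimum alignment identity, percent.
#' @param alnlen_min_aa Minimum alignment length in columns.
#' @param matrix Substitution matrix name (a Biostrings data matrix).
#' @param gap_open,gap_extend Affine gap costs (a gap of length L costs
#'   `gap_open + L * gap_extend`).
#' @param db_size_aa Effective database length in residues for the E-value.
#' @param lambda,K Karlin-Altschul parameters for the gapped matrix.
#' @return List of parameters.
#' @export
search_params <- function(evalue_max = 1e-10, identity_min_pct = 30,
                          alnlen_min_aa = 200, matrix = "BLOSUM62",
                          gap_open = 11, gap_extend = 1,
                          db_size_aa = 1e7, lambda = 0.267, K = 0.041) {
  stopifnot(evalue_max > 0, identity_min_pct > 0, identity_min_pct <= 100,
            alnlen_min_aa > 0)
  list(evalue_max = evalue_max, identity_min_pct = identity_min_pct,
       alnlen_min_aa = alnlen_min_aa, matrix = matrix, gap_open = gap_open,
       gap_extend = gap_extend, db_size_aa = db_size_aa,
       lambda = lambda, K = K)
}

check_protein_alphabet <- function(x, what = "sequence") {
  x <- gsub("\\*$", "", x)
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", x)
  if (any(bad)) stop(what, " contains invalid residue characters")
  if (any(!nzchar(x))) stop(what, " is empty")
  invisible(x)
}

## Batch local alignment of many queries against one subject; returns the
## 12-column tabular hit frame (query = reference, subject = gene).
align_local_batch <- function(query_protein, subject_proteins, params) {
  check_protein_alphabet(query_protein, "query")
  check_protein_alphabet(subject_proteins, "subject")
  qset <- Biostrings::AAString(gsub("\\*$", "", query_protein))
  sset <- Biostrings::AAStringSet(gsub("\\*$", "", subject_proteins))
  aln <- Biostrings::pairwiseAlignment(
    pattern = sset, subject = qset, type = "local",
    substitutionMatrix = params$matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  ## aligned strings: pattern = gene (subject of the hit), subject = reference
  pat <- as.character(Biostrings::alignedPattern(aln))
  sub <- as.character(Biostrings::alignedSubject(aln))
  n <- length(pat)
  aligned <- data.frame(subject_aln = pat, query_aln = sub,
                        stringsAsFactors = FALSE)
  stats <- vapply(seq_len(n), function(i) {
    a <- strsplit(pat[i], "")[[1]]
    b <- strsplit(sub[i], "")[[1]]
    gap_a <- a == "-"; gap_b <- b == "-"
    matches <- sum(!gap_a & !gap_b & a == b)
    mismatches <- sum(!gap_a & !gap_b & a != b)
    gap_opens <- sum(diff(c(FALSE, gap_a)) == 1L) +
      sum(diff(c(FALSE, gap_b)) == 1L)
    c(matches, mismatches, gap_opens, length(a))
  }, numeric(4))
  scores <- Biostrings::score(aln)
  cols <- stats[4, ]
  out <- data.frame(
    query_id = NA_character_,
    subject_id = if (is.null(names(subject_proteins))) NA_character_ else
      names(subject_proteins),
    pct_identity = 100 * stats[1, ] / pmax(cols, 1),
    aln_length = as.integer(cols),
    mismatches = as.integer(stats[2, ]),
    gap_opens = as.integer(stats[3, ]),
    q_start = Biostrings::start(Biostrings::subject(aln)),
    q_end = Biostrings::end(Biostrings::subject(aln)),
    s_start = Biostrings::start(Biostrings::pattern(aln)),
    s_end = Biostrings::end(Biostrings::pattern(aln)),
    evalue = params$K * nchar(query_protein) * params$db_size_aa *
      exp(-params$lambda * scores),
    bit_score = (params$lambda * scores - log(params$K)) / log(2),
    raw_score = scores,
    stringsAsFactors = FALSE
  )
  attr(out, "aligned") <- aligned
  out
}

#' Local protein alignment with search statistics
#'
#' Smith-Waterman local alignment with affine gaps under the configured
#' substitution matrix. Identity is matches / alignment columns x 100; the
#' E-value follows Karlin-Altschul, `E = K * m * n * exp(-lambda * S)`, with
#' m the query length and n the effective database size.
#'
#' @param query_protein Reference (query) protein sequence.
#' @param subject_protein Candidate (subject) protein sequence.
#' @param params A [search_params()] list.
#' @return One-row data.frame in the 12-column tabular-hit layout (plus a
#'   `raw_score` column). The aligned strings are attached as the `aligned`
#'   attribute (data.frame with query_aln, subject_aln).
#' @export
align_local <- function(query_protein, subject_protein,
                        params = search_params()) {
  hit <- align_local_batch(query_protein,
                           stats::setNames(subject_protein, "subject"),
                           params)
  hit$subject_id <- "subject"
  hit
}

hit_passes <- function(hits, params) {
  hits$evalue <= params$evalue_max &
    hits$pct_identity >= params$identity_min_pct &
    hits$aln_length >= params$alnlen_min_aa
}

## Minimum raw score compatible with the E-value cutoff: from
## E = K m n exp(-lambda S) <= evalue_max. Used as an exact prefilter so the
## (costly) traceback runs only on genes that could pass.
min_passing_score <- function(query_len, params) {
  log(params$K * query_len * params$db_size_aa / params$evalue_max) /
    params$lambda
}

local_scores <- function(query_protein, subject_proteins, params) {
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(gsub("\\*$", "", subject_proteins)),
    subject = Biostrings::AAString(gsub("\\*$", "", query_protein)),
    type = "local", substitutionMatrix = params$matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    scoreOnly = TRUE)
}

#' Find candidate pCODH genes in a genome bundle
#'
#' Aligns every gene protein against every clade-representative reference and
#' keeps hits passing all of: E-value <= `evalue_max`, identity >=
#' `identity_min_pct`, alignment length >= `alnlen_min_aa`. One best hit is
#' retained per (reference, gene) pair; a gene is a candidate if at least one
#' reference passes.
#'
#' @param bundle A `genome_bundle`.
#' @param reference_set Output of [make_reference_set()] (or any list with a
#'   `proteins` named character vector).
#' @param params A [search_params()] list.
#' @return data.frame of passing hits with columns genome_id + the tabular
#'   hit columns (query_id = reference id, subject_id = gene id).
#' @export
find_candidates <- function(bundle, reference_set, params = search_params()) {
  refs <- reference_set$proteins
  if (length(refs) == 0) stop("empty reference set")
  genes <- stats::setNames(bundle$genes$protein, bundle$genes$gene_id)
  check_protein_alphabet(genes, "gene protein")
  out <- lapply(names(refs), function(rid) {
    scores <- local_scores(refs[[rid]], genes, params)
    keep <- scores >= min_passing_score(nchar(refs[[rid]]), params) - 1e-9
    if (!any(keep)) return(NULL)
    hits <- align_local_batch(refs[[rid]], genes[keep], params)
    hits$query_id <- rid
    hits[hit_passes(hits, params), , drop = FALSE]
  })
  out <- Filter(Negate(is.null), out)
  if (length(out) == 0) {
    out <- align_local_batch(refs[[1]], genes[1], params)[0, ]
    out$query_id <- character(0)
  } else out <- do.call(rbind, out)
  out <- cbind(genome_id = rep(bundle$genome_id, nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Assign a Ni-CODH clade from passing hits
#'
#' The clade of the reference with the highest alignment identity wins; ties
#' are broken by higher bit score, then by lexicographic clade label.
#'
#' @param gene_id Candidate gene id.
#' @param hits Passing hits for this gene (rows of [find_candidates()] output
#'   with `subject_id == gene_id`).
#' @param clade_map data.frame reference_id -> clade.
#' @return One-row data.frame: gene_id, clade, best_identity_pct,
#'   best_reference_id.
#' @export
assign_clade <- function(gene_id, hits, clade_map) {
  hits <- hits[hits$subject_id == gene_id, , drop = FALSE]
  if (nrow(hits) == 0) stop("no passing hit for gene ", gene_id)
  hits$clade <- clade_map$clade[match(hits$query_id, clade_map$reference_id)]
  ord <- order(-hits$pct_identity, -hits$bit_score, hits$clade)
  best <- hits[ord[1], ]
  data.frame(gene_id = gene_id, clade = best$clade,
             best_identity_pct = best$pct_identity,
             best_reference_id = best$query_id, stringsAsFactors = FALSE)
}

#' Screen a genome for Mo-CODH (CoxL) candidates
#'
#' Genes passing the same alignment thresholds against the CoxL reference
#' AND containing the exact Mo-CODH active-site motif AYRCSFR.
#'
#' @param bundle A `genome_bundle`.
#' @param coxl_reference Named character vector with the CoxL protein.
#' @param params A [search_params()] list.
#' @return Character vector of gene ids (possibly empty).
#' @export
find_mo_codh <- function(bundle, coxl_reference, params = search_params()) {
  stopifnot(length(coxl_reference) == 1)
  genes <- stats::setNames(bundle$genes$protein, bundle$genes$gene_id)
  has_motif <- grepl("AYRCSFR", genes, fixed = TRUE)
  if (!any(has_motif)) return(character(0))
  genes <- genes[has_motif]
  scores <- local_scores(coxl_reference[[1]], genes, params)
  keep <- scores >= min_passing_score(nchar(coxl_reference[[1]]), params) - 1e-9
  if (!any(keep)) return(character(0))
  hits <- align_local_batch(coxl_reference[[1]], genes[keep], params)
  hits$subject_id[hit_passes(hits, params)]
}

#' Screen many genomes and report validated pCODH genes
#'
#' Runs the homolog search, applies the motif filter, and assigns clades to
#' survivors (candidates are filtered first, then clades reported for the
#' validated set).
#'
#' @param bundles List of `genome_bundle`s.
#' @param reference_set Output of [make_reference_set()].
#' @param motif_config A [motif_config()].
#' @param params A [search_params()] list.
#' @return List with `hits` (all passing hits), `candidates` (per-gene clade
#'   calls for all candidates) and `validated` (candidates with
#'   `overall_pass`, i.e. the pCODH set; columns genome_id, gene_id, clade,
#'   best_identity_pct, best_reference_id, overall_pass).
#' @export
screen_genomes <- function(bundles, reference_set,
                           motif_config = default_motif_config(reference_set),
                           params = search_params()) {
  all_hits <- list(); cand_rows <- list()
  for (b in bundles) {
    hits <- find_candidates(b, reference_set, params)
    if (nrow(hits) > 0) all_hits[[length(all_hits) + 1L]] <- hits
    for (gid in unique(hits$subject_id)) {
      call <- assign_clade(gid, hits, reference_set$clade_map)
      prot <- b$genes$protein[b$genes$gene_id == gid]
      ## map motif positions through the best-matching reference when the
      ## candidate belongs to a clade other than the anchor's
      via <- if (call$best_reference_id != motif_config$anchor_reference_id)
        reference_set$proteins[[call$best_reference_id]] else NULL
      report <- check_motifs(prot, motif_config, params, via_sequence = via)
      call$genome_id <- b$genome_id
      call$overall_pass <- report$overall_pass
      cand_rows[[length(cand_rows) + 1L]] <- call
    }
  }
  hits <- if (length(all_hits) > 0) do.call(rbind, all_hits) else NULL
  candidates <- if (length(cand_rows) > 0) do.call(rbind, cand_rows) else
    data.frame(gene_id = character(0), clade = character(0),
               best_identity_pct = numeric(0),
               best_reference_id = character(0), genome_id = character(0),
               overall_pass = logical(0), stringsAsFactors = FALSE)
  cols <- c("genome_id", "gene_id", "clade", "best_identity_pct",
            "best_reference_id", "overall_pass")
  candidates <- candidates[, cols]
  list(hits = hits, candidates = candidates,
       validated = candidates[candidates$overall_pass, , drop = FALSE])
}
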