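#' Construct a motif configuration
#'
#' A motif config names an anchor reference, carries its sequence, and lists
#' the active-site positions to check: the two C-clusters (Ni-Fe-S), the
#' B-cluster and D-cluster (4Fe-4S) and the two acid-base catalysts. Each
#' configured position names the allowed residue(s). Positions are 1-based on
#' the anchor and are mapped onto candidates by global pairwise alignment.
#'
#' @param anchor_reference_id Identifier of the anchor reference.
#' @param anchor_sequence Anchor protein sequence.
#' @param sites data.frame with columns site, position, required (allowed
#'   residues as a string, e.g. "C" or "DE").
#' @param min_map_identity Alignment identity below which position mapping is
#'   considered unreliable and every site is reported `unaligned`
#'   (default 0.20).
#' @return A `motif_config` list.
#' @export
motif_config <- function(anchor_reference_id, anchor_sequence, sites,
                         min_map_identity = 0.20) {
  stopifnot(is.data.frame(sites),
            all(c("site", "position", "required") %in% names(sites)),
            nrow(sites) > 0)
  sites$position <- as.integer(sites$position)
  if (any(sites$position < 1 | sites$position > nchar(anchor_sequence))) {
    stop("motif position outside the anchor sequence")
  }
  if (any(!nzchar(sites$required))) stop("empty required-residue set")
  anchor_aa <- strsplit(anchor_sequence, "")[[1]]
  ok <- mapply(function(p, req) anchor_aa[p] %in% strsplit(req, "")[[1]],
               sites$position, sites$required)
  if (!all(ok)) {
    stop("anchor itself violates configured site(s): ",
         paste(unique(sites$site[!ok]), collapse = ", "))
  }
  structure(list(anchor_reference_id = anchor_reference_id,
                 anchor_sequence = anchor_sequence, sites = sites,
                 min_map_identity = min_map_identity),
            class = "motif_config")
}

#' Default motif configuration for the synthetic reference set
#'
#' Anchored to the clade-F template of [make_reference_set()] with the
#' synthetic stand-in site layout of [synth_motif_sites()]. For real data the
#' config must be re-anchored to a curated CooS reference.
#'
#' @param reference_set Output of [make_reference_set()].
#' @return A `motif_config`.
#' @export
default_motif_config <- function(reference_set) {
  motif_config(reference_set$anchor_id,
               reference_set$proteins[[reference_set$anchor_id]],
               synth_motif_sites())
}

## Global NW alignment of x onto y; returns the position map y -> x (NA at
## gaps) and the matches/columns identity.
align_map <- function(x, y, params) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(x),
    subject = Biostrings::AAString(y),
    type = "global", substitutionMatrix = params$matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  identity <- sum(a != "-" & b != "-" & a == b) / length(a)
  map <- rep(NA_integer_, nchar(y))
  x_pos <- cumsum(a != "-")
  y_pos <- cumsum(b != "-")
  keep <- b != "-" & a != "-"
  map[y_pos[keep]] <- x_pos[keep]
  list(map = map, identity = identity)
}

#' Map anchor positions onto a candidate protein
#'
#' Global (Needleman-Wunsch) pairwise alignment of the candidate to the
#' anchor under the same matrix and gap costs as the homology search; each
#' anchor position maps to a candidate position or to a gap (NA). If the
#' alignment identity falls below `min_map_identity` the mapping is flagged
#' unreliable and downstream sites are reported `unaligned`.
#'
#' For candidates distant from the anchor (e.g. members of another clade at
#' 25-30 % anchor identity), direct pairwise mapping can locally misplace
#' isolated single-residue sites. Passing the candidate's best-matching
#' reference as `via_sequence` routes the mapping through two high-identity
#' alignments (anchor -> reference -> candidate) and composes them, which is
#' the pairwise analogue of the positional homology a multiple alignment
#' provides.
#'
#' @param candidate_protein Candidate protein sequence.
#' @param config A [motif_config()].
#' @param params A [search_params()] list (matrix and gap costs are used).
#' @param via_sequence Optional intermediate reference protein through which
#'   the mapping is composed.
#' @return List with `map` (integer vector over anchor positions; NA = gap),
#'   `identity` (the smaller matches/columns identity of the alignments
#'   used) and `unaligned` (logical).
#' @export
map_anchor_positions <- function(candidate_protein, config,
                                 params = search_params(),
                                 via_sequence = NULL) {
  check_protein_alphabet(candidate_protein, "candidate")
  cand <- gsub("\\*$", "", candidate_protein)
  if (is.null(via_sequence)) {
    am <- align_map(cand, config$anchor_sequence, params)
    map <- am$map
    identity <- am$identity
  } else {
    via <- gsub("\\*$", "", via_sequence)
    m1 <- align_map(via, config$anchor_sequence, params)  # anchor -> via
    m2 <- align_map(cand, via, params)                    # via -> candidate
    map <- rep(NA_integer_, nchar(config$anchor_sequence))
    ok <- !is.na(m1$map)
    map[ok] <- m2$map[m1$map[ok]]
    identity <- min(m1$identity, m2$identity)
  }
  list(map = map, identity = identity,
       unaligned = identity < config$min_map_identity)
}

#' Check active-site motif conservation of a candidate
#'
#' A site is `intact` iff every configured position maps to a non-gap
#' candidate residue in the allowed set; `deleted` if any position maps to a
#' gap; otherwise `substituted` if any mapped residue differs. When the
#' anchor mapping is unreliable all sites are `unaligned`. `overall_pass` is
#' true iff every site is intact (no substitutions and no deletions in any
#' cluster or catalyst site).
#'
#' @param candidate_protein Candidate protein sequence.
#' @param config A [motif_config()].
#' @param params A [search_params()] list.
#' @param via_sequence Optional intermediate reference for position mapping
#'   (see [map_anchor_positions()]).
#' @return List with `status` (named character per site) and `overall_pass`.
#' @export
check_motifs <- function(candidate_protein, config, params = search_params(),
                         via_sequence = NULL) {
  mapping <- map_anchor_positions(candidate_protein, config, params,
                                  via_sequence)
  site_names <- unique(config$sites$site)
  cand_aa <- strsplit(gsub("\\*$", "", candidate_protein), "")[[1]]
  status <- vapply(site_names, function(s) {
    rows <- config$sites[config$sites$site == s, , drop = FALSE]
    if (mapping$unaligned) return("unaligned")
    pos <- mapping$map[rows$position]
    if (anyNA(pos)) return("deleted")
    ok <- mapply(function(p, req) cand_aa[p] %in% strsplit(req, "")[[1]],
                 pos, rows$required)
    if (all(ok)) "intact" else "substituted"
  }, character(1))
  list(status = status, overall_pass = all(status == "intact"))
}

#' Build per-candidate motif reports
#'
#' @param proteins Named character vector of candidate proteins.
#' @param config A [motif_config()].
#' @param params A [search_params()] list.
#' @return data.frame with gene_id, one column per site, overall_pass.
#' @export
motif_report <- function(proteins, config, params = search_params()) {
  rows <- lapply(names(proteins), function(gid) {
    res <- check_motifs(proteins[[gid]], config, params)
    cbind(data.frame(gene_id = gid, stringsAsFactors = FALSE),
          as.data.frame(as.list(res$status), stringsAsFactors = FALSE),
          data.frame(overall_pass = res$overall_pass))
  })
  do.call(rbind, rows)
}

#' Check the PFL Cys-Cys active site
#'
#' K00656 covers pyruvate formate-lyase-like proteins without PFL activity;
#' only sequences conserving the adjacent catalytic Cys-Cys pair are counted
#' as potential PFL. The candidate is globally aligned to the PFL anchor and
#' both configured positions must map to cysteine. Unalignable sequences
#' fail.
#'
#' @param candidate_protein Protein sequence of a K00656-annotated gene.
#' @param pfl_config Output of [default_pfl_config()] (anchor + positions).
#' @param params A [search_params()] list.
#' @return TRUE iff both Cys positions are conserved.
#' @export
check_pfl_active_site <- function(candidate_protein,
                                  pfl_config = default_pfl_config(),
                                  params = search_params()) {
  cfg <- motif_config("PFL_anchor", pfl_config$anchor_sequence,
                      data.frame(site = "pfl_CC",
                                 position = pfl_config$positions,
                                 required = "C", stringsAsFactors = FALSE))
  res <- tryCatch(check_motifs(candidate_protein, cfg, params),
                  error = function(e) NULL)
  !is.null(res) && isTRUE(res$overall_pass)
}

#' Write a motif config to a YAML file
#' @param config A `motif_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_config <- function(config, path) {
  yaml::write_yaml(list(
    anchor_reference_id = config$anchor_reference_id,
    anchor_sequence = config$anchor_sequence,
    min_map_identity = config$min_map_identity,
    sites = lapply(seq_len(nrow(config$sites)), function(i) {
      as.list(config$sites[i, c("site", "position", "required")])
    })), path)
  invisible(path)
}

#' Read a motif config from a YAML file
#' @param path Path to the YAML config.
#' @return A `motif_config`.
#' @export
read_motif_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sites <- do.call(rbind, lapply(raw$sites, function(s) {
    data.frame(site = s$site, position = as.integer(s$position),
               required = s$required, stringsAsFactors = FALSE)
  }))
  motif_config(raw$anchor_reference_id, raw$anchor_sequence, sites,
               min_map_identity = raw$min_map_identity)
}
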