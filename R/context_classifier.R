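#' Default marker rules for the eight genomic context types
#'
#' Each type is a set of marker groups; a group is satisfied when any member
#' gene of the window (focal excluded) carries one of its KO/COG identifiers,
#' and a type has evidence when at least `min_groups` of its groups are
#' satisfied. Single-marker types use one group. The ABC-transporter type
#' requires all three subunit groups (K02049/COG0715, K02050/COG0600,
#' K02051/COG1116) across the window; `abc_min_groups` relaxes this to 2 if
#' desired.
#'
#' @param abc_min_groups Number of ABC subunit groups required (default 3).
#' @return Named list of rules (groups + min_groups), in precedence order.
#' @export
default_marker_rules <- function(abc_min_groups = 3L) {
  list(
    WLP = list(groups = list(c("K14138", "COG1614")), min_groups = 1L),
    PEPCK = list(groups = list(c("K01610", "COG1866")), min_groups = 1L),
    FNOR = list(groups = list("COG1251"), min_groups = 1L),
    ABC_transporter = list(groups = list(c("K02049", "COG0715"),
                                         c("K02050", "COG0600"),
                                         c("K02051", "COG1116")),
                           min_groups = as.integer(abc_min_groups)),
    Fe_hydrogenase = list(groups = list("COG4624"), min_groups = 1L),
    MFS_transporter = list(groups = list(c("K08177", "COG2223")),
                           min_groups = 1L),
    uncharacterized_dehydrogenase = list(groups = list(c("K00004", "COG1063")),
                                         min_groups = 1L),
    cysteine_synthase = list(groups = list(c("K01738", "COG0031")),
                             min_groups = 1L)
  )
}

#' Default auxiliary-gene rules
#'
#' Symbols tallied within windows without affecting type assignment. The
#' narGHIJK KO set is a curated default (the nitrate-reduction operon); all
#' rules are editable.
#'
#' @return Named list symbol -> character vector of KO/COG ids.
#' @export
default_aux_rules <- function() {
  list(
    oxyR = c("K04761", "COG0583"),
    narGHIJK = c("K00370", "K00371", "K00373", "K00374", "K02575"),
    pflAB = c("K04069", "K00656"),
    hypAB = c("K04651", "K04652"),
    cooC = "K07321",
    cooF = c("K00196", "COG0437", "COG1142")
  )
}

#' Extract the rank window around a focal gene
#'
#' Members are the genes on the focal contig whose rank lies within
#' `radius` of the focal gene's rank, regardless of strand; contig edges
#' truncate the window.
#'
#' @param bundle A `genome_bundle`.
#' @param focal_gene_id Focal gene id.
#' @param radius Rank radius (default 15).
#' @return List with focal_gene_id, genome_id, contig_id and `members` (gene
#'   table rows plus a signed `offset` column, ordered by rank).
#' @export
extract_window <- function(bundle, focal_gene_id, radius = 15L) {
  g <- bundle$genes
  row <- g[g$gene_id == focal_gene_id, , drop = FALSE]
  if (nrow(row) == 0) stop("unknown gene_id: ", focal_gene_id)
  members <- g[g$contig_id == row$contig_id &
                 abs(g$rank - row$rank) <= radius, , drop = FALSE]
  members <- members[order(members$rank), , drop = FALSE]
  members$offset <- members$rank - row$rank
  list(focal_gene_id = focal_gene_id, genome_id = bundle$genome_id,
       contig_id = row$contig_id, members = members)
}

gene_markers <- function(members) {
  mapply(function(k, c) union(split_ids(k)[[1]], split_ids(c)[[1]]),
         members$ko, members$cog, SIMPLIFY = FALSE)
}

#' Match context-type markers within a window
#'
#' The focal gene itself is excluded from matching (it may carry misleading
#' annotations). For each type, evidence lists the member genes whose KO/COG
#' sets intersect the type's markers, and `satisfied` says whether the type's
#' combination rule (min_groups) holds.
#'
#' @param window Output of [extract_window()].
#' @param marker_rules Rules from [default_marker_rules()].
#' @return List with `evidence` (type -> data.frame gene_id, marker) and
#'   `satisfied` (named logical).
#' @export
match_markers <- function(window, marker_rules = default_marker_rules()) {
  members <- window$members[window$members$gene_id != window$focal_gene_id, ,
                            drop = FALSE]
  marks <- gene_markers(members)
  evidence <- list(); satisfied <- logical(0)
  for (type in names(marker_rules)) {
    rule <- marker_rules[[type]]
    all_markers <- unique(unlist(rule$groups))
    rows <- list()
    for (i in seq_len(nrow(members))) {
      hit <- intersect(marks[[i]], all_markers)
      if (length(hit) > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = members$gene_id[i], marker = paste(hit, collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
    ev <- if (length(rows) > 0) do.call(rbind, rows) else
      data.frame(gene_id = character(0), marker = character(0),
                 stringsAsFactors = FALSE)
    groups_ok <- vapply(rule$groups, function(gset) {
      any(vapply(marks, function(m) length(intersect(m, gset)) > 0,
                 logical(1)))
    }, logical(1))
    evidence[[type]] <- ev
    satisfied[type] <- sum(groups_ok) >= rule$min_groups
  }
  list(evidence = evidence, satisfied = satisfied)
}

#' Assign a context type from marker evidence
#'
#' Pure function of the evidence: the highest-precedence satisfied type wins,
#' in the order WLP > PEPCK > FNOR > ABC_transporter > Fe_hydrogenase >
#' MFS_transporter > uncharacterized_dehydrogenase > cysteine_synthase;
#' `unclassified` when none is satisfied. Co-occurring secondary evidence is
#' preserved in the evidence map, never discarded.
#'
#' @param marker_evidence Output of [match_markers()].
#' @return Character scalar type name.
#' @export
assign_type <- function(marker_evidence) {
  for (type in context_types()) {
    if (isTRUE(marker_evidence$satisfied[[type]])) return(type)
  }
  "unclassified"
}

#' Tally auxiliary genes within a window
#'
#' @param window Output of [extract_window()].
#' @param aux_rules Rules from [default_aux_rules()].
#' @return Named list symbol -> character vector of gene ids (focal excluded).
#' @export
tally_auxiliary <- function(window, aux_rules = default_aux_rules()) {
  members <- window$members[window$members$gene_id != window$focal_gene_id, ,
                            drop = FALSE]
  marks <- gene_markers(members)
  lapply(aux_rules, function(markers) {
    members$gene_id[vapply(marks, function(m) {
      length(intersect(m, markers)) > 0
    }, logical(1))]
  })
}

#' Classify the genomic contexts of validated pCODH genes
#'
#' @param bundles Named list of `genome_bundle`s (names = genome ids) or a
#'   plain list.
#' @param validated data.frame with genome_id and gene_id of validated genes.
#' @param radius Rank radius (default 15).
#' @param marker_rules Rules from [default_marker_rules()].
#' @param aux_rules Rules from [default_aux_rules()].
#' @return data.frame with one row per focal gene: genome_id, gene_id,
#'   assigned_type, evidence_genes, evidence_types, auxiliary.
#' @export
classify_contexts <- function(bundles, validated, radius = 15L,
                              marker_rules = default_marker_rules(),
                              aux_rules = default_aux_rules()) {
  by_id <- stats::setNames(bundles,
                           vapply(bundles, `[[`, character(1), "genome_id"))
  rows <- lapply(seq_len(nrow(validated)), function(i) {
    b <- by_id[[validated$genome_id[i]]]
    if (is.null(b)) stop("no bundle for genome ", validated$genome_id[i])
    w <- extract_window(b, validated$gene_id[i], radius)
    ev <- match_markers(w, marker_rules)
    aux <- tally_auxiliary(w, aux_rules)
    type <- assign_type(ev)
    ev_genes <- if (type == "unclassified") "" else
      paste(ev$evidence[[type]]$gene_id, collapse = ";")
    data.frame(
      genome_id = validated$genome_id[i], gene_id = validated$gene_id[i],
      assigned_type = type, evidence_genes = ev_genes,
      evidence_types = paste(names(ev$satisfied)[ev$satisfied],
                             collapse = ";"),
      auxiliary = paste(names(aux)[lengths(aux) > 0], collapse = ";"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(
    genome_id = character(0), gene_id = character(0),
    assigned_type = character(0), evidence_genes = character(0),
    evidence_types = character(0), auxiliary = character(0),
    stringsAsFactors = FALSE)
  out
}
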