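#' Default symbol-to-KO map for WLP profiling
#'
#' Gene symbols of the Wood-Ljungdahl pathway, its accessory machinery and
#' the formate-acquisition routes, each mapped to its KEGG-orthology ids.
#' `oxlT` (K08177) deliberately also appears among the MFS context markers
#' (documented overlap). `fdh_other` covers non-catalytic Fdh subunits; the
#' catalytic K00123 is kept under `fdoG` only so no KO is mapped to two
#' symbols.
#'
#' @return Named list symbol -> character vector of KO ids.
#' @export
default_symbol_map <- function() {
  list(
    cooC = "K07321", cooF = "K00196",
    acsB = "K14138", acsC = "K00197", acsD = "K00194", acsE = "K15023",
    cdhC = "K00193",
    fhs = "K01938", folD = "K01491", metF = "K00297", metV = "K25007",
    rnfA = "K03617", rnfB = "K03616", rnfC = "K03615", rnfD = "K03614",
    rnfE = "K03612", rnfG = "K03613", rnfC2 = "K25008",
    ech = c("K15830", "K15832"),
    hdrA = "K03388", hdrB = "K03389", hdrC = "K03390", mvhD = "K14127",
    por = "K03737",
    porA = "K00169", porB = "K00170", porC = "K00171", porD = "K00172",
    fdhA = "K05299", fdhF = "K22015", fdoG = "K00123",
    fdh_other = c("K00122", "K00124", "K00125", "K00126", "K00127",
                  "K22515", "K22516"),
    focB = "K03459", focA = "K06212", oxlT = "K08177", yfdC = "K21990",
    fdhC = "K21993",
    pfl = c("K04069", "K00656")
  )
}

FDH_CATALYTIC <- c("fdhA", "fdhF", "fdoG")
FORMATE_TRANSPORTERS <- c("focA", "focB", "oxlT", "yfdC", "fdhC")

#' Which genomes carry a Cys-Cys-validated PFL
#'
#' @param bundles List of `genome_bundle`s.
#' @param pfl_config Output of [default_pfl_config()].
#' @param params A [search_params()] list.
#' @return Named logical over genome ids.
#' @export
validated_pfl_flags <- function(bundles, pfl_config = default_pfl_config(),
                                params = search_params()) {
  vapply(bundles, function(b) {
    kos <- split_ids(b$genes$ko)
    idx <- which(vapply(kos, function(k) "K00656" %in% k, logical(1)))
    any(vapply(idx, function(i) {
      check_pfl_active_site(b$genes$protein[i], pfl_config, params)
    }, logical(1)))
  }, logical(1), USE.NAMES = FALSE) |>
    stats::setNames(vapply(bundles, `[[`, character(1), "genome_id"))
}

#' Build a genome x symbol presence matrix
#'
#' `presence[genome, symbol]` is TRUE iff any gene of the genome carries any
#' KO of the symbol; multi-KO genes count toward every matched symbol. With
#' `validate_pfl = TRUE` (the default, mirroring the Cys-Cys filter) a
#' K00656-annotated gene counts toward `pfl` only if its protein conserves
#' the Cys-Cys active site; K04069 (pflA) counts as annotated.
#'
#' @param bundles List of `genome_bundle`s.
#' @param symbol_map Named list from [default_symbol_map()].
#' @param validate_pfl Apply the Cys-Cys filter to K00656 genes.
#' @param pfl_config PFL anchor config.
#' @param params A [search_params()] list.
#' @return Logical matrix, rownames = genome ids, colnames = symbols, with an
#'   attribute `fdh_gs_coannotated` counting genes carrying both an Fdh
#'   catalytic KO and the glutamate-synthase KO K00266 (reported, never
#'   excluded).
#' @export
build_presence_matrix <- function(bundles, symbol_map = default_symbol_map(),
                                  validate_pfl = TRUE,
                                  pfl_config = default_pfl_config(),
                                  params = search_params()) {
  if (length(symbol_map) == 0) stop("empty symbol map")
  genome_ids <- vapply(bundles, `[[`, character(1), "genome_id")
  mat <- matrix(FALSE, nrow = length(bundles), ncol = length(symbol_map),
                dimnames = list(genome_ids, names(symbol_map)))
  fdh_kos <- unique(unlist(symbol_map[intersect(FDH_CATALYTIC,
                                                names(symbol_map))]))
  coann <- 0L
  for (i in seq_along(bundles)) {
    b <- bundles[[i]]
    kos <- split_ids(b$genes$ko)
    for (sym in names(symbol_map)) {
      target <- symbol_map[[sym]]
      hit_genes <- which(vapply(kos, function(k) {
        length(intersect(k, target)) > 0
      }, logical(1)))
      if (validate_pfl && sym == "pfl" && length(hit_genes) > 0) {
        hit_genes <- Filter(function(j) {
          k <- kos[[j]]
          if (!"K00656" %in% k) return(TRUE)  # pflA-only annotation
          "K04069" %in% setdiff(k, "K00656") ||
            check_pfl_active_site(b$genes$protein[j], pfl_config, params)
        }, hit_genes)
      }
      mat[i, sym] <- length(hit_genes) > 0
    }
    coann <- coann + sum(vapply(kos, function(k) {
      length(intersect(k, fdh_kos)) > 0 && "K00266" %in% k
    }, logical(1)))
  }
  attr(mat, "fdh_gs_coannotated") <- coann
  mat
}

#' Classify one genome's WLP completeness and formate route
#'
#' A genome is pCODH/ACS-encoding iff it carries a validated pCODH gene AND
#' acsB (K14138). `fdh_status` is `fdh_lacking` iff none of the Fdh catalytic
#' subunits (fdhA, fdhF, fdoG) is present. The formate route is the first
#' available of: fdh (any catalytic subunit), pfl (Cys-Cys-validated PFL),
#' transporter (any of focA/focB/oxlT/yfdC/fdhC), none.
#'
#' @param presence_row Named logical vector (one presence-matrix row).
#' @param has_validated_pcodh Does the genome carry a motif-validated pCODH?
#' @param pfl_validated Does the genome carry a Cys-Cys-validated PFL?
#' @return One-row data.frame: is_pcodh_acs, fdh_status, formate_route.
#' @export
classify_genome <- function(presence_row, has_validated_pcodh,
                            pfl_validated) {
  has_fdh <- any(presence_row[FDH_CATALYTIC])
  route <- if (has_fdh) "fdh" else if (isTRUE(pfl_validated)) "pfl" else
    if (any(presence_row[FORMATE_TRANSPORTERS])) "transporter" else "none"
  data.frame(
    is_pcodh_acs = isTRUE(has_validated_pcodh) &&
      isTRUE(unname(presence_row["acsB"])),
    fdh_status = if (has_fdh) "has_any_fdh" else "fdh_lacking",
    formate_route = route, stringsAsFactors = FALSE)
}

#' Profile many genomes
#'
#' @param bundles List of `genome_bundle`s.
#' @param validated_genomes Character vector of genome ids carrying at least
#'   one motif-validated pCODH gene.
#' @param symbol_map Named list from [default_symbol_map()].
#' @param validate_pfl Apply the Cys-Cys filter (default TRUE).
#' @param pfl_config PFL anchor config.
#' @param params A [search_params()] list.
#' @return List with `presence` (matrix) and `profiles` (data.frame
#'   genome_id, is_pcodh_acs, fdh_status, formate_route).
#' @export
profile_genomes <- function(bundles, validated_genomes,
                            symbol_map = default_symbol_map(),
                            validate_pfl = TRUE,
                            pfl_config = default_pfl_config(),
                            params = search_params()) {
  presence <- build_presence_matrix(bundles, symbol_map, validate_pfl,
                                    pfl_config, params)
  pfl_ok <- validated_pfl_flags(bundles, pfl_config, params)
  rows <- lapply(rownames(presence), function(gid) {
    cbind(data.frame(genome_id = gid, stringsAsFactors = FALSE),
          classify_genome(presence[gid, ], gid %in% validated_genomes,
                          pfl_ok[[gid]]))
  })
  list(presence = presence, profiles = do.call(rbind, rows))
}

#' Per-genus presence proportions
#'
#' Fraction of genomes in each genus carrying each symbol; genomes with an
#' empty genus label are grouped as `unassigned`. Weighted by genome counts,
#' genus rows reaggregate exactly to the global fraction.
#'
#' @param presence Presence matrix from [build_presence_matrix()].
#' @param taxonomy data.frame with genome_id and genus columns.
#' @param symbols Symbols to report (default all columns).
#' @return data.frame: genus, n_genomes, one fraction column per symbol.
#' @export
genus_proportions <- function(presence, taxonomy,
                              symbols = colnames(presence)) {
  genus <- taxonomy$genus[match(rownames(presence), taxonomy$genome_id)]
  genus[is.na(genus) | !nzchar(genus)] <- "unassigned"
  out <- lapply(split(seq_len(nrow(presence)), genus), function(idx) {
    fr <- colMeans(presence[idx, symbols, drop = FALSE])
    cbind(data.frame(n_genomes = length(idx)),
          as.data.frame(as.list(fr), check.names = FALSE))
  })
  res <- do.call(rbind, out)
  res <- cbind(data.frame(genus = rownames(res), stringsAsFactors = FALSE),
               res)
  rownames(res) <- NULL
  res[order(res$genus), , drop = FALSE]
}
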