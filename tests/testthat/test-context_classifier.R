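test_that("windows are rank-based, strand-agnostic and edge-truncated", {
  pg <- fx_wlp_genome()
  focal <- fx_focal_gene(pg)
  w <- extract_window(pg$bundle, focal)
  expect_lte(nrow(w$members), 31L)
  expect_true(all(abs(w$members$offset) <= 15))
  expect_equal(w$members$offset[w$members$gene_id == focal], 0L)
  expect_equal(length(unique(w$members$contig_id)), 1L)

  # focal near the contig start: truncated window
  g2 <- pg$bundle$genes$gene_id[pg$bundle$genes$contig_id == "c1" &
                                  pg$bundle$genes$rank == 2]
  w2 <- extract_window(pg$bundle, g2)
  expect_equal(nrow(w2$members), 2 + 15 + 1)
  expect_error(extract_window(pg$bundle, "nope"), "unknown gene_id")
})

test_that("windows of adjacent focal genes are independent and complete", {
  pg <- fx_wlp_genome()
  g <- pg$bundle$genes
  ids <- g$gene_id[g$contig_id == "c1" & g$rank %in% c(15, 17)]
  w1 <- extract_window(pg$bundle, ids[1])
  w2 <- extract_window(pg$bundle, ids[2])
  expect_equal(nrow(w1$members), 31L)
  expect_equal(nrow(w2$members), 31L)
  expect_gt(length(intersect(w1$members$gene_id, w2$members$gene_id)), 0L)
})

test_that("marker matching follows the documented combination rules", {
  pg <- fx_wlp_genome()
  w <- extract_window(pg$bundle, fx_focal_gene(pg))
  ev <- match_markers(w)
  expect_true(ev$satisfied[["WLP"]])
  expect_gt(nrow(ev$evidence$WLP), 0L)

  # two of three ABC subunits are not enough by default, but satisfy min 2
  w2 <- w
  w2$members$ko[2] <- "K02049"
  w2$members$ko[3] <- "K02050"
  ev2 <- match_markers(w2)
  expect_false(ev2$satisfied[["ABC_transporter"]])
  ev2b <- match_markers(w2, default_marker_rules(abc_min_groups = 2))
  expect_true(ev2b$satisfied[["ABC_transporter"]])

  # unannotated window: no evidence at all
  spec <- plant_spec("TEMPTY", NULL, data.frame(
    template_name = "REF_B", target_identity = 0.8, motif_state = "intact",
    contig_id = "c1", rank_slot = 16L, strand = "+", stringsAsFactors = FALSE),
    context_type = "none", seed = 61)
  pg0 <- plant_genome(spec, fx_reference_set())
  ev0 <- match_markers(extract_window(pg0$bundle, fx_focal_gene(pg0)))
  expect_true(all(!ev0$satisfied))
  expect_equal(assign_type(ev0), "unclassified")
})

test_that("the focal gene's own annotations never count as evidence", {
  pg <- fx_wlp_genome()
  focal <- fx_focal_gene(pg)
  b <- pg$bundle
  g <- b$genes
  g$ko[g$gene_id == focal] <- "COG1251"  # misleading annotation on focal
  spec_none_bundle <- genome_bundle("TFOC", NULL, b$contigs, g)
  w <- extract_window(spec_none_bundle, focal)
  ev <- match_markers(w)
  expect_false(ev$satisfied[["FNOR"]])
})

test_that("type assignment resolves co-occurring evidence by precedence", {
  pg <- fx_wlp_genome()
  b <- pg$bundle
  g <- b$genes
  focal <- fx_focal_gene(pg)
  slot <- which(g$contig_id == "c1" & g$rank == 12)
  g$cog[slot] <- "COG1251"  # add FNOR evidence inside the WLP window
  b2 <- genome_bundle("TPREC", NULL, b$contigs, g)
  ev <- match_markers(extract_window(b2, focal))
  expect_true(ev$satisfied[["WLP"]] && ev$satisfied[["FNOR"]])
  expect_equal(assign_type(ev), "WLP")
  # secondary evidence is preserved, not discarded
  expect_gt(nrow(ev$evidence$FNOR), 0L)
})

test_that("all eight planted context types are recovered", {
  rs <- fx_reference_set()
  for (ct in context_types()) {
    spec <- plant_spec(paste0("T8_", ct), NULL, data.frame(
      template_name = "REF_E", target_identity = 0.75,
      motif_state = "intact", contig_id = "c1", rank_slot = 16L,
      strand = "+", stringsAsFactors = FALSE),
      context_type = ct, seed = 71)
    pg <- plant_genome(spec, rs)
    w <- extract_window(pg$bundle, fx_focal_gene(pg))
    expect_equal(assign_type(match_markers(w)), ct)
  }
})

test_that("growing the radius never removes marker evidence", {
  rs <- fx_reference_set()
  spec <- plant_spec("TRAD", NULL, data.frame(
    template_name = "REF_E", target_identity = 0.75, motif_state = "intact",
    contig_id = "c1", rank_slot = 16L, strand = "+", stringsAsFactors = FALSE),
    context_type = "Fe_hydrogenase", seed = 73)
  pg <- plant_genome(spec, rs)
  focal <- fx_focal_gene(pg)
  prev <- character(0)
  for (r in c(2L, 5L, 10L, 15L)) {
    w <- extract_window(pg$bundle, focal, radius = r)
    ev <- match_markers(w)
    now <- names(ev$satisfied)[ev$satisfied]
    expect_true(all(prev %in% now))
    expect_lte(nrow(w$members), 2L * r + 1L)
    prev <- now
  }
})

test_that("auxiliary genes are tallied by symbol", {
  rs <- fx_reference_set()
  spec <- plant_spec("TAUX", NULL, data.frame(
    template_name = "REF_E", target_identity = 0.75, motif_state = "intact",
    contig_id = "c1", rank_slot = 16L, strand = "+", stringsAsFactors = FALSE),
    context_type = "PEPCK", seed = 79)
  pg <- plant_genome(spec, rs)
  focal <- fx_focal_gene(pg)
  b <- pg$bundle
  g <- b$genes
  g$ko[g$contig_id == "c1" & g$rank == 13] <- "K00196"  # cooF
  b2 <- genome_bundle("TAUX", NULL, b$contigs, g)
  aux <- tally_auxiliary(extract_window(b2, focal))
  expect_length(aux$oxyR, 1L)   # planted adjacent upstream of focal
  expect_length(aux$cooF, 1L)
  expect_length(aux$narGHIJK, 0L)
})

test_that("classify_contexts reports one typed row per focal gene", {
  pg <- fx_wlp_genome()
  validated <- data.frame(genome_id = pg$bundle$genome_id,
                          gene_id = fx_focal_gene(pg),
                          stringsAsFactors = FALSE)
  out <- classify_contexts(list(pg$bundle), validated)
  expect_equal(out$assigned_type, "WLP")
  expect_match(out$auxiliary, "cooC")
})
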