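test_that("the reference set has six divergent motif-bearing templates", {
  rs <- fx_reference_set()
  expect_length(rs$proteins, 6L)
  expect_true(all(nchar(rs$proteins) >= 600))
  expect_setequal(rs$clade_map$clade, c("B", "C", "D", "E", "F", "mini"))
  pairs <- utils::combn(names(rs$proteins), 2)
  pid <- apply(pairs, 2, function(p) {
    global_identity(rs$proteins[[p[1]]], rs$proteins[[p[2]]])
  })
  expect_true(all(pid < 0.60))
  sites <- synth_motif_sites()
  for (prot in rs$proteins) {
    aa <- strsplit(prot, "")[[1]]
    ok <- mapply(function(p, req) aa[p] %in% strsplit(req, "")[[1]],
                 sites$position, sites$required)
    expect_true(all(ok))
  }
})

test_that("the reference set is deterministic under a fixed seed", {
  expect_identical(make_reference_set(42), make_reference_set(42))
  expect_false(identical(make_reference_set(42)$proteins,
                         make_reference_set(43)$proteins))
})

test_that("mutate_to_identity realizes the target and honors protection", {
  rs <- fx_reference_set()
  tpl <- rs$proteins[["REF_E"]]
  expect_identical(mutate_to_identity(tpl, 1.0, seed = 1), tpl)
  sites <- synth_motif_sites()
  for (t in c(0.5, 0.7, 0.9)) {
    mut <- mutate_to_identity(tpl, t, protected_positions = sites$position,
                              seed = 11)
    expect_lt(abs(global_identity(tpl, mut) - t), 0.02)
    aa_t <- strsplit(tpl, "")[[1]]; aa_m <- strsplit(mut, "")[[1]]
    expect_true(all(aa_m[sites$position] == aa_t[sites$position]))
  }
  expect_error(
    mutate_to_identity("MKVL", 0, protected_positions = 1:3, seed = 1),
    "infeasible")
})

test_that("planted WLP context places acsB within 15 ranks of the focal gene", {
  pg <- fx_wlp_genome()
  focal <- fx_focal_gene(pg)
  marker <- pg$truth[pg$truth$fact_type == "context_marker" &
                       pg$truth$key == "acsB", ]
  expect_equal(nrow(marker), 1L)
  g <- pg$bundle$genes
  expect_true("K14138" %in% split_ids(g$ko[g$gene_id == marker$gene_id])[[1]])
  rank_focal <- g$rank[g$gene_id == focal]
  rank_marker <- g$rank[g$gene_id == marker$gene_id]
  expect_lte(abs(rank_marker - rank_focal), 15L)
})

test_that("planted motif damage and bare contexts are recorded as ground truth", {
  rs <- fx_reference_set()
  spec <- plant_spec("TDMG", NULL, data.frame(
    template_name = "REF_C", target_identity = 0.8,
    motif_state = "substituted", contig_id = "c1", rank_slot = 16L,
    strand = "+", stringsAsFactors = FALSE), seed = 31)
  pg <- plant_genome(spec, rs)
  expect_identical(
    pg$truth$value[pg$truth$key == "expected_pass"], "FALSE")

  spec_none <- plant_spec("TNONE", NULL, data.frame(
    template_name = "REF_C", target_identity = 0.8, motif_state = "intact",
    contig_id = "c1", rank_slot = 16L, strand = "+",
    stringsAsFactors = FALSE), context_type = "none", seed = 32)
  pg2 <- plant_genome(spec_none, rs)
  w <- extract_window(pg2$bundle, fx_focal_gene(pg2))
  others <- w$members[w$members$offset != 0, ]
  expect_true(all(!nzchar(others$ko)) && all(!nzchar(others$cog)))
})

test_that("rank slots that cannot host the context window are rejected", {
  rs <- fx_reference_set()
  spec <- plant_spec("TEDGE", NULL, data.frame(
    template_name = "REF_B", target_identity = 0.8, motif_state = "intact",
    contig_id = "c1", rank_slot = 0L, strand = "+", stringsAsFactors = FALSE),
    context_type = "uncharacterized_dehydrogenase", seed = 33)
  expect_error(plant_genome(spec, rs), "contig too small")
})

test_that("simulated reads come from the weighted genes and are reproducible", {
  co <- fx_quant_cohort()
  ab <- stats::setNames(c(1, 0, 0), co$focals)
  sim <- simulate_reads(co$bundles, ab, read_length = 80, n_reads = 200,
                        seed = 9)
  g <- co$ref_genes[[co$focals[1]]]
  in_gene <- vapply(sim$reads, function(r) {
    grepl(r, g, fixed = TRUE) || grepl(revcomp(r), g, fixed = TRUE)
  }, logical(1))
  expect_true(all(in_gene))
  expect_equal(sum(sim$truth_counts$count), 200)

  sim2 <- simulate_reads(co$bundles, ab, read_length = 80, n_reads = 200,
                         seed = 9)
  expect_identical(sim$reads, sim2$reads)
  expect_error(simulate_reads(co$bundles, ab * 0, 80, 10, 1), "all-zero")
})

test_that("read counts follow the weight x length sampling law", {
  co <- fx_quant_cohort()
  # two genes of equal length, weights 1 and 3
  ab <- stats::setNames(c(1, 3, 0), co$focals)
  lens <- nchar(co$ref_genes[co$focals])
  expect_equal(lens[[1]], lens[[2]])  # same template length by construction
  sim <- simulate_reads(co$bundles, ab, read_length = 100, n_reads = 10000,
                        seed = 21)
  cts <- stats::setNames(sim$truth_counts$count, sim$truth_counts$gene_id)
  p_hat <- cts[[co$focals[2]]] / 10000
  se <- sqrt(0.75 * 0.25 / 10000)
  expect_lt(abs(p_hat - 0.75), 4 * se)
})
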