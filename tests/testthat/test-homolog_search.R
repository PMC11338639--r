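test_that("align_local reports exact identity on identical sequences", {
  withr::with_seed(5, {
    p <- random_protein_str(300)
    hit <- align_local(p, p)
    expect_equal(hit$pct_identity, 100)
    expect_equal(hit$aln_length, 300L)
    expect_equal(hit$q_start, 1L)
    expect_equal(hit$q_end, 300L)
  })
})

test_that("align_local identity tracks a 50 %-mutated copy", {
  rs <- fx_reference_set()
  tpl <- rs$proteins[["REF_B"]]
  mut <- mutate_to_identity(tpl, 0.5, seed = 17)
  hit <- align_local(tpl, mut)
  expect_lt(abs(hit$pct_identity - 50), 2)
})

test_that("unrelated random proteins never pass the E-value cutoff", {
  params <- search_params()
  withr::with_seed(23, {
    evals <- vapply(1:100, function(i) {
      align_local(random_protein_str(300), random_protein_str(300),
                  params)$evalue
    }, numeric(1))
  })
  expect_true(all(evals > params$evalue_max))
})

test_that("planted homologs are detected and sub-threshold ones are not", {
  rs <- fx_reference_set()
  pg <- fx_wlp_genome()   # planted at 70 % identity
  hits <- find_candidates(pg$bundle, rs)
  expect_true(fx_focal_gene(pg) %in% hits$subject_id)

  spec <- plant_spec("TLOW", NULL, data.frame(
    template_name = "REF_E", target_identity = 0.20, motif_state = "intact",
    contig_id = "c1", rank_slot = 16L, strand = "+", stringsAsFactors = FALSE),
    seed = 53)
  pg_low <- plant_genome(spec, rs)
  hits_low <- find_candidates(pg_low$bundle, rs)
  expect_false(fx_focal_gene(pg_low) %in% hits_low$subject_id)
  expect_error(find_candidates(pg$bundle, list(proteins = character(0))),
               "empty reference set")
})

test_that("alignment-length cutoff separates 190-aa from 210-aa fragments", {
  rs <- fx_reference_set()
  pg <- fx_wlp_genome()
  b <- pg$bundle
  for (L in c(190L, 210L)) {
    frag <- substr(rs$proteins[["REF_E"]], 151, 150 + L)
    g <- b$genes
    slot <- which(g$rank == 5 & g$contig_id == "c1")
    g$protein[slot] <- frag
    g$end[slot] <- g$start[slot] + 3L * (L + 1L)  # keep interval plausible
    b2 <- genome_bundle("TLEN", NULL, b$contigs, g)
    hits <- find_candidates(b2, rs)
    gid <- g$gene_id[slot]
    if (L < 200) expect_false(gid %in% hits$subject_id)
    else expect_true(gid %in% hits$subject_id)
  }
})

test_that("clade assignment picks max identity with documented tie-breaks", {
  rs <- fx_reference_set()
  hits <- data.frame(
    query_id = c("REF_E", "REF_B"), subject_id = "g1",
    pct_identity = c(75, 40), bit_score = c(500, 200),
    stringsAsFactors = FALSE)
  expect_equal(assign_clade("g1", hits, rs$clade_map)$clade, "E")

  tie <- data.frame(query_id = c("REF_E", "REF_B"), subject_id = "g1",
                    pct_identity = 50, bit_score = 100,
                    stringsAsFactors = FALSE)
  expect_equal(assign_clade("g1", tie, rs$clade_map)$clade, "B")
  expect_error(assign_clade("g2", hits, rs$clade_map), "no passing hit")
})

test_that("Mo-CODH screen demands both homology and the exact AYRCSFR motif", {
  coxl <- make_coxl_reference(1)
  pg <- fx_wlp_genome()
  b <- pg$bundle
  expect_length(find_mo_codh(b, coxl), 0L)

  g <- b$genes
  slot <- which(g$rank == 3 & g$contig_id == "c1")
  g$protein[slot] <- mutate_to_identity(coxl[[1]], 0.8,
                                        protected_positions = 401:407,
                                        seed = 3)
  g$end[slot] <- g$start[slot] + 3L * (nchar(g$protein[slot]) + 1L)
  b2 <- genome_bundle("TMO", NULL, b$contigs, g)
  expect_identical(find_mo_codh(b2, coxl), g$gene_id[slot])

  g$protein[slot] <- sub("AYRCSFR", "AYRCSFS", g$protein[slot], fixed = TRUE)
  b3 <- genome_bundle("TMO2", NULL, b$contigs, g)
  expect_length(find_mo_codh(b3, coxl), 0L)
})

test_that("tightening any threshold never enlarges the candidate set", {
  rs <- fx_reference_set()
  pg <- fx_wlp_genome()
  base <- search_params()
  cand <- function(p) unique(find_candidates(pg$bundle, rs, p)$subject_id)
  base_set <- cand(base)
  withr::with_seed(7, {
    for (i in 1:5) {
      stricter <- search_params(
        evalue_max = base$evalue_max / 10^stats::runif(1, 0, 5),
        identity_min_pct = base$identity_min_pct + stats::runif(1, 0, 40),
        alnlen_min_aa = base$alnlen_min_aa + sample(0:300, 1))
      expect_true(all(cand(stricter) %in% base_set))
    }
  })
})
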