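test_that("anchor maps to itself and constructed deletions map to gaps", {
  cfg <- fx_motif_config()
  anchor <- cfg$anchor_sequence
  m <- map_anchor_positions(anchor, cfg)
  expect_identical(m$map, seq_len(nchar(anchor)))
  expect_false(m$unaligned)

  aa <- strsplit(anchor, "")[[1]]
  del100 <- paste(aa[-100], collapse = "")
  m2 <- map_anchor_positions(del100, cfg)
  expect_true(is.na(m2$map[100]))
  expect_identical(m2$map[101:nchar(anchor)], 100:(nchar(anchor) - 1L))
})

test_that("site positions stay mapped under 10 % off-site mutations", {
  cfg <- fx_motif_config()
  sites <- synth_motif_sites()
  mut <- mutate_to_identity(cfg$anchor_sequence, 0.9,
                            protected_positions = sites$position, seed = 41)
  m <- map_anchor_positions(mut, cfg)
  expect_true(all(!is.na(m$map[sites$position])))
  expect_identical(m$map[sites$position], sites$position)
})

test_that("check_motifs separates intact, substituted and deleted sites", {
  cfg <- fx_motif_config()
  anchor <- cfg$anchor_sequence
  expect_true(check_motifs(anchor, cfg)$overall_pass)

  aa <- strsplit(anchor, "")[[1]]
  sites <- synth_motif_sites()
  p_sub <- sites$position[sites$site == "C_cluster_1"][1]
  aa_sub <- aa; aa_sub[p_sub] <- "A"
  r <- check_motifs(paste(aa_sub, collapse = ""), cfg)
  expect_false(r$overall_pass)
  expect_equal(unname(r$status["C_cluster_1"]), "substituted")

  b_pos <- sites$position[sites$site == "B_cluster"]
  r2 <- check_motifs(paste(aa[-b_pos], collapse = ""), cfg)
  expect_false(r2$overall_pass)
  expect_equal(unname(r2$status["B_cluster"]), "deleted")
})

test_that("unalignable candidates are unaligned, not substituted", {
  cfg <- fx_motif_config()
  junk <- withr::with_seed(2, random_protein_str(400))
  r <- check_motifs(junk, cfg)
  expect_true(all(r$status == "unaligned"))
  expect_false(r$overall_pass)
})

test_that("adding positions to a site never converts a fail into a pass", {
  cfg <- fx_motif_config()
  aa <- strsplit(cfg$anchor_sequence, "")[[1]]
  sites <- synth_motif_sites()
  p_sub <- sites$position[sites$site == "C_cluster_2"][1]
  aa[p_sub] <- "G"
  cand <- paste(aa, collapse = "")
  expect_false(check_motifs(cand, cfg)$overall_pass)
  wider <- sites
  extra <- data.frame(site = "C_cluster_2", position = 500L,
                      required = strsplit(cfg$anchor_sequence, "")[[1]][500],
                      stringsAsFactors = FALSE)
  cfg2 <- motif_config(cfg$anchor_reference_id, cfg$anchor_sequence,
                       rbind(wider, extra))
  expect_false(check_motifs(cand, cfg2)$overall_pass)
})

test_that("a config whose anchor violates its own sites is rejected", {
  cfg <- fx_motif_config()
  bad <- synth_motif_sites()
  bad$required[1] <- "W"   # anchor carries C at that position
  expect_error(motif_config("x", cfg$anchor_sequence, bad), "anchor itself")
})

test_that("motif configs round-trip through YAML", {
  cfg <- fx_motif_config()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_motif_config(cfg, f)
  back <- read_motif_config(f)
  expect_identical(back$anchor_sequence, cfg$anchor_sequence)
  expect_identical(back$sites$position, cfg$sites$position)
  expect_identical(back$sites$required, cfg$sites$required)
})

test_that("the PFL Cys-Cys filter accepts the anchor and rejects damage", {
  pc <- default_pfl_config()
  expect_true(check_pfl_active_site(pc$anchor_sequence, pc))
  aa <- strsplit(pc$anchor_sequence, "")[[1]]
  for (p in pc$positions) {
    damaged <- aa; damaged[p] <- "S"
    expect_false(check_pfl_active_site(paste(damaged, collapse = ""), pc))
  }
  expect_false(check_pfl_active_site("MKVLITGGA", pc))
})
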