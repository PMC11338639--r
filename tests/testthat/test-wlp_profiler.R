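test_that("presence is genome-wide and respects multi-KO genes", {
  pg <- fx_wlp_genome()
  m <- build_presence_matrix(list(pg$bundle))
  expect_true(m[1, "acsB"])
  expect_true(m[1, "fhs"])
  expect_false(m[1, "fdhA"])
  expect_error(build_presence_matrix(list(pg$bundle), list()),
               "empty symbol map")

  # a gene with two KOs counts for both symbols
  b <- pg$bundle
  g <- b$genes
  g$ko[g$rank == 3 & g$contig_id == "c1"] <- "K01938;K01491"
  b2 <- genome_bundle("TMKO", NULL, b$contigs, g)
  m2 <- build_presence_matrix(list(b2))
  expect_true(m2[1, "fhs"] && m2[1, "folD"])
})

test_that("the Cys-Cys filter gates pfl counting unless disabled", {
  pg <- fx_wlp_genome()
  b <- pg$bundle
  g <- b$genes
  # break the planted pflB protein: damage one catalytic Cys
  pc <- default_pfl_config()
  slot <- which(vapply(split_ids(g$ko), function(k) "K00656" %in% k,
                       logical(1)))
  aa <- strsplit(g$protein[slot], "")[[1]]
  aa[pc$positions[1]] <- "S"
  g$protein[slot] <- paste(aa, collapse = "")
  # drop pflA so the K00656 gene is the only pfl evidence
  g$ko[vapply(split_ids(g$ko), function(k) "K04069" %in% k, logical(1))] <- ""
  b2 <- genome_bundle("TPFL", NULL, b$contigs, g)
  m_on <- build_presence_matrix(list(b2), validate_pfl = TRUE)
  m_off <- build_presence_matrix(list(b2), validate_pfl = FALSE)
  expect_false(m_on[1, "pfl"])
  expect_true(m_off[1, "pfl"])
  expect_false(validated_pfl_flags(list(b2))[["TPFL"]])
})

test_that("genome classification follows the fdh > pfl > transporter order", {
  symbols <- names(default_symbol_map())
  row <- stats::setNames(rep(FALSE, length(symbols)), symbols)
  r1 <- row; r1[c("acsB", "fdhA", "pfl")] <- TRUE
  out1 <- classify_genome(r1, TRUE, TRUE)
  expect_equal(out1$fdh_status, "has_any_fdh")
  expect_equal(out1$formate_route, "fdh")
  expect_true(out1$is_pcodh_acs)

  r2 <- row; r2[c("acsB", "pfl", "fdhC")] <- TRUE
  out2 <- classify_genome(r2, TRUE, TRUE)
  expect_equal(out2$fdh_status, "fdh_lacking")
  expect_equal(out2$formate_route, "pfl")

  r3 <- row; r3[c("acsB", "fdhC")] <- TRUE
  expect_equal(classify_genome(r3, TRUE, FALSE)$formate_route, "transporter")
  r4 <- row; r4["acsB"] <- TRUE
  expect_equal(classify_genome(r4, TRUE, FALSE)$formate_route, "none")
  expect_false(classify_genome(r4, FALSE, FALSE)$is_pcodh_acs)
})

test_that("presence matrices are idempotent across rebuilds", {
  pg <- fx_wlp_genome()
  m1 <- build_presence_matrix(list(pg$bundle))
  m2 <- build_presence_matrix(list(pg$bundle))
  expect_identical(m1, m2)
})

test_that("genus proportions are exact and reaggregate to the global rate", {
  co <- fx_quant_cohort()
  bundles <- co$bundles
  presence <- build_presence_matrix(bundles)
  taxonomy <- data.frame(
    genome_id = vapply(bundles, `[[`, character(1), "genome_id"),
    genus = vapply(bundles, function(b) b$taxonomy[["genus"]], character(1)),
    stringsAsFactors = FALSE)
  gp <- genus_proportions(presence, taxonomy, symbols = "acsB")
  expect_true(all(gp$acsB >= 0 & gp$acsB <= 1))
  global <- sum(gp$acsB * gp$n_genomes) / sum(gp$n_genomes)
  expect_equal(global, mean(presence[, "acsB"]))
  # a 3-of-4 direct check
  pm <- matrix(c(TRUE, TRUE, TRUE, FALSE), ncol = 1,
               dimnames = list(paste0("g", 1:4), "fhs"))
  tax <- data.frame(genome_id = paste0("g", 1:4), genus = "Blautia",
                    stringsAsFactors = FALSE)
  expect_equal(genus_proportions(pm, tax)$fhs, 0.75)
})
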