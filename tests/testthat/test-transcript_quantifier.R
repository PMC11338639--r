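test_that("the k-mer index covers both strands and rejects duplicates", {
  g31 <- withr::with_seed(3, paste(sample(c("A", "C", "G", "T"), 31,
                                          replace = TRUE), collapse = ""))
  idx <- build_kmer_index(c(gA = g31))
  expect_setequal(ls(idx$map), unique(c(g31, revcomp(g31))))
  expect_error(build_kmer_index(c(gA = g31, gA = g31)), "unique gene ids")
  expect_error(build_kmer_index(c(gA = substr(g31, 1, 20))), "at least k")
})

test_that("reads map to their source gene; shared reads are discarded", {
  co <- fx_quant_cohort()
  idx <- build_kmer_index(co$ref_genes)
  g <- co$ref_genes[[1]]
  read <- substr(g, 101, 200)
  out <- assign_reads(c(r1 = read, r2 = revcomp(read)), idx)
  expect_equal(out$assignments$gene_id, rep(names(co$ref_genes)[1], 2))

  # two identical genes: every k-mer is shared, ties are discarded
  idx2 <- build_kmer_index(c(gA = g, gB = g))
  out2 <- assign_reads(c(r1 = read), idx2)
  expect_equal(out2$mapped_reads, 0)
  expect_equal(out2$ambiguous_reads, 1)
})

test_that("read accounting is conserved", {
  co <- fx_quant_cohort()
  sim <- simulate_reads(co$bundles, stats::setNames(c(1, 1, 1), co$focals),
                        read_length = 100, n_reads = 500, seed = 13)
  junk <- withr::with_seed(14, paste(sample(c("A", "C", "G", "T"), 100,
                                            replace = TRUE), collapse = ""))
  reads <- c(sim$reads, junkread = junk)
  idx <- build_kmer_index(co$ref_genes)
  out <- assign_reads(reads, idx)
  expect_equal(out$mapped_reads + out$ambiguous_reads + out$unassigned_reads,
               length(reads))
  expect_equal(sum(out$counts), out$mapped_reads)
})

test_that("RPKM follows its formula and scale invariance", {
  expect_equal(compute_rpkm(10, 2000, 1e6), 5.0)
  expect_equal(compute_rpkm(0, 2000, 1e6), 0)
  expect_error(compute_rpkm(1, 0, 100), "positive")
  expect_equal(compute_rpkm(c(0, 5), c(1000, 1000), 0), c(0, 0))
  withr::with_seed(15, {
    for (i in 1:20) {
      counts <- rpois(10, 50); lens <- sample(300:3000, 10)
      mapped <- sum(counts)
      expect_equal(compute_rpkm(2 * counts, lens, 2 * mapped),
                   compute_rpkm(counts, lens, mapped))
    }
  })
})

test_that("TPM renormalizes RPKM to one million", {
  expect_equal(compute_tpm(c(5, 5)), c(5e5, 5e5))
  expect_equal(compute_tpm(c(0, 0)), c(0, 0))
  withr::with_seed(16, {
    for (i in 1:1000) {
      v <- stats::rexp(sample(2:30, 1))
      expect_lt(abs(sum(compute_tpm(v)) - 1e6) / 1e6, 1e-9)
    }
  })
})

test_that("external count tables quantify without reads", {
  co <- fx_quant_cohort()
  cts <- data.frame(gene_id = co$focals[1:2],
                    length_nt = nchar(co$ref_genes[co$focals[1:2]]),
                    count = c(10, 30), stringsAsFactors = FALSE)
  qd <- quantify_dataset(co$ref_genes, counts = cts)
  expect_equal(qd$mapped_reads, 40)
  expect_equal(sum(qd$quant$tpm), 1e6)
  bad <- data.frame(gene_id = "ghost", length_nt = 100, count = 1)
  expect_error(quantify_dataset(co$ref_genes, counts = bad), "unknown gene")
})

test_that("detection and aggregation follow the metadata", {
  co <- fx_quant_cohort()
  sim <- simulate_reads(co$bundles, stats::setNames(c(1, 1, 0), co$focals),
                        read_length = 100, n_reads = 400, seed = 17)
  qd <- quantify_dataset(co$ref_genes, reads = sim$reads)
  agg <- detect_and_aggregate(qd, co$metadata)
  expect_true(agg$detected)
  wlp_frac <- agg$by_context$read_fraction[agg$by_context$group == "WLP"]
  expect_equal(wlp_frac, 1.0)  # only WLP-context genes were expressed

  qd0 <- quantify_dataset(co$ref_genes,
                          counts = data.frame(gene_id = co$focals[1],
                                              length_nt = 100, count = 0))
  expect_false(detect_and_aggregate(qd0, co$metadata)$detected)

  expect_error(detect_and_aggregate(qd, co$metadata[-1, ]),
               "metadata missing.*QG1")
})
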