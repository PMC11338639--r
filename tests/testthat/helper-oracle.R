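# Independent exhaustive affine-gap local-alignment oracle for short
# sequences (gap of length L costs open + L * extend). Used to check the
# package's aligner, never to implement it.
sw_oracle_score <- function(a, b, submat, gap_open = 11, gap_extend = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[av[i - 1], bv[j - 1]]
      M[i, j] <- max(0, s + max(M[i - 1, j - 1], X[i - 1, j - 1],
                                Y[i - 1, j - 1]))
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                     Y[i, j - 1] - gap_extend)
      best <- max(best, M[i, j], X[i, j], Y[i, j])
    }
  }
  best
}

# Independent scorer for a reported pairwise alignment: recomputes the score
# and the matches/columns identity directly from the aligned strings.
audit_alignment <- function(q_aln, s_aln, submat, gap_open = 11,
                            gap_extend = 1) {
  a <- strsplit(q_aln, "")[[1]]
  b <- strsplit(s_aln, "")[[1]]
  stopifnot(length(a) == length(b))
  gap_a <- a == "-"; gap_b <- b == "-"
  score <- sum(vapply(which(!gap_a & !gap_b),
                      function(i) submat[a[i], b[i]], numeric(1)))
  gap_cost <- function(g) {
    runs <- rle(g)
    sum(vapply(which(runs$values), function(r) {
      gap_open + gap_extend * runs$lengths[r]
    }, numeric(1)))
  }
  score <- score - gap_cost(gap_a) - gap_cost(gap_b)
  matches <- sum(!gap_a & !gap_b & a == b)
  list(score = score, matches = matches, columns = length(a),
       identity_pct = 100 * matches / length(a))
}

random_protein_str <- function(n) {
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}
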