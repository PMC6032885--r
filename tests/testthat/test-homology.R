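sm <- default_submatrix()

test_that("local alignment recovers self-alignment and the zero floor", {
  al <- local_align("ACDE", "ACDE")
  expect_equal(al$score, sum(diag(sm[c("A", "C", "D", "E"),
                                     c("A", "C", "D", "E")])))
  expect_equal(al$span_a, c(0L, 4L))
  expect_equal(al$span_b, c(0L, 4L))
  # all-negative scoring: empty alignment, score 0
  neg <- local_align("AAAA", "WWWW")
  expect_equal(neg$score, 0)
  expect_equal(diff(neg$span_a), 0L)
  # X is neutral, other junk is an error
  expect_equal(local_align("XXXX", "ACDE")$score, 0)
  expect_error(local_align("AC-E", "ACDE"), "invalid residue")
})

test_that("local alignment equals brute-force enumeration on small instances", {
  set.seed(41)
  for (rep in 1:10) {
    a <- rand_seq(sample(2:4, 1))
    b <- rand_seq(sample(2:4, 1))
    expect_equal(local_align(a, b, sm)$score,
                 bf_local_score(a, b, sm, 11, 1),
                 info = paste(a, b))
  }
})

test_that("local alignment agrees with an independent aligner and is symmetric", {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(7)
  for (rep in 1:15) {
    a <- rand_seq(sample(10:50, 1), AA)
    b <- rand_seq(sample(10:50, 1), AA)
    mine <- local_align(a, b)$score
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = BLOSUM62,
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
    expect_equal(mine, ref, info = paste("pair", rep))
    expect_equal(mine, local_align(b, a)$score)
  }
})

test_that("E-values follow the Karlin-Altschul form", {
  # S' = 10 bits, m = n = 100: E = 10^4 / 2^10
  S10 <- (10 * log(2) + log(0.041)) / 0.267
  expect_equal(evalue(S10, 100, 100)$bits, 10)
  expect_equal(evalue(S10, 100, 100)$evalue, 10000 / 1024,
               tolerance = 1e-10)
  # E decreases monotonically in S, vanishing in the limit
  es <- vapply(c(10, 50, 100, 500), function(s)
    evalue(s, 100, 100)$evalue, numeric(1))
  expect_true(all(diff(es) < 0))
  expect_lt(evalue(1e4, 100, 100)$evalue, 1e-300)
  # linear in search space
  e1 <- evalue(50, 100, 100)$evalue
  expect_equal(evalue(50, 100, 200)$evalue, 2 * e1)
})

test_that("reciprocal best hits keep identical copies and drop impostors", {
  set.seed(11)
  AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  qres <- vapply(1:3, function(i) rand_seq(60, AA), character(1))
  queries <- seq_set(paste0("q", 1:3), qres)
  source <- queries
  target <- seq_set(paste0("t", 1:3), qres)   # exact copies
  hits <- reciprocal_best_hits(queries, source, target)
  expect_equal(nrow(hits), 3)
  expect_equal(hits$query_id[order(hits$candidate_id)], paste0("q", 1:3))
  # a candidate whose reverse best hit is a different family is excluded
  target2 <- seq_set(c("t1", "imp"), c(qres[1], qres[2]))
  hits2 <- reciprocal_best_hits(queries[1, ], source, target2)
  expect_equal(hits2$candidate_id, "t1")
  # empty proteome: empty result
  expect_equal(nrow(reciprocal_best_hits(queries, source,
                                         seq_set(character(0),
                                                 character(0)))), 0)
})

test_that("shuffled decoys fail the RBH screen while a diverged orthologue passes", {
  set.seed(23)
  AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  q <- rand_seq(80, AA)
  qv <- strsplit(q, "")[[1]]
  # diverged true orthologue: 25% of positions substituted
  mut <- qv
  idx <- sample(80, 20)
  mut[idx] <- vapply(mut[idx], function(r) sample(setdiff(AA, r), 1), "x")
  decoys <- vapply(1:5, function(i)
    paste(sample(qv), collapse = ""), character(1))
  queries <- seq_set("q1", q)
  source <- seq_set(c("q1", paste0("bg", 1:3)),
                    c(q, vapply(1:3, function(i) rand_seq(80, AA),
                                character(1))))
  target <- seq_set(c("orth", paste0("d", 1:5)), c(paste(mut, collapse = ""),
                                                   decoys))
  hits <- reciprocal_best_hits(queries, source, target, e_max = 1e-4)
  expect_equal(hits$candidate_id, "orth")
})

test_that("PSSM scores match the log-odds closed forms", {
  # uniform column: all residue scores 0
  aa20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  mod_u <- build_pssm(aa20, pseudocount = 1)
  expect_lt(max(abs(mod_u$scores[, aa20])), 1e-12)
  # all-A two-row column, pseudocount 1: 2*log2((1 + 1/20) / (1/20 * 2))
  mod_a <- build_pssm(c("A", "A"), pseudocount = 1)
  expect_equal(unname(mod_a$scores[1, "A"]),
               2 * log2((1 + 1 / 20) / ((1 / 20) * 2)))
  # pseudocount -> 0 approaches 2*log2(20)
  mod_0 <- build_pssm(c("A", "A"), pseudocount = 1e-9)
  expect_equal(unname(mod_0$scores[1, "A"]), 2 * log2(20), tolerance = 1e-6)
  expect_error(build_pssm(c("-", "-")), "all-gap")
})

test_that("domain scan finds embedded blocks at the right offsets", {
  set.seed(31)
  AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  consensus <- rand_seq(30, AA)
  model <- build_pssm(rep(consensus, 3), name = "Dom")
  seqres <- paste0(rand_seq(40, AA), consensus, rand_seq(25, AA))
  arch <- scan_domains(seqres, list(model))
  # exhaustive check: the reported window is the best-scoring one
  expect_equal(nrow(arch), 1)
  expect_equal(arch$start, 40)
  expect_equal(arch$end, 70)
  # all-X sequence: window scores 0, below threshold
  expect_equal(nrow(scan_domains(strrep("X", 80), list(model))), 0)
  # two embedded copies, in coordinate order, never overlapping
  two <- paste0(consensus, rand_seq(20, AA), consensus)
  arch2 <- scan_domains(two, list(model))
  expect_equal(nrow(arch2), 2)
  expect_true(all(diff(arch2$start) > 0))
  expect_true(all(arch2$start[-1] >= arch2$end[-nrow(arch2)]))
  expect_equal(attr(arch2, "string"), "Dom-Dom")
})
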