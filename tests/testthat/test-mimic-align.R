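test_that("forced-by-scoring alignments come out as expected", {
  p <- scoring_params()
  a <- needleman_wunsch("ACGU", "ACGU", p)
  expect_equal(a$score, 8)
  expect_false(grepl("-", a$aligned_a, fixed = TRUE))
  expect_false(grepl("-", a$aligned_b, fixed = TRUE))
  # single mismatch (-3) beats two gaps (-8)
  b <- needleman_wunsch("A", "G", p)
  expect_equal(b$score, -3)
  expect_equal(b$aligned_a, "A")
  expect_equal(b$aligned_b, "G")
  expect_error(needleman_wunsch("", "ACGU", p), "empty")
})

test_that("alignment structure is internally consistent", {
  set.seed(101)
  p <- scoring_params()
  for (i in 1:40) {
    a <- rand_rna(sample(16:30, 1)); b <- rand_rna(sample(16:30, 1))
    aln <- needleman_wunsch(a, b, p)
    expect_identical(gsub("-", "", aln$aligned_a, fixed = TRUE), a)
    expect_identical(gsub("-", "", aln$aligned_b, fixed = TRUE), b)
    expect_equal(nchar(aln$aligned_a), nchar(aln$aligned_b))
    # score re-derives from the columns
    expect_equal(xkmir:::alignment_score(aln, p), aln$score)
    # pos_map points each query base at its column
    cols <- strsplit(aln$aligned_a, "")[[1]]
    expect_identical(paste(cols[aln$pos_map], collapse = ""), a)
  }
})

test_that("DP score equals exhaustive enumeration on short random pairs", {
  set.seed(202)
  p <- scoring_params()
  for (i in 1:150) {
    a <- rand_rna(sample(1:7, 1)); b <- rand_rna(sample(1:7, 1))
    expect_equal(needleman_wunsch(a, b, p)$score, bf_align_max(a, b),
                 info = paste(a, b))
  }
})

test_that("affine gaps price a run as open + (L-1) * extend", {
  p <- scoring_params(gap_open = -5, gap_extend = -1)
  aln <- needleman_wunsch("ACGUACGU", "ACGU", p)
  # 4 matches (+8) and one length-4 gap (-5 -1 -1 -1 = -8)
  expect_equal(aln$score, 0)
  expect_equal(xkmir:::alignment_score(aln, p), 0)
  expect_error(scoring_params(gap_open = -1, gap_extend = -5), "gap_open")
})

test_that("score is symmetric and self-alignment is perfect", {
  set.seed(303)
  p <- scoring_params()
  for (i in 1:25) {
    a <- rand_rna(sample(16:24, 1)); b <- rand_rna(sample(16:24, 1))
    expect_equal(needleman_wunsch(a, b, p)$score,
                 needleman_wunsch(b, a, p)$score)
    self <- needleman_wunsch(a, a, p)
    expect_equal(self$score, nchar(a) * p$match)
    sp <- seed_aligned_properly(self)
    expect_true(sp$ok); expect_equal(sp$matches, 6L)
  }
})

test_that("harsher mismatch penalties never increase a pairwise score", {
  set.seed(404)
  for (i in 1:25) {
    a <- rand_rna(20); b <- rand_rna(20)
    s1 <- needleman_wunsch(a, b, scoring_params(mismatch = -2))$score
    s2 <- needleman_wunsch(a, b, scoring_params(mismatch = -3))$score
    s3 <- needleman_wunsch(a, b, scoring_params(mismatch = -5))$score
    expect_true(s1 >= s2 && s2 >= s3)
  }
})

test_that("seed extraction takes positions 2-7 and rejects short input", {
  expect_equal(seed_of("AUCGAUCG"), "UCGAUC")
  expect_equal(seed_of("AAAAAAAA"), "AAAAAA")
  expect_error(seed_of("AUCGAUC"), "too short")
})

test_that("seed filter demands a gapless span and enough identities", {
  p <- scoring_params()
  q <- "ACGUACGUACGUACGUACGU"
  # identical: 6/6
  r <- seed_aligned_properly(needleman_wunsch(q, q, p))
  expect_true(r$ok); expect_equal(r$matches, 6L)
  # one substitution inside the seed: 5/6 fails at 6, passes at 5
  h <- q; substr(h, 4, 4) <- "A"
  aln <- needleman_wunsch(q, h, p)
  r6 <- seed_aligned_properly(aln, min_matches = 6)
  r5 <- seed_aligned_properly(aln, min_matches = 5)
  expect_false(r6$ok); expect_equal(r6$matches, 5L)
  expect_true(r5$ok); expect_equal(r5$matches, 5L)
  # a deletion inside the seed forces a gapped span
  hgap <- paste0(substr(q, 1, 3), substr(q, 5, nchar(q)))
  rg <- seed_aligned_properly(needleman_wunsch(q, hgap, p))
  expect_false(rg$ok)
})

test_that("best host match selects the top score with deterministic ties", {
  p <- scoring_params()
  q <- mirna_row("q1", "ACGUACGUACGUACGUACGU")
  hosts <- rbind(mirna_row("h-copy", q$seq),
                 mirna_row("h-rand", "UUUGGGCCCAAAUUUGGGCC"))
  hit <- best_host_match(q, hosts, p)
  expect_equal(hit$hit_id, "h-copy")
  expect_true(hit$seed_ok)
  # identical score and seed_matches: lexicographically smaller id wins
  twins <- rbind(mirna_row("hB", q$seq), mirna_row("hA", q$seq))
  expect_equal(best_host_match(q, twins, p)$hit_id, "hA")
  expect_error(best_host_match(q, twins[0, ], p), "empty host")
})

test_that("catalogue screen keeps every query, flags instead of dropping", {
  set.seed(505)
  queries <- do.call(rbind, lapply(1:3, function(i) {
    mirna_row(paste0("q", i), rand_rna(21))
  }))
  hosts <- do.call(rbind, lapply(1:10, function(i) {
    mirna_row(paste0("h", i), rand_rna(21))
  }))
  sc <- screen_catalogue(queries, hosts)
  expect_s3_class(sc, "mimic_screen")
  expect_equal(sc$query_id, queries$id)
  expect_type(sc$seed_ok, "logical")
  expect_warning(empty <- screen_catalogue(queries[0, ], hosts), "empty")
  expect_equal(nrow(empty), 0L)
})

test_that("screening is deterministic: identical inputs, identical tables", {
  cfg <- sim_config(seed = 99, n_query = 4, n_host = 20)
  m1 <- gen_mirnas(cfg); m2 <- gen_mirnas(cfg)
  s1 <- screen_catalogue(m1$queries, m1$hosts)
  s2 <- screen_catalogue(m2$queries, m2$hosts)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
})
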