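test_that("a planted 6mer core is found at the planted position", {
  m <- mirna_row("m1", "AUCGAUCGAUCGAUCGAUCG")
  core <- revcomp_rna(seed_of(m$seq))  # RC of "UCGAUC"
  # flanks chosen to satisfy neither extension: left != complement of nt 8,
  # right != A
  m8c <- chartr("ACGU", "UGCA", substr(m$seq, 8, 8))
  left <- setdiff(c("C", "G"), m8c)[1]
  u <- utr_row("g1", paste0(strrep("C", 19), left, core, "C", strrep("C", 19)))
  sites <- scan_sites(m, u)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$position, 21L)
  expect_equal(sites$site_class, "6mer")
})

test_that("site classes follow the canonical taxonomy", {
  m <- mirna_row("m1", "AUCGAUCGAUCGAUCGAUCG")
  core <- revcomp_rna(seed_of(m$seq))
  m8c <- chartr("ACGU", "UGCA", substr(m$seq, 8, 8))
  not_m8 <- setdiff(c("C", "G"), m8c)[1]
  mk <- function(left, right) {
    utr_row("g", paste0(strrep("C", 10), left, core, right, strrep("C", 10)))
  }
  expect_equal(scan_sites(m, mk(m8c, "A"))$site_class, "8mer")
  expect_equal(scan_sites(m, mk(m8c, "C"))$site_class, "7mer-m8")
  expect_equal(scan_sites(m, mk(not_m8, "A"))$site_class, "7mer-A1")
  expect_equal(scan_sites(m, mk(not_m8, "C"))$site_class, "6mer")
  # the m8-extended site starts one base 5' of the core
  expect_equal(scan_sites(m, mk(m8c, "A"))$position, 11L)
  expect_equal(scan_sites(m, mk(not_m8, "A"))$position, 12L)
})

test_that("every reported site re-verifies against the sequences", {
  set.seed(42)
  site_len <- c("6mer" = 6L, "7mer-A1" = 7L, "7mer-m8" = 7L, "8mer" = 8L)
  for (i in 1:20) {
    m <- mirna_row("m", rand_rna(21))
    u <- utr_row("g", rand_rna(3000))
    sites <- scan_sites(m, u)
    if (nrow(sites) == 0) next
    for (r in seq_len(nrow(sites))) {
      cls <- sites$site_class[r]; pos <- sites$position[r]
      core_at <- if (cls %in% c("7mer-m8", "8mer")) pos + 1L else pos
      core <- substring(u$seq, core_at, core_at + 5L)
      expect_identical(core, revcomp_rna(seed_of(m$seq)))
      if (cls %in% c("7mer-m8", "8mer")) {
        expect_identical(substring(u$seq, pos, pos),
                         chartr("ACGU", "UGCA", substr(m$seq, 8, 8)))
      }
      if (cls %in% c("7mer-A1", "8mer")) {
        expect_identical(substring(u$seq, core_at + 6L, core_at + 6L), "A")
      }
      expect_lte(pos + site_len[[cls]] - 1L, nchar(u$seq))
    }
  }
})

test_that("background site counts on random UTRs match the analytic null", {
  # i.i.d. uniform bases: core matches are ~ Binomial(L-5, 4^-6); the total
  # over replicates must fall in the central 99% Poisson envelope
  set.seed(7)
  L <- 10000L
  n_rep <- 100L
  total <- 0L
  for (i in seq_len(n_rep)) {
    m <- mirna_row("m", rand_rna(21))
    u <- utr_row("g", rand_rna(L))
    total <- total + nrow(scan_sites(m, u))
  }
  lambda <- n_rep * (L - 5) * 4^-6
  expect_gte(total, qpois(0.005, lambda))
  expect_lte(total, qpois(0.995, lambda))
})

test_that("scanning is position-independent", {
  set.seed(8)
  m <- mirna_row("m", rand_rna(22))
  u <- utr_row("g", rand_rna(2000))
  s0 <- scan_sites(m, u)
  u2 <- utr_row("g", paste0(rand_rna(100), u$seq))
  s1 <- scan_sites(m, u2)
  # sites of the original UTR reappear shifted by exactly 100
  expect_true(all(s0$position + 100L %in% s1$position))
  shifted <- s1[s1$position > 100L, ]
  expect_equal(shifted$position, s0$position + 100L)
  expect_equal(shifted$site_class, s0$site_class)
})

test_that("class weights dominate the AU-context bonus", {
  expect_equal(score_site("8mer", 0), 4)
  expect_equal(score_site("6mer", 1), 1.5)
  for (au in c(0, 0.3, 1)) {
    expect_true(score_site("8mer", au) > score_site("7mer-m8", au))
    expect_true(score_site("7mer-m8", au) > score_site("7mer-A1", au))
    expect_true(score_site("7mer-A1", au) > score_site("6mer", au))
  }
  # the bonus can never flip classes
  expect_true(score_site("7mer-m8", 0) > score_site("7mer-A1", 1))
})

test_that("only the best site per UTR is retained, ties to the 5'-most", {
  sites <- data.frame(
    mirna_id = "m", gene_id = c("g1", "g1", "g2", "g2"),
    position = c(10L, 40L, 40L, 10L),
    site_class = c("8mer", "6mer", "6mer", "6mer"),
    score = c(4, 1, 1.2, 1.2), stringsAsFactors = FALSE)
  best <- best_site_per_utr(sites)
  expect_equal(nrow(best), 2L)
  expect_equal(best$site_class[best$gene_id == "g1"], "8mer")
  expect_equal(best$position[best$gene_id == "g2"], 10L)
  expect_equal(nrow(best_site_per_utr(sites[0, ])), 0L)
})

test_that("target sets are ranked, deduplicated and truncated at k", {
  set.seed(9)
  per_gene <- data.frame(
    mirna_id = "m", gene_id = sprintf("g%03d", 1:150),
    position = 1L, site_class = "6mer",
    score = round(runif(150), 3), stringsAsFactors = FALSE)
  top <- top_k_targets(per_gene, k = 100)
  expect_equal(nrow(top), 100L)
  expect_equal(top$rank, 1:100)
  expect_true(all(diff(top$score) <= 0))
  expect_false(any(duplicated(top$gene_id)))
  expect_equal(nrow(top_k_targets(per_gene[1:37, ], k = 100)), 37L)
  # equal scores rank by gene id ascending
  tie <- per_gene[1:2, ]; tie$score <- 1
  expect_equal(top_k_targets(tie, k = 2)$gene_id, c("g001", "g002"))
})

test_that("planted sites are recovered with correct class by the full stage", {
  cfg <- sim_config(
    seed = 21, n_query = 2, n_host = 2, n_utrs = 30,
    utr_len_range = c(200L, 400L),
    planted_sites = data.frame(
      mirna_id = c("csi-sim-001", "csi-sim-001", "csi-sim-002"),
      gene_id = c("gene0001", "gene0005", "gene0010"),
      site_class = c("8mer", "7mer-A1", "7mer-m8"),
      core_position = c(50L, 120L, 77L), stringsAsFactors = FALSE))
  mi <- gen_mirnas(cfg)
  ut <- gen_utrs(cfg, mi$queries)
  targets <- predict_targets(mi$queries, ut$utrs, k = 100)
  for (r in seq_len(nrow(ut$truth))) {
    tr <- ut$truth[r, ]
    hit <- targets[targets$mirna_id == tr$mirna_id &
                   targets$gene_id == tr$gene_id, ]
    expect_equal(nrow(hit), 1L)
    # the planted site wins per-UTR selection unless a stronger-class chance
    # site exists; at these UTR lengths that is not the case
    expect_equal(hit$site_class, tr$site_class)
    expect_equal(hit$position, tr$position)
  }
})
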