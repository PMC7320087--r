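test_that("the pre-screen keeps near-complementary sites and drops weak ones", {
  m <- catalog$mature_seq[1]
  txs <- c(good = paste0(random_rna_str(100), rna_revcomp(m),
                         random_rna_str(100)))
  set.seed(3)
  hits <- prescreen_targets(m, txs)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$coverage_percent, 100)
  expect_equal(hits$identity_percent, 100)
  expect_equal(hits$site_start, 101L)
  expect_equal(hits$site_end, 100L + nchar(m))
  # only half the mature complemented: below coverage
  half <- c(tx = paste0(random_rna_str(80),
                        rna_revcomp(substr(m, 1, nchar(m) %/% 2)),
                        random_rna_str(80)))
  expect_equal(nrow(prescreen_targets(m, half)), 0L)
  expect_warning(out <- prescreen_targets(m, character(0)), "empty")
  expect_equal(nrow(out), 0L)
})

test_that("identity thresholding follows the ratio arithmetic", {
  # 22-nt mature; full-length site with k interior mismatched columns has
  # identity (22-k)/22: five mismatches 77.3% (kept), six 72.7% (dropped)
  m <- catalog$mature_seq[1]  # 22 nt
  corrupt_site <- function(k) {
    site <- strsplit(rna_revcomp(m), "")[[1]]
    mb <- strsplit(m, "")[[1]]
    nonpair <- c(A = "C", C = "A", G = "A", U = "C")
    pos <- seq(4, 19, length.out = k)  # interior, spread out
    for (p in round(pos)) site[22 - p + 1] <- nonpair[[mb[p]]]
    paste(site, collapse = "")
  }
  tx5 <- c(t = corrupt_site(5))
  h5 <- prescreen_targets(m, tx5)
  expect_equal(nrow(h5), 1L)
  expect_equal(h5$identity_percent, 100 * 17 / 22, tolerance = 1e-6)
  tx6 <- c(t = corrupt_site(6))
  expect_equal(nrow(prescreen_targets(m, tx6)), 0L)
})

test_that("duplex alignment reports per-position pairing states", {
  m <- "CGUACGUACGUACGUACGUACG"
  aln <- align_duplex(m, rna_revcomp(m))
  expect_true(all(aln$states == "WC"))
  expect_equal(sum(aln$gaps_after), 0L)
  # G at position 10 opposite U in the site: G:U wobble
  stopifnot(substr(m, 10, 10) == "G")
  site <- strsplit(rna_revcomp(m), "")[[1]]
  site[22 - 10 + 1] <- "U"
  aln_gu <- align_duplex(m, paste(site, collapse = ""))
  expect_equal(aln_gu$states[10], "GU")
  expect_equal(sum(aln_gu$states == "WC"), 21L)
  # 22-mer against a 21-nt site: exactly one miRNA-side gap
  site21 <- paste(strsplit(rna_revcomp(m), "")[[1]][-11], collapse = "")
  aln_gap <- align_duplex(m, site21)
  expect_equal(sum(aln_gap$states == "GAP_M"), 1L)
  expect_equal(sum(aln_gap$states %in% c("WC", "GU")), 21L)
  expect_error(align_duplex("", "ACGU"), "empty")
})

test_that("duplex alignment scores are bracketed by an independent aligner", {
  # the duplex wobble bonus is directional ((G,A) and (U,C) in
  # mature-versus-complemented-site space), which pairwiseAlignment's
  # symmetric matrices cannot express; bracket the hand-rolled score
  # between a no-wobble and a symmetrized-wobble reference
  base <- matrix(-1, 5, 5, dimnames = list(c("A","C","G","U","N"),
                                           c("A","C","G","U","N")))
  diag(base) <- 2
  wob <- base
  wob["G", "A"] <- wob["A", "G"] <- 1
  wob["U", "C"] <- wob["C", "U"] <- 1
  ref_score <- function(m, site, mat)
    Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::RNAString(m), Biostrings::RNAString(rna_revcomp(site)),
      type = "global", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 2))
  set.seed(19)
  for (i in 1:10) {
    m <- random_rna_str(20)
    site <- random_rna_str(sample(18:22, 1))
    got <- align_duplex(m, site)$score
    expect_gte(got, ref_score(m, site, base))
    expect_lte(got, ref_score(m, site, wob))
  }
})

test_that("seed rules pass and fail on the constructed truth table", {
  m <- catalog$mature_seq[1]
  verdict <- function(violation)
    apply_seed_rules(align_duplex(m, build_site(m, violation)))
  ok <- verdict("none")
  expect_true(ok$pass)
  mm <- verdict("seed_mismatch")
  expect_false(mm$pass)
  expect_match(mm$reasons, "seed mismatch", all = FALSE)
  gu2 <- verdict("seed_gu")
  expect_false(gu2$pass)
  expect_equal(gu2$seed_gu, 2L)
  expect_match(gu2$reasons, "G:U", all = FALSE)
  g4 <- verdict("gaps4")
  expect_true(g4$pass)
  expect_equal(g4$gaps_9_21, 4L)
  g5 <- verdict("gaps5")
  expect_false(g5$pass)
  expect_equal(g5$gaps_9_21, 5L)
  expect_match(g5$reasons, "gaps", all = FALSE)
  short <- align_duplex("ACGUACG", rna_revcomp("ACGUACG"))
  expect_error(apply_seed_rules(short), "shorter than 8")
})

test_that("a single G:U in the seed is tolerated", {
  m <- catalog$mature_seq[1]
  mb <- strsplit(m, "")[[1]]
  p <- which(mb[2:8] %in% c("G", "U"))[1] + 1L
  site <- strsplit(rna_revcomp(m), "")[[1]]
  site[nchar(m) - p + 1] <- if (mb[p] == "G") "U" else "G"
  v <- apply_seed_rules(align_duplex(m, paste(site, collapse = "")))
  expect_true(v$pass)
  expect_equal(v$seed_gu, 1L)
})

test_that("corrupting any seed position always breaks a perfect site", {
  set.seed(29)
  nonpair <- c(A = "C", C = "A", G = "A", U = "C")
  for (rep in 1:8) {
    m <- random_rna_str(22)
    expect_true(apply_seed_rules(align_duplex(m, rna_revcomp(m)))$pass)
    for (p in 2:8) {
      site <- strsplit(rna_revcomp(m), "")[[1]]
      site[22 - p + 1] <- nonpair[[substr(m, p, p)]]
      v <- apply_seed_rules(align_duplex(m, paste(site, collapse = "")))
      expect_false(v$pass)
    }
  }
})

test_that("target scanning recovers implanted compliant sites only", {
  m1 <- catalog$mature_seq[1]
  m2 <- catalog$mature_seq[10]
  # one miRNA, two transcripts with compliant sites -> two rows
  txs <- c(a = paste0(random_rna_str(150), rna_revcomp(m1), random_rna_str(150)),
           b = paste0(random_rna_str(60), rna_revcomp(m1), random_rna_str(240)))
  set.seed(8)
  res <- scan_targets(c(mir1 = m1), txs)
  expect_equal(nrow(res), 2L)
  expect_setequal(res$transcript_id, c("a", "b"))
  # zero compliant sites -> empty table, no error
  none <- scan_targets(c(mir1 = m1), c(x = random_rna_str(300)))
  expect_equal(nrow(none), 0L)
  # implanted compliant + violating sites: only compliant pass
  sites <- list(
    list(mirna_id = "mir1", mature = m1),
    list(mirna_id = "mir1", mature = m1, violation = "seed_mismatch"),
    list(mirna_id = "mir2", mature = m2, violation = "gaps5"),
    list(mirna_id = "mir2", mature = m2))
  tx <- make_transcripts(n = 4, length = 400, sites = sites, seed = 21)
  got <- scan_targets(c(mir1 = m1, mir2 = m2), tx$transcripts)
  truth_ok <- tx$truth[tx$truth$rule_compliant, ]
  expect_equal(nrow(got), nrow(truth_ok))
  for (i in seq_len(nrow(truth_ok))) {
    t <- truth_ok[i, ]
    expect_true(any(got$mirna_id == t$mirna_id &
                    got$transcript_id == t$transcript_id &
                    got$site_start <= t$start & got$site_end >= t$end - 1))
  }
})
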