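test_that("GC content and MFEI follow their definitions", {
  expect_equal(compute_gc("GCGC"), 100)
  expect_equal(compute_gc("AUAU"), 0)
  expect_equal(compute_gc("GAUC"), 50)
  expect_error(compute_gc(""), "empty")
  expect_equal(truncate_2dp(compute_mfei(-24.00, 64, 29.69)), 1.26)
  expect_equal(truncate_2dp(compute_mfei(-16.10, 60, 38.33)), 0.70)
  expect_equal(compute_mfei(-10, 100, 50), 0.20)
  expect_error(compute_mfei(-10, 100, 0), "GC")
  expect_error(compute_mfei(-10, 0, 50), "length")
  expect_error(compute_mfei(10, 100, 50), "MFE")
})

test_that("the mature must sit within one arm, outside the terminal loop", {
  a <- parse_hairpin(rna_structure("GGGGGGAAAACCCCCC", "((((((....))))))"))
  expect_equal(mature_arm_check(a, c(1, 6)),
               list(pass = TRUE, arm = "five_prime"))
  expect_equal(mature_arm_check(a, c(11, 16))$arm, "three_prime")
  # one nucleotide into the loop fails
  expect_false(mature_arm_check(a, c(4, 7))$pass)
  # split across both arms fails
  expect_false(mature_arm_check(a, c(1, 16))$pass)
  expect_error(mature_arm_check(a, c(10, 30)), "coordinate error")
  two <- parse_hairpin(rna_structure("GGAAACCGGAAACC", "((...))((...))"))
  expect_error(mature_arm_check(two, c(1, 2)), "single-hairpin")
})

test_that("star mismatches count mature positions unpaired to the opposite arm", {
  perfect <- make_hairpin(catalog$mature_seq[1], loop_len = 8,
                          n_star_mismatches = 0, seed = 1)
  f <- fold(perfect)
  expect_equal(count_star_mismatches(f, attr(perfect, "mature_range")), 0L)
  three <- make_hairpin(catalog$mature_seq[1], loop_len = 8,
                        n_star_mismatches = 3, seed = 1)
  expect_identical(attr(three, "verified"), "full")
  f3 <- fold(three)
  expect_equal(count_star_mismatches(f3, attr(three, "mature_range")), 3L)
  # a mature reaching into the terminal loop is a caller error
  a <- rna_structure("GGGGGGAAAACCCCCC", "((((((....))))))")
  expect_error(count_star_mismatches(a, c(4, 8)), "terminal loop")
})

test_that("windows are trimmed to the minimal enclosing hairpin", {
  mature <- catalog$mature_seq[4]
  hp <- make_hairpin(mature, loop_len = 8, n_star_mismatches = 0, seed = 9)
  L <- nchar(hp)
  # embed the hairpin in unpairable flanks so the fold leaves them open
  win <- paste0(strrep("N", 6), hp, strrep("N", 8))
  f <- fold(win)
  tr <- trim_to_hairpin(win, f, attr(hp, "mature_range") + 6L)
  expect_equal(tr$start, 7L)
  expect_equal(tr$end, 6L + L)
  expect_equal(tr$seq, hp[[1]])
  expect_equal(tr$mature_range, attr(hp, "mature_range"))
  # already minimal: identity
  fh <- fold(hp)
  tr2 <- trim_to_hairpin(hp, fh, attr(hp, "mature_range"))
  expect_equal(as.vector(tr2$seq), hp[[1]])
  # no pairs around the mature: anatomy error
  open <- fold("AAAAAAAAAAAAAAAAAAAA")
  expect_error(trim_to_hairpin("AAAAAAAAAAAAAAAAAAAA", open, c(2, 5)),
               "anatomy error")
})

test_that("trimmed precursors refold into the same single hairpin", {
  set.seed(77)
  for (i in sample(nrow(catalog), 6)) {
    hp <- make_hairpin(catalog$mature_seq[i], loop_len = 8,
                       n_star_mismatches = 2, seed = i)
    win <- paste0(strrep("N", 10), hp, strrep("N", 10))
    f <- fold(win)
    tr <- trim_to_hairpin(win, f, attr(hp, "mature_range") + 10L)
    rf <- fold(tr$seq)
    a <- parse_hairpin(rf)
    expect_equal(a$n_hairpin_loops, 1L)
    expect_true(mature_arm_check(a, tr$mature_range)$pass)
    expect_equal(mature_arm_check(a, tr$mature_range)$arm, attr(hp, "arm"))
  }
})

test_that("classification applies every criterion and lists all violations", {
  hp <- make_hairpin(catalog$mature_seq[1], loop_len = 8,
                     n_star_mismatches = 2, seed = 3)
  ts <- fold(hp)
  cand <- list(structure = ts, mature_range = attr(hp, "mature_range"),
               mfei = compute_mfei(ts$energy, nchar(hp), compute_gc(hp)))
  ok <- classify_candidate(cand, filter_thresholds())
  expect_equal(ok$verdict, "accepted")
  expect_length(ok$reasons, 0L)
  expect_equal(ok$arm, "five_prime")
  expect_equal(ok$star_mismatches, 2L)
  # low MFEI alone
  low <- cand; low$mfei <- 0.65
  r1 <- classify_candidate(low, filter_thresholds())
  expect_equal(r1$verdict, "rejected")
  expect_match(r1$reasons, "MFEI below threshold", all = FALSE)
  # two violated criteria are both reported
  r2 <- classify_candidate(low, filter_thresholds(max_star_mismatches = 1))
  expect_length(r2$reasons, 2L)
  expect_match(r2$reasons, "star mismatches", all = FALSE)
})

test_that("a nine-mismatch star is rejected under the default thresholds", {
  mature <- catalog$mature_seq[catalog$name == "spi-miR-9-3p"]
  hp <- make_hairpin(mature, loop_len = 8, n_star_mismatches = 9, seed = 1)
  expect_identical(attr(hp, "verified"), "full")  # realized count is 9
  ts <- fold(hp)
  cand <- list(structure = ts, mature_range = attr(hp, "mature_range"),
               mfei = compute_mfei(ts$energy, nchar(hp), compute_gc(hp)))
  v <- classify_candidate(cand, filter_thresholds())
  expect_equal(v$verdict, "rejected")
  expect_equal(v$star_mismatches, 9L)
  # eight mismatches ("fewer than nine") still passes that criterion
  v8 <- classify_candidate(cand, filter_thresholds(max_star_mismatches = 9))
  expect_false("star mismatches above threshold (9 > 9)" %in% v8$reasons)
})

test_that("relaxing thresholds never turns an accepted candidate rejected", {
  set.seed(13)
  for (i in sample(nrow(catalog), 5)) {
    hp <- make_hairpin(catalog$mature_seq[i], loop_len = 8,
                       n_star_mismatches = sample(0:3, 1), seed = i)
    ts <- fold(hp)
    cand <- list(structure = ts, mature_range = attr(hp, "mature_range"),
                 mfei = compute_mfei(ts$energy, nchar(hp), compute_gc(hp)))
    strict <- filter_thresholds(max_star_mismatches = 3, min_mfei = 0.9)
    relaxed <- filter_thresholds(max_star_mismatches = 8, min_mfei = 0.5)
    if (classify_candidate(cand, strict)$verdict == "accepted")
      expect_equal(classify_candidate(cand, relaxed)$verdict, "accepted")
  }
})
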