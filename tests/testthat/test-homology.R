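test_that("nucleotide normalization maps to the RNA alphabet", {
  expect_equal(normalize_to_rna("acgt"), "ACGU")
  expect_equal(normalize_to_rna("ACGU"), "ACGU")
  expect_equal(normalize_to_rna("ACGTN"), "ACGUN")
  expect_error(normalize_to_rna("ACGX"), "invalid nucleotide")
})

test_that("reverse complement is an involution with the expected pairing", {
  expect_equal(rna_revcomp("ACGU"), "ACGU")
  expect_equal(rna_revcomp("AAGG"), "CCUU")
  set.seed(11)
  for (i in 1:20) {
    s <- random_rna_str(sample(5:40, 1))
    expect_equal(rna_revcomp(rna_revcomp(s)), s)
  }
})

test_that("exact matching finds plus- and minus-strand occurrences", {
  genome <- c(chr = "UUACGUUU")
  hits <- find_exact_matches(c(ref = "ACGU"), genome)
  plus <- hits[hits$strand == "+", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$start, 3L)
  expect_equal(plus$end, 6L)
  expect_equal(plus$matched_seq, "ACGU")
  # ACGU is its own reverse complement: the same locus is a minus hit too
  expect_equal(hits$start[hits$strand == "-"], 3L)
  # N never matches
  expect_equal(nrow(find_exact_matches(c(r = "ACGU"), c(c = "UUACGNUU"))), 0L)
  expect_error(find_exact_matches(character(0), genome), "empty reference")
})

test_that("exact matching equals a brute-force substring scan", {
  set.seed(101)
  for (rep in 1:15) {
    genome <- c(g1 = random_rna_str(600), g2 = random_rna_str(400))
    refs <- stats::setNames(
      vapply(1:4, function(i) random_rna_str(sample(3:6, 1)), ""),
      paste0("r", 1:4))
    got <- find_exact_matches(refs, genome)
    want <- brute_force_matches(refs, genome)
    expect_equal(nrow(got), nrow(want))
    key <- function(df) sort(paste(df$ref_id, df$contig, df$start, df$strand))
    expect_equal(key(got), key(want))
  }
})

test_that("reverse-complementing the genome mirrors the hit set", {
  set.seed(5)
  genome <- c(g = random_rna_str(500))
  refs <- c(a = random_rna_str(4), b = random_rna_str(5))
  fwd <- find_exact_matches(refs, genome)
  rc_genome <- c(g = rna_revcomp(genome[["g"]]))
  rev <- find_exact_matches(refs, rc_genome)
  n <- nchar(genome[["g"]])
  # a + hit at [s, e] becomes a - hit at [n - e + 1, n - s + 1]
  mapped <- data.frame(start = n - fwd$end + 1L,
                       strand = ifelse(fwd$strand == "+", "-", "+"),
                       ref_id = fwd$ref_id)
  key <- function(df) sort(paste(df$ref_id, df$start, df$strand))
  expect_equal(key(mapped), key(rev[, c("start", "strand", "ref_id")]))
})

test_that("implanted references are each found exactly once at their locus", {
  idx <- c(2, 30, 77)
  g <- make_genome(n_contigs = 2, contig_len = 8000,
                   implants = implant_specs(idx), seed = 42)
  refs <- stats::setNames(catalog$mature_seq[idx], catalog$name[idx])
  hits <- find_exact_matches(refs, g$genome)
  for (i in seq_len(nrow(g$truth))) {
    t <- g$truth[i, ]
    at_locus <- hits[hits$contig == t$contig & hits$start == t$mature_start &
                     hits$strand == t$strand, ]
    expect_equal(nrow(at_locus), 1L)
    expect_equal(at_locus$ref_id, t$name)
  }
})

test_that("precursor windows are excised with boundary truncation", {
  genome <- c(c1 = "UUACGUUUAG")
  hit <- list(ref_id = "r", contig = "c1", start = 3L, end = 6L,
              strand = "+", matched_seq = "ACGU")
  w <- extract_precursor_window(genome, hit, flank = 200)
  expect_equal(w$window_seq, genome[["c1"]])
  expect_equal(w$flank_up, 2L)
  expect_equal(w$flank_down, 4L)
  expect_equal(w$mature_offset, 2L)
  w0 <- extract_precursor_window(genome, hit, flank = 0)
  expect_equal(w0$window_seq, "ACGU")
  expect_equal(w0$mature_offset, 0L)
  bad <- hit; bad$end <- 99L
  expect_error(extract_precursor_window(genome, bad), "coordinate error")
})

test_that("minus-strand windows are the reverse complement of the slice", {
  contig <- paste(rep(c("A", "C", "G", "U", "G", "A"), 5), collapse = "")
  genome <- c(c1 = contig)
  hit <- list(ref_id = "r", contig = "c1", start = 11L, end = 16L,
              strand = "-", matched_seq = rna_revcomp(substr(contig, 11, 16)))
  w <- extract_precursor_window(genome, hit, flank = 4)
  expect_equal(w$window_seq, rna_revcomp(substr(contig, 7, 20)))
  mat <- substr(w$window_seq, w$mature_offset + 1,
                w$mature_offset + nchar(hit$matched_seq))
  expect_equal(mat, hit$matched_seq)
  expect_equal(w$flank_up, 4L)
  expect_equal(w$flank_down, 4L)
})

test_that("the protein-coding filter removes windows with qualifying ORFs", {
  mkwin <- function(seq) list(window_seq = seq,
                              hit = list(matched_seq = "ACGU"))
  set.seed(2)
  short <- mkwin(random_rna_str(60))
  expect_length(exclude_protein_coding(list(short), 300)$kept, 1L)
  # AUG + 99 non-stop codons + UAA = 303 nt
  orf <- paste0("AUG", paste(rep("GCU", 99), collapse = ""), "UAA")
  with_orf <- mkwin(paste0(random_rna_str(20), orf, random_rna_str(20)))
  res <- exclude_protein_coding(list(with_orf), 300)
  expect_length(res$kept, 0L)
  expect_equal(res$rejected$length[1], 303L)
  # degenerate threshold: any complete ORF disqualifies
  tiny <- mkwin(paste0("CCC", "AUGUAA", "CCC"))
  expect_length(exclude_protein_coding(list(tiny), 0)$kept, 0L)
})

test_that("duplicate loci are collapsed keeping the smallest ref_id", {
  h <- data.frame(
    ref_id = c("dre-miR-1", "gmo-miR-1", "dre-miR-1"),
    contig = c("c", "c", "c"), start = c(10L, 10L, 50L),
    end = c(31L, 31L, 71L), strand = c("+", "+", "+"),
    matched_seq = "X", stringsAsFactors = FALSE)
  d <- dedupe_hits(h)
  expect_equal(nrow(d), 2L)
  expect_equal(attr(d, "n_collapsed"), 1L)
  expect_equal(d$ref_id[d$start == 10L], "dre-miR-1")
  e <- dedupe_hits(h[0, ])
  expect_equal(nrow(e), 0L)
  expect_equal(attr(e, "n_collapsed"), 0L)
})
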