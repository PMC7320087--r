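# Shared fixtures and independent oracles for the test suite.

catalog <- load_catalog()

# Fold changes reported for the eight qPCR-validated miRNAs (brain over
# liver, U6-normalized).
fig1_folds <- c(
  "spi-miR338" = 109.13, "spi-miR26" = 98.36, "spi-miR129a" = 45.93,
  "spi-miR128" = 23.50, "spi-miR132" = 20.35, "spi-miR212" = 11.10,
  "spi-miR129b" = 7.00, "spi-miR9" = 6.23
)

random_rna_str <- function(n, letters = c("A", "C", "G", "U")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# Brute-force oracle for exact matching: scan every substring of both
# strands of every contig.
brute_force_matches <- function(refs, genome) {
  out <- list()
  for (contig in names(genome)) {
    seq <- genome[[contig]]
    n <- nchar(seq)
    for (id in names(refs)) {
      pat <- refs[[id]]
      L <- nchar(pat)
      rcpat <- rna_revcomp(pat)
      if (L > n) next
      for (s in seq_len(n - L + 1)) {
        sub <- substr(seq, s, s + L - 1)
        if (sub == pat) {
          out[[length(out) + 1L]] <- data.frame(
            ref_id = id, contig = contig, start = s, end = s + L - 1L,
            strand = "+", stringsAsFactors = FALSE)
        }
        if (sub == rcpat) {
          out[[length(out) + 1L]] <- data.frame(
            ref_id = id, contig = contig, start = s, end = s + L - 1L,
            strand = "-", stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(ref_id = character(), contig = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df[order(df$contig, df$start, df$ref_id, df$strand), , drop = FALSE]
}

# Build a target site (reverse complement of the mature) with a named rule
# violation, mirroring the synthetic-transcript construction but returning
# the bare site for direct duplex alignment.
build_site <- function(mature, violation = "none") {
  L <- nchar(mature)
  site <- strsplit(rna_revcomp(mature), "")[[1]]
  mb <- strsplit(mature, "")[[1]]
  nonpair <- c(A = "C", C = "A", G = "A", U = "C")
  if (violation == "seed_mismatch") {
    site[L - 5 + 1] <- nonpair[[mb[5]]]
  } else if (violation == "seed_gu") {
    gu_ok <- which(mb[2:8] %in% c("G", "U")) + 1L
    stopifnot(length(gu_ok) >= 2)
    for (p in gu_ok[1:2]) site[L - p + 1] <- if (mb[p] == "G") "U" else "G"
  } else if (violation %in% c("gaps4", "gaps5")) {
    ng <- if (violation == "gaps4") 4L else 5L
    site <- site[-((L - (10L + ng - 1L) + 1L):(L - 10L + 1L))]
  }
  paste(site, collapse = "")
}

# Standard implant set used by recovery tests: catalog matures with two
# star mismatches so each implant has exactly one exact-match locus.
implant_specs <- function(idx) {
  lapply(seq_along(idx), function(i)
    list(mature = catalog$mature_seq[idx[i]], name = catalog$name[idx[i]],
         n_star_mismatches = 2L,
         arm = c("five_prime", "three_prime")[(i %% 2) + 1]))
}
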