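# Substitution matrix in "mature vs reverse-complemented site" space:
# equality is a Watson-Crick duplex pair; (G,A) and (U,C) are the G:U
# wobbles after complementing the site strand.
duplex_score <- function(m, r) {
  if (m == r && m %in% c("A", "C", "G", "U")) return(2)
  if ((m == "G" && r == "A") || (m == "U" && r == "C")) return(1)
  -1
}

prescreen_matrix <- function() {
  letters <- c("A", "C", "G", "U", "N")
  mat <- matrix(-1, 5, 5, dimnames = list(letters, letters))
  diag(mat) <- 2
  mat["N", ] <- -4
  mat[, "N"] <- -4
  mat
}

#' Pre-screen transcripts for complementary target sites
#'
#' Locally aligns the reverse complement of a mature miRNA against each
#' transcript (match +2, mismatch -1, gap -2) and keeps sites where at
#' least `min_coverage` percent of the mature is aligned and at least
#' `min_identity` percent of the aligned columns match. After a passing
#' site is found the transcript is split around it and the flanks are
#' re-screened, so multiple non-overlapping sites per transcript are
#' reported.
#'
#' @param mature Mature miRNA sequence (RNA string).
#' @param transcripts Named character vector of transcript sequences.
#' @param min_coverage,min_identity Percent thresholds (default 75).
#' @return `data.frame` with `transcript_id`, `site_start`, `site_end`
#'   (1-based transcript coordinates), `coverage_percent`,
#'   `identity_percent`, `site_seq`.
#' @export
prescreen_targets <- function(mature, transcripts, min_coverage = 75,
                              min_identity = 75) {
  stopifnot(is.character(mature), length(mature) == 1)
  empty <- data.frame(transcript_id = character(), site_start = integer(),
                      site_end = integer(), coverage_percent = numeric(),
                      identity_percent = numeric(), site_seq = character(),
                      stringsAsFactors = FALSE)
  if (length(transcripts) == 0) {
    warning("empty transcript set")
    return(empty)
  }
  rc <- rna_revcomp(mature)
  submat <- prescreen_matrix()
  L <- nchar(rc)
  hits <- list()
  screen <- function(tx_id, seq, offset) {
    if (nchar(seq) < ceiling(L * min_coverage / 100)) return(invisible())
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::RNAString(rc), Biostrings::RNAString(seq),
      type = "local", substitutionMatrix = submat,
      gapOpening = 0, gapExtension = 2
    )
    pr <- Biostrings::pattern(aln)
    cov <- 100 * (Biostrings::end(pr@range) - Biostrings::start(pr@range) + 1) / L
    ident <- Biostrings::pid(aln, type = "PID1")
    s <- Biostrings::start(Biostrings::subject(aln)@range)
    e <- Biostrings::end(Biostrings::subject(aln)@range)
    if (cov >= min_coverage && ident >= min_identity) {
      hits[[length(hits) + 1L]] <<- data.frame(
        transcript_id = tx_id, site_start = offset + s, site_end = offset + e,
        coverage_percent = cov, identity_percent = ident,
        site_seq = substr(seq, s, e), stringsAsFactors = FALSE
      )
      if (s > 1) screen(tx_id, substr(seq, 1, s - 1), offset)
      if (e < nchar(seq)) screen(tx_id, substr(seq, e + 1, nchar(seq)), offset + e)
    }
    invisible()
  }
  for (tx_id in names(transcripts)) screen(tx_id, transcripts[[tx_id]], 0L)
  if (length(hits) == 0) return(empty)
  out <- do.call(rbind, hits)
  out <- out[order(out$transcript_id, out$site_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Align a miRNA-target duplex position by position
#'
#' Global Needleman-Wunsch alignment of the mature against the
#' reverse-complemented site (Watson-Crick +2, G:U wobble +1, mismatch -1,
#' gap -2, linear). Ties are resolved deterministically, preferring a
#' substitution over a gap in the site over a gap in the miRNA. States are
#' reported per mature position 1..L counted from the miRNA 5' end:
#' `WC`, `GU`, `MM`, or `GAP_M` (mature base opposite a gap); gaps in the
#' miRNA (unopposed site bases) are recorded between mature positions in
#' `gaps_after`.
#'
#' @param mature Mature miRNA (RNA string).
#' @param site Target site 5'->3' as read on the transcript.
#' @return A `duplex_alignment` list: `states` (length-L character),
#'   `gaps_after` (integer vector of length L+1; element i+1 counts site
#'   gaps between mature positions i and i+1), `score`, `mature`, `site`.
#' @export
align_duplex <- function(mature, site) {
  if (!nzchar(mature) || !nzchar(site)) stop("empty duplex input")
  m <- strsplit(mature, "")[[1]]
  r <- strsplit(rna_revcomp(site), "")[[1]]
  nm <- length(m)
  nr <- length(r)
  S <- matrix(0, nm + 1, nr + 1)
  S[, 1] <- -2 * (0:nm)
  S[1, ] <- -2 * (0:nr)
  for (i in seq_len(nm)) {
    for (j in seq_len(nr)) {
      S[i + 1, j + 1] <- max(S[i, j] + duplex_score(m[i], r[j]),
                             S[i, j + 1] - 2,
                             S[i + 1, j] - 2)
    }
  }
  states <- character(nm)
  gaps_after <- integer(nm + 1)
  i <- nm; j <- nr
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && S[i + 1, j + 1] == S[i, j] + duplex_score(m[i], r[j])) {
      states[i] <- if (m[i] == r[j]) "WC"
        else if ((m[i] == "G" && r[j] == "A") || (m[i] == "U" && r[j] == "C")) "GU"
        else "MM"
      i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 2) {
      states[i] <- "GAP_M"
      i <- i - 1
    } else {
      gaps_after[i + 1L] <- gaps_after[i + 1L] + 1L
      j <- j - 1
    }
  }
  structure(list(states = states, gaps_after = gaps_after,
                 score = S[nm + 1, nr + 1], mature = mature, site = site),
            class = "duplex_alignment")
}

#' Apply the seed-region duplex rules
#'
#' The three rules, with positions counted from the miRNA 5' end:
#' (1) no mismatches in the seed region (positions 2-8; a gap inside the
#' seed also violates it), (2) at most one G:U pair in the seed, and
#' (3) no more than four gaps on the miRNA side between positions 9 and 21.
#'
#' @param aln A `duplex_alignment` from [align_duplex()].
#' @return List with `pass`, `seed_mismatches`, `seed_gu`, `gaps_9_21`,
#'   `reasons`.
#' @export
apply_seed_rules <- function(aln) {
  states <- aln$states
  L <- length(states)
  if (L < 8) stop("alignment shorter than 8 positions: seed undefined")
  seed <- 2:8
  seed_mm <- sum(states[seed] %in% c("MM", "GAP_M")) +
    sum(aln$gaps_after[(2:7) + 1L])
  seed_gu <- sum(states[seed] == "GU")
  span <- 9:min(21L, L)
  gaps <- sum(states[span] == "GAP_M")
  # interstitial miRNA-side gaps count at the position of the following base
  gap_pos <- which(aln$gaps_after > 0) - 1L   # gap sits after this position
  gaps <- gaps + sum(aln$gaps_after[gap_pos[gap_pos + 1L >= 9 & gap_pos + 1L <= 21] + 1L])
  reasons <- character(0)
  if (seed_mm > 0) reasons <- c(reasons, "seed mismatch")
  if (seed_gu > 1) reasons <- c(reasons, "more than one G:U in seed")
  if (gaps > 4) reasons <- c(reasons, "more than four gaps in positions 9-21")
  list(pass = length(reasons) == 0, seed_mismatches = seed_mm,
       seed_gu = seed_gu, gaps_9_21 = gaps, reasons = reasons)
}

#' Scan transcripts for rule-compliant miRNA target sites
#'
#' Runs the complementarity pre-screen and the seed rules for every
#' (miRNA, transcript) combination. One miRNA may target several
#' transcripts and one transcript may carry several sites.
#'
#' @param matures Named character vector of mature sequences (or catalog
#'   `data.frame` with `name` and `mature_seq`).
#' @param transcripts Named character vector of transcript sequences.
#' @param min_coverage,min_identity Pre-screen thresholds (percent).
#' @param keep_failing Keep prescreened sites that fail the seed rules
#'   (with `pass = FALSE`)? Default `FALSE`.
#' @return `data.frame` with `mirna_id`, `transcript_id`, `site_start`,
#'   `site_end`, `coverage_percent`, `identity_percent`,
#'   `seed_mismatches`, `seed_gu`, `gaps_9_21`, `pass`.
#' @export
scan_targets <- function(matures, transcripts, min_coverage = 75,
                         min_identity = 75, keep_failing = FALSE) {
  if (is.data.frame(matures))
    matures <- stats::setNames(matures$mature_seq, matures$name)
  rows <- list()
  for (id in names(matures)) {
    sites <- prescreen_targets(matures[[id]], transcripts,
                               min_coverage, min_identity)
    for (k in seq_len(nrow(sites))) {
      aln <- align_duplex(matures[[id]], sites$site_seq[k])
      verdict <- apply_seed_rules(aln)
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = id, transcript_id = sites$transcript_id[k],
        site_start = sites$site_start[k], site_end = sites$site_end[k],
        coverage_percent = sites$coverage_percent[k],
        identity_percent = sites$identity_percent[k],
        seed_mismatches = verdict$seed_mismatches,
        seed_gu = verdict$seed_gu, gaps_9_21 = verdict$gaps_9_21,
        pass = verdict$pass, stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna_id = character(), transcript_id = character(),
               site_start = integer(), site_end = integer(),
               coverage_percent = numeric(), identity_percent = numeric(),
               seed_mismatches = integer(), seed_gu = integer(),
               gaps_9_21 = integer(), pass = logical(),
               stringsAsFactors = FALSE)
  if (!keep_failing) out <- out[out$pass, , drop = FALSE]
  rownames(out) <- NULL
  out
}
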