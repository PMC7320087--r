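#' Find exact genomic matches of mature miRNAs on both strands
#'
#' Every occurrence of every reference sequence is reported, on the forward
#' strand and as a reverse-complement (minus-strand) locus. Coordinates are
#' 1-based inclusive on the forward strand; `matched_seq` is the sequence as
#' read 5'->3' on the hit strand, i.e. always equal to the reference.
#' Matching is exact: `N` in the genome never matches.
#'
#' @param refs Named character vector of reference mature sequences
#'   (names are reference identifiers), or a `data.frame` with columns
#'   `ref_id` and `seq`.
#' @param genome Named character vector of contig sequences in the RNA
#'   alphabet (see [normalize_to_rna()]).
#' @return `data.frame` with columns `ref_id`, `contig`, `start`, `end`,
#'   `strand`, `matched_seq`, sorted by contig, start, ref_id.
#' @export
find_exact_matches <- function(refs, genome) {
  if (is.data.frame(refs)) refs <- stats::setNames(refs$seq, refs$ref_id)
  if (length(refs) == 0) stop("empty reference set")
  stopifnot(is.character(genome), !is.null(names(genome)))
  refs <- normalize_to_rna(refs)
  out <- list()
  for (contig in names(genome)) {
    subject <- Biostrings::RNAString(genome[[contig]])
    for (id in names(refs)) {
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") refs[[id]] else rna_revcomp(refs[[id]])
        m <- Biostrings::matchPattern(Biostrings::RNAString(pat), subject,
                                      fixed = TRUE)
        if (length(m) == 0) next
        out[[length(out) + 1L]] <- data.frame(
          ref_id = id, contig = contig,
          start = Biostrings::start(m), end = Biostrings::end(m),
          strand = strand, matched_seq = refs[[id]],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(ref_id = character(), contig = character(),
                      start = integer(), end = integer(),
                      strand = character(), matched_seq = character(),
                      stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$contig, hits$start, hits$ref_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Collapse duplicate hits at identical loci
#'
#' Hits identical in (contig, start, end, strand) — e.g. the same locus
#' matched by orthologous references from two species — are collapsed,
#' keeping the lexicographically smallest `ref_id`.
#'
#' @param hits Hit `data.frame` from [find_exact_matches()].
#' @return Deduplicated hits; the number of collapsed rows is available as
#'   `attr(, "n_collapsed")`.
#' @export
dedupe_hits <- function(hits) {
  if (nrow(hits) == 0) {
    attr(hits, "n_collapsed") <- 0L
    return(hits)
  }
  hits <- hits[order(hits$contig, hits$start, hits$end, hits$strand,
                     hits$ref_id), , drop = FALSE]
  key <- paste(hits$contig, hits$start, hits$end, hits$strand)
  keep <- !duplicated(key)
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_collapsed") <- sum(!keep)
  out
}

#' Excise a precursor window around a genomic hit
#'
#' Returns the hit extended by `flank` nucleotides on both sides, oriented
#' 5'->3' on the hit strand (minus-strand windows are reverse-complemented).
#' Flanks are truncated at contig boundaries and the obtained lengths
#' recorded.
#'
#' @param genome Named character vector of contigs.
#' @param hit One-row hit `data.frame` (or list) with `contig`, `start`,
#'   `end`, `strand`, `ref_id`, `matched_seq`.
#' @param flank Nucleotides requested on each side (default 200).
#' @return List with `hit`, `window_seq`, `mature_offset` (0-based start of
#'   the mature within the window), `flank_up`, `flank_down`.
#' @export
extract_precursor_window <- function(genome, hit, flank = 200L) {
  hit <- as.list(hit)
  contig <- genome[[hit$contig]]
  if (is.null(contig)) stop("coordinate error: unknown contig ", hit$contig)
  len <- nchar(contig)
  if (hit$start < 1 || hit$end > len || hit$start > hit$end)
    stop("coordinate error: hit ", hit$start, "-", hit$end,
         " outside contig ", hit$contig, " (length ", len, ")")
  a <- max(1L, hit$start - flank)
  b <- min(len, hit$end + flank)
  fwd <- substr(contig, a, b)
  if (hit$strand == "+") {
    window_seq <- fwd
    mature_offset <- hit$start - a
    flank_up <- hit$start - a
    flank_down <- b - hit$end
  } else {
    window_seq <- rna_revcomp(fwd)
    mature_offset <- b - hit$end
    flank_up <- b - hit$end
    flank_down <- hit$start - a
  }
  list(hit = hit, window_seq = window_seq, mature_offset = mature_offset,
       flank_up = flank_up, flank_down = flank_down)
}

# All complete ORFs (AUG..stop, same frame, length incl. stop) in 6 frames.
find_orfs <- function(seq, min_len = 0L) {
  orfs <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rna_revcomp(seq)
    n <- nchar(s)
    for (frame in 1:3) {
      starts <- seq.int(frame, n - 2L, by = 3L)
      if (frame > n - 2L) next
      codons <- substring(s, starts, starts + 2L)
      open <- NA_integer_
      for (i in seq_along(codons)) {
        if (is.na(open) && codons[i] == "AUG") open <- i
        if (!is.na(open) && codons[i] %in% c("UAA", "UAG", "UGA")) {
          len <- 3L * (i - open + 1L)
          if (len >= min_len) {
            orfs[[length(orfs) + 1L]] <- data.frame(
              strand = strand, frame = frame,
              start = starts[open], end = starts[i] + 2L, length = len,
              stringsAsFactors = FALSE
            )
          }
          open <- NA_integer_
        }
      }
    }
  }
  if (length(orfs) == 0) {
    return(data.frame(strand = character(), frame = integer(),
                      start = integer(), end = integer(), length = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, orfs)
}

#' Remove candidate windows that code for proteins
#'
#' A window is discarded when any of its six reading frames contains a
#' complete open reading frame (AUG through stop codon, in frame) of at
#' least `min_orf` nucleotides. Rejections are logged with the offending
#' frame and coordinates.
#'
#' @param windows List of precursor windows from
#'   [extract_precursor_window()].
#' @param min_orf Minimum qualifying ORF length in nt (default 300).
#' @return List with `kept` (windows passing) and `rejected`
#'   (`data.frame` of window index, strand, frame, start, end, length).
#' @export
exclude_protein_coding <- function(windows, min_orf = 300L) {
  kept <- list()
  rejected <- list()
  for (i in seq_along(windows)) {
    orfs <- find_orfs(windows[[i]]$window_seq, min_len = min_orf)
    if (nrow(orfs) == 0) {
      kept[[length(kept) + 1L]] <- windows[[i]]
    } else {
      rejected[[length(rejected) + 1L]] <- cbind(window = i, orfs[1, ])
    }
  }
  list(
    kept = kept,
    rejected = if (length(rejected)) do.call(rbind, rejected) else
      data.frame(window = integer(), strand = character(), frame = integer(),
                 start = integer(), end = integer(), length = integer())
  )
}
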