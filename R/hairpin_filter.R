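#' GC content of an RNA sequence
#'
#' @param seq RNA string (non-empty).
#' @return Percentage of G+C, full precision.
#' @export
compute_gc <- function(seq) {
  stopifnot(is.character(seq))
  if (any(nchar(seq) == 0)) stop("cannot compute GC of an empty sequence")
  gc <- nchar(gsub("[^GC]", "", seq))
  100 * gc / nchar(seq)
}

#' Minimum folding free energy index (MFEI)
#'
#' `MFEI = (|MFE| / length * 100) / GC%`, the length- and
#' composition-normalized stability index that separates miRNA precursors
#' (high values) from tRNA/rRNA/mRNA (roughly 0.59-0.66). The catalog
#' report form truncates to two decimals (see [truncate_2dp()]).
#'
#' @param mfe Folding energy in kcal/mol (<= 0).
#' @param length Sequence length in nt (> 0).
#' @param gc GC percentage (> 0).
#' @return MFEI at full precision (vectorized).
#' @export
compute_mfei <- function(mfe, length, gc) {
  if (any(length <= 0)) stop("length must be positive")
  if (any(gc <= 0)) stop("GC% must be positive: MFEI undefined")
  if (any(mfe > 0)) stop("MFE must be <= 0")
  (abs(mfe) / length * 100) / gc
}

#' Filtering thresholds for precursor candidates
#'
#' @param max_star_mismatches Maximum mature positions unpaired against the
#'   star strand ("fewer than nine mismatches", i.e. <= 8).
#' @param min_mfei Minimum MFEI; 0.70 is the smallest value in the packaged
#'   catalog and sits above the mRNA band (0.62-0.66).
#' @param min_loop Minimum hairpin loop length in nt.
#' @return List of thresholds.
#' @export
filter_thresholds <- function(max_star_mismatches = 8L, min_mfei = 0.70,
                              min_loop = 3L) {
  stopifnot(max_star_mismatches >= 0, min_mfei >= 0, min_loop >= 0)
  list(max_star_mismatches = as.integer(max_star_mismatches),
       min_mfei = min_mfei, min_loop = as.integer(min_loop))
}

#' Check that the mature lies within one arm of a hairpin
#'
#' Passes iff every mature position lies inside exactly one arm of the stem
#' and none falls in the terminal loop; the arm label feeds the catalog's
#' Location column.
#'
#' @param anatomy Single-hairpin anatomy from [parse_hairpin()].
#' @param mature_range `c(start, end)`, 1-based inclusive positions of the
#'   mature within the structure.
#' @return List with `pass` (logical) and `arm` (`"five_prime"`,
#'   `"three_prime"`, or `NA` on failure).
#' @export
mature_arm_check <- function(anatomy, mature_range) {
  if (is.null(anatomy$five_arm))
    stop("anatomy is not from a single-hairpin structure")
  pos <- seq(mature_range[1], mature_range[2])
  if (any(pos < 1) || any(pos > anatomy$n))
    stop("coordinate error: mature range outside structure")
  in_loop <- any(pos >= anatomy$terminal_loop[1] &
                 pos <= anatomy$terminal_loop[2])
  in5 <- all(pos >= anatomy$five_arm[1] & pos <= anatomy$five_arm[2])
  in3 <- all(pos >= anatomy$three_arm[1] & pos <= anatomy$three_arm[2])
  if (in_loop || (!in5 && !in3)) {
    list(pass = FALSE, arm = NA_character_)
  } else {
    list(pass = TRUE, arm = if (in5) "five_prime" else "three_prime")
  }
}

#' Count mismatches between the mature and its star sequence
#'
#' A mismatch is any mature position lacking a pairing partner on the
#' opposite arm of the hairpin (covering both mismatched and bulged
#' positions; the two are not distinguished). Positions paired into the
#' terminal loop or within the mature itself therefore also count.
#'
#' @param structure An [rna_structure()] folding into a single hairpin.
#' @param mature_range `c(start, end)` of the mature within the structure.
#' @return Integer mismatch count.
#' @export
count_star_mismatches <- function(structure, mature_range) {
  anatomy <- parse_hairpin(structure)
  if (is.null(anatomy$five_arm))
    stop("structure is not a single hairpin")
  pos <- seq(mature_range[1], mature_range[2])
  if (any(pos >= anatomy$terminal_loop[1] & pos <= anatomy$terminal_loop[2]))
    stop("mature overlaps the terminal loop; run mature_arm_check first")
  in5 <- all(pos >= anatomy$five_arm[1] & pos <= anatomy$five_arm[2])
  opp <- if (in5) anatomy$three_arm else anatomy$five_arm
  partner <- structure$partner[pos]
  sum(is.na(partner) | partner < opp[1] | partner > opp[2])
}

#' Trim a precursor window to its minimal hairpin
#'
#' Identifies the hairpin loop closed by the mature's base pairs (majority
#' vote when a long window's fold pairs a few mature edge positions into
#' other helices), walks to the outermost stem pair of that single-hairpin
#' subtree, and returns the subsequence spanning that pair, extended if
#' necessary so the whole mature is contained. This converts ~400-nt
#' candidate windows into minimal precursors.
#'
#' @param window A precursor window (list with `window_seq`) or a plain RNA
#'   string.
#' @param structure Fold of the full window ([rna_structure()]).
#' @param mature_range `c(start, end)` of the mature within the window.
#' @return List with `seq` (trimmed precursor), `start`, `end`
#'   (1-based window coordinates) and `mature_range` relative to the
#'   trimmed sequence.
#' @export
trim_to_hairpin <- function(window, structure, mature_range) {
  seq <- if (is.list(window)) window$window_seq else window
  partner <- structure$partner
  n <- length(partner)
  mat <- seq.int(mature_range[1], mature_range[2])
  if (all(is.na(partner[mat])))
    stop("anatomy error: mature has no pairs to a star region")
  opens <- which(!is.na(partner) & partner > seq_len(n))
  # hairpin loops, keyed by the opening position of their closing pair
  loop_at <- opens[vapply(opens, function(i) {
    all(is.na(partner[seq(i + 1, length.out = partner[i] - i - 1)]))
  }, TRUE)]
  # vote: each mature pair enclosing exactly one loop nominates that loop
  votes <- integer(0)
  for (p in mat) {
    q <- partner[p]
    if (is.na(q) || q %in% mat) next
    a <- min(p, q); b <- max(p, q)
    inside <- loop_at[loop_at > a & loop_at < b]
    if (length(inside) == 1) votes <- c(votes, inside)
  }
  if (length(votes) == 0)
    stop("anatomy error: mature pairs span more than one hairpin")
  target <- as.integer(names(sort(table(votes), decreasing = TRUE))[1])
  # outermost stem pair whose subtree contains only the target loop
  stem <- opens[vapply(opens, function(a) {
    b <- partner[a]
    inside <- loop_at[loop_at >= a & loop_at < b]
    length(inside) == 1 && inside == target
  }, TRUE)]
  a <- min(stem)
  b <- partner[a]
  lo <- min(a, mature_range[1])
  hi <- max(b, mature_range[2])
  list(seq = substr(seq, lo, hi), start = lo, end = hi,
       mature_range = mature_range - lo + 1L)
}

#' Classify a precursor candidate against the filtering criteria
#'
#' A candidate is accepted iff its (trimmed) structure is a single hairpin,
#' the mature lies within one arm and outside the terminal loop, the mature
#' has at most `max_star_mismatches` unpaired positions against the star
#' strand, and the MFEI is at least `min_mfei`. Every violated criterion is
#' reported.
#'
#' @param cand List with `structure` ([rna_structure()] of the trimmed
#'   precursor), `mature_range` (trimmed coordinates) and `mfei`.
#' @param th Thresholds from [filter_thresholds()].
#' @return List with `verdict` (`"accepted"`/`"rejected"`), `reasons`
#'   (character vector), `arm`, `star_mismatches`.
#' @export
classify_candidate <- function(cand, th = filter_thresholds()) {
  reasons <- character(0)
  arm <- NA_character_
  star_mm <- NA_integer_
  anatomy <- tryCatch(parse_hairpin(cand$structure), error = function(e) NULL)
  if (is.null(anatomy)) {
    reasons <- c(reasons, "no stem-loop structure")
  } else if (anatomy$n_hairpin_loops != 1L) {
    reasons <- c(reasons, "not a single hairpin")
  } else {
    chk <- mature_arm_check(anatomy, cand$mature_range)
    if (!chk$pass) {
      reasons <- c(reasons, "mature not confined to one arm outside the terminal loop")
    } else {
      arm <- chk$arm
      star_mm <- count_star_mismatches(cand$structure, cand$mature_range)
      if (star_mm > th$max_star_mismatches)
        reasons <- c(reasons, sprintf("star mismatches above threshold (%d > %d)",
                                      star_mm, th$max_star_mismatches))
    }
  }
  if (is.na(cand$mfei) || cand$mfei < th$min_mfei)
    reasons <- c(reasons, "MFEI below threshold")
  list(verdict = if (length(reasons)) "rejected" else "accepted",
       reasons = reasons, arm = arm, star_mismatches = star_mm)
}

# Locate the star region: best local alignment of the mature's reverse
# complement within the window, with the mature itself masked out. Returns
# c(start, end) in window coordinates, or NULL when no credible star
# exists (fewer than half the mature aligned, or non-positive score).
locate_star <- function(window_seq, mature_range) {
  L <- mature_range[2] - mature_range[1] + 1L
  chars <- strsplit(window_seq, "")[[1]]
  chars[seq(mature_range[1], mature_range[2])] <- "N"
  masked <- paste(chars, collapse = "")
  rc <- rna_revcomp(substr(window_seq, mature_range[1], mature_range[2]))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::RNAString(rc), Biostrings::RNAString(masked),
    type = "local", substitutionMatrix = prescreen_matrix(),
    gapOpening = 0, gapExtension = 2
  )
  pr <- Biostrings::pattern(aln)@range
  if (Biostrings::score(aln) <= 0 ||
      (Biostrings::end(pr) - Biostrings::start(pr) + 1) < L / 2) return(NULL)
  c(Biostrings::start(Biostrings::subject(aln)@range),
    Biostrings::end(Biostrings::subject(aln)@range))
}

#' Fold, trim and classify a precursor window
#'
#' Locates the star region of the mature by complementarity within the
#' window, folds the compact mature-to-star span (whole ~400-nt windows
#' fold degenerately under the simple energy model and do not localize the
#' hairpin), trims it to the minimal hairpin with [trim_to_hairpin()],
#' refolds, computes GC/MFE/MFEI and applies [classify_candidate()].
#' Windows offering no star region or no hairpin around the mature are
#' rejected (reason recorded) rather than raising.
#'
#' @param window Window from [extract_precursor_window()].
#' @param th Thresholds from [filter_thresholds()].
#' @return A `precursor_candidate` list: `window`, `structure` (trimmed
#'   fold), `trimmed_seq`, `trim_start`, `trim_end`, `mature_range`,
#'   `gc_percent`, `mfe`, `mfei`, `verdict`, `reasons`, `arm`,
#'   `star_mismatches`.
#' @export
assemble_candidate <- function(window, th = filter_thresholds()) {
  L <- nchar(window$hit$matched_seq)
  mature_range <- c(window$mature_offset + 1L, window$mature_offset + L)
  star <- locate_star(window$window_seq, mature_range)
  trim <- if (is.null(star)) {
    simpleError("no star region found in window")
  } else {
    span <- c(min(mature_range[1], star[1]), max(mature_range[2], star[2]))
    span_seq <- substr(window$window_seq, span[1], span[2])
    span_fold <- fold(span_seq)
    tryCatch({
      tr <- trim_to_hairpin(span_seq, span_fold, mature_range - span[1] + 1L)
      tr$start <- tr$start + span[1] - 1L
      tr$end <- tr$end + span[1] - 1L
      tr
    }, error = function(e) e)
  }
  if (inherits(trim, "error")) {
    out <- list(window = window, structure = NULL, trimmed_seq = NA_character_,
                trim_start = NA_integer_, trim_end = NA_integer_,
                mature_range = mature_range, gc_percent = NA_real_,
                mfe = NA_real_, mfei = NA_real_, verdict = "rejected",
                reasons = conditionMessage(trim), arm = NA_character_,
                star_mismatches = NA_integer_)
    class(out) <- "precursor_candidate"
    return(out)
  }
  ts <- fold(trim$seq)
  gc <- compute_gc(trim$seq)
  mfe <- ts$energy
  mfei <- if (gc > 0 && mfe <= 0) compute_mfei(mfe, nchar(trim$seq), gc)
          else NA_real_
  cand <- list(window = window, structure = ts, trimmed_seq = trim$seq,
               trim_start = trim$start, trim_end = trim$end,
               mature_range = trim$mature_range, gc_percent = gc,
               mfe = mfe, mfei = mfei)
  cls <- classify_candidate(cand, th)
  out <- c(cand, cls)
  class(out) <- "precursor_candidate"
  out
}
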