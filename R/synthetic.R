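# i.i.d. random RNA with configurable GC content.
random_rna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Substitute a star base so it can pair its opposite mature base neither
# Watson-Crick nor G:U.
nonpairing_base <- function(mature_base) {
  c(A = "C", C = "A", G = "A", U = "C")[[mature_base]]
}

#' Construct a synthetic precursor hairpin
#'
#' Builds `mature + loop + star` (or the 3'-arm mirror), where the star is
#' the reverse complement of the mature with the bases opposite
#' `n_star_mismatches` mature positions deleted, leaving those positions
#' bulged against the star. Deletion (rather than substitution) makes the
#' mismatch count structurally guaranteed: the star then has exactly
#' `L - n` bases, so no more than `L - n` mature positions can ever pair.
#' The loop is drawn from `{A, C}` only, so it cannot pair internally, and
#' deleted positions sit mid-stem in blocks of at most three (longer freed
#' runs could fold back on themselves; loop-adjacent bulges would blur the
#' terminal loop). The construct is verified by refolding: a single
#' hairpin, the mature confined to one arm, and exactly the requested
#' mismatch count, with the loop redrawn on the rare verification failure.
#'
#' @param mature Mature miRNA sequence.
#' @param loop_len Terminal loop length (>= 3; default 8).
#' @param n_star_mismatches Star positions to corrupt (default 0; at most
#'   the mature length).
#' @param seed Integer seed for the loop sequence and mismatch placement;
#'   `NULL` uses the current RNG state.
#' @param arm Which arm carries the mature: `"five_prime"` (default) or
#'   `"three_prime"`.
#' @return Precursor RNA string with attributes `mature_range` (positions
#'   of the mature within the precursor), `arm`, and `mismatch_positions`
#'   (mature positions corrupted in the star).
#' @export
make_hairpin <- function(mature, loop_len = 8L, n_star_mismatches = 0L,
                         seed = NULL, arm = c("five_prime", "three_prime")) {
  arm <- match.arg(arm)
  L <- nchar(mature)
  if (loop_len < 3) stop("loop_len must be >= 3")
  if (n_star_mismatches < 0 || n_star_mismatches > L)
    stop("n_star_mismatches must be in [0, mature length]")
  # central blocks of <= 3 deleted positions separated by 2 kept pairs
  block_positions <- function(n) {
    if (n == 0) return(integer(0))
    nb <- ceiling(n / 3)
    sizes <- c(rep(3L, nb - 1L), n - 3L * (nb - 1L))
    span <- sum(sizes) + 2L * (nb - 1L)
    start <- max(2L, round((L - span) / 2) + 1L)
    pos <- integer(0)
    cur <- start
    for (s in sizes) {
      pos <- c(pos, seq(cur, cur + s - 1L))
      cur <- cur + s + 2L
    }
    if (max(pos) > L - 1L)
      stop("n_star_mismatches too large for this mature length")
    pos
  }
  build <- function(loop, mm_pos) {
    star <- strsplit(rna_revcomp(mature), "")[[1]]
    if (length(mm_pos)) star <- star[-(L - mm_pos + 1L)]
    star <- paste(star, collapse = "")
    if (arm == "five_prime") {
      seq <- paste0(mature, loop, star)
      mature_range <- c(1L, L)
    } else {
      seq <- paste0(star, loop, mature)
      mature_range <- c(nchar(star) + loop_len + 1L,
                        nchar(star) + loop_len + L)
    }
    attr(seq, "mature_range") <- mature_range
    attr(seq, "arm") <- arm
    attr(seq, "mismatch_positions") <- sort(mm_pos)
    seq
  }
  verify <- function(seq) {
    f <- fold(seq)
    a <- tryCatch(parse_hairpin(f), error = function(e) NULL)
    if (is.null(a) || a$n_hairpin_loops != 1L) return("none")
    mr <- attr(seq, "mature_range")
    if (!mature_arm_check(a, mr)$pass) return("single_hairpin")
    if (count_star_mismatches(f, mr) != n_star_mismatches)
      return("single_hairpin")
    "full"
  }
  with_seed(seed, {
    mm_pos <- block_positions(n_star_mismatches)
    hairpin_only <- NULL
    for (attempt in seq_len(25L)) {
      loop <- paste(sample(c("A", "C"), loop_len, replace = TRUE),
                    collapse = "")
      seq <- build(loop, mm_pos)
      level <- verify(seq)
      if (level == "full") {
        attr(seq, "verified") <- "full"
        return(seq)
      }
      if (is.null(hairpin_only) && level == "single_hairpin")
        hairpin_only <- seq
    }
    # heavily corrupted stems fold with migrating bulges; the star-base
    # deficit still guarantees >= n mismatches against the star
    if (is.null(hairpin_only)) {
      warning("make_hairpin: could not verify a single-hairpin fold ",
              "for this mature; returning last construct")
      attr(seq, "verified") <- "none"
      return(seq)
    }
    attr(hairpin_only, "verified") <- "single_hairpin"
    hairpin_only
  })
}

#' Generate a synthetic genome with implanted precursor hairpins
#'
#' Contigs are i.i.d. random RNA with configurable GC; each implant (a
#' hairpin built by [make_hairpin()]) is written into a random
#' non-overlapping location on a random strand, and its locus recorded in
#' the truth table. Byte-identical output for identical seeds.
#'
#' Implanted positives are detectable by construction: a placement whose
#' surrounding window (implant plus `flank` nt on each side) contains a
#' complete open reading frame of at least `min_orf` nt — which the
#' protein-coding filter would discard — is redrawn.
#'
#' @param n_contigs,contig_len Genome dimensions.
#' @param implants List of implant specifications: each a list with
#'   `mature` and optionally `loop_len`, `n_star_mismatches`, `arm`,
#'   `strand`, `name`.
#' @param seed Integer seed.
#' @param gc Background GC fraction (default 0.5).
#' @param min_orf,flank ORF-free guarantee for the implant neighborhood;
#'   set `min_orf = Inf` to disable. Defaults mirror the pipeline defaults.
#' @return List with `genome` (named character vector of contigs) and
#'   `truth` (`data.frame`: `name`, `contig`, `start`, `end`, `strand`,
#'   `mature_seq`, `mature_start`, `mature_end`, `star_mismatches`).
#' @export
make_genome <- function(n_contigs = 1L, contig_len = 10000L,
                        implants = list(), seed = 1L, gc = 0.5,
                        min_orf = 300L, flank = 200L) {
  with_seed(seed, {
    contigs <- stats::setNames(
      vapply(seq_len(n_contigs), function(i) random_rna(contig_len, gc), ""),
      sprintf("contig_%02d", seq_len(n_contigs))
    )
    occupied <- lapply(contigs, function(x) integer(0))
    truth <- list()
    for (k in seq_along(implants)) {
      spec <- implants[[k]]
      hp <- make_hairpin(
        spec$mature,
        loop_len = if (is.null(spec$loop_len)) 8L else spec$loop_len,
        n_star_mismatches = if (is.null(spec$n_star_mismatches)) 0L
                            else spec$n_star_mismatches,
        arm = if (is.null(spec$arm)) "five_prime" else spec$arm
      )
      hlen <- nchar(hp)
      if (hlen > contig_len)
        stop("placement error: implant ", k, " longer than the contigs")
      strand <- if (is.null(spec$strand)) sample(c("+", "-"), 1) else spec$strand
      placed <- FALSE
      for (try in seq_len(1000)) {
        ci <- sample(n_contigs, 1)
        start <- sample(contig_len - hlen + 1L, 1)
        span <- seq(start, start + hlen - 1L)
        if (any(span %in% occupied[[ci]])) next
        ins <- if (strand == "+") hp else rna_revcomp(hp)
        cand <- paste0(substr(contigs[ci], 1, start - 1), ins,
                       substr(contigs[ci], start + hlen, contig_len))
        if (is.finite(min_orf)) {
          wnd <- substr(cand, max(1L, start - flank),
                        min(contig_len, start + hlen - 1L + flank))
          if (nrow(find_orfs(wnd, min_len = min_orf)) > 0) next
        }
        contigs[ci] <- cand
        occupied[[ci]] <- c(occupied[[ci]], span)
        mr <- attr(hp, "mature_range")
        if (strand == "+") {
          m_start <- start + mr[1] - 1L
          m_end <- start + mr[2] - 1L
        } else {
          m_start <- start + hlen - mr[2]
          m_end <- start + hlen - mr[1]
        }
        truth[[length(truth) + 1L]] <- data.frame(
          name = if (is.null(spec$name)) paste0("implant_", k) else spec$name,
          contig = names(contigs)[ci], start = start,
          end = start + hlen - 1L, strand = strand,
          mature_seq = spec$mature, mature_start = m_start,
          mature_end = m_end,
          star_mismatches = if (is.null(spec$n_star_mismatches)) 0L
                            else spec$n_star_mismatches,
          stringsAsFactors = FALSE
        )
        placed <- TRUE
        break
      }
      if (!placed) stop("placement error: could not fit implant ", k)
    }
    list(genome = contigs,
         truth = if (length(truth)) do.call(rbind, truth) else
           data.frame(name = character(), contig = character(),
                      start = integer(), end = integer(), strand = character(),
                      mature_seq = character(), mature_start = integer(),
                      mature_end = integer(), star_mismatches = integer(),
                      stringsAsFactors = FALSE))
  })
}

#' Generate synthetic transcripts with implanted target sites
#'
#' Compliant sites are the exact reverse complement of the mature (passing
#' all seed rules); non-compliant sites violate exactly one named rule.
#' `"gaps4"` builds a site with four miRNA-side gaps in positions 9-21,
#' which is still compliant.
#'
#' @param n Number of transcripts.
#' @param length Transcript length in nt.
#' @param sites List of site specifications: each a list with `mirna_id`,
#'   `mature`, and optional `violation` (one of `NULL`, `"seed_mismatch"`,
#'   `"seed_gu"`, `"gaps5"`, `"gaps4"`) and `transcript` index.
#' @param seed Integer seed.
#' @return List with `transcripts` (named character vector) and `truth`
#'   (`data.frame`: `mirna_id`, `transcript_id`, `start`, `end`,
#'   `violation`, `rule_compliant`).
#' @export
make_transcripts <- function(n = 4L, length = 500L, sites = list(), seed = 1L) {
  with_seed(seed, {
    txs <- stats::setNames(
      vapply(seq_len(n), function(i) random_rna(length), ""),
      sprintf("tx_%02d", seq_len(n))
    )
    occupied <- lapply(seq_len(n), function(i) integer(0))
    truth <- list()
    for (k in seq_along(sites)) {
      spec <- sites[[k]]
      L <- nchar(spec$mature)
      site <- strsplit(rna_revcomp(spec$mature), "")[[1]]
      # site index opposite mature position p is L - p + 1
      viol <- if (is.null(spec$violation)) "none" else spec$violation
      mb <- strsplit(spec$mature, "")[[1]]
      if (viol == "seed_mismatch") {
        site[L - 5 + 1] <- nonpairing_base(mb[5])
      } else if (viol == "seed_gu") {
        gu_ok <- which(mb[2:8] %in% c("G", "U")) + 1L
        if (length(gu_ok) < 2)
          stop("cannot construct two seed G:U pairs for ", spec$mirna_id)
        for (p in gu_ok[1:2])
          site[L - p + 1] <- if (mb[p] == "G") "U" else "G"
      } else if (viol %in% c("gaps4", "gaps5")) {
        ng <- if (viol == "gaps4") 4L else 5L
        drop <- (L - (10L + ng - 1L) + 1L):(L - 10L + 1L)
        site <- site[-drop]
      } else if (viol != "none") {
        stop("unknown violation: ", viol)
      }
      site <- paste(site, collapse = "")
      ti <- if (is.null(spec$transcript)) ((k - 1L) %% n) + 1L else spec$transcript
      pos <- NA_integer_
      for (try in seq_len(1000)) {
        cand <- sample(length - nchar(site) + 1L, 1)
        span <- seq(cand, cand + nchar(site) - 1L)
        if (!any(span %in% occupied[[ti]])) {
          pos <- cand
          occupied[[ti]] <- c(occupied[[ti]], span)
          break
        }
      }
      if (is.na(pos)) stop("placement error: could not fit site ", k)
      txs[ti] <- paste0(substr(txs[ti], 1, pos - 1), site,
                        substr(txs[ti], pos + nchar(site), length))
      truth[[length(truth) + 1L]] <- data.frame(
        mirna_id = spec$mirna_id, transcript_id = names(txs)[ti],
        start = pos, end = pos + nchar(site) - 1L, violation = viol,
        rule_compliant = viol %in% c("none", "gaps4"),
        stringsAsFactors = FALSE
      )
    }
    list(transcripts = txs,
         truth = if (length(truth)) do.call(rbind, truth) else
           data.frame(mirna_id = character(), transcript_id = character(),
                      start = integer(), end = integer(),
                      violation = character(), rule_compliant = logical(),
                      stringsAsFactors = FALSE))
  })
}

#' Generate a synthetic Ct table with known fold changes
#'
#' The reference gene sits at `ref_ct` in both tissues; each gene sits at
#' `base_ct` in the calibrator tissue and at `base_ct - log2(fold)` in the
#' test tissue, so the comparative-Ct method recovers `fold` exactly in the
#' noiseless case. Gaussian noise of `noise_sd` cycles is added per
#' replicate measurement.
#'
#' @param true_folds Named numeric vector of true fold changes
#'   (test over calibrator).
#' @param base_ct Gene Ct in the calibrator tissue (default 28 cycles).
#' @param ref_ct Reference-gene Ct (default 18 cycles).
#' @param noise_sd Replicate noise SD in cycles (default 0.2).
#' @param n_replicates Technical replicates per tissue-by-gene (default 3).
#' @param seed Integer seed.
#' @param test,calibrator Tissue labels.
#' @param reference_gene Reference gene label.
#' @return List with `table` (`data.frame`: `tissue`, `gene`, `replicate`,
#'   `ct`) and `truth` (the `true_folds` input).
#' @export
make_ct_table <- function(true_folds, base_ct = 28, ref_ct = 18,
                          noise_sd = 0.2, n_replicates = 3L, seed = 1L,
                          test = "brain", calibrator = "liver",
                          reference_gene = "U6") {
  stopifnot(noise_sd >= 0, n_replicates >= 1, !is.null(names(true_folds)))
  with_seed(seed, {
    rows <- list()
    add <- function(tissue, gene, mu) {
      rows[[length(rows) + 1L]] <<- data.frame(
        tissue = tissue, gene = gene, replicate = seq_len(n_replicates),
        ct = mu + stats::rnorm(n_replicates, 0, noise_sd),
        stringsAsFactors = FALSE
      )
    }
    for (tissue in c(test, calibrator)) add(tissue, reference_gene, ref_ct)
    for (g in names(true_folds)) {
      add(test, g, base_ct - log2(true_folds[[g]]))
      add(calibrator, g, base_ct)
    }
    list(table = do.call(rbind, rows), truth = true_folds)
  })
}
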