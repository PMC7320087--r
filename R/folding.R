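# Per-pair energies of the folding model, mirrored from the C++ kernel so
# the brute-force oracle and validators score identically.
pair_energy <- function(a, b) {
  key <- paste0(a, b)
  e <- c(GC = -3, CG = -3, AU = -2, UA = -2, GU = -1, UG = -1)[key]
  ifelse(is.na(e), NA_real_, e)
}

pairable <- function(a, b) !is.na(pair_energy(a, b))

partner_from_dotbracket <- function(dot_bracket) {
  chars <- strsplit(dot_bracket, "")[[1]]
  partner <- rep(NA_integer_, length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0) stop("unbalanced dot-bracket")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    } else if (chars[i] != ".") {
      stop("invalid dot-bracket character: ", chars[i])
    }
  }
  if (length(stack) > 0) stop("unbalanced dot-bracket")
  partner
}

dotbracket_from_partner <- function(partner) {
  n <- length(partner)
  chars <- rep(".", n)
  chars[!is.na(partner) & partner > seq_len(n)] <- "("
  chars[!is.na(partner) & partner < seq_len(n)] <- ")"
  paste(chars, collapse = "")
}

#' Construct and validate a secondary structure
#'
#' Builds an `rna_structure` object (sequence, dot-bracket, energy) and
#' enforces its invariants: balanced non-crossing brackets of equal length,
#' every pair Watson-Crick or G:U, and every hairpin loop spanning at least
#' 3 unpaired nucleotides.
#'
#' @param seq RNA string.
#' @param dot_bracket Matching dot-bracket string.
#' @param energy Folding energy in kcal/mol; if `NULL`, the model energy
#'   (sum of pair energies) is computed.
#' @return An object of class `rna_structure` with elements `seq`,
#'   `dot_bracket`, `energy`, `partner` (1-based pairing map, `NA` when
#'   unpaired).
#' @export
rna_structure <- function(seq, dot_bracket, energy = NULL) {
  stopifnot(is.character(seq), length(seq) == 1)
  if (nchar(seq) != nchar(dot_bracket))
    stop("sequence and dot-bracket lengths differ")
  partner <- partner_from_dotbracket(dot_bracket)
  chars <- strsplit(seq, "")[[1]]
  paired <- which(!is.na(partner) & partner > seq_along(partner))
  for (i in paired) {
    j <- partner[i]
    if (!isTRUE(pairable(chars[i], chars[j])))
      stop("invalid base pair ", chars[i], ":", chars[j],
           " at positions ", i, ",", j)
    if (all(is.na(partner[seq(i + 1, length.out = max(0, j - i - 1))])) &&
        j - i - 1 < 3)
      stop("hairpin loop shorter than 3 nt at pair ", i, ",", j)
  }
  if (is.null(energy)) {
    energy <- if (length(paired)) {
      sum(vapply(paired, function(i) pair_energy(chars[i], chars[partner[i]]),
                 0))
    } else 0
  }
  structure(
    list(seq = seq, dot_bracket = dot_bracket, energy = energy,
         partner = partner),
    class = "rna_structure"
  )
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(x$seq, "\n", x$dot_bracket, sprintf(" (%.2f)", x$energy), "\n", sep = "")
  invisible(x)
}

#' Fold an RNA sequence into its minimum-energy secondary structure
#'
#' Deterministic dynamic-programming minimizer under a simple per-pair
#' energy model (GC -3, AU -2, GU -1 kcal/mol; hairpin loops >= 3 nt; no
#' pseudoknots). Equal-energy ties are broken by pairing the 5'-most
#' position first, then its smallest admissible partner, giving a canonical
#' structure. This is a folding heuristic of the package, not a
#' nearest-neighbor thermodynamic engine; absolute energies are
#' model-specific.
#'
#' @param seq RNA string of length >= 10 (`N` allowed, never pairs).
#' @return An [rna_structure()] with `energy <= 0`; energy is 0 iff no
#'   base pairs form.
#' @export
fold <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  if (nchar(seq) < 10) stop("sequence shorter than 10 nt; cannot fold")
  if (grepl("[^ACGUN]", seq)) stop("fold expects an RNA string")
  res <- fold_dp(seq)
  partner <- res$partner
  partner[partner == 0] <- NA_integer_
  structure(
    list(seq = seq, dot_bracket = dotbracket_from_partner(partner),
         energy = res$energy, partner = partner),
    class = "rna_structure"
  )
}

# Enumerate all flattened pair lists c(a1,b1,a2,b2,...) of non-crossing
# structures on chars[i..j] with hairpin loops >= 3. Lists come out sorted
# by opening position.
enumerate_pairings <- function(chars, i, j) {
  if (j - i < 4) return(list(integer(0)))
  res <- enumerate_pairings(chars, i + 1, j)
  for (k in seq(i + 4, j)) {
    if (!isTRUE(pairable(chars[i], chars[k]))) next
    inner <- enumerate_pairings(chars, i + 1, k - 1)
    outer <- if (k + 1 <= j) enumerate_pairings(chars, k + 1, j)
             else list(integer(0))
    for (a in inner) for (b in outer)
      res[[length(res) + 1L]] <- c(i, k, a, b)
  }
  res
}

#' Exhaustive folding oracle for short sequences
#'
#' Enumerates every valid non-crossing pairing (loop >= 3) of a short RNA,
#' scores each with the same energy model as [fold()], and returns the
#' optimum under the same canonical tie-break. Intended as an independent
#' correctness oracle; refuses sequences longer than 14 nt.
#'
#' @param seq RNA string of at most 14 nt.
#' @return An [rna_structure()].
#' @export
brute_force_fold <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  if (nchar(seq) > 14) stop("brute_force_fold refuses sequences > 14 nt")
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  cands <- enumerate_pairings(chars, 1L, n)
  energies <- vapply(cands, function(p) {
    if (length(p) == 0) return(0)
    idx <- matrix(p, ncol = 2, byrow = TRUE)
    sum(vapply(seq_len(nrow(idx)),
               function(r) pair_energy(chars[idx[r, 1]], chars[idx[r, 2]]), 0))
  }, 0)
  best_e <- min(energies)
  opt <- cands[energies == best_e]
  # canonical: pairs sorted by opening position; earlier opening positions
  # win, and for equal openings the larger (outermost) partner wins —
  # mirrors the DP traceback preference exactly
  pick <- opt[[1]]
  if (length(opt) > 1) {
    for (p in opt[-1]) {
      m <- min(length(p), length(pick))
      cmp <- 0L
      if (m > 0) {
        d <- which(p[seq_len(m)] != pick[seq_len(m)])
        if (length(d)) {
          d <- d[1]
          better <- if (d %% 2 == 1) p[d] < pick[d] else p[d] > pick[d]
          cmp <- if (better) -1L else 1L
        }
      }
      if (cmp == -1L) pick <- p
    }
  }
  partner <- rep(NA_integer_, n)
  if (length(pick)) {
    idx <- matrix(pick, ncol = 2, byrow = TRUE)
    partner[idx[, 1]] <- idx[, 2]
    partner[idx[, 2]] <- idx[, 1]
  }
  structure(
    list(seq = seq, dot_bracket = dotbracket_from_partner(partner),
         energy = best_e, partner = partner),
    class = "rna_structure"
  )
}

#' Decompose a secondary structure into hairpin anatomy
#'
#' Identifies every hairpin loop (an unpaired run closed by a base pair
#' with no pairs inside). For single-hairpin structures the 5' and 3' arms
#' of the closing stem and the terminal loop are returned as position
#' ranges; for multi-hairpin structures only the loop census is defined.
#'
#' @param ss An [rna_structure()].
#' @return List with `n_hairpin_loops`, `loops` (list of position ranges),
#'   `paired_partner`, `n` (structure length), and — for single-hairpin
#'   structures — `five_arm`, `three_arm`, `terminal_loop` (each
#'   `c(start, end)`, 1-based inclusive).
#' @export
parse_hairpin <- function(ss) {
  stopifnot(inherits(ss, "rna_structure"))
  partner <- ss$partner
  n <- length(partner)
  opens <- which(!is.na(partner) & partner > seq_len(n))
  if (length(opens) == 0) stop("no stem: structure has zero base pairs")
  # hairpin loops: pairs with no paired position strictly inside
  loops <- list()
  for (i in opens) {
    j <- partner[i]
    interior <- seq(i + 1, length.out = j - i - 1)
    if (all(is.na(partner[interior])))
      loops[[length(loops) + 1L]] <- c(i + 1L, j - 1L)
  }
  out <- list(n_hairpin_loops = length(loops), loops = loops,
              paired_partner = partner, n = n)
  if (length(loops) == 1) {
    p <- loops[[1]][1] - 1L
    q <- loops[[1]][2] + 1L
    s5 <- min(opens)
    s3 <- partner[s5]
    out$five_arm <- c(s5, p)
    out$three_arm <- c(q, s3)
    out$terminal_loop <- loops[[1]]
  }
  out
}

#' Write structures in dot-bracket (Vienna) format
#'
#' One record per structure: a `>id` header, the sequence, and the
#' dot-bracket line with the energy in a trailing `( -12.30 )` comment.
#'
#' @param structures Named list of [rna_structure()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dotbracket <- function(structures, path) {
  stopifnot(is.list(structures), !is.null(names(structures)))
  lines <- unlist(lapply(names(structures), function(id) {
    s <- structures[[id]]
    c(paste0(">", id), s$seq,
      sprintf("%s ( %.2f )", s$dot_bracket, s$energy))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read structures from a dot-bracket (Vienna) file
#'
#' @param path File written by [write_dotbracket()] or compatible.
#' @return Named list of [rna_structure()] objects.
#' @export
read_dotbracket <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 3 != 0) stop("malformed dot-bracket file: ", path)
  out <- list()
  for (i in seq(1, length(lines), by = 3)) {
    id <- sub("^>", "", lines[i])
    seq <- lines[i + 1]
    m <- regmatches(lines[i + 2],
                    regexec("^([().]+)\\s*\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$",
                            lines[i + 2]))[[1]]
    if (length(m) != 3) stop("malformed structure line for record ", id)
    out[[id]] <- rna_structure(seq, m[2], as.numeric(m[3]))
  }
  out
}
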