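#' Path to the packaged sardine miRNA catalog
#'
#' The package ships a transcription of the published catalog of 101
#' conserved *Sardina pilchardus* miRNAs (name, mature length, query miRNA,
#' mature sequence, precursor arm, precursor length, GC%, MFE, MFEI) as a
#' tab-separated fixture.
#'
#' @return File path of the catalog TSV.
#' @export
catalog_path <- function() {
  system.file("extdata", "sardine_mirna_catalog.tsv",
              package = "mirhomology", mustWork = TRUE)
}

#' Load the miRNA catalog
#'
#' Reads the catalog TSV and validates every record: the mature length must
#' equal the sequence length, sequences must be RNA, precursors at least as
#' long as their matures, MFE negative, MFEI positive and GC% in (0, 100).
#' The packaged catalog must contain exactly 101 records.
#'
#' @param path Catalog TSV; defaults to the packaged fixture.
#' @param expected_n Expected record count used as an integrity check;
#'   `NA` disables the check (for user-supplied catalogs).
#' @return A `data.frame` with columns `name`, `length_mature`, `query`,
#'   `mature_seq`, `arm`, `length_precursor`, `gc_percent`, `mfe`, `mfei`.
#' @export
load_catalog <- function(path = catalog_path(), expected_n = 101L) {
  cat <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "length_mature", "query", "mature_seq", "arm",
            "length_precursor", "gc_percent", "mfe", "mfei")
  if (!all(need %in% names(cat))) {
    stop("catalog is missing column(s): ",
         paste(setdiff(need, names(cat)), collapse = ", "))
  }
  cat <- cat[, need]
  for (i in seq_len(nrow(cat))) {
    r <- cat[i, ]
    where <- paste0("catalog row ", i, " (", r$name, "): ")
    if (grepl("[^ACGU]", r$mature_seq))
      stop(where, "mature sequence is not RNA")
    if (r$length_mature != nchar(r$mature_seq))
      stop(where, "length_mature disagrees with mature_seq")
    if (!r$arm %in% c("five_prime", "three_prime"))
      stop(where, "arm must be five_prime or three_prime")
    if (r$length_precursor < r$length_mature)
      stop(where, "precursor shorter than mature")
    if (!is.finite(r$mfe) || r$mfe >= 0) stop(where, "MFE must be negative")
    if (!is.finite(r$mfei) || r$mfei <= 0) stop(where, "MFEI must be positive")
    if (r$gc_percent <= 0 || r$gc_percent >= 100)
      stop(where, "GC% out of range")
  }
  if (!is.na(expected_n) && nrow(cat) != expected_n) {
    stop("catalog integrity: expected ", expected_n, " records, found ",
         nrow(cat))
  }
  cat
}

#' Summarize a miRNA catalog
#'
#' Computes the headline descriptive statistics of a catalog: record count,
#' modal mature length, precursor length range and (integer-rounded) mean,
#' arm percentages (1 decimal), percentage of matures starting with U
#' (nearest integer), mean precursor GC% (2 decimals), and MFE/MFEI range
#' and mean (2 decimals).
#'
#' @param records Catalog `data.frame` as returned by [load_catalog()].
#' @return A one-row `data.frame` of summary statistics.
#' @export
summarize_catalog <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("cannot summarize an empty catalog")
  n <- nrow(records)
  lm <- records$length_mature
  modal <- as.integer(names(sort(table(lm), decreasing = TRUE))[1])
  p3 <- round(100 * mean(records$arm == "three_prime"), 1)
  p5 <- round(100 * mean(records$arm == "five_prime"), 1)
  data.frame(
    n_records = n,
    modal_mature_length = modal,
    precursor_min = min(records$length_precursor),
    precursor_max = max(records$length_precursor),
    precursor_mean = as.integer(round(mean(records$length_precursor))),
    pct_three_prime = p3,
    pct_five_prime = p5,
    pct_u_start = as.integer(round(100 * mean(substr(records$mature_seq, 1, 1) == "U"))),
    gc_mean = round(mean(records$gc_percent), 2),
    mfe_min = round(min(records$mfe), 2),
    mfe_max = round(max(records$mfe), 2),
    mfe_mean = round(mean(records$mfe), 2),
    mfei_min = round(min(records$mfei), 2),
    mfei_max = round(max(records$mfei), 2),
    mfei_mean = round(mean(records$mfei), 2)
  )
}

#' Truncate a value to two decimals
#'
#' The published MFEI column truncates (floors) rather than rounds; a small
#' epsilon guards against floating-point representation of exact hundredths.
#'
#' @param x Numeric vector.
#' @return `x` truncated to 2 decimal places.
#' @export
truncate_2dp <- function(x) floor(round(x * 100, 6)) / 100

#' Recompute the MFEI column of a catalog
#'
#' Applies the MFEI formula `(|MFE| / precursor length * 100) / GC%` to each
#' record, truncates the result to two decimals, and counts agreement with
#' the printed `mfei` column.
#'
#' @param records Catalog `data.frame`.
#' @return List with `per_record` (`data.frame` of name, printed, recomputed,
#'   agreement flag) and `n_agree` (count of agreeing rows).
#' @export
recompute_mfei_column <- function(records) {
  if (any(records$gc_percent == 0)) stop("GC% of zero: MFEI undefined")
  recomputed <- truncate_2dp(
    compute_mfei(records$mfe, records$length_precursor, records$gc_percent)
  )
  agree <- abs(recomputed - records$mfei) < 1e-9
  list(
    per_record = data.frame(
      name = records$name,
      mfei_printed = records$mfei,
      mfei_recomputed = recomputed,
      agrees = agree
    ),
    n_agree = sum(agree)
  )
}

#' Write a catalog summary as TSV and a text report
#'
#' @param summary One-row `data.frame` from [summarize_catalog()].
#' @param tsv_path,txt_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, the report lines.
#' @export
write_catalog_summary <- function(summary, tsv_path = NULL, txt_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(summary, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  lines <- c(
    sprintf("miRNA catalog: %d records", summary$n_records),
    sprintf("modal mature length: %d nt", summary$modal_mature_length),
    sprintf("precursor length: %d-%d nt (mean %d nt)",
            summary$precursor_min, summary$precursor_max, summary$precursor_mean),
    sprintf("arm location: %.1f%% 3' arm, %.1f%% 5' arm",
            summary$pct_three_prime, summary$pct_five_prime),
    sprintf("matures starting with U: %d%%", summary$pct_u_start),
    sprintf("precursor GC content: mean %.2f%%", summary$gc_mean),
    sprintf("MFE: %.2f to %.2f kcal/mol (mean %.2f)",
            summary$mfe_min, summary$mfe_max, summary$mfe_mean),
    sprintf("MFEI: %.2f to %.2f (mean %.2f)",
            summary$mfei_min, summary$mfei_max, summary$mfei_mean)
  )
  if (!is.null(txt_path)) writeLines(lines, txt_path)
  invisible(lines)
}
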