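#' Read a Ct table
#'
#' @param path TSV with columns `tissue`, `gene`, `replicate`, `ct`.
#' @return Validated `data.frame`.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("tissue", "gene", "replicate", "ct")
  if (!all(need %in% names(df)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(df$ct)) || any(df$ct <= 0)) stop("Ct values must be positive")
  if (any(df$replicate < 1)) stop("replicate indices start at 1")
  df
}

#' Mean and standard deviation of replicate Ct values
#'
#' @param ct Numeric vector of replicate Ct measurements for one
#'   tissue-by-gene cell (at least one value).
#' @return List with `mean` and `sd` (`NA` for a single replicate).
#' @export
mean_ct <- function(ct) {
  if (length(ct) == 0) stop("no replicate Ct values")
  list(mean = mean(ct), sd = if (length(ct) > 1) stats::sd(ct) else NA_real_)
}

#' Comparative-Ct fold change (2^-ddCt)
#'
#' `dCt_test = Ct_gene,test - Ct_ref,test`; likewise for the calibrator;
#' `ddCt = dCt_test - dCt_cal`; `fold = 2^-ddCt`. Amplification efficiency
#' is fixed at 2.
#'
#' @param ct_gene_test,ct_ref_test,ct_gene_cal,ct_ref_cal Mean Ct values
#'   (cycles) of the gene and the reference in the test and calibrator
#'   samples.
#' @return List with `delta_ct_test`, `delta_ct_calibrator`,
#'   `delta_delta_ct`, `fold_change`.
#' @export
fold_change <- function(ct_gene_test, ct_ref_test, ct_gene_cal, ct_ref_cal) {
  vals <- c(ct_gene_test, ct_ref_test, ct_gene_cal, ct_ref_cal)
  if (length(vals) != 4 || any(is.na(vals)))
    stop("all four Ct inputs are required")
  d_test <- ct_gene_test - ct_ref_test
  d_cal <- ct_gene_cal - ct_ref_cal
  ddct <- d_test - d_cal
  list(delta_ct_test = d_test, delta_ct_calibrator = d_cal,
       delta_delta_ct = ddct, fold_change = 2^(-ddct))
}

#' Per-gene fold changes between two tissues
#'
#' Averages replicates on the Ct scale, normalizes each gene to the
#' reference gene within each tissue, and reports 2^-ddCt of the test
#' tissue relative to the calibrator. Genes missing in either tissue are
#' skipped with a warning.
#'
#' @param table Ct `data.frame` (`tissue`, `gene`, `replicate`, `ct`).
#' @param test,calibrator Tissue labels (e.g. `"brain"`, `"liver"`).
#' @param reference_gene Internal reference (default `"U6"`).
#' @return `data.frame` with `gene`, `delta_ct_test`,
#'   `delta_ct_calibrator`, `delta_delta_ct`, `fold_change`, `sd_test`,
#'   `sd_calibrator` (replicate SDs of the gene's Ct).
#' @export
tissue_contrast <- function(table, test, calibrator, reference_gene = "U6") {
  stopifnot(is.data.frame(table))
  cell <- function(tissue, gene) {
    ct <- table$ct[table$tissue == tissue & table$gene == gene]
    if (length(ct) == 0) return(NULL)
    mean_ct(ct)
  }
  ref_test <- cell(test, reference_gene)
  ref_cal <- cell(calibrator, reference_gene)
  if (is.null(ref_test) || is.null(ref_cal))
    stop("reference gene '", reference_gene, "' missing in '",
         if (is.null(ref_test)) test else calibrator, "'")
  genes <- setdiff(unique(table$gene), reference_gene)
  rows <- list()
  for (g in genes) {
    g_test <- cell(test, g)
    g_cal <- cell(calibrator, g)
    if (is.null(g_test) || is.null(g_cal)) {
      warning("gene '", g, "' not measured in both tissues; skipped")
      next
    }
    fc <- fold_change(g_test$mean, ref_test$mean, g_cal$mean, ref_cal$mean)
    rows[[length(rows) + 1L]] <- data.frame(
      gene = g, delta_ct_test = fc$delta_ct_test,
      delta_ct_calibrator = fc$delta_ct_calibrator,
      delta_delta_ct = fc$delta_delta_ct, fold_change = fc$fold_change,
      sd_test = g_test$sd, sd_calibrator = g_cal$sd,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), delta_ct_test = numeric(),
               delta_ct_calibrator = numeric(), delta_delta_ct = numeric(),
               fold_change = numeric(), sd_test = numeric(),
               sd_calibrator = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
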