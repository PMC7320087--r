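#' Pipeline configuration
#'
#' Collects every tunable parameter of the discovery, target and expression
#' stages with its default. The resolved configuration is serialized into
#' the header of every report the pipeline writes.
#'
#' @param flank Nucleotides excised on each side of a genomic hit (200).
#' @param min_orf Minimum ORF length for the protein-coding filter (300 nt).
#' @param max_star_mismatches,min_mfei,min_loop Hairpin filter thresholds
#'   (see [filter_thresholds()]).
#' @param min_coverage,min_identity Target pre-screen thresholds (75%).
#' @param reference_gene,calibrator,test_tissue qPCR settings
#'   (U6; liver as calibrator; brain as test).
#' @param dedupe Collapse identical loci hit by several references (TRUE).
#' @param seed Integer seed recorded with every run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(flank = 200L, min_orf = 300L,
                            max_star_mismatches = 8L, min_mfei = 0.70,
                            min_loop = 3L, min_coverage = 75,
                            min_identity = 75, reference_gene = "U6",
                            calibrator = "liver", test_tissue = "brain",
                            dedupe = TRUE, seed = 1L) {
  stopifnot(flank >= 0, min_orf >= 0, min_coverage >= 0, min_coverage <= 100,
            min_identity >= 0, min_identity <= 100)
  structure(
    list(flank = as.integer(flank), min_orf = as.integer(min_orf),
         thresholds = filter_thresholds(max_star_mismatches, min_mfei,
                                        min_loop),
         min_coverage = min_coverage, min_identity = min_identity,
         reference_gene = reference_gene, calibrator = calibrator,
         test_tissue = test_tissue, dedupe = isTRUE(dedupe),
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

config_header <- function(config) {
  th <- config$thresholds
  c(sprintf("# mirhomology %s",
            as.character(utils::packageVersion("mirhomology"))),
    sprintf("# flank=%d min_orf=%d max_star_mismatches=%d min_mfei=%.2f min_loop=%d",
            config$flank, config$min_orf, th$max_star_mismatches,
            th$min_mfei, th$min_loop),
    sprintf("# min_coverage=%g min_identity=%g reference_gene=%s calibrator=%s test_tissue=%s dedupe=%s seed=%d",
            config$min_coverage, config$min_identity, config$reference_gene,
            config$calibrator, config$test_tissue, config$dedupe,
            config$seed))
}

write_report_tsv <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(config_header(config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

as_contig_set <- function(x, what) {
  if (is.character(x) && length(x) == 1 && is.null(names(x)) &&
      file.exists(x)) {
    return(read_rna_fasta(x))
  }
  if (!is.character(x) || is.null(names(x)))
    stop(what, " must be a named character vector or a FASTA path")
  normalize_to_rna(x)
}

#' Run the full miRNA discovery stage
#'
#' Chains exact homology search, locus deduplication, precursor-window
#' excision, the protein-coding filter, folding, hairpin trimming and the
#' filtering criteria, and returns a catalog-style table of accepted
#' precursors plus per-stage counts.
#'
#' @param genome Named character vector of contigs or a FASTA path.
#' @param refs Named character vector of reference matures or a FASTA path.
#' @param config A [pipeline_config()].
#' @param out_dir If non-`NULL`, `discovery_catalog.tsv`,
#'   `discovery_candidates.tsv` and `discovery_structures.db` are written
#'   there.
#' @return List with `catalog` (accepted rows: `name`, `length_mature`,
#'   `query`, `mature_seq`, `arm`, `length_precursor`, `gc_percent`, `mfe`,
#'   `mfei`, plus locus columns), `candidates` (all verdicts), and `log`
#'   (named stage counts).
#' @export
run_discovery <- function(genome, refs, config = pipeline_config(),
                          out_dir = NULL) {
  genome <- as_contig_set(genome, "genome")
  refs <- as_contig_set(refs, "refs")
  lens <- nchar(refs)
  if (any(lens < 18 | lens > 26))
    warning(sum(lens < 18 | lens > 26),
            " reference(s) outside the typical 18-26 nt mature range")
  hits <- find_exact_matches(refs, genome)
  n_hits <- nrow(hits)
  n_collapsed <- 0L
  if (config$dedupe) {
    hits <- dedupe_hits(hits)
    n_collapsed <- attr(hits, "n_collapsed")
  }
  windows <- lapply(seq_len(nrow(hits)), function(i)
    extract_precursor_window(genome, hits[i, ], flank = config$flank))
  orf <- exclude_protein_coding(windows, min_orf = config$min_orf)
  cands <- lapply(orf$kept, assemble_candidate, th = config$thresholds)
  cand_row <- function(cc) {
    h <- cc$window$hit
    data.frame(
      name = sprintf("%s|%s:%d%s", h$ref_id, h$contig, h$start, h$strand),
      length_mature = nchar(h$matched_seq), query = h$ref_id,
      mature_seq = h$matched_seq,
      arm = cc$arm,
      length_precursor = if (is.na(cc$trimmed_seq)) NA_integer_
                         else nchar(cc$trimmed_seq),
      gc_percent = round(cc$gc_percent, 2), mfe = cc$mfe,
      mfei = if (is.na(cc$mfei)) NA_real_ else truncate_2dp(cc$mfei),
      contig = h$contig, start = h$start, end = h$end, strand = h$strand,
      verdict = cc$verdict,
      reasons = paste(cc$reasons, collapse = "; "),
      stringsAsFactors = FALSE
    )
  }
  cand_table <- if (length(cands)) do.call(rbind, lapply(cands, cand_row))
    else data.frame()
  accepted <- if (nrow(cand_table))
    cand_table[cand_table$verdict == "accepted",
               c("name", "length_mature", "query", "mature_seq", "arm",
                 "length_precursor", "gc_percent", "mfe", "mfei", "contig",
                 "start", "end", "strand")]
    else data.frame()
  rownames(accepted) <- NULL
  log <- list(n_refs = length(refs), n_hits = n_hits,
              n_collapsed = n_collapsed, n_windows = length(windows),
              n_orf_rejected = length(windows) - length(orf$kept),
              n_folded = length(cands),
              n_accepted = sum(vapply(cands, function(x) x$verdict, "") ==
                                 "accepted"),
              n_rejected = sum(vapply(cands, function(x) x$verdict, "") ==
                                 "rejected"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report_tsv(accepted, file.path(out_dir, "discovery_catalog.tsv"),
                     config)
    write_report_tsv(cand_table,
                     file.path(out_dir, "discovery_candidates.tsv"), config)
    acc <- cands[vapply(cands, function(x) x$verdict, "") == "accepted"]
    if (length(acc)) {
      structures <- stats::setNames(
        lapply(acc, function(x) x$structure),
        vapply(acc, function(x) {
          h <- x$window$hit
          sprintf("%s|%s:%d%s", h$ref_id, h$contig, h$start, h$strand)
        }, "")
      )
      write_dotbracket(structures,
                       file.path(out_dir, "discovery_structures.db"))
    }
  }
  list(catalog = accepted, candidates = cands, candidate_table = cand_table,
       log = log)
}

#' Run the target-prediction stage
#'
#' @param catalog Catalog `data.frame` (columns `name`, `mature_seq`) or
#'   named character vector of matures.
#' @param transcripts Named character vector or FASTA path.
#' @param config A [pipeline_config()].
#' @param out_file If non-`NULL`, the target table is written there with a
#'   provenance header.
#' @return Target table from [scan_targets()].
#' @export
run_targets <- function(catalog, transcripts, config = pipeline_config(),
                        out_file = NULL) {
  transcripts <- as_contig_set(transcripts, "transcripts")
  targets <- scan_targets(catalog, transcripts,
                          min_coverage = config$min_coverage,
                          min_identity = config$min_identity)
  if (!is.null(out_file)) write_report_tsv(targets, out_file, config)
  targets
}

#' Run the expression-quantification stage
#'
#' @param ct_table Ct `data.frame` or TSV path
#'   (`tissue`, `gene`, `replicate`, `ct`).
#' @param config A [pipeline_config()].
#' @param out_file If non-`NULL`, fold changes are written there.
#' @return Fold-change table from [tissue_contrast()].
#' @export
run_expression <- function(ct_table, config = pipeline_config(),
                           out_file = NULL) {
  if (is.character(ct_table)) ct_table <- read_ct_table(ct_table)
  res <- tissue_contrast(ct_table, test = config$test_tissue,
                         calibrator = config$calibrator,
                         reference_gene = config$reference_gene)
  if (!is.null(out_file)) write_report_tsv(res, out_file, config)
  res
}
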