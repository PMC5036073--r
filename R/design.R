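# Run design: end layouts, sample sheets and the run configuration.
#
# A tagged amplicon end reads, 5' to 3':
#   [phaser 0-3 nt][sample barcode 8 nt][random tag 10 nt][gene primer][gene ...]
# The forward end carries the 27F annealing sequence, the reverse end the
# 1391R annealing sequence (read orientation). Both are configurable.

#' Default 27F annealing sequence (bacterial 16S forward primer)
#' @export
PRIMER_27F <- "AGAGTTTGATCMTGGCTCAG"

#' Default 1391R annealing sequence (bacterial 16S reverse primer)
#' @export
PRIMER_1391R <- "GACGGGCGGTGWGTRCA"

#' Describe the synthetic layout of one tagged amplicon end
#'
#' @param end_label `"FORWARD"` or `"REVERSE"`.
#' @param gene_primer the primer annealing sequence expected downstream of the
#'   random tag (IUPAC codes allowed).
#' @param phaser_lengths allowed phaser lengths, scanned in ascending order.
#' @param barcode_length,tag_length,gene_prefix_length layout element widths.
#' @return an object of class `end_design`.
#' @export
end_design <- function(end_label = c("FORWARD", "REVERSE"),
                       gene_primer = if (match.arg(end_label) == "FORWARD")
                         PRIMER_27F else PRIMER_1391R,
                       phaser_lengths = 0:3,
                       barcode_length = 8L,
                       tag_length = 10L,
                       gene_prefix_length = 14L) {
  end_label <- match.arg(end_label)
  stopifnot(barcode_length > 0L, tag_length > 0L, nchar(gene_primer) > 0L,
            all(phaser_lengths >= 0L), gene_prefix_length > 0L)
  structure(list(
    end_label = end_label,
    phaser_lengths = sort(unique(as.integer(phaser_lengths))),
    barcode_length = as.integer(barcode_length),
    tag_length = as.integer(tag_length),
    gene_primer = toupper(gene_primer),
    gene_prefix_length = as.integer(gene_prefix_length)
  ), class = "end_design")
}

#' @export
print.end_design <- function(x, ...) {
  cat(sprintf("<end_design %s> phaser %s | barcode %d | tag %d | primer %s\n",
              x$end_label, paste(range(x$phaser_lengths), collapse = "-"),
              x$barcode_length, x$tag_length, x$gene_primer))
  invisible(x)
}

# layout offset where the biological insert (post-primer) begins, for a given
# phaser length; 0-based
insert_start_for <- function(design, phaser_len) {
  phaser_len + design$barcode_length + design$tag_length +
    nchar(design$gene_primer)
}

#' Build and validate a sample sheet
#'
#' Each sample is identified by an ordered (forward barcode, reverse barcode)
#' pair. Within each barcode set the minimum pairwise Hamming distance must be
#' at least 3 so that decoding with one tolerated mismatch is unambiguous.
#'
#' @param samples data.frame with columns `sample`, `barcode_f`, `barcode_r`.
#' @param barcode_length expected barcode width (default 8).
#' @return an object of class `sample_sheet`.
#' @export
sample_sheet <- function(samples, barcode_length = 8L) {
  need <- c("sample", "barcode_f", "barcode_r")
  if (!all(need %in% names(samples)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  samples <- data.frame(sample = as.character(samples$sample),
                        barcode_f = toupper(as.character(samples$barcode_f)),
                        barcode_r = toupper(as.character(samples$barcode_r)),
                        stringsAsFactors = FALSE)
  bad <- nchar(samples$barcode_f) != barcode_length |
    nchar(samples$barcode_r) != barcode_length
  if (any(bad))
    stop("barcode of wrong length for sample(s): ",
         paste(samples$sample[bad], collapse = ", "))
  combo <- paste(samples$barcode_f, samples$barcode_r)
  if (anyDuplicated(combo))
    stop("duplicated barcode combination: ", combo[duplicated(combo)][1])
  if (anyDuplicated(samples$sample))
    stop("duplicated sample name")
  for (side in c("barcode_f", "barcode_r")) {
    set <- unique(samples[[side]])
    d <- hamming_pairwise_min(set)
    if (d < 3)
      stop(sprintf(
        "minimum pairwise Hamming distance in the %s set is %d (< 3); ",
        if (side == "barcode_f") "forward" else "reverse", d),
        "1-mismatch decoding would be ambiguous")
  }
  structure(list(samples = samples,
                 forward_set = unique(samples$barcode_f),
                 reverse_set = unique(samples$barcode_r),
                 barcode_length = as.integer(barcode_length)),
            class = "sample_sheet")
}

#' Load a sample sheet from a TSV/CSV file
#'
#' The file must have columns `sample`, `barcode_f`, `barcode_r` (tab- or
#' comma-separated, with header). Barcodes are upper-cased and validated as in
#' [sample_sheet()].
#'
#' @param path file path.
#' @param barcode_length expected barcode width.
#' @return a `sample_sheet`.
#' @export
load_sample_sheet <- function(path, barcode_length = 8L) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "")
  sample_sheet(df, barcode_length = barcode_length)
}

#' @export
print.sample_sheet <- function(x, ...) {
  cat(sprintf("<sample_sheet> %d samples, %d forward x %d reverse barcodes\n",
              nrow(x$samples), length(x$forward_set), length(x$reverse_set)))
  invisible(x)
}

#' Assemble the run configuration
#'
#' Houses every tunable threshold of the pipeline with the defaults used
#' throughout: dual-tag signature clustering at identity > 0.89, one tolerated
#' mismatch when matching tags to consensus tags, two tolerated mismatches in
#' the primer-annealing screen, the strict 10-fold contig coverage rule,
#' assembly k-mer size 31 and Q20 quality trimming.
#'
#' @param forward_design,reverse_design [end_design()] objects.
#' @param identity_threshold signature clustering identity (0, 1].
#' @param tag_mismatch_budget mismatches tolerated when binning reads by tag.
#' @param primer_max_mismatch mismatches tolerated in the primer screen.
#' @param contig_fold coverage fold for the chimera contig filter (> 1).
#' @param k assembly k-mer size; `map_k` the map-back anchor k-mer size.
#' @param quality_trim_q PHRED threshold for 3' quality trimming.
#' @param correct_min_count solid k-mer count for error correction.
#' @param map_min_identity minimum identity for map-back read placement.
#' @param adapter_stubs named character vector of synthetic stubs searched for
#'   3' read-through trimming.
#' @param seed integer random seed recorded with the run.
#' @param out_dir output directory for file-emitting stages.
#' @return an object of class `run_config`.
#' @export
run_config <- function(forward_design = end_design("FORWARD"),
                       reverse_design = end_design("REVERSE"),
                       identity_threshold = 0.89,
                       tag_mismatch_budget = 1L,
                       primer_max_mismatch = 2L,
                       contig_fold = 10,
                       k = 31L,
                       map_k = 15L,
                       quality_trim_q = 20L,
                       correct_min_count = 3L,
                       map_min_identity = 0.90,
                       adapter_stubs = c(nextera = "CTGTCTCTTATACACATCT",
                                         pe = "AGATCGGAAGAGC"),
                       seed = 1L,
                       out_dir = NULL) {
  stopifnot(inherits(forward_design, "end_design"),
            inherits(reverse_design, "end_design"),
            identity_threshold > 0, identity_threshold <= 1,
            contig_fold > 1, k > 1, tag_mismatch_budget >= 0)
  structure(list(
    forward_design = forward_design, reverse_design = reverse_design,
    identity_threshold = identity_threshold,
    tag_mismatch_budget = as.integer(tag_mismatch_budget),
    primer_max_mismatch = as.integer(primer_max_mismatch),
    contig_fold = contig_fold, k = as.integer(k), map_k = as.integer(map_k),
    quality_trim_q = as.integer(quality_trim_q),
    correct_min_count = as.integer(correct_min_count),
    map_min_identity = map_min_identity,
    adapter_stubs = adapter_stubs,
    seed = as.integer(seed), out_dir = out_dir
  ), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n",
      sprintf("  clustering identity > %.2f, tag budget %d, primer tol %d\n",
              x$identity_threshold, x$tag_mismatch_budget,
              x$primer_max_mismatch),
      sprintf("  assembly k=%d (map k=%d), Q%d trim, %gx contig filter\n",
              x$k, x$map_k, x$quality_trim_q, x$contig_fold), sep = "")
  invisible(x)
}

#' Read a run configuration from YAML/JSON
#'
#' Recognised keys mirror the [run_config()] arguments; `forward_primer` and
#' `reverse_primer` override the end-design annealing sequences.
#' @param path YAML (or JSON) file.
#' @return a `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  fd <- end_design("FORWARD",
                   gene_primer = vals$forward_primer %||% PRIMER_27F)
  rd <- end_design("REVERSE",
                   gene_primer = vals$reverse_primer %||% PRIMER_1391R)
  keep <- intersect(names(vals), setdiff(names(formals(run_config)),
                                         c("forward_design", "reverse_design",
                                           "adapter_stubs")))
  do.call(run_config, c(list(forward_design = fd, reverse_design = rd),
                        vals[keep]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
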