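# FASTQ/FASTA input and output. Paired reads travel as a plain data.frame
# ("read pair table") with columns pair_id, seq1, qual1, seq2, qual2; quality
# strings stay PHRED+33-encoded until arithmetic needs integers.

#' Read paired-end FASTQ files into a read pair table
#'
#' Both files must be PHRED+33 FASTQ (plain or gzip) with records in the same
#' order. Mate identifiers are reconciled after stripping `/1`, `/2` and
#' whitespace-delimited descriptions.
#'
#' @param path_r1,path_r2 file paths of the two mate files.
#' @return data.frame with columns `pair_id`, `seq1`, `qual1`, `seq2`, `qual2`
#'   (qualities as PHRED+33 strings).
#' @export
read_fastq_pairs <- function(path_r1, path_r2) {
  for (p in c(path_r1, path_r2))
    if (!file.exists(p)) stop("FASTQ file not found: ", p)
  read_one <- function(p) withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(p),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  r1 <- read_one(path_r1)
  r2 <- read_one(path_r2)
  if (length(r1) != length(r2))
    stop(sprintf(
      "mismatched record counts (%d in %s, %d in %s); first unpaired record %d",
      length(r1), path_r1, length(r2), path_r2,
      min(length(r1), length(r2)) + 1L))
  id1 <- strip_mate_suffix(names(r1))
  id2 <- strip_mate_suffix(names(r2))
  bad <- which(id1 != id2)
  if (length(bad))
    stop(sprintf("mate ID mismatch at record %d: '%s' vs '%s'",
                 bad[1], id1[bad[1]], id2[bad[1]]))
  data.frame(pair_id = id1,
             seq1 = as.character(r1),
             qual1 = as.character(Biostrings::quality(r1)),
             seq2 = as.character(r2),
             qual2 = as.character(Biostrings::quality(r2)),
             stringsAsFactors = FALSE, row.names = NULL)
}

strip_mate_suffix <- function(ids) {
  ids <- sub("\\s.*$", "", ids)
  sub("/[12]$", "", ids)
}

#' Write a read pair table as two FASTQ files
#'
#' @param pairs read pair table as returned by [read_fastq_pairs()].
#' @param path_r1,path_r2 output paths (".gz" suffix compresses).
#' @export
write_fastq_pairs <- function(pairs, path_r1, path_r2) {
  write_one <- function(seqs, quals, ids, path, mate) {
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(seqs),
      Biostrings::PhredQuality(quals))
    names(x) <- paste0(ids, "/", mate)
    Biostrings::writeQualityScaledXStringSet(
      x, path, compress = grepl("\\.gz$", path))
  }
  write_one(pairs$seq1, pairs$qual1, pairs$pair_id, path_r1, 1L)
  write_one(pairs$seq2, pairs$qual2, pairs$pair_id, path_r2, 2L)
  invisible(NULL)
}

#' Write consensus records as FASTA plus FASTQ
#'
#' Record IDs encode sample, cluster and length as
#' `<sample>|<cluster_id>|len=<n>`. Qualities are PHRED+33 with 93 (`~`) as
#' the cap; values outside 0-93 are an error.
#'
#' @param records list of `consensus_seq` objects (see [call_consensus()]), or
#'   a list of lists with fields `cluster_id`, `sample`, `sequence`, `quality`.
#' @param fasta_path,fastq_path output paths; either may be `NULL` to skip.
#' @export
write_fasta_with_quality <- function(records, fasta_path = NULL,
                                     fastq_path = NULL) {
  records <- unname(records)
  seqs <- vapply(records, function(r) r$sequence, character(1))
  ids <- vapply(records, function(r)
    sprintf("%s|%s|len=%d", r$sample %||% "NA", r$cluster_id %||% "NA",
            nchar(r$sequence)), character(1))
  quals <- vapply(records, function(r) {
    if (length(r$quality) != nchar(r$sequence))
      stop("sequence and quality lengths differ for ", r$cluster_id)
    int_to_phred(r$quality)
  }, character(1))
  if (!is.null(fasta_path)) {
    x <- Biostrings::DNAStringSet(seqs); names(x) <- ids
    Biostrings::writeXStringSet(x, fasta_path)
  }
  if (!is.null(fastq_path)) {
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(quals))
    names(x) <- ids
    Biostrings::writeQualityScaledXStringSet(x, fastq_path, compress = FALSE)
  }
  invisible(ids)
}
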