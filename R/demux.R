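# Demultiplexing: decode the phaser/barcode/tag/primer layout on each read
# end, classify read pairs as end+end or end+internal, and assign samples.
#
# The decoding rule: scan the allowed phaser lengths in ascending order; at
# each offset the 8-nt window must match exactly one known barcode with at
# most one mismatch AND the primer annealing sequence must follow the random
# tag with at most `primer_max_mismatch` mismatches (IUPAC-aware). The first
# satisfying offset wins. Reads lacking both conditions on an end carry no
# parse for that end.

#' Decode the synthetic layout of one read end (vectorised)
#'
#' @param seqs character vector of read sequences.
#' @param design an [end_design()].
#' @param barcode_set known barcodes for this end.
#' @param primer_max_mismatch tolerated mismatches in the primer screen.
#' @return data.frame with one row per read: `ok`, `phaser_len`,
#'   `barcode_observed`, `barcode_assigned`, `barcode_mismatches`, `tag`,
#'   `primer_mismatches`, `gene_prefix`, `insert_start` (0-based offset where
#'   the post-primer biological sequence begins).
#' @export
parse_ends <- function(seqs, design, barcode_set, primer_max_mismatch = 2L) {
  n <- length(seqs)
  out <- data.frame(ok = logical(n), phaser_len = NA_integer_,
                    barcode_observed = NA_character_,
                    barcode_assigned = NA_character_,
                    barcode_mismatches = NA_integer_,
                    tag = NA_character_, primer_mismatches = NA_integer_,
                    gene_prefix = NA_character_, insert_start = NA_integer_,
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  bl <- design$barcode_length; tl <- design$tag_length
  pl <- nchar(design$gene_primer); gl <- design$gene_prefix_length
  bmat <- seq_matrix(toupper(barcode_set))
  len <- nchar(seqs)
  for (p in design$phaser_lengths) {
    need <- p + bl + tl + pl + gl
    todo <- which(!out$ok & len >= need)
    if (!length(todo)) next
    bw <- substr(seqs[todo], p + 1L, p + bl)
    W <- seq_matrix(bw)
    within <- integer(length(todo)); best_mm <- rep(bl, length(todo))
    best_i <- rep(NA_integer_, length(todo))
    for (j in seq_len(ncol(bmat))) {
      d <- hamming_to(bmat[, j], W)
      hit <- d <= 1L
      within <- within + hit
      upd <- hit & d < best_mm
      best_mm[upd] <- d[upd]; best_i[upd] <- j
    }
    pw <- substr(seqs[todo], p + bl + tl + 1L, p + bl + tl + pl)
    pmm <- iupac_mismatch(design$gene_primer, pw)
    ok <- within == 1L & pmm <= primer_max_mismatch
    if (any(ok)) {
      i <- todo[ok]
      out$ok[i] <- TRUE
      out$phaser_len[i] <- p
      out$barcode_observed[i] <- bw[ok]
      out$barcode_assigned[i] <- barcode_set[best_i[ok]]
      out$barcode_mismatches[i] <- best_mm[ok]
      out$tag[i] <- substr(seqs[i], p + bl + 1L, p + bl + tl)
      out$primer_mismatches[i] <- pmm[ok]
      out$insert_start[i] <- p + bl + tl + pl
      out$gene_prefix[i] <- substr(seqs[i], p + bl + tl + pl + 1L,
                                   p + bl + tl + pl + gl)
    }
  }
  out
}

#' Decode a single read end
#'
#' Scalar convenience wrapper around [parse_ends()]; returns `NULL` when the
#' end does not decode (absence is a valid outcome, not an error).
#' @inheritParams parse_ends
#' @param seq a single read sequence.
#' @return one-row data.frame as in [parse_ends()], or `NULL`.
#' @export
parse_end <- function(seq, design, barcode_set, primer_max_mismatch = 2L) {
  res <- parse_ends(seq, design, barcode_set, primer_max_mismatch)
  if (!res$ok[1]) return(NULL)
  res[1, , drop = FALSE]
}

#' Assign samples from an ordered barcode pair (vectorised)
#'
#' @param bc_f,bc_r assigned forward/reverse barcodes.
#' @param sheet a [sample_sheet()].
#' @return character vector: sample name, or `"INVALID_COMBINATION"` for a
#'   pairing of known barcodes never assigned to a sample.
#' @export
assign_sample <- function(bc_f, bc_r, sheet) {
  key <- paste(bc_f, bc_r)
  lookup <- stats::setNames(sheet$samples$sample,
                            paste(sheet$samples$barcode_f,
                                  sheet$samples$barcode_r))
  out <- unname(lookup[key])
  out[is.na(out)] <- "INVALID_COMBINATION"
  out
}

#' Classify read pairs as end+end, end+internal or unassigned
#'
#' Each mate is tested against both end designs. Exactly one forward and one
#' reverse parse make an end+end pair (sample assigned from the barcode
#' combination); exactly one parsed mate makes an end+internal pair (the other
#' mate is the internal fragment end); no parse leaves the pair unassigned.
#' Pairs whose mates parse as the same end, or where one mate parses as both
#' ends, are counted as anomalies and left unassigned rather than guessed.
#'
#' @param pairs read pair table ([read_fastq_pairs()]).
#' @param config a [run_config()].
#' @param sheet a [sample_sheet()].
#' @return data.frame (class `classified_pairs`): per pair the
#'   `fragment_class` (`END_END`/`END_INTERNAL`/`UNASSIGNED`), the parsed
#'   end label and mate indices, barcodes, tags, gene prefixes, insert
#'   starts, `sample`, and an `anomaly` flag.
#' @export
classify_pairs <- function(pairs, config, sheet) {
  n <- nrow(pairs)
  tol <- config$primer_max_mismatch
  p1f <- parse_ends(pairs$seq1, config$forward_design, sheet$forward_set, tol)
  p1r <- parse_ends(pairs$seq1, config$reverse_design, sheet$reverse_set, tol)
  p2f <- parse_ends(pairs$seq2, config$forward_design, sheet$forward_set, tol)
  p2r <- parse_ends(pairs$seq2, config$reverse_design, sheet$reverse_set, tol)

  lab <- function(f, r) ifelse(f & r, "BOTH",
                        ifelse(f, "F", ifelse(r, "R", "NONE")))
  l1 <- lab(p1f$ok, p1r$ok); l2 <- lab(p2f$ok, p2r$ok)

  cls <- rep("UNASSIGNED", n)
  anomaly <- l1 == "BOTH" | l2 == "BOTH" |
    (l1 == l2 & l1 %in% c("F", "R"))
  ee <- !anomaly & ((l1 == "F" & l2 == "R") | (l1 == "R" & l2 == "F"))
  ei <- !anomaly & !ee & xor(l1 %in% c("F", "R"), l2 %in% c("F", "R"))
  cls[ee] <- "END_END"; cls[ei] <- "END_INTERNAL"

  f_mate <- ifelse(l1 == "F", 1L, ifelse(l2 == "F", 2L, NA_integer_))
  r_mate <- ifelse(l1 == "R", 1L, ifelse(l2 == "R", 2L, NA_integer_))
  f_mate[anomaly] <- NA_integer_; r_mate[anomaly] <- NA_integer_

  pick <- function(col, mate, tabs) {
    out <- rep(NA, n)
    i1 <- which(mate == 1L); i2 <- which(mate == 2L)
    out[i1] <- tabs[[1]][[col]][i1]
    out[i2] <- tabs[[2]][[col]][i2]
    out
  }
  ftabs <- list(p1f, p2f); rtabs <- list(p1r, p2r)
  res <- data.frame(
    pair_id = pairs$pair_id,
    fragment_class = cls,
    anomaly = anomaly,
    f_mate = f_mate,
    r_mate = r_mate,
    end_label = ifelse(cls == "END_INTERNAL",
                       ifelse(is.na(f_mate), "REVERSE", "FORWARD"),
                       NA_character_),
    internal_mate = ifelse(cls == "END_INTERNAL",
                           ifelse(!is.na(f_mate), 3L - f_mate, 3L - r_mate),
                           NA_integer_),
    bc_f = as.character(pick("barcode_assigned", f_mate, ftabs)),
    bc_r = as.character(pick("barcode_assigned", r_mate, rtabs)),
    tag_f = as.character(pick("tag", f_mate, ftabs)),
    tag_r = as.character(pick("tag", r_mate, rtabs)),
    prefix_f = as.character(pick("gene_prefix", f_mate, ftabs)),
    prefix_r = as.character(pick("gene_prefix", r_mate, rtabs)),
    insert_start_f = as.integer(pick("insert_start", f_mate, ftabs)),
    insert_start_r = as.integer(pick("insert_start", r_mate, rtabs)),
    sample = NA_character_,
    stringsAsFactors = FALSE
  )
  if (any(ee))
    res$sample[ee] <- assign_sample(res$bc_f[ee], res$bc_r[ee], sheet)
  class(res) <- c("classified_pairs", class(res))
  res
}

#' Classify a single read pair
#'
#' @param pair one-row read pair table (or a list with `pair_id`, `seq1`,
#'   `qual1`, `seq2`, `qual2`).
#' @inheritParams classify_pairs
#' @return one-row `classified_pairs` data.frame.
#' @export
classify_pair <- function(pair, config, sheet) {
  classify_pairs(as.data.frame(pair, stringsAsFactors = FALSE), config, sheet)
}

#' Rate of invalid barcode combinations among end+end pairs
#'
#' The fraction of read pairs whose two barcodes are both known but whose
#' ordered pairing was never assigned to a sample - a lower bound on the
#' in-vitro recombination rate. Accepts either a `classified_pairs` table or
#' a raw invalid count.
#'
#' @param x `classified_pairs` data.frame, or the count of invalid-combination
#'   pairs.
#' @param total total number of read pairs considered.
#' @return list with `n_invalid`, `total` and `rate` (percent).
#' @export
invalid_combination_rate <- function(x, total) {
  if (total <= 0) stop("total must be > 0")
  n_invalid <- if (is.data.frame(x)) {
    sum(x$fragment_class == "END_END" &
          !is.na(x$sample) & x$sample == "INVALID_COMBINATION")
  } else as.numeric(x)
  list(n_invalid = n_invalid, total = total,
       rate = 100 * n_invalid / total)
}

#' Summary counts for a classification table
#' @param classified `classified_pairs` data.frame.
#' @return named list of per-class counts and the anomaly count.
#' @export
classification_counts <- function(classified) {
  tab <- table(factor(classified$fragment_class,
                      levels = c("END_END", "END_INTERNAL", "UNASSIGNED")))
  c(as.list(tab),
    list(anomalies = sum(classified$anomaly),
         invalid_combination = sum(classified$sample == "INVALID_COMBINATION",
                                   na.rm = TRUE),
         total = nrow(classified)))
}
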