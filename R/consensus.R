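# Map-back consensus with per-base PHRED qualities. Bin reads are re-placed
# on the kept contigs by a shared-k-mer anchor and gapless comparison
# (substitutions only -- bins are single-template), then a quality-weighted
# consensus is called per column with an additive, capped PHRED model:
#   Q = min(93, max(0, sum(qual of agreeing) - sum(qual of disagreeing))).

#' Map bin reads onto a contig
#'
#' Each read is anchored by its first k-mer (default k = 15) that occurs at a
#' unique position in the contig and compared gaplessly at that offset; up to
#' three distinct candidate offsets are tried. Reads below `min_identity`
#' over the overlap stay unmapped.
#'
#' @param contig a contig (from [assemble_bin()]) or a sequence string.
#' @param seqs,quals oriented read sequences and PHRED+33 quality strings.
#' @param k anchor k-mer size.
#' @param min_identity minimum identity over the aligned overlap.
#' @return object of class `pileup`: list with `qsum` and `count` (5 x L
#'   matrices over A,C,G,T,N), `depth`, `n_mapped`, `contig` sequence.
#' @export
map_reads <- function(contig, seqs, quals, k = 15L, min_identity = 0.90) {
  cseq <- if (is.list(contig)) contig$sequence else contig
  L <- nchar(cseq)
  ckm <- substring(cseq, 1:(L - k + 1L), k:L)
  u <- unique(ckm)
  pos_of <- match(ckm, u)
  occ <- tabulate(pos_of, length(u))
  unique_km <- u[occ == 1L]
  unique_pos <- match(unique_km, ckm)  # contig start (1-based) of each

  cint <- utf8ToInt(cseq)
  pos_all <- integer(0); base_all <- integer(0); qual_all <- integer(0)
  n_mapped <- 0L

  for (ri in seq_along(seqs)) {
    s <- seqs[ri]; n <- nchar(s)
    if (n < k) next
    rkm <- substring(s, 1:(n - k + 1L), k:n)
    hit <- match(rkm, unique_km)
    cand <- which(!is.na(hit))
    if (!length(cand)) next
    offsets <- unique(unique_pos[hit[cand]] - cand)  # 0-based shift
    rint <- utf8ToInt(s)
    qint <- utf8ToInt(quals[ri]) - 33L
    for (off in offsets[seq_len(min(3L, length(offsets)))]) {
      a <- max(1L, 1L - off); b <- min(n, L - off)
      if (b - a + 1L < k) next
      rseg <- rint[a:b]
      cseg <- cint[(a + off):(b + off)]
      agree <- rseg == cseg & rseg != .N_INT
      if (mean(agree) < min_identity) next
      n_mapped <- n_mapped + 1L
      pos_all <- c(pos_all, (a:b) + off)
      base_all <- c(base_all, rseg)
      qual_all <- c(qual_all, qint[a:b])
      break
    }
  }

  qsum <- matrix(0, nrow = 5L, ncol = L, dimnames = list(.BASES, NULL))
  count <- matrix(0L, nrow = 5L, ncol = L, dimnames = list(.BASES, NULL))
  if (length(pos_all)) {
    brow <- match(base_all, .BASE_INT)
    ok <- !is.na(brow)
    key <- (pos_all[ok] - 1L) * 5L + brow[ok]
    qs <- rowsum(as.numeric(qual_all[ok]), key)
    ct <- rowsum(rep(1L, sum(ok)), key)
    kk <- as.integer(rownames(qs))
    qsum[kk] <- qs[, 1L]
    count[kk] <- ct[, 1L]
  }
  structure(list(qsum = qsum, count = count,
                 depth = colSums(count), n_mapped = n_mapped,
                 contig = cseq),
            class = "pileup")
}

#' Call a consensus sequence with PHRED qualities from a pileup
#'
#' Per column the consensus base is the quality-weighted plurality (ties by
#' base order A < C < G < T; N never wins a tie); its PHRED score is the
#' summed quality of agreeing bases minus that of disagreeing bases, clamped
#' to 0..93. Columns without coverage fall back to the contig base at
#' quality 0.
#'
#' @param pileup a `pileup` from [map_reads()].
#' @param cluster_id,sample identifiers carried through to the record.
#' @return object of class `consensus_seq`: list with `sequence`, `quality`
#'   (integer PHRED), `coverage`, `cluster_id`, `sample`.
#' @export
call_consensus <- function(pileup, cluster_id = NA_character_,
                           sample = NA_character_) {
  if (!inherits(pileup, "pileup")) stop("call_consensus needs a pileup")
  L <- ncol(pileup$qsum)
  if (L == 0L) stop("cannot call a consensus from an empty pileup")
  pick <- max.col(t(pileup$qsum), ties.method = "first")
  tot <- colSums(pileup$qsum)
  agree <- pileup$qsum[cbind(pick, seq_len(L))]
  q <- .clamp(agree - (tot - agree), 0, 93)
  covered <- pileup$depth > 0L
  basev <- .BASE_INT[pick]
  if (any(!covered)) {
    basev[!covered] <- utf8ToInt(pileup$contig)[!covered]
    q[!covered] <- 0
  }
  structure(list(sequence = intToUtf8(basev),
                 quality = as.integer(round(q)),
                 coverage = as.integer(pileup$depth),
                 cluster_id = cluster_id, sample = sample),
            class = "consensus_seq")
}

#' @export
print.consensus_seq <- function(x, ...) {
  cat(sprintf("<consensus_seq %s> %d nt, median Q%d, median coverage %g\n",
              x$cluster_id, nchar(x$sequence),
              as.integer(stats::median(x$quality)),
              stats::median(x$coverage)))
  invisible(x)
}

#' Per-position quality/coverage profile over a set of consensus sequences
#'
#' @param consensuses list of `consensus_seq` objects.
#' @return data.frame per position index (1..max length): `n` sequences
#'   reaching it, `mean_quality`, `median_quality`, `median_coverage`.
#' @export
quality_profile <- function(consensuses) {
  if (!length(consensuses))
    return(data.frame(position = integer(0), n = integer(0),
                      mean_quality = numeric(0), median_quality = numeric(0),
                      median_coverage = numeric(0)))
  lens <- vapply(consensuses, function(x) length(x$quality), integer(1))
  L <- max(lens)
  qm <- matrix(NA_real_, nrow = length(consensuses), ncol = L)
  cm <- matrix(NA_real_, nrow = length(consensuses), ncol = L)
  for (i in seq_along(consensuses)) {
    qm[i, seq_len(lens[i])] <- consensuses[[i]]$quality
    cm[i, seq_len(lens[i])] <- consensuses[[i]]$coverage
  }
  data.frame(
    position = seq_len(L),
    n = colSums(!is.na(qm)),
    mean_quality = apply(qm, 2, mean, na.rm = TRUE),
    median_quality = apply(qm, 2, stats::median, na.rm = TRUE),
    median_coverage = apply(cm, 2, stats::median, na.rm = TRUE)
  )
}
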