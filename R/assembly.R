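# Per-bin micro-assembly: synthetic-sequence trimming, BWA-style 3' quality
# trimming, k-mer spectrum error correction and de Bruijn contig assembly,
# followed by the strict 10-fold coverage filter that suppresses
# chimera-derived side contigs. Bins hold reads from a single progenitor
# molecule, so the assembler works on one strand: reads are oriented to the
# 27F -> 1391R direction before assembly using their parsed end (or their
# mate's) as the anchor.

#' Trim synthetic sequence from a read
#'
#' Removes (i) the phaser/barcode/tag/primer prefix of a parsed end read
#' (everything before `insert_start`), and (ii) 3' read-through into
#' configured adapter stubs (exact match first, then a 1-mismatch scan).
#' Both operate in read (as-sequenced) orientation. Reads are never discarded
#' here, only shortened.
#'
#' @param seq,qual read sequence and PHRED+33 quality string.
#' @param insert_start 0-based offset of the biological insert for a parsed
#'   end read, or `NA`/`0` for internal reads.
#' @param config a [run_config()].
#' @return list with trimmed `seq` and `qual`.
#' @export
trim_synthetic <- function(seq, qual, insert_start = NA, config = run_config()) {
  if (!is.na(insert_start) && insert_start > 0L) {
    seq <- substr(seq, insert_start + 1L, nchar(seq))
    qual <- substr(qual, insert_start + 1L, nchar(qual))
  }
  # 3' read-through into an adapter stub
  for (stub in config$adapter_stubs) {
    if (nchar(seq) < nchar(stub)) next
    pos <- find_stub(seq, stub)
    if (!is.na(pos)) {
      seq <- substr(seq, 1L, pos - 1L)
      qual <- substr(qual, 1L, pos - 1L)
    }
  }
  list(seq = seq, qual = qual)
}

# Trim partial primer-annealing sequence at the extremities of a
# template-forward oriented read: suffix of the forward primer at the 5' end,
# prefix of the reverse-complemented reverse primer at the 3' end (minimum
# overlap 8 nt, one mismatch tolerated, IUPAC-aware). Primer-annealing
# sequence is primer-derived, not template-derived, so it is synthetic
# wherever it appears.
trim_primer_bleed <- function(seq, qual, config) {
  fp <- config$forward_design$gene_primer
  ov <- primer_overlap_5p(seq, fp)
  if (ov > 0L) {
    seq <- substr(seq, ov + 1L, nchar(seq))
    qual <- substr(qual, ov + 1L, nchar(qual))
  }
  rp <- revcomp_iupac(config$reverse_design$gene_primer)
  ov <- primer_overlap_3p(seq, rp)
  if (ov > 0L) {
    seq <- substr(seq, 1L, nchar(seq) - ov)
    qual <- substr(qual, 1L, nchar(qual) - ov)
  }
  list(seq = seq, qual = qual)
}

# longest suffix of `primer` (length >= min_ov) matching the start of `seq`
# with <= 1 mismatch; returns the overlap length (0 if none)
primer_overlap_5p <- function(seq, primer, min_ov = 8L) {
  m <- nchar(primer); n <- nchar(seq)
  if (min(m, n) < min_ov) return(0L)
  for (ov in seq(min(m, n), min_ov)) {
    mm <- iupac_mismatch(substr(primer, m - ov + 1L, m), substr(seq, 1L, ov))
    if (mm <= 1L) return(ov)
  }
  0L
}

primer_overlap_3p <- function(seq, primer_rc, min_ov = 8L) {
  m <- nchar(primer_rc); n <- nchar(seq)
  if (min(m, n) < min_ov) return(0L)
  for (ov in seq(min(m, n), min_ov)) {
    mm <- iupac_mismatch(substr(primer_rc, 1L, ov),
                         substr(seq, n - ov + 1L, n))
    if (mm <= 1L) return(ov)
  }
  0L
}

# reverse complement that preserves IUPAC degeneracy codes
revcomp_iupac <- function(x) {
  comp <- chartr("ACGTMRWSYKVHDBN", "TGCAKYWSRMBDHVN", x)
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""),
         character(1))
}

#' 3' quality trimming by running sum
#'
#' BWA-style: the read is cut at the position maximising the running sum of
#' `q_threshold - q` taken from the 3' end; an all-high-quality read is
#' untouched.
#'
#' @param seq,qual sequence and PHRED+33 quality string.
#' @param q_threshold PHRED threshold (default 20).
#' @return list with `seq`, `qual`.
#' @export
quality_trim <- function(seq, qual, q_threshold = 20L) {
  q <- utf8ToInt(qual) - 33L
  if (!length(q)) return(list(seq = seq, qual = qual))
  d <- q_threshold - q
  s <- rev(cumsum(rev(d)))
  if (max(s) <= 0) return(list(seq = seq, qual = qual))
  cut <- max(which(s == max(s)))  # ties: shortest trim wins
  list(seq = substr(seq, 1L, cut - 1L), qual = substr(qual, 1L, cut - 1L))
}

# k-mer spectrum of a set of reads: named is avoided; returns list(kmers=
# unique kmer strings, counts)
kmer_spectrum <- function(seqs, k) {
  km <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
  if (!length(km)) return(list(kmers = character(0), counts = integer(0)))
  u <- unique(km)
  list(kmers = u, counts = tabulate(match(km, u), length(u)))
}

#' k-mer spectrum error correction of a bin's reads
#'
#' A base is suspect when every k-mer covering it has count below
#' `min_count`; it is corrected iff exactly one substitution lifts all its
#' covering k-mers to `>= min_count`, with at most `max_corrections` changes
#' per read. Bins with fewer than `min_reads` reads are returned unchanged.
#'
#' @param seqs character vector of (trimmed, oriented) read sequences.
#' @param k k-mer size (default 31).
#' @param min_count solid k-mer threshold (default 3).
#' @param min_reads minimum viable bin size (default 3).
#' @param max_corrections per-read correction cap (default 2).
#' @return corrected read sequences.
#' @export
correct_errors <- function(seqs, k = 31L, min_count = 3L, min_reads = 3L,
                           max_corrections = 2L) {
  if (length(seqs) < min_reads) return(seqs)
  sp <- kmer_spectrum(seqs, k)
  if (!length(sp$kmers)) return(seqs)
  count_of <- function(km) {
    i <- match(km, sp$kmers)
    out <- sp$counts[i]
    out[is.na(i)] <- 0L
    out
  }
  # one batch pass flags reads carrying any weak k-mer; only those enter the
  # per-read repair loop
  long <- which(nchar(seqs) >= k)
  km_by_read <- lapply(seqs[long], function(s) {
    n <- nchar(s)
    substring(s, 1:(n - k + 1L), k:n)
  })
  all_counts <- count_of(unlist(km_by_read, use.names = FALSE))
  has_weak <- vapply(split(all_counts < min_count,
                           rep(seq_along(km_by_read),
                               lengths(km_by_read))),
                     any, logical(1))
  bases <- c("A", "C", "G", "T")
  for (ri in long[has_weak]) {
    s <- seqs[ri]
    n <- nchar(s); nk <- n - k + 1L
    fixes <- 0L
    repeat {
      weak <- count_of(substring(s, 1:nk, k:n)) < min_count
      if (!any(weak)) break
      # base i is suspect iff no strong k-mer covers it
      strong_cum <- cumsum(!weak)
      i_all <- seq_len(n)
      j0 <- pmax(1L, i_all - k + 1L); j1 <- pmin(i_all, nk)
      covered <- j1 >= j0
      nstrong <- strong_cum[pmax(j1, 1L)] -
        ifelse(j0 > 1L, strong_cum[j0 - 1L], 0L)
      sus <- which(covered & nstrong == 0L)
      # an isolated substitution leaves only a handful of bases without any
      # strong covering k-mer; a fully weak read is low coverage, not an
      # error, and is left alone
      if (!length(sus) || length(sus) > 2L * k) break
      # evaluate all (position, base) candidates with one spectrum lookup
      cand_pos <- integer(0); cand_base <- character(0)
      cand_km <- character(0); cand_grp <- integer(0)
      g <- 0L
      for (i in sus) {
        cur <- substr(s, i, i)
        for (b in setdiff(bases, cur)) {
          g <- g + 1L
          s2 <- s
          substr(s2, i, i) <- b
          a0 <- max(1L, i - k + 1L); a1 <- min(i, nk)
          cov <- substring(s2, a0:a1, (a0:a1) + k - 1L)
          cand_pos <- c(cand_pos, i); cand_base <- c(cand_base, b)
          cand_km <- c(cand_km, cov); cand_grp <- c(cand_grp, rep(g, length(cov)))
        }
      }
      ok_all <- count_of(cand_km) >= min_count
      grp_ok <- vapply(split(ok_all, cand_grp), all, logical(1))
      fixed_one <- FALSE
      for (i in unique(cand_pos)) {
        hits <- which(cand_pos == i & grp_ok)
        if (length(hits) == 1L) {
          substr(s, i, i) <- cand_base[hits]
          fixes <- fixes + 1L
          fixed_one <- TRUE
          break  # re-derive the spectrum profile of the read
        }
      }
      if (!fixed_one || fixes >= max_corrections) break
    }
    seqs[ri] <- s
  }
  seqs
}

#' De Bruijn assembly of one template bin
#'
#' Builds the graph over solid k-mers (count at least 2, floor 1 for bins
#' with fewer than 10 reads), prunes dead-end tips shorter than `2k` that
#' hang off a branch, and emits maximal unambiguous paths as contigs with
#' per-base coverage derived from the k-mer counts.
#'
#' @param seqs oriented, trimmed, corrected read sequences.
#' @param k k-mer size (default 31).
#' @return list of contigs, each a list with `sequence`, `coverage`
#'   (per-base), `mean_coverage`; class `contig`.
#' @export
assemble_bin <- function(seqs, k = 31L) {
  seqs <- seqs[nchar(seqs) >= k]
  if (!length(seqs)) return(list())
  floor_ct <- if (length(seqs) < 10L) 1L else 2L
  sp <- kmer_spectrum(seqs, k)
  solid <- sp$counts >= floor_ct
  kmers <- sp$kmers[solid]; counts <- sp$counts[solid]
  if (!length(kmers)) return(list())

  contigs <- build_unitigs(kmers, counts, k)
  # prune short tips hanging off branches, then rebuild once
  tips <- vapply(contigs, function(cg) isTRUE(cg$is_tip), logical(1))
  if (any(tips) && !all(tips)) {
    drop_km <- unlist(lapply(contigs[tips], function(cg) cg$kmers))
    keep <- !(kmers %in% drop_km)
    contigs <- build_unitigs(kmers[keep], counts[keep], k)
  }
  # minimum contig length 2k, unless nothing longer was assembled; short
  # leftovers are unresolvable error/chimera debris, not template fragments
  lens <- vapply(contigs, function(cg) nchar(cg$sequence), integer(1))
  if (any(lens >= 2L * k)) contigs <- contigs[lens >= 2L * k]
  lapply(contigs, function(cg) {
    structure(list(sequence = cg$sequence, coverage = cg$coverage,
                   mean_coverage = mean(cg$coverage)), class = "contig")
  })
}

# maximal non-branching paths of the de Bruijn graph (kmers as edges over
# (k-1)-mer nodes); marks tips (< 2k nt dead-ends attached to a branch)
build_unitigs <- function(kmers, counts, k) {
  if (!length(kmers)) return(list())
  pref <- substr(kmers, 1L, k - 1L)
  suf <- substr(kmers, 2L, k)
  nodes <- unique(c(pref, suf))
  pid <- match(pref, nodes); sid <- match(suf, nodes)
  nn <- length(nodes)
  outdeg <- tabulate(pid, nn); indeg <- tabulate(sid, nn)
  out_edges <- split(seq_along(kmers), factor(pid, levels = seq_len(nn)))

  visited <- logical(length(kmers))
  res <- list()
  emit <- function(path) {
    first <- kmers[path[1L]]
    tail_chars <- substr(kmers[path[-1L]], k, k)
    seqv <- paste0(first, paste(tail_chars, collapse = ""))
    L <- length(path) + k - 1L
    # per-base coverage: mean count of k-mers covering each base
    add <- numeric(L + 1L); den <- numeric(L + 1L)
    for (e in seq_along(path)) {
      c_e <- counts[path[e]]
      add[e] <- add[e] + c_e; add[e + k] <- add[e + k] - c_e
      den[e] <- den[e] + 1; den[e + k] <- den[e + k] - 1
    }
    cov <- cumsum(add)[1:L] / cumsum(den)[1:L]
    start <- pid[path[1L]]; end <- sid[path[length(path)]]
    is_tip <- L < 2L * k &&
      ((indeg[start] == 0L && (outdeg[end] > 1L || indeg[end] > 1L)) ||
       (outdeg[end] == 0L && (indeg[start] > 1L || outdeg[start] > 1L)))
    res[[length(res) + 1L]] <<- list(sequence = seqv, coverage = cov,
                                     kmers = kmers[path], is_tip = is_tip)
  }
  walk <- function(e0) {
    path <- e0; visited[e0] <<- TRUE
    node <- sid[e0]
    while (indeg[node] == 1L && outdeg[node] == 1L) {
      e <- out_edges[[node]][1L]
      if (visited[e]) break
      path <- c(path, e); visited[e] <<- TRUE
      node <- sid[e]
    }
    path
  }
  starts <- which(!(indeg[pid] == 1L & outdeg[pid] == 1L))
  for (e0 in starts) if (!visited[e0]) emit(walk(e0))
  # leftover cycles
  for (e0 in seq_along(kmers)) if (!visited[e0]) emit(walk(e0))
  res
}

#' Strict coverage-fold contig filter
#'
#' With `M` the highest mean coverage in the bin, a contig is dropped iff
#' `mean_coverage * fold < M` (strict; a contig at exactly `M / fold` is
#' kept). Order is preserved. This removes low-abundance contigs assembled
#' from chimera-derived end+internal reads.
#'
#' @param contigs list of contigs from [assemble_bin()].
#' @param fold coverage fold (default 10).
#' @return the kept contigs, in input order.
#' @export
filter_contigs <- function(contigs, fold = 10) {
  if (!length(contigs)) return(contigs)
  mc <- vapply(contigs, function(cg) cg$mean_coverage, numeric(1))
  M <- max(mc)
  contigs[!(mc * fold < M)]
}

#' Assemble one template bin end to end
#'
#' Orients and trims the bin's reads, quality-trims them, drops reads
#' shorter than `2k`, applies k-mer error correction, assembles, and applies
#' the coverage filter.
#'
#' @param reads data.frame with columns `seq`, `qual`, `insert_start`,
#'   `orient` (`"F"` keep, `"R"` reverse-complement first) -- see
#'   the pipeline bin builder.
#' @param config a [run_config()].
#' @return object of class `assembly_result`: list with `contigs` (before
#'   filter), `kept`, `reconstructed_length`, `is_full_length`
#'   (`reconstructed_length >= 1300`), and the prepared reads.
#' @export
assemble_template <- function(reads, config = run_config()) {
  prep <- prepare_reads(reads, config)
  keep <- nchar(prep$seq) >= 2L * config$k
  corrected <- correct_errors(prep$seq[keep], k = config$k,
                              min_count = config$correct_min_count)
  contigs <- assemble_bin(corrected, k = config$k)
  kept <- filter_contigs(contigs, fold = config$contig_fold)
  len <- sum(vapply(kept, function(cg) nchar(cg$sequence), integer(1)))
  structure(list(contigs = contigs, kept = kept,
                 reconstructed_length = len,
                 is_full_length = len >= 1300L,
                 reads = data.frame(seq = prep$seq[keep],
                                    qual = prep$qual[keep],
                                    stringsAsFactors = FALSE)),
            class = "assembly_result")
}

# strip synthetic sequence and quality-trim in read orientation, then orient
# to template-forward and remove primer bleed at the extremities; batch
# versions of the scalar ops, applied bin by bin
prepare_reads <- function(reads, config) {
  n <- nrow(reads)
  seqs <- character(n); quals <- character(n)
  for (i in seq_len(n)) {
    tr <- trim_synthetic(reads$seq[i], reads$qual[i],
                         reads$insert_start[i], config)
    tr <- quality_trim(tr$seq, tr$qual, config$quality_trim_q)
    seqs[i] <- tr$seq; quals[i] <- tr$qual
  }
  rr <- which(reads$orient == "R" & nchar(seqs) > 0L)
  if (length(rr)) {
    seqs[rr] <- revcomp(seqs[rr])
    quals[rr] <- vapply(quals[rr], function(q)
      intToUtf8(rev(utf8ToInt(q))), character(1), USE.NAMES = FALSE)
  }
  trim_primer_bleed_batch(seqs, quals, config)
}

# vectorised primer-bleed trimming over a bin's oriented reads
trim_primer_bleed_batch <- function(seqs, quals, config, min_ov = 8L) {
  trim_side <- function(pattern_of_ov, cut, primer_len) {
    done <- logical(length(seqs))
    for (ov in seq(primer_len, min_ov)) {
      idx <- which(!done & nchar(seqs) >= ov)
      if (!length(idx)) next
      pat <- pattern_of_ov(ov)
      win <- pat$window(seqs[idx], ov)
      mm <- iupac_mismatch(pat$pattern, win)
      hit <- idx[mm <= 1L]
      if (length(hit)) {
        res <- cut(seqs[hit], quals[hit], ov)
        seqs[hit] <<- res$seq; quals[hit] <<- res$qual
        done[hit] <- TRUE
      }
    }
  }
  fp <- config$forward_design$gene_primer
  m <- nchar(fp)
  if (m >= min_ov)
    trim_side(function(ov) list(pattern = substr(fp, m - ov + 1L, m),
                                window = function(s, ov) substr(s, 1L, ov)),
              function(s, q, ov)
                list(seq = substr(s, ov + 1L, nchar(s)),
                     qual = substr(q, ov + 1L, nchar(q))), m)
  rp <- revcomp_iupac(config$reverse_design$gene_primer)
  m2 <- nchar(rp)
  if (m2 >= min_ov)
    trim_side(function(ov) list(pattern = substr(rp, 1L, ov),
                                window = function(s, ov)
                                  substr(s, nchar(s) - ov + 1L, nchar(s))),
              function(s, q, ov)
                list(seq = substr(s, 1L, nchar(s) - ov),
                     qual = substr(q, 1L, nchar(q) - ov)), m2)
  list(seq = seqs, qual = quals)
}

#' @export
print.assembly_result <- function(x, ...) {
  cat(sprintf(
    "<assembly_result> %d contig(s) (%d kept), %d nt reconstructed%s\n",
    length(x$contigs), length(x$kept), x$reconstructed_length,
    if (x$is_full_length) " [full-length]" else ""))
  invisible(x)
}
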