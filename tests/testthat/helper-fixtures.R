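# Shared fixture builders. All synthetic layouts are constructed in code so
# tests carry no data files.

FWD <- end_design("FORWARD")
REV <- end_design("REVERSE")

# concrete (degeneracy-free) instances of the default primer sites
FWD_SITE <- "AGAGTTTGATCATGGCTCAG"   # 27F with M -> A
REV_SITE <- "GACGGGCGGTGTGTACA"      # 1391R with W -> T, R -> A

tiny_sheet <- function() {
  sample_sheet(data.frame(
    sample = c("S1", "S2"),
    barcode_f = c("AAAAAAAA", "CCCCCCCC"),
    barcode_r = c("GGGGGGGG", "TTTTTTTT"),
    stringsAsFactors = FALSE))
}

rand_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# build a read carrying the synthetic end layout:
# phaser + barcode + tag + primer_site + gene
layout_read <- function(barcode, tag, gene, phaser = "",
                        primer_site = FWD_SITE) {
  paste0(phaser, barcode, tag, primer_site, gene)
}

q40 <- function(n) strrep("I", n)

# write a two-mate FASTQ pair to tempfiles; returns c(r1, r2)
write_pair_fastq <- function(ids, seq1, qual1, seq2, qual2) {
  r1 <- tempfile(fileext = "_R1.fastq"); r2 <- tempfile(fileext = "_R2.fastq")
  writeLines(as.vector(rbind(paste0("@", ids, "/1"), seq1, "+", qual1)), r1)
  writeLines(as.vector(rbind(paste0("@", ids, "/2"), seq2, "+", qual2)), r2)
  c(r1, r2)
}

# Independent reference implementation of the greedy signature clustering:
# plain loops and strsplit, no shared code with the package internals.
brute_force_cluster <- function(composites, threshold = 0.89) {
  hd <- function(a, b) {
    x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
    sum(x != y | x == "N" | y == "N")
  }
  tab <- table(composites)
  u <- names(tab); cnt <- as.integer(tab)
  o <- order(-cnt, u); u <- u[o]; cnt <- cnt[o]
  L <- nchar(u[1])
  ok <- function(a, b) (L - hd(a, b)) / L >= threshold
  cents <- character(0); members <- list()
  assign <- integer(length(u))
  for (i in seq_along(u)) {
    placed <- FALSE
    for (ci in seq_along(cents)) {
      if (ok(u[i], cents[ci])) { assign[i] <- ci; placed <- TRUE; break }
    }
    if (!placed) { cents <- c(cents, u[i]); assign[i] <- length(cents) }
  }
  consensus_of <- function(idx) {
    mat <- do.call(rbind, strsplit(u[idx], ""))
    w <- cnt[idx]
    paste(vapply(seq_len(ncol(mat)), function(p) {
      sc <- c(A = 0, C = 0, G = 0, T = 0, N = 0)
      for (r in seq_len(nrow(mat))) sc[mat[r, p]] <- sc[mat[r, p]] + w[r]
      names(sc)[which.max(sc)]  # first max: A<C<G<T then N
    }, character(1)), collapse = "")
  }
  cons <- vapply(seq_along(cents), function(ci)
    consensus_of(which(assign == ci)), character(1))
  assign2 <- assign
  for (i in seq_along(u)) {
    for (ci in seq_along(cons)) {
      if (ok(u[i], cons[ci])) { assign2[i] <- ci; break }
    }
  }
  live <- sort(unique(assign2))
  assign2 <- match(assign2, live)
  cons2 <- vapply(seq_along(live), function(ci)
    consensus_of(which(assign2 == ci)), character(1))
  ab <- vapply(seq_along(live), function(ci)
    sum(cnt[assign2 == ci]), integer(1))
  # canonical member partition keyed by sorted member composites
  parts <- lapply(seq_along(live), function(ci) sort(u[assign2 == ci]))
  list(consensus = cons2, abundance = ab, partition = parts)
}
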