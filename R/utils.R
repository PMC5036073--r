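# Low-level sequence utilities shared by every stage. Sequences are plain
# character strings over ACGTN; per-base qualities travel as PHRED+33 strings
# and are expanded to integers only where arithmetic is needed.

.BASES <- c("A", "C", "G", "T", "N")
.BASE_INT <- utf8ToInt(paste(.BASES, collapse = ""))
.N_INT <- utf8ToInt("N")

# IUPAC degeneracy: which concrete bases satisfy each code. N in a *read* never
# counts as a match anywhere (design rule), so N is absent from every set.
.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

#' Convert equal-length DNA strings to an integer code matrix
#'
#' @param x character vector of equal-length sequences.
#' @return integer matrix, one column per sequence, one row per position
#'   (UTF-8 code points).
#' @keywords internal
seq_matrix <- function(x) {
  if (length(x) == 0L) return(matrix(integer(0), nrow = 0, ncol = 0))
  w <- unique(nchar(x))
  if (length(w) != 1L) stop("sequences must have equal length")
  matrix(utf8ToInt(paste(x, collapse = "")), nrow = w)
}

#' Hamming distance from one sequence to many
#'
#' N never matches anything, including another N.
#'
#' @param target single sequence (character scalar or integer vector).
#' @param mat integer matrix from [seq_matrix()] (or character vector).
#' @return integer vector of distances.
#' @keywords internal
hamming_to <- function(target, mat) {
  if (is.character(target)) target <- utf8ToInt(target)
  if (is.character(mat)) mat <- seq_matrix(mat)
  if (length(target) != nrow(mat)) stop("length mismatch in Hamming comparison")
  .colSums(mat != target | mat == .N_INT | target == .N_INT,
           nrow(mat), ncol(mat))
}

#' Pairwise Hamming distance within a set of equal-length sequences
#' @keywords internal
hamming_pairwise_min <- function(x) {
  n <- length(x)
  if (n < 2L) return(Inf)
  m <- seq_matrix(x)
  best <- Inf
  for (i in seq_len(n - 1L)) {
    d <- hamming_to(m[, i], m[, (i + 1L):n, drop = FALSE])
    best <- min(best, d)
  }
  best
}

#' Reverse complement of DNA strings
#' @param x character vector over ACGTN.
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Count mismatches of reads against an IUPAC-degenerate pattern
#'
#' A read base matches a pattern position if it is one of the concrete bases
#' the IUPAC code stands for; read Ns match nothing.
#'
#' @param pattern single sequence possibly containing IUPAC codes.
#' @param windows character vector of read windows, all `nchar(pattern)` long.
#' @return integer vector of mismatch counts.
#' @keywords internal
iupac_mismatch <- function(pattern, windows) {
  pm <- strsplit(pattern, "")[[1]]
  m <- seq_matrix(windows)
  if (nrow(m) != length(pm)) stop("window width must equal pattern length")
  mm <- integer(ncol(m))
  for (i in seq_along(pm)) {
    allowed <- utf8ToInt(paste(.IUPAC[[pm[i]]], collapse = ""))
    mm <- mm + !(m[i, ] %in% allowed)
  }
  mm
}

#' PHRED+33 string to integer qualities
#' @param q character vector of quality strings.
#' @return list of integer vectors.
#' @keywords internal
phred_to_int <- function(q) lapply(q, function(s) utf8ToInt(s) - 33L)

#' Integer qualities to a PHRED+33 string (capped at 93)
#' @param q integer vector of PHRED scores.
#' @keywords internal
int_to_phred <- function(q) {
  if (any(q < 0L | q > 93L)) stop("PHRED quality outside 0-93")
  intToUtf8(as.integer(q) + 33L)
}

#' Locate a short motif in a read allowing at most one mismatch
#'
#' Exact search first (fixed-string), then a sliding scan tolerating one
#' mismatch. Returns the first (leftmost) start position, or NA.
#' @keywords internal
find_stub <- function(read, stub, max_mismatch = 1L) {
  hit <- regexpr(stub, read, fixed = TRUE)
  if (hit > 0L) return(as.integer(hit))
  n <- nchar(read); m <- nchar(stub)
  if (n < m) return(NA_integer_)
  r <- utf8ToInt(read); s <- utf8ToInt(stub)
  k <- n - m + 1L
  mm <- integer(k)
  for (i in seq_len(m)) {
    seg <- r[i:(i + k - 1L)]
    mm <- mm + (seg != s[i] | seg == .N_INT)
  }
  w <- which(mm <= max_mismatch)
  if (length(w)) w[1L] else NA_integer_
}

#' Majority-vote consensus of equal-length sequences
#'
#' Per-position plurality with weights; ties are broken by fixed base order
#' A < C < G < T, and N never wins a tie it is part of (N is only emitted on a
#' strict majority).
#'
#' @param seqs character vector of equal-length sequences.
#' @param weights non-negative numeric weights (default 1 per sequence).
#' @return single consensus sequence.
#' @export
#' @examples
#' consensus_sequence(c("ACGT", "ACGT", "ACGA"))  # "ACGT" (majority)
#' consensus_sequence(c("ACGT", "ACGA"))          # "ACGA" (tie at 4: A < T)
consensus_sequence <- function(seqs, weights = NULL) {
  if (length(seqs) == 0L) stop("consensus of an empty set is undefined")
  if (is.null(weights)) weights <- rep(1, length(seqs))
  m <- seq_matrix(seqs)
  score <- vapply(.BASE_INT, function(b) {
    as.numeric((m == b) %*% weights)
  }, numeric(nrow(m)))
  score <- matrix(score, nrow = nrow(m))  # positions x 5 (A,C,G,T,N)
  pick <- max.col(score, ties.method = "first")
  intToUtf8(.BASE_INT[pick])
}

# clamp helper
.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
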