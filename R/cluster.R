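# Dual-tag signature clustering. Every end+end pair contributes a fixed-order
# 64-nt composite -- tag_f(10) + tag_r(10) + bc_f(8) + bc_r(8) +
# gene_prefix_f(14) + gene_prefix_r(14) -- and composites are clustered
# greedily at > 89% Hamming identity with abundance-sorted centroid order, a
# deterministic stand-in for abundance-sorted UCLUST. All components are
# fixed-length synthetic sequence, so identity is alignment-free (no indels).

#' Build the dual-tag signature of one classified end+end pair
#'
#' @param cp one-row `classified_pairs` entry (END_END with a valid sample).
#' @return the composite signature string.
#' @export
build_signature <- function(cp) {
  if (cp$fragment_class != "END_END")
    stop("signatures are defined for END_END pairs only")
  paste0(cp$tag_f, cp$tag_r, cp$bc_f, cp$bc_r, cp$prefix_f, cp$prefix_r)
}

#' Build signatures for all clusterable pairs of a classification table
#'
#' Keeps END_END pairs assigned to a real sample (invalid barcode
#' combinations are excluded -- they are recombination evidence, not
#' templates).
#'
#' @param classified `classified_pairs` data.frame.
#' @return data.frame with `pair_id`, `sample`, `composite`.
#' @export
build_signatures <- function(classified) {
  keep <- classified$fragment_class == "END_END" &
    !is.na(classified$sample) & classified$sample != "INVALID_COMBINATION"
  cc <- classified[keep, , drop = FALSE]
  data.frame(pair_id = cc$pair_id, sample = cc$sample,
             composite = paste0(cc$tag_f, cc$tag_r, cc$bc_f, cc$bc_r,
                                cc$prefix_f, cc$prefix_r),
             stringsAsFactors = FALSE)
}

#' Per-position plurality consensus of cluster member composites
#'
#' Ties break by base order A < C < G < T; N never wins a tie it is part of.
#'
#' @param members character vector of equal-length composites.
#' @param weights optional per-member weights (e.g. read multiplicities).
#' @return consensus composite.
#' @export
cluster_consensus <- function(members, weights = NULL) {
  if (length(members) == 0L) stop("cannot take the consensus of no members")
  consensus_sequence(members, weights)
}

#' Greedy centroid clustering of dual-tag signatures
#'
#' Unique composites are ordered by multiplicity (descending) then
#' lexicographically, making the outcome invariant to input order. Each
#' composite joins the first existing cluster whose representative it matches
#' at `>= threshold` Hamming identity, else founds a new cluster. A single
#' consensus-refinement pass follows: cluster consensi are computed by
#' weighted per-position plurality, every composite is reassigned against the
#' consensi by the same first-match rule, and consensi are recomputed once.
#'
#' @param signatures data.frame from [build_signatures()] (`pair_id`,
#'   `sample`, `composite`), or a character vector of composites.
#' @param threshold minimum Hamming identity (default 0.89, i.e. at most 7
#'   mismatches over a 64-nt composite).
#' @return object of class `tag_clusters`: list with `clusters` (data.frame:
#'   `cluster_id`, `consensus`, `tag_f`, `tag_r`, `bc_f`, `bc_r`, `sample`,
#'   `abundance`) and `assignment` (data.frame: `pair_id`, `cluster_id`), plus
#'   the design widths used to slice the composite.
#' @export
greedy_cluster <- function(signatures, threshold = 0.89,
                           tag_length = 10L, barcode_length = 8L) {
  if (is.character(signatures))
    signatures <- data.frame(pair_id = paste0("s", seq_along(signatures)),
                             sample = NA_character_, composite = signatures,
                             stringsAsFactors = FALSE)
  comp <- signatures$composite
  if (length(comp) == 0L)
    return(empty_tag_clusters(tag_length, barcode_length))
  L <- unique(nchar(comp))
  if (length(L) != 1L) stop("composites must have equal length")

  cnt_tab <- table(comp)
  ucomp <- names(cnt_tab)
  cnt <- as.integer(cnt_tab)
  ord <- order(-cnt, ucomp)
  ucomp <- ucomp[ord]; cnt <- cnt[ord]
  U <- length(ucomp)
  M <- seq_matrix(ucomp)
  max_mm <- floor(L * (1 - threshold) + 1e-9)

  # pass 1: greedy founding against centroids (the founding composite)
  cents <- matrix(0L, nrow = L, ncol = U)
  assign1 <- integer(U)
  nc <- 0L
  for (i in seq_len(U)) {
    hit <- 0L
    if (nc > 0L) {
      d <- hamming_to(M[, i], cents[, seq_len(nc), drop = FALSE])
      w <- which(d <= max_mm)
      if (length(w)) hit <- w[1L]
    }
    if (hit == 0L) {
      nc <- nc + 1L
      cents[, nc] <- M[, i]
      hit <- nc
    }
    assign1[i] <- hit
  }

  # consensus of pass-1 clusters, weighted by composite multiplicity
  cons <- cluster_consensi(ucomp, cnt, assign1, nc)

  # pass 2: one refinement reassignment against consensi, then recompute
  K <- seq_matrix(cons)
  assign2 <- assign1
  for (i in seq_len(U)) {
    d <- hamming_to(M[, i], K)
    w <- which(d <= max_mm)
    if (length(w)) assign2[i] <- w[1L]
  }
  live <- sort(unique(assign2))
  assign2 <- match(assign2, live)
  cons <- cluster_consensi(ucomp, cnt, assign2, length(live))

  abund <- as.integer(rowsum(cnt, assign2))
  ord2 <- order(-abund, cons)
  cons <- cons[ord2]; abund <- abund[ord2]
  rank <- match(seq_along(ord2), ord2)
  ids <- sprintf("C%05d", seq_along(cons))

  # majority sample per cluster
  comp_cluster <- ids[rank[assign2[match(comp, ucomp)]]]
  sample_of <- vapply(split(signatures$sample, comp_cluster), function(s) {
    s <- s[!is.na(s)]
    if (!length(s)) NA_character_ else names(sort(table(s),
                                                  decreasing = TRUE))[1]
  }, character(1))

  tl <- tag_length; bl <- barcode_length
  clusters <- data.frame(
    cluster_id = ids,
    consensus = cons,
    tag_f = substr(cons, 1L, tl),
    tag_r = substr(cons, tl + 1L, 2L * tl),
    bc_f = substr(cons, 2L * tl + 1L, 2L * tl + bl),
    bc_r = substr(cons, 2L * tl + bl + 1L, 2L * tl + 2L * bl),
    sample = unname(sample_of[ids]),
    abundance = abund,
    stringsAsFactors = FALSE
  )
  assignment <- data.frame(pair_id = signatures$pair_id,
                           cluster_id = comp_cluster,
                           stringsAsFactors = FALSE)
  structure(list(clusters = clusters, assignment = assignment,
                 threshold = threshold, tag_length = tl, barcode_length = bl),
            class = "tag_clusters")
}

cluster_consensi <- function(ucomp, cnt, assign, nc) {
  vapply(seq_len(nc), function(ci) {
    idx <- which(assign == ci)
    cluster_consensus(ucomp[idx], cnt[idx])
  }, character(1))
}

empty_tag_clusters <- function(tag_length, barcode_length) {
  structure(list(
    clusters = data.frame(cluster_id = character(0), consensus = character(0),
                          tag_f = character(0), tag_r = character(0),
                          bc_f = character(0), bc_r = character(0),
                          sample = character(0), abundance = integer(0),
                          stringsAsFactors = FALSE),
    assignment = data.frame(pair_id = character(0), cluster_id = character(0),
                            stringsAsFactors = FALSE),
    threshold = NA_real_, tag_length = tag_length,
    barcode_length = barcode_length), class = "tag_clusters")
}

#' @export
print.tag_clusters <- function(x, ...) {
  cat(sprintf(
    "<tag_clusters> %d clusters from %d end+end pairs (identity > %.2f)\n",
    nrow(x$clusters), nrow(x$assignment), x$threshold))
  if (nrow(x$clusters))
    cat(sprintf("  abundance: min %d, median %s, max %d\n",
                min(x$clusters$abundance),
                format(stats::median(x$clusters$abundance)),
                max(x$clusters$abundance)))
  invisible(x)
}
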