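# Template binning: every read pair (end+end and end+internal) is matched by
# its molecular tag(s) against the kept clusters' consensus tags and grouped
# into per-template bins for assembly. Matching uses unique-best semantics
# within a small mismatch budget; ambiguity (two equally close consensus
# tags, or a tag carried by two equal-abundance surviving clusters) leaves
# the read unassigned rather than guessed.

#' Index the consensus tags of kept clusters
#'
#' @param kept data.frame of kept clusters (from [filter_recombinants()]`$kept`).
#' @return object of class `tag_index` with forward- and reverse-end lookup
#'   tables and recorded collisions (a consensus tag shared by two or more
#'   kept clusters of the same end; such tags answer "ambiguous").
#' @export
index_consensus_tags <- function(kept) {
  side <- function(tags) {
    u <- unique(tags)
    first <- match(u, tags)
    collided <- vapply(u, function(t) sum(tags == t) > 1L, logical(1))
    list(tags = u, cluster_row = first, collided = unname(collided),
         mat = if (length(u)) seq_matrix(u) else NULL)
  }
  structure(list(f = side(kept$tag_f), r = side(kept$tag_r),
                 cluster_id = kept$cluster_id),
            class = "tag_index")
}

#' @export
print.tag_index <- function(x, ...) {
  cat(sprintf("<tag_index> %d clusters; %d/%d unique f/r tags (%d/%d collided)\n",
              length(x$cluster_id), length(x$f$tags), length(x$r$tags),
              sum(x$f$collided), sum(x$r$collided)))
  invisible(x)
}

# match a vector of query tags against one side of the index:
# returns cluster row (into cluster_id) or NA (absent/ambiguous/collision)
match_tags <- function(queries, side, budget) {
  out <- rep(NA_integer_, length(queries))
  if (!length(queries) || is.null(side$mat)) return(out)
  uq <- unique(queries)
  res <- rep(NA_integer_, length(uq))
  for (i in seq_along(uq)) {
    d <- hamming_to(uq[i], side$mat)
    best <- min(d)
    if (best > budget) next
    w <- which(d == best)
    if (length(w) != 1L) next        # equidistant tags: ambiguous
    if (side$collided[w]) next       # tag kept by >= 2 clusters: ambiguous
    res[i] <- side$cluster_row[w]
  }
  out <- res[match(queries, uq)]
  out
}

#' Assign classified read pairs to template bins
#'
#' End+end pairs require both tags to resolve -- each a unique best match
#' within the budget -- to the *same* kept cluster. End+internal pairs match
#' their single tag against the index for their parsed end. Reads whose
#' cluster was discarded by the chimera filter, or whose match is absent or
#' ambiguous, are unassigned.
#'
#' @param classified `classified_pairs` data.frame.
#' @param index a `tag_index` over the kept clusters.
#' @param budget tag mismatch budget (default 1).
#' @return `classified` with columns `cluster_id` (NA when unassigned) and
#'   `bin_role` (`END_END`, `END_INTERNAL_F`, `END_INTERNAL_R`).
#' @export
assign_read_pairs <- function(classified, index, budget = 1L) {
  n <- nrow(classified)
  cluster <- rep(NA_character_, n)
  role <- rep(NA_character_, n)

  ee <- which(classified$fragment_class == "END_END")
  if (length(ee)) {
    mf <- match_tags(classified$tag_f[ee], index$f, budget)
    mr <- match_tags(classified$tag_r[ee], index$r, budget)
    ok <- !is.na(mf) & !is.na(mr) & mf == mr
    cluster[ee[ok]] <- index$cluster_id[mf[ok]]
    role[ee] <- "END_END"
  }
  ei <- which(classified$fragment_class == "END_INTERNAL")
  if (length(ei)) {
    fwd <- classified$end_label[ei] == "FORWARD"
    if (any(fwd)) {
      m <- match_tags(classified$tag_f[ei[fwd]], index$f, budget)
      cluster[ei[fwd][!is.na(m)]] <- index$cluster_id[m[!is.na(m)]]
    }
    if (any(!fwd)) {
      m <- match_tags(classified$tag_r[ei[!fwd]], index$r, budget)
      cluster[ei[!fwd][!is.na(m)]] <- index$cluster_id[m[!is.na(m)]]
    }
    role[ei] <- ifelse(fwd, "END_INTERNAL_F", "END_INTERNAL_R")
  }
  classified$cluster_id <- cluster
  classified$bin_role <- role
  classified
}

#' Assign a single classified pair to a bin
#'
#' @param cp one-row `classified_pairs` entry.
#' @inheritParams assign_read_pairs
#' @return the matched cluster id, or `NA` (unassigned).
#' @export
assign_read_pair <- function(cp, index, budget = 1L) {
  assign_read_pairs(cp, index, budget)$cluster_id[1]
}

#' Per-bin membership summary
#'
#' @param assigned output of [assign_read_pairs()].
#' @return data.frame per bin: `cluster_id`, `end_end_count`,
#'   `internal_count`, `n_reads`.
#' @export
bin_manifest <- function(assigned) {
  a <- assigned[!is.na(assigned$cluster_id), , drop = FALSE]
  if (!nrow(a))
    return(data.frame(cluster_id = character(0), end_end_count = integer(0),
                      internal_count = integer(0), n_reads = integer(0)))
  sp <- split(a$bin_role, a$cluster_id)
  data.frame(cluster_id = names(sp),
             end_end_count = vapply(sp, function(r)
               sum(r == "END_END"), integer(1)),
             internal_count = vapply(sp, function(r)
               sum(r != "END_END"), integer(1)),
             n_reads = lengths(sp),
             row.names = NULL, stringsAsFactors = FALSE)
}
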