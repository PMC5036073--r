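# Dual-tag chimera elimination. A template-switch (in-vitro recombinant)
# molecule inherits its forward tag from one parent and its reverse tag from
# another, so its cluster shares a consensus tag with each parent's cluster
# while being (almost always) less abundant. Any cluster sharing a consensus
# tag -- either end -- with a strictly more abundant cluster is discarded.

#' Filter putative recombinant clusters by the dual-tag abundance rule
#'
#' A cluster is discarded iff some different cluster of strictly greater
#' abundance carries the same consensus forward tag or the same consensus
#' reverse tag. Equal-abundance tag sharers are all kept (no strict
#' dominator). Tag sharing is tested on exact consensus 10-mers;
#' sequencing-error divergence has already been absorbed by clustering (set
#' `tag_mismatch` to 1 to also treat 1-mismatch tags as shared).
#'
#' @param clusters `tag_clusters` object or its `clusters` data.frame.
#' @param tag_mismatch mismatches tolerated when deciding tag sharing
#'   (default 0, exact).
#' @return object of class `filter_result`: `kept` and `discarded` cluster
#'   data.frames (the latter with `reason` in `tag_f_shared`, `tag_r_shared`,
#'   `both_shared`, plus `dominator_id` and `dominator_abundance`).
#' @export
filter_recombinants <- function(clusters, tag_mismatch = 0L) {
  cl <- if (inherits(clusters, "tag_clusters")) clusters$clusters else clusters
  n <- nrow(cl)
  if (n == 0L)
    return(structure(list(kept = cl, discarded = cbind(
      cl, reason = character(0), dominator_id = character(0),
      dominator_abundance = integer(0))), class = "filter_result"))

  dom <- function(tags) {
    # index (in cl) of the most abundant cluster sharing each cluster's tag,
    # excluding itself unless it is the unique maximum
    if (tag_mismatch > 0L) {
      share <- lapply(seq_len(n), function(i)
        which(hamming_to(tags[i], seq_matrix(tags)) <= tag_mismatch))
    } else {
      grp <- split(seq_len(n), tags)
      share <- vector("list", n)
      for (g in grp) share[g] <- list(g)
    }
    dominated <- logical(n); dominator <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      others <- setdiff(share[[i]], i)
      if (!length(others)) next
      stronger <- others[cl$abundance[others] > cl$abundance[i]]
      if (length(stronger)) {
        dominated[i] <- TRUE
        dominator[i] <- stronger[order(-cl$abundance[stronger],
                                       stronger)][1L]
      }
    }
    list(dominated = dominated, dominator = dominator)
  }

  f <- dom(cl$tag_f); r <- dom(cl$tag_r)
  discarded <- f$dominated | r$dominated
  reason <- ifelse(f$dominated & r$dominated, "both_shared",
                   ifelse(f$dominated, "tag_f_shared", "tag_r_shared"))
  # dominator: the more abundant of the two candidates
  dominator <- ifelse(
    f$dominated & (!r$dominated |
                     cl$abundance[f$dominator] >=
                     replace(cl$abundance[r$dominator],
                             is.na(r$dominator), -Inf)),
    f$dominator, r$dominator)

  disc <- cl[discarded, , drop = FALSE]
  if (nrow(disc)) {
    disc$reason <- reason[discarded]
    disc$dominator_id <- cl$cluster_id[dominator[discarded]]
    disc$dominator_abundance <- cl$abundance[dominator[discarded]]
  } else {
    disc$reason <- character(0)
    disc$dominator_id <- character(0)
    disc$dominator_abundance <- integer(0)
  }
  structure(list(kept = cl[!discarded, , drop = FALSE], discarded = disc),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  nk <- nrow(x$kept); nd <- nrow(x$discarded)
  cat(sprintf("<filter_result> kept %d / discarded %d clusters (%.1f%%)\n",
              nk, nd, if (nk + nd) 100 * nd / (nk + nd) else 0))
  invisible(x)
}

#' Recombination statistics from a chimera filter result
#'
#' The read-level recombination rate is the summed abundance of discarded
#' clusters over the end+end read pool; the parental ratio is the mean, over
#' discarded clusters, of dominator abundance over discarded abundance.
#'
#' @param x a `filter_result`, or a numeric vector of discarded-cluster
#'   abundances (e.g. printed counts re-analysed).
#' @param total_end_end_reads size of the end+end read pool.
#' @param dominator_abundances dominator abundances when `x` is a bare
#'   vector (optional; parental ratio is `NA` without them).
#' @return list with `rate` (percent), `discarded_reads`, `total`,
#'   `n_discarded_clusters`, `discarded_cluster_fraction`, `parental_ratio`.
#' @export
recombination_stats <- function(x, total_end_end_reads,
                                dominator_abundances = NULL) {
  if (total_end_end_reads <= 0) stop("total_end_end_reads must be > 0")
  if (inherits(x, "filter_result")) {
    ab <- x$discarded$abundance
    dom <- x$discarded$dominator_abundance
    n_clusters <- nrow(x$kept) + nrow(x$discarded)
  } else {
    ab <- as.numeric(x)
    dom <- dominator_abundances
    n_clusters <- NA_integer_
  }
  ratio <- if (length(ab) && !is.null(dom)) mean(dom / ab) else NA_real_
  list(rate = 100 * sum(ab) / total_end_end_reads,
       discarded_reads = sum(ab),
       total = total_end_end_reads,
       n_discarded_clusters = length(ab),
       discarded_cluster_fraction =
         if (is.na(n_clusters)) NA_real_ else length(ab) / n_clusters,
       parental_ratio = ratio)
}
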