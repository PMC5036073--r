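# Run-level summaries: sequence length distribution, full-length counts, and
# PCR amplification-bias estimation from end+end cluster abundances. The
# "relative mean error" is the coefficient of variation of cluster
# abundances -- sample SD over mean -- a proxy for how unevenly PCR amplified
# individual template molecules.

#' Sequence length summary
#'
#' @param lengths integer vector of reconstructed sequence lengths.
#' @param threshold full-length cutoff, strict (default 1300).
#' @param bins histogram bin width in nt (default 100).
#' @return list with `n`, `min`, `max`, `n_full_length` (strictly greater
#'   than `threshold`), `pct_full_length` (percent, 1 decimal), `histogram`.
#' @export
length_summary <- function(lengths, threshold = 1300L, bins = 100L) {
  lengths <- as.integer(lengths)
  if (!length(lengths))
    return(list(n = 0L, min = NA_integer_, max = NA_integer_,
                n_full_length = 0L, pct_full_length = NA_real_,
                histogram = table(integer(0))))
  brk <- seq(0L, max(lengths) + bins, by = bins)
  nfl <- sum(lengths > threshold)
  list(n = length(lengths), min = min(lengths), max = max(lengths),
       n_full_length = nfl,
       pct_full_length = round(100 * nfl / length(lengths), 1),
       histogram = table(cut(lengths, brk)))
}

#' Estimate PCR amplification bias from cluster abundances
#'
#' @param abundances end+end cluster abundances (reads per cluster).
#' @param exclude_singletons drop abundance-1 clusters (possible
#'   recombinants) before estimating.
#' @param population_sd use the population (n) rather than sample (n-1) SD.
#' @return object of class `bias_estimate`: `n_clusters`, `mean`, `sd`,
#'   `relative_mean_error` (= sd/mean, the coefficient of variation),
#'   `relative_abundance` (per-cluster abundance/mean, the spread of
#'   amplification around the average), `exclude_singletons`.
#' @export
bias_estimate <- function(abundances, exclude_singletons = FALSE,
                          population_sd = FALSE) {
  ab <- as.numeric(abundances)
  if (exclude_singletons) ab <- ab[ab > 1]
  if (length(ab) < 2L)
    stop("bias estimation needs at least 2 clusters",
         if (exclude_singletons) " after excluding singletons" else "")
  m <- mean(ab)
  s <- stats::sd(ab)
  if (population_sd) s <- s * sqrt((length(ab) - 1) / length(ab))
  structure(list(n_clusters = length(ab), mean = m, sd = s,
                 relative_mean_error = s / m,
                 relative_abundance = ab / m,
                 exclude_singletons = exclude_singletons),
            class = "bias_estimate")
}

#' @export
print.bias_estimate <- function(x, ...) {
  cat(sprintf(
    "<bias_estimate> %d clusters%s: mean %.2f, sd %.2f, relative mean error %.2f\n",
    x$n_clusters, if (x$exclude_singletons) " (singletons excluded)" else "",
    x$mean, x$sd, x$relative_mean_error))
  cat(sprintf("  relative abundance spread: %.2f-%.2f x mean\n",
              min(x$relative_abundance), max(x$relative_abundance)))
  invisible(x)
}

#' Write the run report
#'
#' One JSON report collecting per-stage counts and statistics, plus TSVs
#' backing the figure-style outputs (recombinant abundances, length
#' distribution, quality/coverage profile, relative abundance spread).
#'
#' @param stats named list of stage outputs; recognised names:
#'   `classification` (from [classification_counts()]), `invalid`
#'   (from [invalid_combination_rate()]), `recombination` (from
#'   [recombination_stats()]), `bias`/`bias_no_singletons`
#'   ([bias_estimate()]), `lengths` ([length_summary()]), `profile`
#'   ([quality_profile()]).
#' @param out_dir directory to write into (created if needed).
#' @return invisibly, the path of the JSON report.
#' @export
write_report <- function(stats, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list()
  flag_missing <- character(0)
  for (key in c("classification", "invalid", "recombination", "bias",
                "bias_no_singletons", "lengths")) {
    if (is.null(stats[[key]])) {
      flag_missing <- c(flag_missing, key)
    } else {
      x <- stats[[key]]
      if (inherits(x, "bias_estimate"))
        x <- x[c("n_clusters", "mean", "sd", "relative_mean_error")]
      if (key == "lengths") x$histogram <- NULL
      report[[key]] <- x
    }
  }
  report$missing_sections <- as.list(flag_missing)
  path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(stats$profile))
    utils::write.table(stats$profile,
                       file.path(out_dir, "quality_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(stats$bias))
    utils::write.table(
      data.frame(relative_abundance = stats$bias$relative_abundance),
      file.path(out_dir, "relative_abundance.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
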