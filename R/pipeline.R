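# Pipeline orchestration: demux -> cluster -> chimera-filter -> bin ->
# assemble -> consensus -> report, in memory, with optional per-stage file
# outputs and checksum manifests for resumable reruns.

#' Run the full reconstruction pipeline
#'
#' @param input a `sim_run` (from [simulate_run()]), a read pair table, or a
#'   list with `r1`/`r2` FASTQ paths.
#' @param sheet a [sample_sheet()] (taken from the `sim_run` if absent).
#' @param config a [run_config()].
#' @param out_dir if non-NULL, stage outputs, manifests and the JSON report
#'   are written beneath it; unchanged stages are skipped on rerun.
#' @param verbose print per-stage progress counters.
#' @return object of class `long16s_run` with elements `classified`,
#'   `clusters`, `filter`, `assigned`, `assemblies`, `consensus`, `stats`.
#' @export
run_pipeline <- function(input, sheet = NULL, config = run_config(),
                         out_dir = NULL, verbose = FALSE) {
  if (inherits(input, "sim_run")) {
    pairs <- input$pairs
    if (is.null(sheet)) sheet <- input$sheet
  } else if (is.data.frame(input)) {
    pairs <- input
  } else if (is.list(input) && !is.null(input$r1)) {
    pairs <- read_fastq_pairs(input$r1, input$r2)
  } else stop("unsupported input")
  if (is.null(sheet)) stop("a sample sheet is required")
  say <- function(...) if (verbose) message(sprintf(...))

  # --- demux ---------------------------------------------------------------
  classified <- stage_cached(out_dir, "demux",
    params = config[c("primer_max_mismatch")],
    inputs = NULL, n_pairs = nrow(pairs),
    load = load_classified, save = save_classified,
    compute = function() classify_pairs(pairs, config, sheet), say = say)
  counts <- classification_counts(classified)
  invalid <- invalid_combination_rate(classified, nrow(classified))
  say("demux: %d end+end, %d end+internal, %d unassigned",
      counts$END_END, counts$END_INTERNAL, counts$UNASSIGNED)

  # --- dual-tag clustering -------------------------------------------------
  signatures <- build_signatures(classified)
  tc <- stage_cached(out_dir, "cluster",
    params = config["identity_threshold"], inputs = "demux",
    n_pairs = nrow(pairs),
    load = load_clusters, save = save_clusters,
    compute = function() greedy_cluster(
      signatures, config$identity_threshold,
      tag_length = config$forward_design$tag_length,
      barcode_length = config$forward_design$barcode_length), say = say)
  say("cluster: %d clusters from %d signatures",
      nrow(tc$clusters), nrow(signatures))

  # --- chimera filter ------------------------------------------------------
  fr <- filter_recombinants(tc)
  rec <- recombination_stats(fr, max(1L, nrow(signatures)))
  say("chimera-filter: kept %d, discarded %d (%.1f%% of end+end reads)",
      nrow(fr$kept), nrow(fr$discarded), rec$rate)

  # --- binning -------------------------------------------------------------
  idx <- index_consensus_tags(fr$kept)
  assigned <- assign_read_pairs(classified, idx, config$tag_mismatch_budget)
  manifest <- bin_manifest(assigned)
  say("bin: %d bins, %d reads binned", nrow(manifest),
      sum(manifest$n_reads))

  # --- assembly + consensus ------------------------------------------------
  rows_by_bin <- split(which(!is.na(assigned$cluster_id)),
                       assigned$cluster_id[!is.na(assigned$cluster_id)])
  pair_row <- match(assigned$pair_id, pairs$pair_id)
  assemblies <- list(); consensus <- list()
  for (cid in names(rows_by_bin)) {
    reads <- bin_read_table(assigned, pairs, pair_row, rows_by_bin[[cid]])
    asm <- assemble_template(reads, config)
    asm$cluster_id <- cid
    assemblies[[cid]] <- asm
    smp <- fr$kept$sample[match(cid, fr$kept$cluster_id)]
    for (ci in seq_along(asm$kept)) {
      pl <- map_reads(asm$kept[[ci]], asm$reads$seq, asm$reads$qual,
                      k = config$map_k, min_identity = config$map_min_identity)
      id <- if (ci == 1L) cid else sprintf("%s.%d", cid, ci)
      consensus[[id]] <- call_consensus(pl, cluster_id = id, sample = smp)
    }
  }
  say("assemble: %d bins assembled, %d consensus sequences",
      length(assemblies), length(consensus))

  # --- run statistics ------------------------------------------------------
  lengths <- vapply(assemblies, function(a) a$reconstructed_length,
                    integer(1))
  stats <- list(
    classification = counts,
    invalid = invalid,
    recombination = rec,
    lengths = length_summary(lengths),
    profile = quality_profile(consensus)
  )
  kept_ab <- fr$kept$abundance
  if (length(kept_ab) >= 2L) stats$bias <- bias_estimate(kept_ab)
  if (sum(kept_ab > 1) >= 2L)
    stats$bias_no_singletons <- bias_estimate(kept_ab,
                                              exclude_singletons = TRUE)

  res <- structure(list(classified = classified, clusters = tc, filter = fr,
                        assigned = assigned, bin_manifest = manifest,
                        assemblies = assemblies, consensus = consensus,
                        stats = stats, config = config),
                   class = "long16s_run")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' @export
print.long16s_run <- function(x, ...) {
  s <- x$stats
  cat("<long16s_run>\n")
  cat(sprintf("  %d pairs: %d end+end / %d end+internal / %d unassigned\n",
              s$classification$total, s$classification$END_END,
              s$classification$END_INTERNAL, s$classification$UNASSIGNED))
  cat(sprintf("  %d clusters, %d kept after chimera filter (recombination %.1f%%)\n",
              nrow(x$clusters$clusters), nrow(x$filter$kept),
              s$recombination$rate))
  cat(sprintf("  %d assemblies, %d (%.1f%%) > 1300 nt\n",
              s$lengths$n, s$lengths$n_full_length,
              s$lengths$pct_full_length))
  if (!is.null(s$bias))
    cat(sprintf("  amplification bias (relative mean error): %.2f\n",
                s$bias$relative_mean_error))
  invisible(x)
}

# per-bin read table: orient + locate synthetic prefixes from the parse
bin_read_table <- function(assigned, pairs, pair_row, rows) {
  seqs <- character(0); quals <- character(0)
  ins <- integer(0); orient <- character(0)
  for (i in rows) {
    pr <- pair_row[i]
    role <- assigned$bin_role[i]
    get_mate <- function(m) {
      if (m == 1L) c(pairs$seq1[pr], pairs$qual1[pr])
      else c(pairs$seq2[pr], pairs$qual2[pr])
    }
    if (role == "END_END") {
      f <- get_mate(assigned$f_mate[i]); r <- get_mate(assigned$r_mate[i])
      seqs <- c(seqs, f[1], r[1]); quals <- c(quals, f[2], r[2])
      ins <- c(ins, assigned$insert_start_f[i], assigned$insert_start_r[i])
      orient <- c(orient, "F", "R")
    } else if (role == "END_INTERNAL_F") {
      tm <- 3L - assigned$internal_mate[i]
      t <- get_mate(tm); o <- get_mate(assigned$internal_mate[i])
      seqs <- c(seqs, t[1], o[1]); quals <- c(quals, t[2], o[2])
      ins <- c(ins, assigned$insert_start_f[i], NA_integer_)
      orient <- c(orient, "F", "R")
    } else {
      tm <- 3L - assigned$internal_mate[i]
      t <- get_mate(tm); o <- get_mate(assigned$internal_mate[i])
      seqs <- c(seqs, t[1], o[1]); quals <- c(quals, t[2], o[2])
      ins <- c(ins, assigned$insert_start_r[i], NA_integer_)
      orient <- c(orient, "R", "F")
    }
  }
  data.frame(seq = seqs, qual = quals, insert_start = ins, orient = orient,
             stringsAsFactors = FALSE)
}

# ---- stage caching -------------------------------------------------------

stage_fingerprint <- function(params, inputs, out_dir, n_pairs) {
  dep <- if (!is.null(inputs)) {
    vapply(inputs, function(st) {
      mf <- file.path(out_dir, "manifests", paste0(st, ".json"))
      if (file.exists(mf)) unname(tools::md5sum(mf)) else ""
    }, character(1))
  } else character(0)
  paste(c(vapply(params, function(p) paste(format(p), collapse = ","),
                 character(1)), dep, n_pairs), collapse = "|")
}

stage_cached <- function(out_dir, stage, params, inputs, n_pairs,
                         load, save, compute, say) {
  if (is.null(out_dir)) return(compute())
  mdir <- file.path(out_dir, "manifests")
  dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
  mf <- file.path(mdir, paste0(stage, ".json"))
  fp <- stage_fingerprint(params, inputs, out_dir, n_pairs)
  if (file.exists(mf)) {
    old <- tryCatch(jsonlite::read_json(mf), error = function(e) NULL)
    if (!is.null(old) && identical(old$fingerprint, fp) &&
        all(file.exists(file.path(out_dir, unlist(old$outputs)))) &&
        identical(unname(tools::md5sum(
          file.path(out_dir, unlist(old$outputs)))),
          unlist(old$checksums))) {
      say("%s: up to date, skipped", stage)
      obj <- tryCatch(load(out_dir), error = function(e) NULL)
      if (!is.null(obj)) return(obj)
    }
  }
  obj <- compute()
  outputs <- save(obj, out_dir)
  jsonlite::write_json(list(stage = stage, fingerprint = fp,
                            outputs = outputs,
                            checksums = unname(tools::md5sum(
                              file.path(out_dir, outputs)))),
                       mf, auto_unbox = TRUE)
  obj
}

write_tsv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
read_tsv <- function(path)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    comment.char = "", colClasses = NA, na.strings = "NA")

save_classified <- function(classified, out_dir) {
  write_tsv(as.data.frame(classified), file.path(out_dir, "demux",
                                                 "classified.tsv"))
  "demux/classified.tsv"
}
load_classified <- function(out_dir) {
  df <- read_tsv(file.path(out_dir, "demux", "classified.tsv"))
  for (col in c("pair_id", "bc_f", "bc_r", "tag_f", "tag_r", "prefix_f",
                "prefix_r", "sample", "end_label"))
    df[[col]] <- as.character(df[[col]])
  class(df) <- c("classified_pairs", class(df))
  df
}
save_clusters <- function(tc, out_dir) {
  write_tsv(tc$clusters, file.path(out_dir, "cluster", "clusters.tsv"))
  write_tsv(tc$assignment, file.path(out_dir, "cluster", "assignment.tsv"))
  c("cluster/clusters.tsv", "cluster/assignment.tsv")
}
load_clusters <- function(out_dir) {
  cl <- read_tsv(file.path(out_dir, "cluster", "clusters.tsv"))
  as_chr <- c("cluster_id", "consensus", "tag_f", "tag_r", "bc_f", "bc_r",
              "sample")
  for (col in as_chr) cl[[col]] <- as.character(cl[[col]])
  asn <- read_tsv(file.path(out_dir, "cluster", "assignment.tsv"))
  asn$pair_id <- as.character(asn$pair_id)
  asn$cluster_id <- as.character(asn$cluster_id)
  structure(list(clusters = cl, assignment = asn, threshold = NA_real_,
                 tag_length = nchar(cl$tag_f[1] %||% "AAAAAAAAAA"),
                 barcode_length = nchar(cl$bc_f[1] %||% "AAAAAAAA")),
            class = "tag_clusters")
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(res$filter$kept, file.path(out_dir, "chimera", "kept.tsv"))
  write_tsv(res$filter$discarded,
            file.path(out_dir, "chimera", "discarded.tsv"))
  write_tsv(res$assigned[!is.na(res$assigned$cluster_id),
                         c("pair_id", "cluster_id", "bin_role")],
            file.path(out_dir, "bins", "bin_assignment.tsv"))
  write_tsv(res$bin_manifest, file.path(out_dir, "bins", "manifest.tsv"))
  asm <- data.frame(
    cluster_id = names(res$assemblies),
    n_contigs = vapply(res$assemblies, function(a) length(a$contigs),
                       integer(1)),
    n_kept = vapply(res$assemblies, function(a) length(a$kept), integer(1)),
    reconstructed_length = vapply(res$assemblies,
                                  function(a) a$reconstructed_length,
                                  integer(1)),
    full_length = vapply(res$assemblies, function(a) a$is_full_length,
                         logical(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  write_tsv(asm, file.path(out_dir, "assembly", "assembly.tsv"))
  dir.create(file.path(out_dir, "consensus"), recursive = TRUE,
             showWarnings = FALSE)
  if (length(res$consensus))
    write_fasta_with_quality(res$consensus,
                             file.path(out_dir, "consensus",
                                       "consensus.fasta"),
                             file.path(out_dir, "consensus",
                                       "consensus.fastq"))
  write_report(res$stats, out_dir)
  invisible(out_dir)
}
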