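# Protocol simulator with full ground truth. Emulates the wet-lab pipeline:
# per-template dual 10-nt random tagging, lognormally biased amplification,
# template-switch chimera formation, tagmentation into 400-1,500 bp
# fragments pooled ~7:1 with full-length amplicons, and 2x250 paired-end
# sequencing with substitution errors and position-decaying qualities.
# Every read pair is linked to its source molecule in the truth tables.

#' Simulation configuration
#'
#' Defaults mirror the study-scale run: ~5,000 templates of 1,365 nt across
#' 12 samples, mean sequenced depth 8 end+end copies per template, lognormal
#' amplification bias with CV ~ 2 (sigma = 1.27), a 10% template-switch
#' chimera rate, tagmented fragments of 400-1,500 bp pooled 7:1 with
#' full-length amplicons, and 2x250 reads at 0.5% substitution error.
#'
#' @param n_templates number of progenitor 16S molecules.
#' @param template_length template length in nt (used when no reference).
#' @param reference_fasta optional FASTA of 16S genes to draw templates from.
#' @param n_samples number of samples (diagonal barcode pairing).
#' @param depth mean sequenced end+end copies per template.
#' @param bias_sigma lognormal sdlog of per-template amplification.
#' @param chimera_rate probability an amplified copy is a template-switch
#'   chimera.
#' @param chimera_cross_sample_prob probability a chimera's parents are drawn
#'   pool-wide rather than within the sample (cross-sample recombinants show
#'   up as invalid barcode combinations).
#' @param frag_min,frag_max tagmented fragment size range (bp).
#' @param tagmented_ratio tagmented:full-length read-pair ratio.
#' @param read_length read length (nt).
#' @param error_rate per-base substitution error probability.
#' @param q0,q_decay,q_noise quality model: PHRED at cycle 1, linear decay to
#'   cycle `read_length`, and per-base Gaussian noise SD.
#' @param tag_length random molecular tag length.
#' @param seed integer seed for [simulate_run()].
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_templates = 5000L, template_length = 1365L,
                       reference_fasta = NULL, n_samples = 12L,
                       depth = 8, bias_sigma = 1.27,
                       chimera_rate = 0.10, chimera_cross_sample_prob = 0,
                       frag_min = 400L, frag_max = 1500L,
                       tagmented_ratio = 7, read_length = 250L,
                       error_rate = 0.005, q0 = 38L, q_decay = 12,
                       q_noise = 1.5, tag_length = 10L, seed = 1L) {
  stopifnot(chimera_rate >= 0, chimera_rate <= 1, frag_min <= frag_max,
            depth >= 1, n_templates >= 1, n_samples >= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d templates x %d nt, %d samples | depth %g, sigma %.2f, chimera %.0f%%\n",
    x$n_templates, x$template_length, x$n_samples, x$depth, x$bias_sigma,
    100 * x$chimera_rate))
  cat(sprintf("  fragments %d-%d bp at %g:1, reads 2x%d, error %.3f\n",
              x$frag_min, x$frag_max, x$tagmented_ratio, x$read_length,
              x$error_rate))
  invisible(x)
}

#' Generate a barcode set with guaranteed decoding margin
#'
#' Greedy rejection sampling of random barcodes keeping minimum pairwise
#' Hamming distance >= `min_dist` (3 by default, so one tolerated mismatch
#' decodes unambiguously). Uses the current RNG state.
#'
#' @param n number of barcodes.
#' @param length barcode length.
#' @param min_dist minimum pairwise Hamming distance.
#' @return character vector of barcodes.
#' @export
make_barcode_set <- function(n, length = 8L, min_dist = 3L) {
  out <- character(0)
  tries <- 0L
  while (length(out) < n) {
    cand <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                  collapse = "")
    if (!length(out) ||
        min(hamming_to(cand, seq_matrix(out))) >= min_dist)
      out <- c(out, cand)
    tries <- tries + 1L
    if (tries > 1000L * n) stop("barcode set generation did not converge")
  }
  out
}

instantiate_iupac <- function(pattern) {
  s <- strsplit(pattern, "")[[1]]
  paste(vapply(s, function(b) {
    opts <- .IUPAC[[b]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

#' Draw tagged template molecules
#'
#' Templates carry a forward-primer-compatible 5' terminus and the reverse
#' complement of the reverse primer at the 3' terminus (degenerate positions
#' instantiated per template); cores are random, or drawn from
#' `reference_fasta` when given. Each template receives independent uniform
#' random tags at both ends (duplicate draws allowed -- tag collisions are
#' part of the model) and a sample.
#'
#' @param config a [sim_config()].
#' @param run_cfg a [run_config()] providing the end designs.
#' @return list with `templates` data.frame (`template_id`, `sample`,
#'   `tag_f`, `tag_r`, `sequence`, `insert`) and `sheet` (a
#'   [sample_sheet()]).
#' @export
simulate_templates <- function(config, run_cfg = run_config()) {
  n <- config$n_templates
  fp <- run_cfg$forward_design$gene_primer
  rp <- run_cfg$reverse_design$gene_primer
  bl <- run_cfg$forward_design$barcode_length

  bc_f <- make_barcode_set(config$n_samples, bl)
  bc_r <- make_barcode_set(config$n_samples, bl)
  sheet <- sample_sheet(data.frame(
    sample = sprintf("S%02d", seq_len(config$n_samples)),
    barcode_f = bc_f, barcode_r = bc_r, stringsAsFactors = FALSE), bl)

  fl <- nchar(fp); rl <- nchar(rp)
  if (!is.null(config$reference_fasta)) {
    ref <- Biostrings::readDNAStringSet(config$reference_fasta)
    pickn <- sample(length(ref), n, replace = TRUE)
    cores <- as.character(ref[pickn])
  } else {
    core_len <- config$template_length - fl - rl
    stopifnot(core_len > 0)
    cores <- random_dna(n, core_len)
  }
  f_sites <- vapply(seq_len(n), function(i) instantiate_iupac(fp),
                    character(1))
  r_sites <- vapply(seq_len(n), function(i) instantiate_iupac(rp),
                    character(1))
  seqs <- paste0(f_sites, cores, revcomp(r_sites))
  data_templates <- data.frame(
    template_id = seq_len(n),
    sample = sprintf("S%02d", (seq_len(n) - 1L) %% config$n_samples + 1L),
    tag_f = random_dna(n, config$tag_length),
    tag_r = random_dna(n, config$tag_length),
    sequence = seqs,
    insert = substr(seqs, fl + 1L, nchar(seqs) - rl),
    stringsAsFactors = FALSE)
  list(templates = data_templates, sheet = sheet)
}

#' Amplify templates with lognormal bias and template-switch chimeras
#'
#' Each template's sequenced copy number is `max(1, round(depth *
#' lognormal(0, sigma)))`. With probability `chimera_rate` a copy is replaced
#' by a chimera: a breakpoint uniform in the template interior joins the
#' prefix of one random parent to the suffix of another (distinct) parent,
#' inheriting tag_f/barcode_f from the prefix parent and tag_r/barcode_r
#' from the suffix parent. Parents are drawn within the copy's sample unless
#' a cross-sample draw fires.
#'
#' @param templates templates data.frame from [simulate_templates()].
#' @param config a [sim_config()].
#' @return molecules data.frame: `molecule_id`, `is_chimera`, `template_id`
#'   (NA for chimeras), `parent_a`, `parent_b`, `breakpoint`, `sample_f`,
#'   `sample_r`, `tag_f`, `tag_r`.
#' @export
simulate_amplification <- function(templates, config) {
  n <- nrow(templates)
  copies <- pmax(1L, as.integer(round(
    config$depth * stats::rlnorm(n, 0, config$bias_sigma))))
  src <- rep(seq_len(n), copies)
  m <- length(src)
  chim <- stats::runif(m) < config$chimera_rate

  mol <- data.frame(
    molecule_id = seq_len(m),
    is_chimera = chim,
    template_id = ifelse(chim, NA_integer_, src),
    parent_a = NA_integer_, parent_b = NA_integer_,
    breakpoint = NA_integer_,
    stringsAsFactors = FALSE)

  if (any(chim)) {
    by_sample <- split(seq_len(n), templates$sample)
    for (i in which(chim)) {
      cross <- stats::runif(1) < config$chimera_cross_sample_prob
      pool <- if (cross) seq_len(n) else by_sample[[templates$sample[src[i]]]]
      if (length(pool) < 2L) pool <- seq_len(n)
      pa <- sample(pool, 1L)
      repeat {
        pb <- sample(pool, 1L)
        if (pb != pa) break
      }
      mol$parent_a[i] <- pa; mol$parent_b[i] <- pb
      L <- nchar(templates$sequence[pa])
      rng <- if (L >= 81L) 40:(L - 40L) else max(2L, L %/% 2L)
      mol$breakpoint[i] <- rng[sample.int(length(rng), 1L)]
    }
  }
  pa <- ifelse(mol$is_chimera, mol$parent_a, src)
  pb <- ifelse(mol$is_chimera, mol$parent_b, src)
  mol$sample_f <- templates$sample[pa]
  mol$sample_r <- templates$sample[pb]
  mol$tag_f <- templates$tag_f[pa]
  mol$tag_r <- templates$tag_r[pb]
  mol
}

molecule_sequences <- function(templates, molecules) {
  out <- character(nrow(molecules))
  plain <- !molecules$is_chimera
  out[plain] <- templates$sequence[molecules$template_id[plain]]
  if (any(!plain)) {
    i <- which(!plain)
    a <- templates$sequence[molecules$parent_a[i]]
    b <- templates$sequence[molecules$parent_b[i]]
    bp <- molecules$breakpoint[i]
    out[i] <- paste0(substr(a, 1L, bp), substr(b, bp + 1L, nchar(b)))
  }
  out
}

#' Fragment the amplified pool and sequence it
#'
#' Full-length molecules are emitted as end+end read pairs (one per
#' molecule). Tagmented fragments are drawn uniformly from the pool with a
#' uniform cut, retained when the fragment is within the size range and
#' carries exactly one tagged end, and pooled with the full-length pairs at
#' `tagmented_ratio`:1. Each fragment yields one read pair reading inward
#' from its two ends; which physical mate carries the tagged end is random.
#' Substitution errors and position-decaying qualities are applied per base.
#'
#' @param templates,molecules from the previous stages.
#' @param sheet the [sample_sheet()] of the simulated run.
#' @param config a [sim_config()].
#' @param run_cfg a [run_config()] (end designs; phaser lengths).
#' @return list with `pairs` (read pair table) and `read_truth` data.frame
#'   (`pair_id`, `molecule_id`, `frag_class` FULL/TAG_LEFT/TAG_RIGHT,
#'   `frag_len`, `tagged_mate`, `is_chimera`, `template_id`).
#' @export
simulate_fragments_and_reads <- function(templates, molecules, sheet,
                                         config, run_cfg = run_config()) {
  bc_of <- function(samples, side) {
    i <- match(samples, sheet$samples$sample)
    sheet$samples[[side]][i]
  }
  m <- nrow(molecules)
  rl <- config$read_length
  phl <- run_cfg$forward_design$phaser_lengths

  tseq <- molecule_sequences(templates, molecules)
  draw_phasers <- function() {
    lens <- phl[sample.int(length(phl), m, replace = TRUE)]
    vapply(lens, function(l)
      if (l == 0L) "" else paste(sample(c("A", "C", "G", "T"), l, TRUE),
                                 collapse = ""), character(1))
  }
  ph_f <- draw_phasers()
  ph_r <- draw_phasers()
  syn_f <- paste0(ph_f, bc_of(molecules$sample_f, "barcode_f"),
                  molecules$tag_f)
  syn_r <- paste0(ph_r, bc_of(molecules$sample_r, "barcode_r"),
                  molecules$tag_r)
  amp <- paste0(syn_f, tseq, revcomp(syn_r))
  alen <- nchar(amp)

  # end+end pairs: one per molecule
  full_a <- substr(amp, 1L, rl)
  full_b <- revcomp(substr(amp, alen - rl + 1L, alen))

  # tagmented fragments; cut points fall between the primer annealing sites
  # (the tagged synthetic end plus its primer region is decoded and trimmed,
  # and the untagged cut must not leave undecodable partial primer sequence
  # on the internal read)
  n_tag <- round(config$tagmented_ratio * m)
  src <- if (n_tag > 0L) sample.int(m, n_tag, replace = TRUE) else integer(0)
  side <- sample(c("L", "R"), n_tag, replace = TRUE)
  fpl <- nchar(run_cfg$forward_design$gene_primer)
  rpl <- nchar(run_cfg$reverse_design$gene_primer)
  tlen <- nchar(tseq)[src]  # template length of the source molecule
  syn_len <- ifelse(side == "L", nchar(syn_f[src]), nchar(syn_r[src]))
  # cut in template coordinates within [fpl + 1, L - rpl]
  fmin <- pmax(config$frag_min,
               syn_len + ifelse(side == "L", fpl, rpl) + 1L)
  fmax <- pmin(config$frag_max,
               syn_len + tlen - ifelse(side == "L", rpl, fpl))
  feasible <- fmax >= fmin & fmax >= rl
  src <- src[feasible]; side <- side[feasible]
  fmin <- fmin[feasible]; fmax <- fmax[feasible]
  n_tag <- length(src)
  flen <- floor(stats::runif(n_tag, fmin, fmax + 1))
  frag <- ifelse(side == "L",
                 substr(amp[src], 1L, flen),
                 substr(amp[src], alen[src] - flen + 1L, alen[src]))
  tag_a <- substr(frag, 1L, rl)                      # from fragment 5' end
  tag_b <- revcomp(substr(frag, flen - rl + 1L, flen))  # from fragment 3' end

  seq_a <- c(full_a, tag_a)
  seq_b <- c(full_b, tag_b)
  n_pairs <- length(seq_a)
  frag_class <- c(rep("FULL", m), ifelse(side == "L", "TAG_LEFT", "TAG_RIGHT"))
  mol_id <- c(molecules$molecule_id, molecules$molecule_id[src])
  frag_len <- c(alen, flen)
  # the tagged end of a TAG_RIGHT fragment is its 3' end (read b)
  tagged_is_a <- frag_class != "TAG_RIGHT"

  swap <- stats::runif(n_pairs) < 0.5
  seq1 <- ifelse(swap, seq_b, seq_a)
  seq2 <- ifelse(swap, seq_a, seq_b)
  tagged_mate <- ifelse(frag_class == "FULL", NA_integer_,
                        ifelse(tagged_is_a == !swap, 1L, 2L))

  seq1 <- add_errors(seq1, config$error_rate)
  seq2 <- add_errors(seq2, config$error_rate)
  qual1 <- sim_qualities(nchar(seq1), config)
  qual2 <- sim_qualities(nchar(seq2), config)

  ids <- sprintf("sim%07d", seq_len(n_pairs))
  pairs <- data.frame(pair_id = ids, seq1 = seq1, qual1 = qual1,
                      seq2 = seq2, qual2 = qual2, stringsAsFactors = FALSE)
  read_truth <- data.frame(
    pair_id = ids, molecule_id = mol_id, frag_class = frag_class,
    frag_len = frag_len, tagged_mate = tagged_mate,
    is_chimera = molecules$is_chimera[mol_id],
    template_id = molecules$template_id[mol_id],
    stringsAsFactors = FALSE)
  list(pairs = pairs, read_truth = read_truth)
}

# substitution errors at a fixed per-base rate, chunked to bound memory
add_errors <- function(seqs, rate, chunk = 20000L) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  base_int <- utf8ToInt("ACGT")
  for (lo in seq(1L, length(seqs), by = chunk)) {
    hi <- min(lo + chunk - 1L, length(seqs))
    w <- unique(nchar(seqs[lo:hi]))
    for (wd in w) {
      sel <- lo:hi
      sel <- sel[nchar(seqs[sel]) == wd]
      mat <- seq_matrix(seqs[sel])
      hitn <- stats::rbinom(1L, length(mat), rate)
      if (hitn > 0L) {
        pos <- sample.int(length(mat), hitn)
        cur <- mat[pos]
        sub <- vapply(cur, function(b)
          sample(setdiff(base_int, b), 1L), integer(1))
        mat[pos] <- sub
        seqs[sel] <- apply(mat, 2L, intToUtf8)
      }
    }
  }
  seqs
}

# position-decaying quality strings with Gaussian noise, clamped to 2..40
sim_qualities <- function(widths, config) {
  vapply(widths, function(w) {
    pos <- seq_len(w)
    q <- config$q0 - config$q_decay * (pos - 1) / max(1L, w - 1L) +
      stats::rnorm(w, 0, config$q_noise)
    int_to_phred(as.integer(.clamp(round(q), 2L, 40L)))
  }, character(1))
}

#' Simulate a complete tagged-amplicon sequencing run
#'
#' Seeds the RNG from `config$seed` and runs template drawing,
#' amplification and sequencing. The same configuration and seed always
#' produce identical output.
#'
#' @param config a [sim_config()].
#' @param run_cfg a [run_config()] used for layout definitions (its seed is
#'   not consulted here).
#' @return list of class `sim_run`: `pairs`, `truth` (list with `templates`,
#'   `molecules`, `reads`), `sheet`, `config`, `run_cfg`.
#' @export
simulate_run <- function(config = sim_config(), run_cfg = run_config()) {
  set.seed(config$seed)
  tpl <- simulate_templates(config, run_cfg)
  mol <- simulate_amplification(tpl$templates, config)
  sr <- simulate_fragments_and_reads(tpl$templates, mol, tpl$sheet,
                                     config, run_cfg)
  structure(list(pairs = sr$pairs,
                 truth = list(templates = tpl$templates, molecules = mol,
                              reads = sr$read_truth),
                 sheet = tpl$sheet, config = config, run_cfg = run_cfg),
            class = "sim_run")
}

#' @export
print.sim_run <- function(x, ...) {
  cat(sprintf(
    "<sim_run> %d read pairs from %d molecules (%d templates, %d chimeric molecules)\n",
    nrow(x$pairs), nrow(x$truth$molecules), nrow(x$truth$templates),
    sum(x$truth$molecules$is_chimera)))
  invisible(x)
}
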