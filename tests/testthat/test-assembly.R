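# Trimming, error correction, de Bruijn assembly and the coverage filter.

test_that("synthetic prefixes and adapter read-through are trimmed", {
  cfg <- run_config()
  # parsed end read: first 40 nt removed
  s <- paste0(strrep("G", 40), strrep("A", 60))
  tr <- trim_synthetic(s, q40(100), insert_start = 40L, config = cfg)
  expect_equal(tr$seq, strrep("A", 60))
  expect_equal(nchar(tr$qual), 60L)
  # internal read with a Nextera stub at the 3' end
  stub <- unname(cfg$adapter_stubs["nextera"])
  s2 <- paste0(strrep("A", 80), stub, "T")
  tr2 <- trim_synthetic(s2, q40(nchar(s2)), NA, cfg)
  expect_equal(tr2$seq, strrep("A", 80))
  # stub with one mismatch still found
  stub1 <- stub
  substr(stub1, 5, 5) <- if (substr(stub1, 5, 5) == "A") "C" else "A"
  s3 <- paste0(strrep("A", 80), stub1)
  expect_equal(trim_synthetic(s3, q40(nchar(s3)), NA, cfg)$seq,
               strrep("A", 80))
  # read with no synthetic content is unchanged
  s4 <- rand_dna(1, 120)
  expect_equal(trim_synthetic(s4, q40(120), NA, cfg)$seq, s4)
})

test_that("quality trimming matches a brute-force running-sum oracle", {
  bwa_oracle <- function(q, thr) {
    # best suffix cut maximising sum(thr - q) over the removed tail
    L <- length(q)
    best <- 0; best_cut <- L + 1L
    for (cut in L:1) {
      s <- sum(thr - q[cut:L])
      if (s > best) { best <- s; best_cut <- cut }
    }
    best_cut - 1L
  }
  set.seed(7)
  for (rep in 1:25) {
    q <- sample(2:40, 80, replace = TRUE)
    s <- rand_dna(1, 80)
    got <- quality_trim(s, intToUtf8(q + 33L), 20L)
    expect_equal(nchar(got$seq), bwa_oracle(q, 20L))
    expect_equal(got$seq, substr(s, 1, nchar(got$seq)))
  }
  # all-Q40 unchanged; trailing Q2 removed; all-Q2 fully trimmed
  expect_equal(nchar(quality_trim(strrep("A", 50), q40(50))$seq), 50L)
  q <- c(rep(40L, 40), rep(2L, 10))
  expect_equal(nchar(quality_trim(strrep("A", 50), intToUtf8(q + 33))$seq),
               40L)
  expect_equal(nchar(quality_trim(strrep("A", 50),
                                  intToUtf8(rep(2L, 50) + 33))$seq), 0L)
})

test_that("a lone substitution among exact copies is reverted", {
  set.seed(9)
  tpl <- rand_dna(1, 120)
  reads <- rep(tpl, 30)
  mut <- tpl
  substr(mut, 60, 60) <- if (substr(tpl, 60, 60) == "A") "G" else "A"
  reads[7] <- mut
  fixed <- correct_errors(reads, k = 31)
  expect_equal(fixed[7], tpl)
  expect_equal(fixed[-7], reads[-7])
  # error-free input unchanged
  expect_equal(correct_errors(rep(tpl, 30), k = 31), rep(tpl, 30))
})

test_that("ambiguous corrections leave the base unchanged", {
  set.seed(10)
  tpl1 <- rand_dna(1, 100)
  tpl2 <- tpl1; tpl3 <- tpl1
  substr(tpl2, 50, 50) <- "A"; substr(tpl3, 50, 50) <- "C"
  if (substr(tpl1, 50, 50) %in% c("A", "C")) {
    substr(tpl2, 50, 50) <- "G"; substr(tpl3, 50, 50) <- "T"
  }
  bad <- tpl1
  substr(bad, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                                 c(substr(tpl2, 50, 50),
                                   substr(tpl3, 50, 50),
                                   substr(tpl1, 50, 50)))[1]
  reads <- c(rep(tpl2, 10), rep(tpl3, 10), bad)
  fixed <- correct_errors(reads, k = 31)
  expect_equal(fixed[21], bad)  # two equally plausible fixes -> untouched
})

tile_reads <- function(tpl, step = 60L, width = 100L) {
  starts <- seq(1L, nchar(tpl) - width + 1L, by = step)
  starts <- unique(c(starts, nchar(tpl) - width + 1L))
  substring(tpl, starts, starts + width - 1L)
}

test_that("error-free tiling reads reassemble the template exactly", {
  set.seed(14)
  tpl <- rand_dna(1, 1365)
  reads <- rep(tile_reads(tpl), 5)
  contigs <- assemble_bin(reads, k = 31)
  expect_length(contigs, 1L)
  expect_equal(contigs[[1]]$sequence, tpl)
  expect_equal(length(contigs[[1]]$coverage), 1365L)
  expect_equal(contigs[[1]]$mean_coverage, mean(contigs[[1]]$coverage))
})

test_that("a coverage gap wider than k splits the assembly in two", {
  set.seed(15)
  tpl <- rand_dna(1, 1000)
  left <- substring(tpl, c(1, 80, 160, 240), c(1, 80, 160, 240) + 159)
  right <- substring(tpl, c(560, 640, 720, 800), c(560, 640, 720, 800) + 199)
  contigs <- assemble_bin(rep(c(left, right), 4), k = 31)
  expect_length(contigs, 2L)
  expect_equal(vapply(contigs, function(cg) cg$sequence, character(1)),
               c(substr(tpl, 1, 399), substr(tpl, 560, 999)))
})

test_that("a noisy simulated bin assembles to the template after correction", {
  set.seed(16)
  tpl <- rand_dna(1, 800)
  reads <- rep(tile_reads(tpl, step = 25L, width = 150L), 5)  # ~30x
  # 1% substitution errors
  reads <- vapply(reads, function(s) {
    n <- nchar(s)
    hits <- which(stats::runif(n) < 0.01)
    for (i in hits) {
      substr(s, i, i) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(s, i, i)), 1)
    }
    s
  }, character(1), USE.NAMES = FALSE)
  corrected <- correct_errors(reads, k = 31)
  contigs <- assemble_bin(corrected, k = 31)
  kept <- filter_contigs(contigs)
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$sequence, tpl)
})

test_that("the 10-fold coverage filter is strict at the boundary", {
  mk <- function(cov) structure(list(sequence = strrep("A", 40),
                                     coverage = rep(cov, 40),
                                     mean_coverage = cov), class = "contig")
  # 9 * 10 < 100 -> dropped
  kept <- filter_contigs(list(mk(100), mk(9)))
  expect_equal(vapply(kept, function(x) x$mean_coverage, numeric(1)), 100)
  # 10 * 10 == 100 -> kept (not strict)
  kept2 <- filter_contigs(list(mk(100), mk(10)))
  expect_length(kept2, 2L)
  expect_length(filter_contigs(list(mk(3))), 1L)
  expect_length(filter_contigs(list()), 0L)
})

test_that("the coverage filter is idempotent and scale-invariant", {
  set.seed(18)
  mk <- function(cov) structure(list(sequence = strrep("A", 40),
                                     coverage = rep(cov, 40),
                                     mean_coverage = cov), class = "contig")
  covs <- c(100, 55, 12, 10, 9.9, 3, 1)
  one <- filter_contigs(lapply(covs, mk))
  expect_equal(filter_contigs(one), one)
  scaled <- filter_contigs(lapply(covs * 7.3, mk))
  expect_equal(vapply(scaled, function(x) x$mean_coverage, numeric(1)) / 7.3,
               vapply(one, function(x) x$mean_coverage, numeric(1)))
})

test_that("low-coverage chimeric contamination is removed by the filter", {
  set.seed(20)
  tpl <- rand_dna(1, 900)
  alien <- rand_dna(1, 900)  # divergent chimera-derived sequence
  reads <- rep(tile_reads(tpl, step = 30L, width = 120L), 6)   # ~24x
  chim <- tile_reads(alien, step = 60L, width = 120L)          # ~2x
  contigs <- assemble_bin(c(reads, chim), k = 31)
  kept <- filter_contigs(contigs)
  seqs <- vapply(kept, function(cg) cg$sequence, character(1))
  expect_true(tpl %in% seqs)
  expect_false(any(vapply(seqs, function(s)
    grepl(s, alien, fixed = TRUE) || grepl(alien, s, fixed = TRUE),
    logical(1))))
})
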