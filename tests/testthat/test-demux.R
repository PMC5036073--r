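# End-layout decoding, pair classification and sample assignment.

test_that("an exact layout parses with zero mismatches and the right tag", {
  tag <- "GATCGATCGA"
  gene <- strrep("T", 20)
  seq <- layout_read("AAAAAAAA", tag, gene)
  p <- parse_end(seq, FWD, tiny_sheet()$forward_set)
  expect_equal(p$phaser_len, 0L)
  expect_equal(p$barcode_assigned, "AAAAAAAA")
  expect_equal(p$barcode_mismatches, 0L)
  expect_equal(p$tag, tag)
  expect_equal(p$insert_start, 8L + 10L + nchar(FWD_SITE))
  expect_equal(p$gene_prefix, strrep("T", 14))
})

test_that("phasers are scanned ascending and one barcode mismatch tolerated", {
  tag <- "GATCGATCGA"
  gene <- strrep("T", 20)
  # 2-nt phaser, one mismatch in the barcode
  seq <- layout_read("AAAAAAAT", tag, gene, phaser = "GG")
  p <- parse_end(seq, FWD, tiny_sheet()$forward_set)
  expect_equal(p$phaser_len, 2L)
  expect_equal(p$barcode_mismatches, 1L)
  expect_equal(p$barcode_assigned, "AAAAAAAA")
  expect_equal(p$tag, tag)
})

test_that("two barcode mismatches or a failed primer screen give no parse", {
  tag <- "GATCGATCGA"; gene <- strrep("T", 20)
  expect_null(parse_end(layout_read("AAAAAATT", tag, gene),
                        FWD, tiny_sheet()$forward_set))
  # barcode exact but 3 mismatches in the primer region (tolerance 2)
  bad_site <- FWD_SITE
  substr(bad_site, 3, 3) <- "T"; substr(bad_site, 6, 6) <- "C"
  substr(bad_site, 9, 9) <- "C"
  expect_null(parse_end(layout_read("AAAAAAAA", tag, gene,
                                    primer_site = bad_site),
                        FWD, tiny_sheet()$forward_set))
  # 2 primer mismatches pass
  ok_site <- FWD_SITE
  substr(ok_site, 3, 3) <- "T"; substr(ok_site, 6, 6) <- "C"
  expect_false(is.null(parse_end(layout_read("AAAAAAAA", tag, gene,
                                             primer_site = ok_site),
                                 FWD, tiny_sheet()$forward_set)))
})

test_that("degenerate primer bases match their IUPAC expansions", {
  # 27F has M at position 12: both A and C match there
  for (b in c("A", "C")) {
    site <- FWD_SITE
    substr(site, 12, 12) <- b
    p <- parse_end(layout_read("AAAAAAAA", "GATCGATCGA", strrep("T", 20),
                               primer_site = site),
                   FWD, tiny_sheet()$forward_set)
    expect_equal(p$primer_mismatches, 0L)
  }
  # read N never matches
  site <- FWD_SITE
  substr(site, 12, 12) <- "N"
  p <- parse_ends(layout_read("AAAAAAAA", "GATCGATCGA", strrep("T", 20),
                              primer_site = site),
                  FWD, tiny_sheet()$forward_set)
  expect_equal(p$primer_mismatches[1], 1L)
})

test_that("pairs classify as end+end / end+internal / unassigned", {
  sheet <- tiny_sheet()
  cfg <- run_config()
  gene <- strrep("T", 40)
  fwd_read <- layout_read("AAAAAAAA", "GATCGATCGA", gene)
  rev_read <- layout_read("GGGGGGGG", "TTTTAAAACC", strrep("C", 40),
                          primer_site = REV_SITE)
  none <- strrep("G", nchar(fwd_read))
  mk <- function(s1, s2) data.frame(pair_id = "p", seq1 = s1,
                                    qual1 = q40(nchar(s1)), seq2 = s2,
                                    qual2 = q40(nchar(s2)),
                                    stringsAsFactors = FALSE)
  ee <- classify_pair(mk(fwd_read, rev_read), cfg, sheet)
  expect_equal(ee$fragment_class, "END_END")
  expect_equal(ee$sample, "S1")
  expect_equal(ee$f_mate, 1L)
  # swapped mates still end+end
  ee2 <- classify_pair(mk(rev_read, fwd_read), cfg, sheet)
  expect_equal(ee2$fragment_class, "END_END")
  expect_equal(ee2$f_mate, 2L)
  # reverse end + unparseable mate -> end+internal (REVERSE)
  ei <- classify_pair(mk(rev_read, none), cfg, sheet)
  expect_equal(ei$fragment_class, "END_INTERNAL")
  expect_equal(ei$end_label, "REVERSE")
  expect_equal(ei$internal_mate, 2L)
  # neither parses
  un <- classify_pair(mk(none, none), cfg, sheet)
  expect_equal(un$fragment_class, "UNASSIGNED")
  # two forward parses are an anomaly, not a guess
  an <- classify_pair(mk(fwd_read, fwd_read), cfg, sheet)
  expect_equal(an$fragment_class, "UNASSIGNED")
  expect_true(an$anomaly)
})

test_that("sample assignment flags cross-pairings as invalid", {
  sheet <- tiny_sheet()
  expect_equal(assign_sample("AAAAAAAA", "GGGGGGGG", sheet), "S1")
  expect_equal(assign_sample("CCCCCCCC", "TTTTTTTT", sheet), "S2")
  expect_equal(assign_sample("AAAAAAAA", "TTTTTTTT", sheet),
               "INVALID_COMBINATION")
})

test_that("invalid-combination rate matches direct arithmetic", {
  expect_equal(invalid_combination_rate(0, 100)$rate, 0)
  expect_equal(invalid_combination_rate(10, 40)$rate, 25)
  expect_error(invalid_combination_rate(1, 0), "> 0")
})

test_that("1-mismatch decoding never misassigns with distance-3 barcodes", {
  set.seed(21)
  bcs <- make_barcode_set(6, 8, min_dist = 3)
  # exhaustive single-error corruption of every barcode
  for (b in bcs) {
    for (pos in 1:8) {
      for (sub in setdiff(c("A", "C", "G", "T"), substr(b, pos, pos))) {
        corrupted <- b
        substr(corrupted, pos, pos) <- sub
        seq <- layout_read(corrupted, "GATCGATCGA", strrep("T", 20))
        p <- parse_end(seq, FWD, bcs)
        expect_equal(p$barcode_assigned, b)
        expect_equal(p$barcode_mismatches, 1L)
      }
    }
  }
})

test_that("error-free simulated full-length fragments all classify end+end", {
  sc <- sim_config(n_templates = 15, n_samples = 3, depth = 3,
                   bias_sigma = 0.3, chimera_rate = 0, tagmented_ratio = 0,
                   error_rate = 0, seed = 99)
  sim <- simulate_run(sc)
  cls <- classify_pairs(sim$pairs, sim$run_cfg, sim$sheet)
  expect_true(all(cls$fragment_class == "END_END"))
  truth_sample <- sim$truth$templates$sample[
    sim$truth$molecules$template_id[
      sim$truth$reads$molecule_id[match(cls$pair_id,
                                        sim$truth$reads$pair_id)]]]
  expect_equal(cls$sample, truth_sample)
})

test_that("classification is deterministic", {
  sc <- sim_config(n_templates = 8, n_samples = 2, depth = 3,
                   bias_sigma = 0.3, chimera_rate = 0.1, tagmented_ratio = 2,
                   error_rate = 0.01, seed = 3)
  sim <- simulate_run(sc)
  cfg <- sim$run_cfg
  a <- classify_pairs(sim$pairs, cfg, sim$sheet)
  b <- classify_pairs(sim$pairs, cfg, sim$sheet)
  expect_identical(a, b)
})
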