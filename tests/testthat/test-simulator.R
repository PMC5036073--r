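# Ground-truth simulator: determinism, counting, chimera and fragment models.

test_that("template drawing is deterministic and counts match", {
  sc <- sim_config(n_templates = 100, n_samples = 4, seed = 51)
  set.seed(sc$seed)
  a <- simulate_templates(sc)
  set.seed(sc$seed)
  b <- simulate_templates(sc)
  expect_identical(a, b)
  expect_equal(nrow(a$templates), 100L)
  expect_equal(nchar(a$templates$sequence), rep(1365L, 100))
  expect_equal(nchar(a$templates$tag_f), rep(10L, 100))
  expect_true(all(table(a$templates$sample) == 25))
  # templates decode with the forward design: start with a 27F-compatible site
  expect_true(all(long16s::parse_ends(
    paste0("AAAAAAAA", "GATCGATCGA", a$templates$sequence),
    FWD, "AAAAAAAA")$ok))
})

test_that("tag collisions track the birthday bound at n = 5000", {
  sc <- sim_config(n_templates = 5000, seed = 52)
  set.seed(sc$seed)
  tpl <- simulate_templates(sc)$templates
  n <- 5000; space <- 4^10
  expected_dups <- n - space * (1 - (1 - 1 / space)^n)
  sd_approx <- sqrt(expected_dups)
  for (tags in list(tpl$tag_f, tpl$tag_r)) {
    dups <- n - length(unique(tags))
    expect_lte(abs(dups - expected_dups), max(3 * sd_approx, 6))
  }
})

test_that("amplification bias and chimera labelling behave as configured", {
  sc <- sim_config(n_templates = 300, n_samples = 3, depth = 6,
                   bias_sigma = 0.8, chimera_rate = 0.1, seed = 53)
  set.seed(sc$seed)
  tpl <- simulate_templates(sc)$templates
  mol <- simulate_amplification(tpl, sc)
  # chimera fraction within the 99% binomial interval of 0.1
  m <- nrow(mol)
  half <- 2.576 * sqrt(0.1 * 0.9 / m)
  expect_lt(abs(mean(mol$is_chimera) - 0.1), half)
  # chimeras have two distinct parents and within-sample barcodes by default
  ch <- mol[mol$is_chimera, ]
  expect_true(all(ch$parent_a != ch$parent_b))
  expect_true(all(tpl$sample[ch$parent_a] == tpl$sample[ch$parent_b]))
  expect_true(all(ch$tag_f == tpl$tag_f[ch$parent_a]))
  expect_true(all(ch$tag_r == tpl$tag_r[ch$parent_b]))
  # r = 0 gives no chimeras; sigma = 0 gives equal copy numbers
  sc0 <- sim_config(n_templates = 50, depth = 4, bias_sigma = 0,
                    chimera_rate = 0, seed = 54)
  set.seed(sc0$seed)
  tpl0 <- simulate_templates(sc0)$templates
  mol0 <- simulate_amplification(tpl0, sc0)
  expect_false(any(mol0$is_chimera))
  expect_true(all(table(mol0$template_id) == 4L))
})

test_that("cross-sample chimeras surface as invalid barcode combinations", {
  sc <- sim_config(n_templates = 60, n_samples = 4, depth = 5,
                   bias_sigma = 0.3, chimera_rate = 0.2,
                   chimera_cross_sample_prob = 1, tagmented_ratio = 0,
                   error_rate = 0, seed = 55)
  sim <- simulate_run(sc)
  cls <- classify_pairs(sim$pairs, sim$run_cfg, sim$sheet)
  inv <- invalid_combination_rate(cls, nrow(cls))
  truth <- sim$truth$reads
  cross <- sim$truth$molecules$sample_f != sim$truth$molecules$sample_r
  expect_equal(inv$n_invalid,
               sum(cross[truth$molecule_id[truth$frag_class == "FULL"]]))
})

test_that("fragment sizes, tag content and pool ratio follow the config", {
  sc <- sim_config(n_templates = 30, n_samples = 2, depth = 5,
                   bias_sigma = 0.3, chimera_rate = 0, tagmented_ratio = 7,
                   error_rate = 0, seed = 56)
  sim <- simulate_run(sc)
  truth <- sim$truth$reads
  tagm <- truth[truth$frag_class != "FULL", ]
  expect_true(all(tagm$frag_len >= 400 & tagm$frag_len <= 1500))
  # ratio within 5% of 7:1
  ratio <- nrow(tagm) / sum(truth$frag_class == "FULL")
  expect_lt(abs(ratio - 7) / 7, 0.05)
  # read ids and truth records are in bijection
  expect_setequal(truth$pair_id, sim$pairs$pair_id)
  expect_false(anyDuplicated(truth$pair_id) > 0)
})

test_that("the same config and seed reproduce the run byte for byte", {
  sc <- sim_config(n_templates = 10, n_samples = 2, depth = 3,
                   bias_sigma = 0.5, chimera_rate = 0.1, tagmented_ratio = 3,
                   error_rate = 0.01, seed = 57)
  a <- simulate_run(sc); b <- simulate_run(sc)
  expect_identical(a$pairs, b$pairs)
  expect_identical(a$truth, b$truth)
  f1 <- tempfile(); f2 <- tempfile(); g1 <- tempfile(); g2 <- tempfile()
  write_fastq_pairs(a$pairs, f1, f2)
  write_fastq_pairs(b$pairs, g1, g2)
  expect_identical(readLines(f1), readLines(g1))
  expect_identical(readLines(f2), readLines(g2))
})

test_that("error-free single-template runs survive the whole pipeline", {
  sc <- sim_config(n_templates = 1, n_samples = 1, depth = 10,
                   bias_sigma = 0, chimera_rate = 0, tagmented_ratio = 12,
                   error_rate = 0, seed = 58)
  sim <- simulate_run(sc)
  res <- run_pipeline(sim)
  expect_equal(nrow(res$filter$kept), 1L)
  expect_equal(res$consensus[[1]]$sequence, sim$truth$templates$insert[1])
})
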