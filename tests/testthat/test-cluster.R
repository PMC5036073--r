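# Dual-tag signature construction and greedy clustering.

test_that("signatures concatenate components in fixed order to 64 nt", {
  cp <- data.frame(fragment_class = "END_END",
                   tag_f = strrep("T", 10), tag_r = strrep("A", 10),
                   bc_f = strrep("C", 8), bc_r = strrep("G", 8),
                   prefix_f = strrep("A", 14), prefix_r = strrep("C", 14),
                   stringsAsFactors = FALSE)
  sig <- build_signature(cp)
  expect_equal(nchar(sig), 64L)
  expect_equal(sig, paste0(strrep("T", 10), strrep("A", 10), strrep("C", 8),
                           strrep("G", 8), strrep("A", 14), strrep("C", 14)))
  cp$fragment_class <- "END_INTERNAL"
  expect_error(build_signature(cp), "END_END")
})

test_that("consensus plurality, tie-break and N handling follow the rules", {
  expect_equal(cluster_consensus(c("ACGT", "ACGT", "ACGA")), "ACGT")
  expect_equal(cluster_consensus(c("ACGT", "ACGA")), "ACGA")  # tie: A < T
  expect_equal(cluster_consensus("GATTACA"), "GATTACA")
  # N loses any tie it is part of, wins only strict majorities
  expect_equal(cluster_consensus(c("AN", "AN", "AC")), "AN")
  expect_equal(cluster_consensus(c("AN", "AC")), "AC")
  expect_error(cluster_consensus(character(0)))
})

test_that("identity threshold on the 64-nt composite is boundary-exact", {
  set.seed(31)
  base <- rand_dna(1, 64)
  mutate <- function(s, k) {
    pos <- sample(64, k)
    v <- strsplit(s, "")[[1]]
    v[pos] <- vapply(v[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste(v, collapse = "")
  }
  # 6/64 mismatches: identity 90.6% >= 0.89 -> one cluster
  tc6 <- greedy_cluster(c(base, mutate(base, 6)))
  expect_equal(nrow(tc6$clusters), 1L)
  expect_equal(tc6$clusters$abundance, 2L)
  # 7/64 = 89.06% still joins; 8/64 = 87.5% splits
  expect_equal(nrow(greedy_cluster(c(base, mutate(base, 7)))$clusters), 1L)
  expect_equal(nrow(greedy_cluster(c(base, mutate(base, 8)))$clusters), 2L)
})

test_that("greedy clustering matches the brute-force reference", {
  set.seed(17)
  for (rep in 1:5) {
    # near-duplicates plus background noise, with multiplicities
    seeds <- rand_dna(4, 64)
    comps <- c(rep(seeds[1], 5), rep(seeds[2], 3),
               vapply(1:6, function(i) {
                 s <- seeds[sample(4, 1)]
                 pos <- sample(64, sample(0:5, 1))
                 v <- strsplit(s, "")[[1]]
                 for (p in pos) v[p] <- sample(c("A", "C", "G", "T"), 1)
                 paste(v, collapse = "")
               }, character(1)),
               rand_dna(6, 64))
    comps <- sample(comps)
    got <- greedy_cluster(comps)
    ref <- brute_force_cluster(comps)
    expect_equal(sort(got$clusters$consensus), sort(ref$consensus))
    expect_equal(got$clusters$abundance[order(got$clusters$consensus)],
                 ref$abundance[order(ref$consensus)])
  }
})

test_that("clustering is invariant to input permutation and conserves reads", {
  set.seed(41)
  comps <- c(rep(rand_dna(1, 64), 4), rand_dna(8, 64))
  a <- greedy_cluster(comps)
  b <- greedy_cluster(rev(comps))
  expect_equal(a$clusters$consensus, b$clusters$consensus)
  expect_equal(a$clusters$abundance, b$clusters$abundance)
  expect_equal(sum(a$clusters$abundance), length(comps))
})

test_that("members stay within the identity threshold of their consensus", {
  sc <- sim_config(n_templates = 30, n_samples = 3, depth = 4,
                   bias_sigma = 0.8, chimera_rate = 0.05,
                   tagmented_ratio = 0, error_rate = 0.01, seed = 8)
  sim <- simulate_run(sc)
  cls <- classify_pairs(sim$pairs, sim$run_cfg, sim$sheet)
  sig <- build_signatures(cls)
  tc <- greedy_cluster(sig)
  expect_equal(sum(tc$clusters$abundance), nrow(sig))
  cons <- tc$clusters$consensus[match(tc$assignment$cluster_id,
                                      tc$clusters$cluster_id)]
  for (i in seq_len(nrow(sig))) {
    d <- sum(strsplit(sig$composite[i], "")[[1]] !=
               strsplit(cons[i], "")[[1]])
    expect_lte(d, 7)
  }
})

test_that("clusters map 1:1 to templates on clean deep simulations", {
  sc <- sim_config(n_templates = 60, n_samples = 3, depth = 6,
                   bias_sigma = 0.3, chimera_rate = 0, tagmented_ratio = 0,
                   error_rate = 0.005, seed = 12)
  sim <- simulate_run(sc)
  cls <- classify_pairs(sim$pairs, sim$run_cfg, sim$sheet)
  sig <- build_signatures(cls)
  tc <- greedy_cluster(sig)
  truth_tpl <- sim$truth$molecules$template_id[
    sim$truth$reads$molecule_id[match(tc$assignment$pair_id,
                                      sim$truth$reads$pair_id)]]
  # every cluster's members come from a single template, and >= 99% of
  # templates have exactly one cluster
  purity <- vapply(split(truth_tpl, tc$assignment$cluster_id),
                   function(t) length(unique(t)) == 1L, logical(1))
  expect_true(all(purity))
  clusters_per_template <- table(vapply(
    split(truth_tpl, tc$assignment$cluster_id), function(t) t[1], integer(1)))
  expect_gte(mean(clusters_per_template == 1L), 0.99)
})
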