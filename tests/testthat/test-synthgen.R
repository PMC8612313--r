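test_that("zero mutation gives exact duplicates within groups, disjoint across", {
  spec <- synth_spec(n_groups = 4, size_distribution = "fixed", fixed_size = 5,
                     vocab_size = 500, template_length = 20, mutation_rate = 0,
                     n_singletons = 0, script_marker_rate = 0, seed = 1)
  corp <- generate_corpus(spec)
  docs <- preprocess(corp$messages, tokenizer_whitespace(), character(),
                     min_tokens = 20, keep = "none")
  D <- unclass(distance_matrix(docs))
  truth <- corp$truth$truth_id[match(docs$message_id, corp$truth$message_id)]
  same <- outer(truth, truth, "==")
  diag(same) <- NA
  expect_true(all(D[same & !is.na(same)] == 0))
  expect_true(all(D[!same & !is.na(same)] == 1))
})

test_that("generation is deterministic for a fixed spec", {
  spec <- synth_spec(n_groups = 5, min_size = 2, max_size = 10,
                     vocab_size = 1000, template_length = 21,
                     mutation_rate = 0.1, n_singletons = 5,
                     combined_pairs = 2, seed = 99)
  c1 <- generate_corpus(spec)
  c2 <- generate_corpus(spec)
  expect_identical(c1$messages, c2$messages)
  expect_identical(c1$truth, c2$truth)
})

test_that("hybrid clustering recovers a mildly mutated planted partition exactly", {
  spec <- synth_spec(n_groups = 2, size_distribution = "fixed", fixed_size = 10,
                     vocab_size = 600, template_length = 25,
                     mutation_rate = 0.05, n_singletons = 0,
                     script_marker_rate = 0, seed = 12)
  corp <- generate_corpus(spec)
  docs <- preprocess(corp$messages, tokenizer_whitespace(), character(),
                     min_tokens = 20, keep = "none")
  truth <- corp$truth$truth_id[match(docs$message_id, corp$truth$message_id)]
  pred <- hybrid_cluster(docs, lambda = 0.6, u = 0.5, seed = 4)
  expect_equal(pairwise_prf(pred, truth)$f_score, 1)
})

test_that("spec validation rejects impossible vocabularies", {
  expect_error(synth_spec(n_groups = 10, template_length = 50, vocab_size = 400),
               "vocabulary too small")
  expect_error(synth_spec(template_length = 10), "template_length")
})

test_that("ground truth conserves all non-mixed messages and marks mixed ones", {
  spec <- synth_spec(n_groups = 4, min_size = 2, max_size = 8,
                     vocab_size = 800, template_length = 20,
                     mutation_rate = 0.05, n_singletons = 6,
                     combined_pairs = 3, seed = 7)
  corp <- generate_corpus(spec)
  expect_equal(nrow(corp$truth), nrow(corp$messages))
  expect_equal(sum(corp$truth$kind == "mixed"), 3)
  expect_true(all(is.na(corp$truth$truth_id[corp$truth$kind == "mixed"])))
  expect_true(all(!is.na(corp$truth$truth_id[corp$truth$kind != "mixed"])))
  # singleton ids do not collide with group ids
  expect_length(
    intersect(corp$truth$truth_id[corp$truth$kind == "singleton"],
              corp$truth$truth_id[corp$truth$kind == "template"]), 0)
  # a combined message sits far from nothing: it overlaps two templates
  mixed_id <- corp$truth$message_id[corp$truth$kind == "mixed"][1]
  docs <- preprocess(corp$messages, tokenizer_whitespace(), character(),
                     min_tokens = 20, keep = "none")
  D <- unclass(distance_matrix(docs))
  mixed_row <- D[docs$message_id == mixed_id, ]
  # distance to its component groups is high but below 1 (partial overlap)
  expect_true(any(mixed_row > 0 & mixed_row < 1))
})

test_that("power-law sizes are long-tailed and totals can be pinned", {
  spec <- synth_spec(n_groups = 500, alpha = 2, min_size = 2, max_size = 10000,
                     vocab_size = 10100 * 2, template_length = 20,
                     mutation_rate = 0, n_singletons = 0,
                     script_marker_rate = 0, seed = 3)
  sizes <- withr::with_seed(spec$seed, rumormill:::draw_group_sizes(spec))
  expect_gte(max(sizes), 10 * median(sizes))

  spec2 <- synth_spec(n_groups = 20, min_size = 2, max_size = 40,
                      total_messages = 300, vocab_size = 2000,
                      template_length = 20, n_singletons = 30,
                      combined_pairs = 5, seed = 2)
  corp2 <- generate_corpus(spec2)
  expect_equal(nrow(corp2$messages), 300)
})

test_that("script markers are planted at the configured rate and detectable", {
  spec <- synth_spec(n_groups = 5, size_distribution = "fixed", fixed_size = 20,
                     vocab_size = 1000, template_length = 20,
                     mutation_rate = 0, n_singletons = 0,
                     script_marker_rate = 0.5, seed = 21)
  corp <- generate_corpus(spec)
  flags <- flag_script_origin(corp$messages$text)
  expect_equal(flags, corp$truth$script_marker)
  expect_gt(mean(flags), 0.3)
  expect_lt(mean(flags), 0.7)
})

test_that("empirical within/between distances match the analytic expectations", {
  spec <- synth_spec(n_groups = 2, size_distribution = "fixed",
                     fixed_size = 100, vocab_size = 5000,
                     template_length = 50, mutation_rate = 0.1,
                     n_singletons = 0, script_marker_rate = 0, seed = 6)
  sep <- expected_separation(spec)
  expect_equal(expected_separation(synth_spec(mutation_rate = 0))$within_mean, 0,
               tolerance = 1e-12)
  corp <- generate_corpus(spec)
  docs <- preprocess(corp$messages, tokenizer_whitespace(), character(),
                     min_tokens = 1, keep = "none")
  truth <- corp$truth$truth_id[match(docs$message_id, corp$truth$message_id)]
  D <- unclass(distance_matrix(docs))
  same <- outer(truth, truth, "==")
  ut <- upper.tri(D)
  within <- D[same & ut]     # ~200 docs -> thousands of within pairs
  between <- D[!same & ut]
  expect_lt(abs(mean(within) - sep$within_mean), sep$tolerance)
  expect_lte(mean(within), sep$within_bound)
  expect_gt(mean(between), 0.995)
})

test_that("a synthetic corpus round-trips through the corpus_io schema", {
  spec <- synth_spec(n_groups = 3, size_distribution = "fixed", fixed_size = 4,
                     vocab_size = 500, template_length = 20,
                     mutation_rate = 0.05, n_singletons = 2, seed = 14)
  corp <- generate_corpus(spec)
  dir <- withr::local_tempdir()
  write_synth_corpus(corp, dir)
  back <- read_messages(file.path(dir, "messages.csv"))
  expect_equal(back$message_id, corp$messages$message_id)
  expect_equal(back$text, corp$messages$text)
  expect_equal(as.numeric(back$report_timestamp),
               as.numeric(corp$messages$report_timestamp))
  expect_true(file.exists(file.path(dir, "truth.csv")))
  spec_back <- jsonlite::read_json(file.path(dir, "spec.json"))
  expect_equal(spec_back$seed, 14)
})
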