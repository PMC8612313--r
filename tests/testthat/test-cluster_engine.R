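test_that("threshold HAC merges below lambda and separates above it", {
  # two identical docs share a label
  D <- unclass(distance_matrix(make_docs(c("a", "b"), c("a", "b"))))
  lab <- hac_cluster(D, lambda = 0.6)
  expect_equal(lab[[1]], lab[[2]])

  # all pairwise distances above lambda: all labels distinct
  D <- unclass(distance_matrix(make_docs(c("a", "b"), c("c", "d"), c("e", "f"))))
  lab <- hac_cluster(D, lambda = 0.6)
  expect_equal(length(unique(lab)), 3)

  expect_equal(hac_cluster(matrix(numeric(0), 0, 0)), integer(0))
  expect_equal(length(hac_cluster(matrix(0, 1, 1))), 1)
})

test_that("HAC recovers planted triplets, matching the agglomeration oracle", {
  set.seed(3)
  # two planted triplets: within-group distance < 0.2, between > 0.9
  g1 <- lapply(1:3, function(i) c(sprintf("a%02d", 1:18), sprintf("x%d", i)))
  g2 <- lapply(1:3, function(i) c(sprintf("b%02d", 1:18), sprintf("y%d", i)))
  docs <- make_docs(c(g1, g2))
  D <- unclass(distance_matrix(docs))
  expect_true(all(D[1:3, 1:3] < 0.2))
  expect_true(all(D[1:3, 4:6] > 0.9))
  lab <- hac_cluster(D, lambda = 0.6)
  expect_true(same_partition(lab, c(1, 1, 1, 2, 2, 2)))
  expect_true(same_partition(lab, oracle_hac(D, 0.6)))
})

test_that("HAC agrees with the brute-force oracle on small seeded corpora", {
  for (s in 1:40) {
    set.seed(s)
    n <- sample(2:8, 1)
    docs <- random_corpus(n)
    D <- unclass(distance_matrix(docs))
    for (linkage in c("average", "complete", "single")) {
      expect_true(
        same_partition(hac_cluster(D, 0.6, linkage), oracle_hac(D, 0.6, linkage)),
        label = sprintf("seed %d, n %d, linkage %s", s, n, linkage))
    }
    # generic real-valued distances exercise the merge logic without ties
    M <- matrix(0, n, n)
    M[upper.tri(M)] <- runif(n * (n - 1) / 2)
    M <- M + t(M)
    rownames(M) <- colnames(M) <- as.character(seq_len(n))
    expect_true(same_partition(hac_cluster(M, 0.6), oracle_hac(M, 0.6)))
  }
})

test_that("hybrid clustering at u = 1 reduces exactly to full HAC", {
  for (s in 1:5) {
    set.seed(200 + s)
    spec <- synth_spec(n_groups = 6, min_size = 2, max_size = 15,
                       vocab_size = 1500, template_length = 22,
                       mutation_rate = 0.08, n_singletons = 8, seed = 200 + s)
    corp <- generate_corpus(spec)
    docs <- preprocess(corp$messages, tokenizer_whitespace(), character(),
                       min_tokens = 20, keep = "none")
    D <- distance_matrix(docs)
    gold <- hac_cluster(D, 0.6)
    hy <- hybrid_cluster(docs, u = 1.0, seed = s, dmat = D)
    expect_true(same_partition(hy, gold))
  }
})

test_that("hybrid clustering recovers well-separated planted groups", {
  spec <- synth_spec(n_groups = 2, size_distribution = "fixed", fixed_size = 10,
                     vocab_size = 500, template_length = 25,
                     mutation_rate = 0.05, n_singletons = 0,
                     script_marker_rate = 0, seed = 5)
  corp <- generate_corpus(spec)
  docs <- preprocess(corp$messages, tokenizer_whitespace(), character(),
                     min_tokens = 20, keep = "none")
  hy <- hybrid_cluster(docs, u = 0.5, seed = 17)
  truth <- corp$truth$truth_id[match(docs$message_id, corp$truth$message_id)]
  expect_true(same_partition(hy, truth))
  # and the full-HAC oracle on the same corpus agrees
  expect_true(same_partition(hy, hac_cluster(distance_matrix(docs), 0.6)))
})

test_that("a corpus with all pairwise distances above lambda yields singletons", {
  docs <- make_docs(lapply(1:6, function(i) sprintf("t%d_%02d", i, 1:20)))
  hy <- hybrid_cluster(docs, u = 0.5, seed = 1)
  expect_equal(length(unique(as.integer(hy))), 6)
  # every document went through the second pass (degenerate sample fallback)
  expect_true(all(attr(hy, "pass") == 2L))
})

test_that("hybrid labelings conserve documents, are deterministic, and keep passes apart", {
  set.seed(77)
  spec <- synth_spec(n_groups = 8, min_size = 2, max_size = 20,
                     vocab_size = 2000, template_length = 22,
                     mutation_rate = 0.1, n_singletons = 12, seed = 77)
  corp <- generate_corpus(spec)
  docs <- preprocess(corp$messages, tokenizer_whitespace(), character(),
                     min_tokens = 20, keep = "none")
  h1 <- hybrid_cluster(docs, u = 0.6, seed = 42)
  h2 <- hybrid_cluster(docs, u = 0.6, seed = 42)
  expect_identical(as.integer(h1), as.integer(h2))
  # conservation: one label per doc, no sentinel remains
  expect_equal(length(h1), nrow(docs))
  expect_true(all(as.integer(h1) >= 0))
  # pass-2 labels never collide with pass-1 labels
  p <- attr(h1, "pass")
  if (any(p == 2L)) {
    expect_length(intersect(as.integer(h1)[p == 1L], as.integer(h1)[p == 2L]), 0)
    expect_gt(min(as.integer(h1)[p == 2L]), max(c(as.integer(h1)[p == 1L], 0L)))
  }
})

test_that("hybrid clustering rejects a train portion that samples < 2 docs", {
  docs <- make_docs(c("a", "b"), c("c", "d"), c("e", "f"))
  expect_error(hybrid_cluster(docs, u = 0.3, seed = 1), "at least 2")
})

test_that("group_table sizes, ordering and exemplars follow the contract", {
  docs <- make_docs(list(c("a", "b", "c"), c("a", "b"), c("z", "q")),
                    ids = c("m1", "m2", "m3"))
  lab <- setNames(c(0L, 0L, 1L), docs$message_id)
  gt <- group_table(lab, docs)
  expect_equal(gt$size, c(2L, 1L))
  expect_equal(sum(gt$size), 3)
  expect_equal(gt$exemplar_id[1], "m1")  # longest member

  expect_equal(nrow(group_table(integer(0))), 0)

  # ties in size are ordered by smallest member id
  lab2 <- setNames(c(1L, 1L, 2L, 2L, 3L), c("m5", "m6", "m1", "m2", "m9"))
  gt2 <- group_table(lab2)
  expect_equal(gt2$group_id, c(2L, 1L, 3L))
})

test_that("assignments round-trip through CSV", {
  docs <- make_docs(c("a", "b"), c("a", "b"), c("c", "d"))
  lab <- hybrid_cluster(docs, u = 1.0, seed = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_assignments(lab, f)
  back <- read_assignments(f)
  expect_equal(as.integer(back), as.integer(lab))
  expect_equal(names(back), names(lab))
  expect_equal(attr(back, "pass"), attr(lab, "pass"))
})
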