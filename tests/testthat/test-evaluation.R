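test_that("candidate-set sampling has the protocol's shape and determinism", {
  kb <- generate_kb(generator_spec(n_syndromes = 10, seed = 1))
  s2 <- sample_candidate_sets(kb, 2, 10, seed = 5)
  s3 <- sample_candidate_sets(kb, 3, 10, seed = 6)
  expect_length(c(s2, s3), 20L)
  expect_true(all(vapply(s2, function(s) length(unique(s)) == 2L, logical(1))))
  expect_true(all(vapply(s3, function(s) length(unique(s)) == 3L, logical(1))))
  # size |H| returns the full base every time
  full <- sample_candidate_sets(kb, 10, 3, seed = 1)
  expect_true(all(vapply(full, function(s) setequal(s, names(kb$syndromes)),
                         logical(1))))
  expect_error(sample_candidate_sets(kb, 11, 1, seed = 1), "outside")
  # reproducibility over seed pairs
  for (seed in 1:20) {
    expect_identical(sample_candidate_sets(kb, 2, 5, seed = seed),
                     sample_candidate_sets(kb, 2, 5, seed = seed))
  }
  a <- sample_candidate_sets(kb, 2, 10, seed = 1)
  b <- sample_candidate_sets(kb, 2, 10, seed = 2)
  expect_false(identical(a, b))
})

test_that("the two-syndrome worked example generates three questions", {
  kb <- fixture_table2()
  rep <- run_protocol(kb, protocol_config(set_sizes = 2, sets_per_size = 1,
                                          seed = 1))
  expect_identical(nrow(rep$per_set), 1L)
  expect_identical(rep$per_set$question_count, 3L)
})

test_that("total overlap collapses every consultation to one question", {
  # all syndromes share one identical single-symptom question
  q <- kb_question(1, "q?", "cold-and-heat", list(
    kb_answer("A1", "a", next_syndrome = "s1"),
    kb_answer("A2", "b", next_syndrome = "s2"),
    kb_answer("A3", "c", next_syndrome = "s3")))
  kb <- inquiry_kb(list(q), list(
    kb_syndrome("s1", data.frame(question = 1, answer = "A1")),
    kb_syndrome("s2", data.frame(question = 1, answer = "A2")),
    kb_syndrome("s3", data.frame(question = 1, answer = "A3"))))
  rep <- run_protocol(kb, protocol_config(set_sizes = c(2, 3),
                                          sets_per_size = 5, seed = 2))
  expect_true(all(rep$per_set$question_count == 1L))
  expect_equal(unname(rep$avg_questions_by_size), c(1, 1))
})

test_that("question counts respect the union bounds", {
  for (seed in 1:10) {
    kb <- make_random_kb(seed)
    cfg <- protocol_config(set_sizes = 2, sets_per_size = 5, seed = seed)
    rep <- run_protocol(kb, cfg)
    for (i in seq_len(nrow(rep$per_set))) {
      members <- strsplit(rep$per_set$candidates[i], "; ", fixed = TRUE)[[1]]
      lens <- vapply(members, function(n)
        nrow(syndrome_symptoms(kb, n)), integer(1))
      qc <- rep$per_set$question_count[i]
      expect_lte(qc, sum(lens))   # dedup can only shrink
      expect_gte(qc, max(lens))   # never below the longest member
    }
  }
})

test_that("with fixed-length disjoint syndromes, average questions grow with set size", {
  kb <- generate_kb(generator_spec(n_syndromes = 8, n_categories = 13,
                                   questions_per_category = 3,
                                   symptoms_per_syndrome = c(3, 3),
                                   overlap = 0, seed = 9))
  rep <- run_protocol(kb, protocol_config(set_sizes = c(1, 2, 3),
                                          sets_per_size = 4, seed = 9))
  avg <- rep$avg_questions_by_size
  expect_equal(unname(avg), c(3, 6, 9))  # disjoint unions add exactly
})

test_that("the protocol report is a pure function of kb and config", {
  kb <- generate_kb(generator_spec(n_syndromes = 8, seed = 4))
  cfg <- protocol_config(seed = 17, policy = "oracle")
  r1 <- run_protocol(kb, cfg)
  r2 <- run_protocol(kb, cfg)
  expect_identical(r1$per_set, r2$per_set)
  expect_identical(r1$avg_questions_by_size, r2$avg_questions_by_size)
  expect_identical(r1$recovery_rate, r2$recovery_rate)
})

test_that("oracle consultations on generated bases always recover the truth", {
  for (seed in c(42, 7, 19)) {
    kb <- generate_kb(generator_spec(seed = seed))
    expect_true(pairwise_non_subset(kb))
    rep <- run_protocol(kb, protocol_config(policy = "oracle", seed = seed))
    expect_identical(rep$recovery_rate, 1)
    expect_true(all(rep$per_set$primary == rep$per_set$truth))
  }
})

test_that("the trim mean drops one extreme at each end", {
  expect_equal(trim_mean(c(1, 3, 3, 3, 10)), 3)
  expect_equal(trim_mean(c(5, 1, 9)), 5)
  expect_warning(mn <- trim_mean(c(1, 2)), "at least 3")
  expect_true(is.na(mn))
})
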