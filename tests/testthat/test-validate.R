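test_that("the worked-example knowledge bases validate cleanly", {
  expect_identical(nrow(validate_kb(fixture_table1(), strict = TRUE)), 0L)
  expect_identical(nrow(validate_kb(fixture_table2(), strict = TRUE)), 0L)
})

test_that("a dangling syndrome reference is reported with every offender listed", {
  kb <- fixture_table1()
  kb$syndromes[["Yang deficiency"]] <- NULL
  rep <- validate_kb(kb)
  expect_true("DANGLING_NEXT" %in% rep$code)
  expect_true(any(grepl("Yang deficiency", rep$message)))
  expect_false(kb_is_valid(rep))
})

test_that("category/id monotonicity is a warning by default, an error in strict mode", {
  q1 <- kb_question(1, "sleep q", "sleep",
                    list(kb_answer("A1", "x", next_syndrome = "s")))
  q2 <- kb_question(2, "pain q", "pain",
                    list(kb_answer("A2", "y", next_syndrome = "t")))
  kb <- inquiry_kb(list(q1, q2), list(
    kb_syndrome("s", data.frame(question = 1, answer = "A1")),
    kb_syndrome("t", data.frame(question = 2, answer = "A2"))))
  rep <- validate_kb(kb)
  expect_identical(rep$code, "CATEGORY_ORDER")
  expect_identical(rep$severity, "warning")
  expect_true(kb_is_valid(rep))
  rep_s <- validate_kb(kb, strict = TRUE)
  expect_identical(rep_s$severity, "error")
  expect_false(kb_is_valid(rep_s))
})

test_that("single-defect mutations are each flagged at the mutated element", {
  # defect-injection harness: one mutation per KB, cycling three defect kinds
  for (seed in 1:51) {
    kb <- make_random_kb(seed)
    kind <- c("deleted_syndrome", "backward_next", "broken_terminal")[(seed %% 3) + 1]
    set.seed(seed)
    if (kind == "deleted_syndrome") {
      victim <- sample(names(kb$syndromes), 1)
      kb$syndromes[[victim]] <- NULL
      rep <- validate_kb(kb)
      expect_false(kb_is_valid(rep))
      expect_true(any(rep$code == "DANGLING_NEXT" &
                        grepl(victim, rep$message, fixed = TRUE)),
                  info = sprintf("seed %d", seed))
    } else if (kind == "backward_next") {
      # redirect one forward pointer back onto its own question
      qids <- as.integer(names(kb$questions))
      hit <- FALSE
      for (q in qids) {
        for (j in seq_along(kb$questions[[as.character(q)]]$answers)) {
          a <- kb$questions[[as.character(q)]]$answers[[j]]
          if (!hit && !is.null(a$next_question)) {
            kb$questions[[as.character(q)]]$answers[[j]]$next_question <- q
            hit <- TRUE
            el <- sprintf("question %d/answer %s", q, a$id)
          }
        }
      }
      expect_true(hit)
      rep <- validate_kb(kb)
      expect_true(any(rep$code == "CYCLE" & rep$element == el),
                  info = sprintf("seed %d", seed))
    } else {
      # point a syndrome's terminal answer at a different syndrome
      stopifnot(length(kb$syndromes) >= 2)
      victim <- sample(names(kb$syndromes), 1)
      other <- setdiff(names(kb$syndromes), victim)[1]
      sym <- kb$syndromes[[victim]]$symptoms
      last_q <- as.character(sym$question[nrow(sym)])
      for (j in seq_along(kb$questions[[last_q]]$answers)) {
        a <- kb$questions[[last_q]]$answers[[j]]
        if (identical(a$next_syndrome, victim) &&
            a$id == sym$answer[nrow(sym)]) {
          kb$questions[[last_q]]$answers[[j]]$next_syndrome <- other
        }
      }
      rep <- validate_kb(kb)
      expect_true(any(rep$code == "NO_TERMINAL" &
                        grepl(victim, rep$element, fixed = TRUE)),
                  info = sprintf("seed %d", seed))
    }
  }
})

test_that("unmutated random knowledge bases yield empty strict reports", {
  for (seed in 1:25) {
    rep <- validate_kb(make_random_kb(seed), strict = TRUE)
    expect_true(kb_is_valid(rep), info = sprintf("seed %d", seed))
  }
})

test_that("a shared terminal pair and an unreachable question are reported", {
  q1 <- kb_question(1, "q1", "cold-and-heat",
                    list(kb_answer("A1", "x", next_syndrome = "s")))
  q2 <- kb_question(2, "q2", "cold-and-heat",
                    list(kb_answer("A2", "y", next_syndrome = "s")))
  kb <- inquiry_kb(list(q1, q2), list(
    kb_syndrome("s", data.frame(question = 1, answer = "A1")),
    kb_syndrome("t", data.frame(question = 1, answer = "A1"))))
  rep <- validate_kb(kb)
  # t's "terminal" answer names s, not t
  expect_true(any(rep$code == "NO_TERMINAL" & grepl("'t'", rep$element)))
  # question 2 is used by no syndrome and targeted by no answer
  expect_true(any(rep$code == "UNREACHABLE_QUESTION" &
                    rep$element == "question 2"))
})
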