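#' Worked-example knowledge base: cold-and-heat question chain
#'
#' A three-question excerpt of the question base (fear of cold, fever,
#' duration) in the cold-and-heat category, with two syndromes. The
#' "Pattern of internal and external excess-cold" sequence is the
#' three-symptom chain z1 = (Fear of cold?, Fear of cold),
#' z2 = (Fever?, Fever), z3 = (Does it last long or short?, Short
#' duration). "Yang deficiency" shares the first two symptoms and ends at
#' the long-duration answer; its sequence is a reconstruction (only its
#' terminal answer is given in the source table).
#'
#' @return An `inquiry_kb` with 3 questions (answers A1-A6) and 2
#'   syndromes.
#' @examples
#' kb <- fixture_table1()
#' resolve_symptom_sequence(kb, 1, c("A1", "A3", "A6"))$terminal
#' @export
fixture_table1 <- function() {
  q1 <- kb_question(1, "Fear of cold?", "cold-and-heat", list(
    kb_answer("A1", "Fear of cold", next_question = 2),
    kb_answer("A2", "No fear of cold", next_question = 2)))
  q2 <- kb_question(2, "Fever?", "cold-and-heat", list(
    kb_answer("A3", "Fever", next_question = 3),
    kb_answer("A4", "No fever", next_question = 3)))
  q3 <- kb_question(3, "Does it last long or short?", "cold-and-heat", list(
    kb_answer("A5", "Long duration", next_syndrome = "Yang deficiency"),
    kb_answer("A6", "Short duration",
              next_syndrome = "Pattern of internal and external excess-cold")))
  yang <- kb_syndrome("Yang deficiency", data.frame(
    question = c(1, 2, 3), answer = c("A1", "A3", "A5")))
  cold <- kb_syndrome("Pattern of internal and external excess-cold", data.frame(
    question = c(1, 2, 3), answer = c("A1", "A3", "A6")))
  inquiry_kb(list(q1, q2, q3), list(yang, cold))
}

#' Worked-example knowledge base: pain questions and two waist/back syndromes
#'
#' The three pain-category questions of the worked rating example — body
#' pain location (nine answers), waist pain quality (six answers), back
#' pain quality (three answers) — together with the two candidate
#' syndromes they discriminate. The symptom sequences are minimal
#' reconstructions consistent with the printed questions and outcome:
#' "syndrome of cold and dampness invading the waist" = (location,
#' Lumbago) then (waist quality, Cold pain and feeling heavy worsens on
#' rainy days); "syndrome of wind and cold and dampness impediment" =
#' (location, Back pain) then (back quality, Fixed or scurrying pain
#' rises when exposed to wind-cold). With the example patient's three
#' symptoms these score 1.0 and 0.5.
#'
#' @return An `inquiry_kb` with 3 questions (answers A1-A18) and 2
#'   syndromes.
#' @examples
#' deduce_qa_list(fixture_table2(), names(fixture_table2()$syndromes))
#' @export
fixture_table2 <- function() {
  waist <- "syndrome of cold and dampness invading the waist"
  imped <- "syndrome of wind and cold and dampness impediment"
  loc <- c("Headache", "Chest pain", "Flank pain", "Stomach duct pain",
           "Lumbago", "Abdominal pain", "Back pain", "Pain in limbs",
           "Body pain")
  q1 <- kb_question(1, "Which part of the body is in pain?", "pain",
    lapply(seq_along(loc), function(i)
      kb_answer(sprintf("A%d", i), loc[i],
                next_question = if (loc[i] == "Back pain") 3 else 2)))
  wq <- c("Frequent soreness", "Cold pain and feeling heavy worsens on rainy days",
          "Stabbing pain", "Pain extending to lower limbs", "Sudden sharp pain",
          "Pain that cannot be tilted")
  q2 <- kb_question(2, "What is the pain in the waist?", "pain",
    lapply(seq_along(wq), function(i) {
      if (i == 2L) kb_answer("A11", wq[i], next_syndrome = waist)
      else kb_answer(sprintf("A%d", 9 + i), wq[i], next_question = 3)
    }))
  bq <- c("Pain that cannot be tilted", "Nape back pain",
          "Fixed or scurrying pain rises when exposed to wind-cold")
  # no forward question exists after q3: the two non-terminal back answers
  # are linked to the clinically nearest syndrome so every chain ends
  q3 <- kb_question(3, "What kind of back pain is it?", "pain", list(
    kb_answer("A16", bq[1], next_syndrome = waist),
    kb_answer("A17", bq[2], next_syndrome = imped),
    kb_answer("A18", bq[3], next_syndrome = imped)))
  s_waist <- kb_syndrome(waist, data.frame(
    question = c(1, 2), answer = c("A5", "A11")))
  s_imped <- kb_syndrome(imped, data.frame(
    question = c(1, 3), answer = c("A7", "A18")))
  inquiry_kb(list(q1, q2, q3), list(s_waist, s_imped))
}

#' The example patient's symptoms for the differentiation worked example
#'
#' Lumbago; cold pain, feeling heavy, worse on rainy days; fixed or
#' scurrying pain rising on exposure to wind-cold — as reported in the
#' differentiation rating example against [fixture_table2()].
#'
#' @return A [patient_record()] with three symptoms.
#' @export
fixture_table3_patient <- function() {
  patient_record(data.frame(question = c(1, 2, 3),
                            answer = c("A5", "A11", "A18")))
}

#' Specification for the synthetic knowledge-base generator
#'
#' @param n_syndromes Number of syndromes.
#' @param n_categories Number of inquiry categories used (first
#'   `n_categories` of the 13, in rank order).
#' @param questions_per_category Questions per category; ids are numbered
#'   sequentially across categories, so strict category/id monotonicity
#'   holds by construction.
#' @param answers_per_question Candidate answers per question (>= 2).
#' @param symptoms_per_syndrome Length-2 integer range for sequence
#'   lengths, drawn uniformly.
#' @param overlap Probability in `[0, 1]` that a symptom's question is
#'   drawn from questions already used by earlier syndromes; 0 makes all
#'   syndromes question-disjoint.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(n_syndromes = 20, n_categories = 13,
                           questions_per_category = 3,
                           answers_per_question = 4,
                           symptoms_per_syndrome = c(2, 6),
                           overlap = 0.3, seed = 1) {
  stopifnot(n_syndromes >= 1, n_categories >= 1, n_categories <= 13,
            questions_per_category >= 1, answers_per_question >= 2,
            length(symptoms_per_syndrome) == 2,
            symptoms_per_syndrome[1] >= 1,
            symptoms_per_syndrome[1] <= symptoms_per_syndrome[2],
            overlap >= 0, overlap <= 1)
  spec <- list(n_syndromes = as.integer(n_syndromes),
               n_categories = as.integer(n_categories),
               questions_per_category = as.integer(questions_per_category),
               answers_per_question = as.integer(answers_per_question),
               symptoms_per_syndrome = as.integer(symptoms_per_syndrome),
               overlap = overlap, seed = as.integer(seed))
  nq <- spec$n_categories * spec$questions_per_category
  if (spec$symptoms_per_syndrome[2] > nq) {
    sdm_stop("infeasible spec: longest sequence (%d) exceeds the %d questions",
             spec$symptoms_per_syndrome[2], nq)
  }
  if (spec$overlap == 0 && spec$n_syndromes * spec$symptoms_per_syndrome[2] > nq) {
    sdm_stop(paste0("infeasible spec: overlap 0 needs up to %d disjoint ",
                    "questions but only %d exist"),
             spec$n_syndromes * spec$symptoms_per_syndrome[2], nq)
  }
  structure(spec, class = "generator_spec")
}

pick_questions <- function(n, all_q, used, overlap) {
  qs <- integer(0)
  for (i in seq_len(n)) {
    shared <- setdiff(used, qs)
    fresh <- setdiff(all_q, union(used, qs))
    pool <- if (length(shared) && stats::runif(1) < overlap) shared
            else if (length(fresh)) fresh else shared
    if (!length(pool)) return(NULL)
    qs <- c(qs, pool[sample.int(length(pool), 1L)])
  }
  sort(qs)
}

#' Generate a random valid inquiry knowledge base
#'
#' Builds a structurally valid synthetic KB emulating the real base's
#' shape: category ranks are assigned first and questions numbered
#' sequentially across ranks (so strict monotonicity holds by
#' construction), every syndrome's sequence ascends with forward next
#' pointers, and each syndrome ends in its own terminal answer. Answers
#' not claimed by any syndrome chain point to the following question, or
#' to a random syndrome at the last question. Output is fully determined
#' by `spec$seed`.
#'
#' @param spec A [generator_spec()] (or arguments for one, via `...`).
#' @param ... Passed to [generator_spec()] when `spec` is missing.
#' @return A valid `inquiry_kb`.
#' @examples
#' kb <- generate_kb(generator_spec(n_syndromes = 5, seed = 42))
#' kb_is_valid(validate_kb(kb, strict = TRUE))
#' @export
generate_kb <- function(spec = NULL, ...) {
  if (is.null(spec)) spec <- generator_spec(...)
  stopifnot(inherits(spec, "generator_spec"))
  with_seed(spec$seed, generate_kb_impl(spec))
}

generate_kb_impl <- function(spec) {
  cats <- inquiry_categories()[seq_len(spec$n_categories)]
  nq <- spec$n_categories * spec$questions_per_category
  category_of <- rep(cats, each = spec$questions_per_category)
  # per-question answer table; next pointers assigned as syndromes claim them
  ans_id <- matrix(sprintf("A%d", seq_len(nq * spec$answers_per_question)),
                   nrow = nq, byrow = TRUE)
  next_q <- matrix(NA_integer_, nrow = nq, ncol = spec$answers_per_question)
  next_s <- matrix(NA_character_, nrow = nq, ncol = spec$answers_per_question)
  claimed <- matrix(FALSE, nrow = nq, ncol = spec$answers_per_question)

  used_q <- integer(0)
  syndromes <- list()
  for (s in seq_len(spec$n_syndromes)) {
    name <- sprintf("syndrome-%03d", s)
    lens <- seq(spec$symptoms_per_syndrome[1], spec$symptoms_per_syndrome[2])
    L <- lens[sample.int(length(lens), 1L)]
    done <- FALSE
    for (attempt in seq_len(100L)) {
      qs <- pick_questions(L, seq_len(nq), used_q, spec$overlap)
      if (is.null(qs)) next
      # plan: slot j used at question qs[i]; reuse an identical chain link
      # when one exists, otherwise claim a free answer slot
      plan <- integer(L); ok <- TRUE
      taken <- claimed
      for (i in seq_len(L)) {
        q <- qs[i]
        if (i < L) {
          hit <- which(taken[q, ] & next_q[q, ] == qs[i + 1L])
          free <- which(!taken[q, ])
          if (length(hit)) plan[i] <- hit[1L]
          else if (length(free)) { plan[i] <- free[1L]; taken[q, free[1L]] <- TRUE }
          else { ok <- FALSE; break }
        } else {
          free <- which(!taken[q, ])
          if (length(free)) { plan[i] <- free[1L]; taken[q, free[1L]] <- TRUE }
          else { ok <- FALSE; break }
        }
      }
      if (!ok) next
      for (i in seq_len(L)) {
        q <- qs[i]; j <- plan[i]
        if (!claimed[q, j]) {
          claimed[q, j] <- TRUE
          if (i < L) next_q[q, j] <- qs[i + 1L] else next_s[q, j] <- name
        }
      }
      syndromes[[s]] <- kb_syndrome(name, data.frame(
        question = qs, answer = ans_id[cbind(qs, plan)],
        stringsAsFactors = FALSE))
      used_q <- union(used_q, qs)
      done <- TRUE
      break
    }
    if (!done) {
      sdm_stop(paste0("generation infeasible: could not place syndrome %d of %d ",
                      "(answers per question %d, overlap %.2f leave no free ",
                      "terminal slot)"), s, spec$n_syndromes,
               spec$answers_per_question, spec$overlap)
    }
  }
  # defaults for unclaimed answers: forward to the next question, or to a
  # random syndrome from the last question
  snames <- vapply(syndromes, function(x) x$name, character(1))
  for (q in seq_len(nq)) for (j in seq_len(spec$answers_per_question)) {
    if (!claimed[q, j]) {
      if (q < nq) next_q[q, j] <- q + 1L
      else next_s[q, j] <- snames[sample.int(length(snames), 1L)]
    }
  }
  questions <- lapply(seq_len(nq), function(q) {
    kb_question(q, sprintf("Synthetic question %d about %s?", q, category_of[q]),
                category_of[q],
                lapply(seq_len(spec$answers_per_question), function(j) {
                  kb_answer(ans_id[q, j], sprintf("Synthetic answer %s", ans_id[q, j]),
                            next_question = if (!is.na(next_q[q, j])) next_q[q, j],
                            next_syndrome = if (!is.na(next_s[q, j])) next_s[q, j])
                }))
  })
  inquiry_kb(questions, syndromes)
}
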