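#' The thirteen inquiry categories in Ten-Brief-Inquiries order
#'
#' The classical "Ten Brief Inquiries" mnemonic fixes the content and order
#' of a TCM consultation. Question-answer pairs in the knowledge base are
#' grouped into thirteen topic categories whose order follows that mnemonic:
#' cold and heat first, then sweat, then pain, and so on. Question ids are
#' numbered sequentially across categories so that the global id order
#' encodes the consultation order.
#'
#' @return Character vector of the 13 category names, in rank order
#'   (rank 1 = asked first).
#' @examples
#' inquiry_categories()
#' @export
inquiry_categories <- function() {
  c("cold-and-heat", "sweat", "pain", "taste", "ears", "eyes", "chest",
    "hypochondrium", "stomach-and-abdomen", "sleep", "thirst", "appetite",
    "stool-and-urine")
}

#' Rank of an inquiry category
#'
#' @param category Character vector of category names.
#' @return Integer ranks in 1..13 (NA for unknown names).
#' @export
category_rank <- function(category) {
  match(category, inquiry_categories())
}

# Text fields are trimmed and marked UTF-8. A true Unicode NFC pass would
# need ICU (stringi), which is not available here; inputs are assumed NFC.
norm_text <- function(x) {
  if (is.null(x)) return(NULL)
  trimws(enc2utf8(as.character(x)))
}

sdm_stop <- function(fmt, ..., class = "sdm_error") {
  stop(structure(class = unique(c(class, "sdm_error", "error", "condition")),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

#' Construct a candidate answer
#'
#' Every answer carries exactly one "next" pointer: either the id of the
#' question to ask next (`next_question`), or the name of the syndrome this
#' question-answer pair terminates (`next_syndrome`). The terminal link is
#' the reverse index from question-answer pairs back to syndromes.
#'
#' @param id Answer id, a string such as `"A3"`; globally unique in the KB.
#' @param text Answer phrase shown to the patient.
#' @param next_question Integer id of the following question, or `NULL`.
#' @param next_syndrome Name of the terminated syndrome, or `NULL`.
#' @return A list of class `kb_answer`.
#' @export
kb_answer <- function(id, text, next_question = NULL, next_syndrome = NULL) {
  if (is.null(next_question) == is.null(next_syndrome)) {
    sdm_stop("answer '%s': exactly one of next_question/next_syndrome must be given", id)
  }
  structure(list(
    id = norm_text(id),
    text = norm_text(text),
    next_question = if (!is.null(next_question)) as.integer(next_question),
    next_syndrome = norm_text(next_syndrome)
  ), class = "kb_answer")
}

#' Construct a question
#'
#' @param id Positive integer id, globally unique and globally ordered
#'   (ids encode the Ten-Brief-Inquiries consultation order).
#' @param text Question phrase.
#' @param category One of [inquiry_categories()].
#' @param answers List of [kb_answer()] objects (the candidate answers the
#'   patient chooses from); non-empty.
#' @return A list of class `kb_question`.
#' @export
kb_question <- function(id, text, category, answers) {
  id <- as.integer(id)
  if (is.na(id) || id < 1L) sdm_stop("question id must be a positive integer")
  category <- norm_text(category)
  if (!category %in% inquiry_categories()) {
    sdm_stop("question %d: unknown category '%s'", id, category)
  }
  if (length(answers) == 0L) sdm_stop("question %d: needs at least one answer", id)
  structure(list(
    id = id,
    text = norm_text(text),
    category = category,
    answers = answers
  ), class = "kb_question")
}

#' Construct a syndrome
#'
#' A syndrome h is an ordered sequence of symptoms z_i = (question, answer),
#' ascending in question id; the final pair's answer must name the syndrome
#' as its `next_syndrome` (the terminal link).
#'
#' @param name Unique syndrome name (matched case-sensitively).
#' @param symptoms A data.frame with integer column `question` and character
#'   column `answer`, one row per symptom, in inquiry order.
#' @return A list of class `kb_syndrome`.
#' @export
kb_syndrome <- function(name, symptoms) {
  symptoms <- as.data.frame(symptoms)
  if (nrow(symptoms) == 0L) sdm_stop("syndrome '%s': symptom sequence is empty", name)
  symptoms$question <- as.integer(symptoms$question)
  symptoms$answer <- norm_text(symptoms$answer)
  rownames(symptoms) <- NULL
  structure(list(name = norm_text(name), symptoms = symptoms[, c("question", "answer")]),
            class = "kb_syndrome")
}

#' Assemble an inquiry knowledge base
#'
#' The inquiry knowledge base is D = H u Q: the syndrome base H (named
#' symptom sequences) plus the question base Q (ordered questions with
#' candidate answers and next pointers). Construction performs no deep
#' validation; run [validate_kb()] for the full invariant check.
#'
#' @param questions List of [kb_question()] objects.
#' @param syndromes List of [kb_syndrome()] objects (may be empty).
#' @param schema_version Serialization schema version string.
#' @return An object of class `inquiry_kb` with components `questions`
#'   (named by id), `syndromes` (named by name) and `schema_version`.
#' @examples
#' kb <- fixture_table1()
#' kb
#' @export
inquiry_kb <- function(questions, syndromes = list(), schema_version = "1") {
  qids <- vapply(questions, function(q) q$id, integer(1))
  if (anyDuplicated(qids)) sdm_stop("duplicate question ids: %s",
                                    paste(unique(qids[duplicated(qids)]), collapse = ", "))
  questions <- questions[order(qids)]
  names(questions) <- as.character(sort(qids))
  snames <- vapply(syndromes, function(s) s$name, character(1))
  if (anyDuplicated(snames)) sdm_stop("duplicate syndrome names: %s",
                                      paste(unique(snames[duplicated(snames)]), collapse = ", "))
  syndromes <- syndromes[order(snames, method = "radix")]
  names(syndromes) <- sort(snames, method = "radix")
  structure(list(schema_version = as.character(schema_version),
                 questions = questions, syndromes = syndromes),
            class = "inquiry_kb")
}

#' @export
print.inquiry_kb <- function(x, ...) {
  nq <- length(x$questions)
  na <- sum(vapply(x$questions, function(q) length(q$answers), integer(1)))
  cats <- unique(vapply(x$questions, function(q) q$category, character(1)))
  cats <- cats[order(category_rank(cats))]
  cat(sprintf("Inquiry knowledge base (schema %s)\n", x$schema_version))
  cat(sprintf("  questions: %d (%d answers) in %d categor%s\n",
              nq, na, length(cats), if (length(cats) == 1L) "y" else "ies"))
  if (length(cats)) cat("  categories:", paste(cats, collapse = ", "), "\n")
  cat(sprintf("  syndromes: %d\n", length(x$syndromes)))
  invisible(x)
}

kb_get_question <- function(kb, id) kb$questions[[as.character(as.integer(id))]]

kb_find_answer <- function(question, answer_id) {
  for (a in question$answers) if (a$id == answer_id) return(a)
  NULL
}

#' Symptom sequence of a syndrome
#'
#' @param kb An `inquiry_kb`.
#' @param name Syndrome name.
#' @return The syndrome's symptom data.frame (`question`, `answer`).
#' @export
syndrome_symptoms <- function(kb, name) {
  s <- kb$syndromes[[name]]
  if (is.null(s)) sdm_stop("unknown syndrome: '%s'", name, class = "sdm_lookup_error")
  s$symptoms
}

#' Follow a chain of answers through the question base
#'
#' Replays an inquiry: starting from `start_question`, each supplied answer
#' selects one candidate answer of the current question, emits the symptom
#' (question, answer), and moves to that answer's next question. The walk
#' ends when the answers are exhausted or a terminal (syndrome-naming)
#' answer is reached. Because next pointers are forward-only, every chain
#' terminates.
#'
#' @param kb An `inquiry_kb`.
#' @param start_question Integer id of the first question.
#' @param answers Character vector of answer ids, one per step.
#' @return List with `symptoms` (data.frame `question`, `answer`) and
#'   `terminal` (syndrome name, or `NULL` if the chain stopped on a
#'   question-reference next).
#' @examples
#' kb <- fixture_table1()
#' resolve_symptom_sequence(kb, 1, c("A1", "A3", "A6"))
#' @export
resolve_symptom_sequence <- function(kb, start_question, answers) {
  cur <- as.integer(start_question)
  if (is.null(kb_get_question(kb, cur))) {
    sdm_stop("start question %d not in the question base", cur, class = "sdm_lookup_error")
  }
  out_q <- integer(0); out_a <- character(0); terminal <- NULL
  for (i in seq_along(answers)) {
    if (is.na(cur)) {
      sdm_stop("step %d: previous answer was terminal, no question to answer", i,
               class = "sdm_traversal_error")
    }
    q <- kb_get_question(kb, cur)
    if (is.null(q)) {
      sdm_stop("step %d: question %d not in the question base", i, cur,
               class = "sdm_traversal_error")
    }
    a <- kb_find_answer(q, answers[[i]])
    if (is.null(a)) {
      sdm_stop("step %d: answer '%s' is not a candidate answer of question %d",
               i, answers[[i]], cur, class = "sdm_traversal_error")
    }
    out_q <- c(out_q, cur); out_a <- c(out_a, a$id)
    if (!is.null(a$next_syndrome)) {
      terminal <- a$next_syndrome
      cur <- NA_integer_
    } else {
      cur <- a$next_question
    }
  }
  list(symptoms = data.frame(question = out_q, answer = out_a,
                             stringsAsFactors = FALSE),
       terminal = terminal)
}
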