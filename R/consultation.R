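#' Patient record
#'
#' The outcome of a consultation: at most one reported symptom per
#' question, plus the set of questions the patient answered "none" to
#' (a "none" contributes no symptom and never counts against a
#' candidate syndrome).
#'
#' @param symptoms Either a data.frame with columns `question`, `answer`,
#'   or a named character vector (names = question ids, values = answer
#'   ids).
#' @param skipped Integer vector of question ids answered "none".
#' @return An object of class `patient_record` with `symptoms` (a named
#'   character vector, names = question ids) and `skipped`.
#' @export
patient_record <- function(symptoms = character(0), skipped = integer(0)) {
  if (is.data.frame(symptoms)) {
    symptoms <- stats::setNames(as.character(symptoms$answer),
                                as.character(as.integer(symptoms$question)))
  } else {
    symptoms <- stats::setNames(as.character(symptoms),
                                as.character(as.integer(names(symptoms))))
  }
  if (anyDuplicated(names(symptoms))) {
    sdm_stop("patient record: more than one symptom for question(s) %s",
             paste(unique(names(symptoms)[duplicated(names(symptoms))]), collapse = ", "))
  }
  skipped <- sort(unique(as.integer(skipped)))
  if (any(as.character(skipped) %in% names(symptoms))) {
    sdm_stop("patient record: a question cannot be both answered and skipped")
  }
  structure(list(symptoms = symptoms[order(as.integer(names(symptoms)))],
                 skipped = skipped),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("Patient record: %d symptom(s), %d question(s) answered 'none'\n",
              length(x$symptoms), length(x$skipped)))
  for (q in names(x$symptoms)) cat(sprintf("  question %s -> %s\n", q, x$symptoms[[q]]))
  invisible(x)
}

new_policy <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = c(paste0("policy_", kind),
                                                       "answer_policy"))
}

#' Answer policies for simulated or scripted consultations
#'
#' `answer_scripted()` replays a fixed map from question id to answer id
#' (or `"none"`); `answer_random()` draws one answer uniformly from each
#' question's candidate answers, imitating a patient in the simulation
#' protocol; `answer_oracle()` answers as a patient who truly has the
#' `truth` syndrome — the planted answer for questions in the syndrome's
#' symptom sequence, `"none"` elsewhere; `answer_interactive()` prompts on
#' the console.
#'
#' @param script Named list/vector mapping question id to answer id or
#'   `"none"`.
#' @param seed Integer seed making the random policy reproducible, or
#'   `NULL` to consume the caller's RNG stream (used inside
#'   [run_protocol()]).
#' @param none_prob Probability that the random policy answers `"none"`
#'   instead of drawing an answer (the published protocol never answers
#'   "none"; default 0).
#' @param truth Name of the planted true syndrome for the oracle policy.
#' @return An `answer_policy` object.
#' @name answer_policies
NULL

#' @rdname answer_policies
#' @export
answer_scripted <- function(script) {
  if (is.null(names(script)) || any(!nzchar(names(script)))) {
    sdm_stop("scripted policy: script must be named by question id",
             class = "sdm_policy_error")
  }
  new_policy("scripted", script = as.list(script))
}

#' @rdname answer_policies
#' @export
answer_random <- function(seed = NULL, none_prob = 0) {
  stopifnot(none_prob >= 0, none_prob <= 1)
  new_policy("random", seed = seed, none_prob = none_prob)
}

#' @rdname answer_policies
#' @export
answer_oracle <- function(truth) {
  new_policy("oracle", truth = norm_text(truth))
}

#' @rdname answer_policies
#' @export
answer_interactive <- function() {
  new_policy("interactive")
}

policy_answer <- function(policy, item, kb) UseMethod("policy_answer")

#' @export
policy_answer.policy_scripted <- function(policy, item, kb) {
  key <- as.character(item$question)
  if (is.null(policy$script[[key]])) {
    sdm_stop("scripted policy: no answer for question %s", key,
             class = "sdm_policy_error")
  }
  as.character(policy$script[[key]])
}

#' @export
policy_answer.policy_random <- function(policy, item, kb) {
  if (policy$none_prob > 0 && stats::runif(1) < policy$none_prob) return("none")
  ids <- vapply(item$answers, function(a) a$id, character(1))
  ids[[sample.int(length(ids), 1L)]]
}

#' @export
policy_answer.policy_oracle <- function(policy, item, kb) {
  sym <- syndrome_symptoms(kb, policy$truth)
  i <- match(item$question, sym$question)
  if (is.na(i)) "none" else sym$answer[i]
}

#' @export
policy_answer.policy_interactive <- function(policy, item, kb) {
  if (!interactive()) {
    sdm_stop("interactive policy requires an interactive session",
             class = "sdm_policy_error")
  }
  repeat {
    cat(sprintf("[%d] %s\n", item$question, item$text))
    for (a in item$answers) cat(sprintf("  %s  %s\n", a$id, a$text))
    ans <- trimws(readline("answer id (or 'none'): "))
    if (ans == "none" || ans %in% vapply(item$answers, `[[`, character(1), "id")) {
      return(ans)
    }
    cat("not a candidate answer, try again\n")
  }
}

# evaluate code under a local RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Run a consultation over a Q&A list
#'
#' Step 2 of the inquiry reasoning model: the questions of the Q&A list
#' are presented strictly in list order; for each, the policy supplies one
#' answer id from the question's candidate answers (or `"none"`), and the
#' chosen (question, answer) pair is recorded as a symptom. Every
#' completed consultation satisfies
#' `length(symptoms) + length(skipped) == length(qalist)`.
#'
#' @param kb An `inquiry_kb`.
#' @param qalist A `qa_list` from [deduce_qa_list()].
#' @param policy An [answer_policies] object.
#' @return A [patient_record()].
#' @examples
#' kb <- fixture_table2()
#' qa <- deduce_qa_list(kb, names(kb$syndromes))
#' run_consultation(kb, qa, answer_random(seed = 1))
#' @export
run_consultation <- function(kb, qalist, policy) {
  stopifnot(inherits(qalist, "qa_list"), inherits(policy, "answer_policy"))
  run <- function() {
    sy <- character(0); sk <- integer(0)
    for (item in qalist$items) {
      ans <- policy_answer(policy, item, kb)
      if (identical(ans, "none")) {
        sk <- c(sk, item$question)
      } else {
        ids <- vapply(item$answers, function(a) a$id, character(1))
        if (!ans %in% ids) {
          sdm_stop("question %d: '%s' is not a candidate answer",
                   item$question, ans, class = "sdm_policy_error")
        }
        sy[[as.character(item$question)]] <- ans
      }
    }
    patient_record(sy, sk)
  }
  if (identical(policy$kind, "random") && !is.null(policy$seed)) {
    with_seed(policy$seed, run())
  } else {
    run()
  }
}
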