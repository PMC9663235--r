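finding <- function(code, severity, element, message) {
  data.frame(code = code, severity = severity, element = element,
             message = message, stringsAsFactors = FALSE)
}

#' Validate an inquiry knowledge base
#'
#' Checks the structural invariants of D = H u Q and returns a report of
#' coded findings rather than raising errors. An empty report means the KB
#' is internally consistent: ids unique, every next pointer resolves, next
#' pointers are forward-only (which rules out cycles and guarantees that
#' every consultation terminates), every syndrome has a non-empty ascending
#' symptom sequence whose last pair carries the syndrome's name as its
#' terminal link, and no question-answer pair is the terminal of two
#' syndromes.
#'
#' Finding codes: `DUPLICATE_ID`, `DANGLING_NEXT`, `CYCLE` (a backward or
#' self next pointer, the precondition for a cycle), `DANGLING_SYMPTOM`,
#' `BAD_SEQUENCE`, `NO_TERMINAL`, `UNREACHABLE_QUESTION` (warning: a
#' question no syndrome uses and no answer points to), and
#' `CATEGORY_ORDER` (question ids not monotone with category rank —
#' a warning by default, an error under `strict`).
#'
#' @param kb An `inquiry_kb`.
#' @param strict If `TRUE`, category/id monotonicity violations are
#'   errors instead of warnings.
#' @return A data.frame of class `kb_validation` with columns `code`,
#'   `severity` (`"error"` or `"warning"`), `element`, `message`;
#'   zero rows when every invariant holds.
#' @examples
#' validate_kb(fixture_table1())
#' @export
validate_kb <- function(kb, strict = FALSE) {
  f <- list()
  qids <- vapply(kb$questions, function(q) q$id, integer(1))

  # global answer-id uniqueness
  aids <- unlist(lapply(kb$questions, function(q)
    vapply(q$answers, function(a) a$id, character(1))))
  dup <- unique(aids[duplicated(aids)])
  for (d in dup) {
    f[[length(f) + 1L]] <- finding("DUPLICATE_ID", "error", d,
                                   sprintf("answer id '%s' is not globally unique", d))
  }

  # per-answer next pointers
  targeted <- integer(0)
  for (q in kb$questions) {
    for (a in q$answers) {
      if (!is.null(a$next_question)) {
        targeted <- c(targeted, a$next_question)
        if (!a$next_question %in% qids) {
          f[[length(f) + 1L]] <- finding("DANGLING_NEXT", "error",
            sprintf("question %d/answer %s", q$id, a$id),
            sprintf("next question %d does not exist", a$next_question))
        } else if (a$next_question <= q$id) {
          f[[length(f) + 1L]] <- finding("CYCLE", "error",
            sprintf("question %d/answer %s", q$id, a$id),
            sprintf("next question %d is not strictly forward of %d",
                    a$next_question, q$id))
        }
      } else if (!is.null(a$next_syndrome)) {
        if (!a$next_syndrome %in% names(kb$syndromes)) {
          f[[length(f) + 1L]] <- finding("DANGLING_NEXT", "error",
            sprintf("question %d/answer %s", q$id, a$id),
            sprintf("next syndrome '%s' does not exist", a$next_syndrome))
        }
      }
    }
  }

  # syndrome sequences
  terminal_of <- character(0)  # "q/a" -> syndrome name
  for (s in kb$syndromes) {
    sym <- s$symptoms
    el <- sprintf("syndrome '%s'", s$name)
    if (anyDuplicated(sym$question)) {
      f[[length(f) + 1L]] <- finding("BAD_SEQUENCE", "error", el,
        "two symptoms share a question id")
    }
    if (is.unsorted(sym$question, strictly = TRUE)) {
      f[[length(f) + 1L]] <- finding("BAD_SEQUENCE", "error", el,
        "symptom sequence is not in ascending question-id order")
    }
    ok_refs <- TRUE
    for (i in seq_len(nrow(sym))) {
      q <- kb_get_question(kb, sym$question[i])
      if (is.null(q)) {
        f[[length(f) + 1L]] <- finding("DANGLING_SYMPTOM", "error", el,
          sprintf("symptom %d refers to missing question %d", i, sym$question[i]))
        ok_refs <- FALSE
      } else if (is.null(kb_find_answer(q, sym$answer[i]))) {
        f[[length(f) + 1L]] <- finding("DANGLING_SYMPTOM", "error", el,
          sprintf("symptom %d refers to missing answer '%s' of question %d",
                  i, sym$answer[i], sym$question[i]))
        ok_refs <- FALSE
      }
    }
    if (ok_refs) {
      last <- nrow(sym)
      q <- kb_get_question(kb, sym$question[last])
      a <- kb_find_answer(q, sym$answer[last])
      if (is.null(a$next_syndrome) || a$next_syndrome != s$name) {
        f[[length(f) + 1L]] <- finding("NO_TERMINAL", "error", el,
          sprintf("last pair (%d, %s) does not carry the syndrome's name as its next",
                  sym$question[last], sym$answer[last]))
      } else {
        key <- sprintf("%d/%s", sym$question[last], sym$answer[last])
        if (key %in% names(terminal_of)) {
          f[[length(f) + 1L]] <- finding("NO_TERMINAL", "error", el,
            sprintf("terminal pair %s is shared with syndrome '%s'",
                    key, terminal_of[[key]]))
        }
        terminal_of[key] <- s$name
      }
      # non-terminal pairs must chain to the next symptom's question
      if (last > 1L) for (i in seq_len(last - 1L)) {
        q <- kb_get_question(kb, sym$question[i])
        a <- kb_find_answer(q, sym$answer[i])
        if (is.null(a$next_question) || a$next_question != sym$question[i + 1L]) {
          f[[length(f) + 1L]] <- finding("BAD_SEQUENCE", "error", el,
            sprintf("answer '%s' of question %d does not chain to question %d",
                    sym$answer[i], sym$question[i], sym$question[i + 1L]))
        }
      }
    }
  }

  # reachability (advisory): a question is reachable if some syndrome uses
  # it or some answer points to it
  used <- unique(unlist(lapply(kb$syndromes, function(s) s$symptoms$question)))
  for (q in kb$questions) {
    if (!q$id %in% used && !q$id %in% targeted) {
      f[[length(f) + 1L]] <- finding("UNREACHABLE_QUESTION", "warning",
        sprintf("question %d", q$id),
        "no syndrome uses this question and no answer points to it")
    }
  }

  # category/id monotonicity: all ids in a lower-ranked category must be
  # smaller than all ids in a higher-ranked category
  ranks <- category_rank(vapply(kb$questions, function(q) q$category, character(1)))
  if (length(qids) > 1L) {
    ord <- order(qids)
    r <- ranks[ord]
    if (is.unsorted(r)) {
      bad <- qids[ord][which(diff(r) < 0)[1] + 1L]
      f[[length(f) + 1L]] <- finding("CATEGORY_ORDER",
        if (strict) "error" else "warning",
        sprintf("question %d", bad),
        "question ids are not monotone with Ten-Brief-Inquiries category rank")
    }
  }

  rep <- if (length(f)) do.call(rbind, f) else
    finding(character(0), character(0), character(0), character(0))
  rownames(rep) <- NULL
  class(rep) <- c("kb_validation", "data.frame")
  rep
}

#' Does a validation report contain any errors?
#'
#' @param report A `kb_validation` report from [validate_kb()].
#' @return `TRUE` when no error-severity finding is present.
#' @export
kb_is_valid <- function(report) {
  !any(report$severity == "error")
}

#' @export
print.kb_validation <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("Knowledge base valid: no findings.\n")
  } else {
    cat(sprintf("%d finding(s) (%d error, %d warning):\n", nrow(x),
                sum(x$severity == "error"), sum(x$severity == "warning")))
    for (i in seq_len(nrow(x))) {
      cat(sprintf("  [%s] %s %s: %s\n", x$severity[i], x$code[i],
                  x$element[i], x$message[i]))
    }
  }
  invisible(x)
}
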