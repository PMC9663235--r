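#' Deduce the ordered question-and-answer list for candidate syndromes
#'
#' Step 1 of the inquiry reasoning model: for each candidate syndrome the
#' syndrome base is searched for its symptoms, the corresponding questions
#' are retrieved from the question base together with their full
#' candidate-answer lists, duplicates are removed, and the items are
#' ordered by ascending question id — which, by construction of the ids,
#' is Ten-Brief-Inquiries category order.
#'
#' The operation is a pure set union: it is idempotent in duplicate
#' candidate names, invariant to candidate order, and monotone (adding a
#' candidate never removes an item).
#'
#' @param kb An `inquiry_kb`.
#' @param candidates Character vector of syndrome names present in `kb`.
#' @return An object of class `qa_list`: a list with component `items`,
#'   each item a list with `question` (id), `text`, `category` and
#'   `answers` (the question's full candidate-answer list: `id`, `text`).
#' @examples
#' kb <- fixture_table2()
#' deduce_qa_list(kb, names(kb$syndromes))
#' @export
deduce_qa_list <- function(kb, candidates) {
  candidates <- unique(norm_text(candidates))
  unknown <- setdiff(candidates, names(kb$syndromes))
  if (length(unknown)) {
    sdm_stop("unknown syndrome name(s): %s", paste(unknown, collapse = ", "),
             class = "sdm_lookup_error")
  }
  qids <- sort(unique(unlist(lapply(candidates, function(n)
    kb$syndromes[[n]]$symptoms$question))))
  items <- lapply(qids, function(id) {
    q <- kb_get_question(kb, id)
    list(question = q$id, text = q$text, category = q$category,
         answers = lapply(q$answers, function(a) list(id = a$id, text = a$text)))
  })
  structure(list(items = items, candidates = candidates), class = "qa_list")
}

#' @export
print.qa_list <- function(x, ...) {
  cat(sprintf("Q&A list: %d question(s) for %d candidate syndrome(s)\n",
              length(x$items), length(x$candidates)))
  for (it in x$items) {
    cat(sprintf("  [%d] %s\n", it$question, it$text))
    for (a in it$answers) cat(sprintf("      %s  %s\n", a$id, a$text))
  }
  invisible(x)
}

#' @export
length.qa_list <- function(x) length(x$items)

qa_list_to_list <- function(qa) {
  lapply(qa$items, function(it)
    list(question = it$question, text = it$text, answers = it$answers))
}
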