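#' Matching degree of a candidate syndrome against a patient record
#'
#' The fraction of the syndrome's symptom sequence found among the
#' patient's reported symptoms, intersecting on (question id, answer id)
#' identity: `|h ∩ patient| / |h|`. Symptoms the patient reports outside
#' the syndrome's sequence neither help nor penalize it, so the degree is
#' monotone non-decreasing as the patient reports more symptoms.
#'
#' @param kb An `inquiry_kb`.
#' @param syndrome Syndrome name.
#' @param patient A [patient_record()].
#' @return A fraction in `[0, 1]`.
#' @export
matching_degree <- function(kb, syndrome, patient) {
  sym <- syndrome_symptoms(kb, syndrome)
  got <- patient$symptoms[as.character(sym$question)]
  sum(!is.na(got) & got == sym$answer) / nrow(sym)
}

#' Differentiate candidate syndromes against a patient's symptoms
#'
#' Step 3 of the inquiry reasoning model: each candidate syndrome's
#' symptom set is retrieved from the syndrome base and compared with the
#' patient's symptoms; candidates meeting the matching criterion (degree
#' at least `threshold`) are confirmed and rated in order of matching
#' degree, the primary syndrome being the confirmed candidate with the
#' highest degree. Ties are broken by matched symptom count (descending),
#' then name (ascending), making the ranking deterministic and invariant
#' to candidate order.
#'
#' @param kb An `inquiry_kb`.
#' @param candidates Character vector of candidate syndrome names.
#' @param patient A [patient_record()].
#' @param threshold Confirmation threshold tau in `[0, 1]`; default 0.6
#'   (confirms full matches, rejects half matches).
#' @return An object of class `sdm_differentiation`: a list with `scored`
#'   (data.frame `name`, `degree`, `matched`, `total`, ordered), `confirmed`
#'   (names with degree >= tau), `primary` (first confirmed name or `NA`)
#'   and `threshold`.
#' @examples
#' kb <- fixture_table2()
#' patient <- patient_record(data.frame(question = c(1, 2, 3),
#'                                      answer = c("A5", "A11", "A18")))
#' differentiate(kb, names(kb$syndromes), patient)
#' @export
differentiate <- function(kb, candidates, patient, threshold = 0.6) {
  candidates <- unique(norm_text(candidates))
  unknown <- setdiff(candidates, names(kb$syndromes))
  if (length(unknown)) {
    sdm_stop("unknown syndrome name(s): %s", paste(unknown, collapse = ", "),
             class = "sdm_lookup_error")
  }
  rows <- lapply(candidates, function(n) {
    sym <- syndrome_symptoms(kb, n)
    got <- patient$symptoms[as.character(sym$question)]
    matched <- sum(!is.na(got) & got == sym$answer)
    data.frame(name = n, degree = matched / nrow(sym), matched = matched,
               total = nrow(sym), stringsAsFactors = FALSE)
  })
  scored <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(0), degree = numeric(0),
               matched = integer(0), total = integer(0))
  ord <- order(-scored$degree, -scored$matched,
               scored$name, method = "radix")
  scored <- scored[ord, , drop = FALSE]
  rownames(scored) <- NULL
  confirmed <- scored$name[scored$degree >= threshold]
  structure(list(scored = scored, confirmed = confirmed,
                 primary = if (length(confirmed)) confirmed[[1]] else NA_character_,
                 threshold = threshold),
            class = "sdm_differentiation")
}

#' @export
print.sdm_differentiation <- function(x, ...) {
  cat(sprintf("Syndrome differentiation (threshold %.2f)\n", x$threshold))
  if (nrow(x$scored) == 0L) {
    cat("  no candidates scored\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(x$scored))) {
    mark <- if (x$scored$name[i] %in% x$confirmed) "*" else " "
    cat(sprintf(" %s %.3f (%d/%d)  %s\n", mark, x$scored$degree[i],
                x$scored$matched[i], x$scored$total[i], x$scored$name[i]))
  }
  cat(if (is.na(x$primary)) "  primary: none confirmed\n"
      else sprintf("  primary: %s\n", x$primary))
  invisible(x)
}

#' @export
summary.sdm_differentiation <- function(object, ...) {
  cat(sprintf("%d candidate(s), %d confirmed at threshold %.2f\n",
              nrow(object$scored), length(object$confirmed), object$threshold))
  print(object$scored)
  invisible(object$scored)
}

differentiation_to_list <- function(d) {
  list(
    threshold = d$threshold,
    scored = lapply(seq_len(nrow(d$scored)), function(i) list(
      name = d$scored$name[i], degree = d$scored$degree[i],
      matched = d$scored$matched[i], total = d$scored$total[i])),
    confirmed = as.list(d$confirmed),
    primary = if (is.na(d$primary)) NULL else d$primary
  )
}
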