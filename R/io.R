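kb_to_list <- function(kb) {
  list(
    schema_version = kb$schema_version,
    questions = lapply(unname(kb$questions), function(q) list(
      id = q$id, text = q$text, category = q$category,
      answers = lapply(q$answers, function(a) list(
        id = a$id, text = a$text,
        next_question = if (is.null(a$next_question)) NULL else a$next_question,
        next_syndrome = if (is.null(a$next_syndrome)) NULL else a$next_syndrome
      ))
    )),
    syndromes = lapply(unname(kb$syndromes), function(s) list(
      name = s$name,
      symptoms = lapply(seq_len(nrow(s$symptoms)), function(i) list(
        question = s$symptoms$question[i], answer = s$symptoms$answer[i]
      ))
    ))
  )
}

#' Serialize a knowledge base to canonical JSON
#'
#' Output is deterministic: questions sorted by id, syndromes by name, so
#' equal knowledge bases serialize byte-identically.
#'
#' @param kb An `inquiry_kb`.
#' @return A single JSON string.
#' @export
kb_to_json <- function(kb) {
  as.character(jsonlite::toJSON(kb_to_list(kb), auto_unbox = TRUE, null = "null",
                                digits = NA, pretty = TRUE))
}

kb_from_list <- function(x, where = "input") {
  need <- function(el, fld) {
    if (is.null(el[[fld]])) sdm_stop("%s: missing field '%s'", where, fld,
                                     class = "sdm_format_error")
    el[[fld]]
  }
  questions <- lapply(seq_along(x$questions), function(i) {
    q <- x$questions[[i]]
    wq <- sprintf("%s: question record %d", where, i)
    answers <- lapply(seq_along(q$answers), function(j) {
      a <- q$answers[[j]]
      kb_answer(need(a, "id"), need(a, "text"),
                next_question = a$next_question, next_syndrome = a$next_syndrome)
    })
    kb_question(need(q, "id"), need(q, "text"), need(q, "category"), answers)
  })
  syndromes <- lapply(seq_along(x$syndromes), function(i) {
    s <- x$syndromes[[i]]
    sym <- do.call(rbind, lapply(s$symptoms, function(z)
      data.frame(question = as.integer(z$question), answer = as.character(z$answer),
                 stringsAsFactors = FALSE)))
    kb_syndrome(need(s, "name"), sym)
  })
  kb <- inquiry_kb(questions, syndromes,
                   schema_version = if (is.null(x$schema_version)) "1" else x$schema_version)
  check_references(kb, where)
  kb
}

# hard reference check at load time: every dangling id is listed at once
check_references <- function(kb, where) {
  rep <- validate_kb(kb)
  bad <- rep[rep$code %in% c("DANGLING_NEXT", "DANGLING_SYMPTOM"), , drop = FALSE]
  if (nrow(bad)) {
    sdm_stop("%s: unresolved references:\n%s", where,
             paste(sprintf("  %s: %s", bad$element, bad$message), collapse = "\n"),
             class = "sdm_validation_error")
  }
  invisible(kb)
}

#' Load an inquiry knowledge base
#'
#' JSON is the canonical lossless format. The CSV dialect mirrors the
#' five-column question-base table (`Question no., Question, Answer no.,
#' Answer, Next`) with continuation rows (blank question cells) attaching
#' further answers to the preceding question; it carries the question base
#' only, so import synthesizes a minimal one-pair syndrome for each
#' terminal answer so that all cross-references resolve.
#'
#' @param path File path.
#' @param format `"json"` or `"csv"`; default inferred from the extension.
#' @return A cross-reference-checked `inquiry_kb`.
#' @examples
#' f <- tempfile(fileext = ".json")
#' save_kb(fixture_table1(), f)
#' kb <- load_kb(f)
#' @export
load_kb <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  if (!file.exists(path)) sdm_stop("no such file: %s", path, class = "sdm_io_error")
  if (format == "json") {
    x <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) sdm_stop("%s: JSON parse failure: %s",
                                               path, conditionMessage(e),
                                               class = "sdm_format_error"))
    kb_from_list(x, where = path)
  } else {
    load_kb_csv(path)
  }
}

load_kb_csv <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = FALSE,
                    fileEncoding = "UTF-8"),
    error = function(e) sdm_stop("%s: CSV parse failure: %s", path,
                                 conditionMessage(e), class = "sdm_format_error"))
  want <- c("Question no.", "Question", "Answer no.", "Answer", "Next")
  if (!identical(names(df), want)) {
    sdm_stop("%s: CSV header must be exactly '%s'", path, paste(want, collapse = ","),
             class = "sdm_format_error")
  }
  questions <- list()
  cur <- NULL
  flush <- function(cur, questions) {
    if (is.null(cur)) return(questions)
    questions[[length(questions) + 1L]] <-
      kb_question(cur$id, cur$text, cur$category, cur$answers)
    questions
  }
  for (i in seq_len(nrow(df))) {
    qno <- trimws(df[["Question no."]][i])
    if (nzchar(qno)) {
      questions <- flush(cur, questions)
      if (is.na(suppressWarnings(as.integer(qno)))) {
        sdm_stop("%s: record %d: question number '%s' is not an integer",
                 path, i, qno, class = "sdm_format_error")
      }
      cur <- list(id = as.integer(qno), text = df[["Question"]][i],
                  category = inquiry_categories()[1L], answers = list())
    } else if (is.null(cur)) {
      sdm_stop("%s: record %d: continuation row before any question", path, i,
               class = "sdm_format_error")
    }
    nxt <- trimws(df[["Next"]][i])
    if (!nzchar(nxt)) sdm_stop("%s: record %d: empty Next cell", path, i,
                               class = "sdm_format_error")
    nq <- suppressWarnings(as.integer(nxt))
    cur$answers[[length(cur$answers) + 1L]] <-
      kb_answer(df[["Answer no."]][i], df[["Answer"]][i],
                next_question = if (!is.na(nq)) nq,
                next_syndrome = if (is.na(nq)) nxt)
  }
  questions <- flush(cur, questions)
  # CSV carries no symptom sequences: reconstruct one-pair syndromes from
  # the terminal links so the KB is self-consistent
  syndromes <- list()
  seen <- character(0)
  for (q in questions) for (a in q$answers) {
    if (!is.null(a$next_syndrome) && !a$next_syndrome %in% seen) {
      seen <- c(seen, a$next_syndrome)
      syndromes[[length(syndromes) + 1L]] <- kb_syndrome(
        a$next_syndrome,
        data.frame(question = q$id, answer = a$id, stringsAsFactors = FALSE))
    }
  }
  kb <- inquiry_kb(questions, syndromes)
  check_references(kb, path)
  kb
}

#' Save an inquiry knowledge base
#'
#' Output is deterministic (records sorted by id/name), so saving the same
#' KB twice yields byte-identical files. CSV export writes the question
#' base in the five-column table dialect; symptom sequences are not
#' representable in CSV (use JSON for lossless round trips).
#'
#' @param kb A validated `inquiry_kb`.
#' @param path Output file path.
#' @param format `"json"` or `"csv"`; default inferred from the extension.
#' @return Invisibly, `path`.
#' @export
save_kb <- function(kb, path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  if (format == "json") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(kb_to_json(kb), con, useBytes = TRUE)
  } else {
    rows <- list()
    for (q in kb$questions) {
      first <- TRUE
      for (a in q$answers) {
        rows[[length(rows) + 1L]] <- data.frame(
          `Question no.` = if (first) as.character(q$id) else "",
          Question = if (first) q$text else "",
          `Answer no.` = a$id, Answer = a$text,
          Next = if (!is.null(a$next_question)) as.character(a$next_question)
                 else a$next_syndrome,
          check.names = FALSE, stringsAsFactors = FALSE)
        first <- FALSE
      }
    }
    df <- do.call(rbind, rows)
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}
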