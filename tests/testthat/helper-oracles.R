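# Independent oracles and randomized-case helpers. These deliberately use
# naive enumeration (set unions, quadratic scans) so they stay independent
# of the package's own code paths.

# brute-force question-count oracle: |union of the candidates' question sets|
oracle_union_questions <- function(kb, candidates) {
  qs <- c()
  for (n in candidates) {
    qs <- c(qs, kb$syndromes[[n]]$symptoms$question)
  }
  sort(unique(qs))
}

# quadratic-scan matching oracle: count (q, a) pairs of the syndrome's
# sequence that appear among the patient's pairs, divide by sequence length
oracle_matching_degree <- function(kb, syndrome, patient) {
  sym <- kb$syndromes[[syndrome]]$symptoms
  pq <- as.integer(names(patient$symptoms))
  pa <- unname(patient$symptoms)
  hits <- 0L
  for (i in seq_len(nrow(sym))) {
    for (j in seq_along(pq)) {
      if (sym$question[i] == pq[j] && sym$answer[i] == pa[j]) hits <- hits + 1L
    }
  }
  hits / nrow(sym)
}

# deterministic random KB: draws generator parameters from conservative
# ranges that keep generation feasible
make_random_kb <- function(seed) {
  set.seed(seed)
  spec <- generator_spec(
    n_syndromes = sample(3:10, 1),
    n_categories = sample(2:13, 1),
    questions_per_category = sample(3:5, 1),
    answers_per_question = sample(3:5, 1),
    symptoms_per_syndrome = sort(sample(1:4, 2, replace = TRUE)),
    overlap = runif(1, 0.1, 0.7),
    seed = sample.int(1e6, 1))
  generate_kb(spec)
}

# random patient: answers a random subset of questions with random valid
# answer ids
make_random_patient <- function(kb, seed) {
  set.seed(seed)
  qids <- as.integer(names(kb$questions))
  n <- sample.int(length(qids), 1)
  picked <- sort(sample(qids, n))
  ans <- vapply(picked, function(q) {
    a <- kb$questions[[as.character(q)]]$answers
    a[[sample.int(length(a), 1)]]$id
  }, character(1))
  patient_record(data.frame(question = picked, answer = ans))
}

# all (question, answer) pairs of a syndrome as "q/a" strings
syndrome_pairs <- function(kb, name) {
  s <- kb$syndromes[[name]]$symptoms
  sprintf("%d/%s", s$question, s$answer)
}

# TRUE when no syndrome's pair set contains another's
pairwise_non_subset <- function(kb) {
  ns <- names(kb$syndromes)
  for (a in ns) for (b in ns) {
    if (a != b && all(syndrome_pairs(kb, a) %in% syndrome_pairs(kb, b))) {
      return(FALSE)
    }
  }
  TRUE
}
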