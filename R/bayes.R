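#' Bayesian diagnostic model over syndromes and symptoms
#'
#' The diagnostic framework treats a syndrome y and an observed symptom x
#' through Bayes' rule, P(y|x) = P(x|y) P(y) / P(x). Symptoms caused by
#' one lesion are assumed conditionally independent given the syndrome,
#' so multi-symptom evidence within one diagnostic modality combines by
#' the naive-Bayes product rule.
#'
#' @param priors Named numeric vector, P(y) per syndrome label; must sum
#'   to 1 (tolerance 1e-9) with entries in `[0, 1]`.
#' @param likelihoods Named list, one element per syndrome label, each a
#'   named numeric vector of P(x|y) per symptom label, entries in `[0, 1]`.
#' @param evidence Optional named numeric vector P(x); when absent,
#'   evidence is computed by marginalization, P(x) = sum_y P(x|y) P(y).
#' @return An object of class `bayes_model`.
#' @examples
#' m <- bayes_model(priors = c(y1 = 0.5, y2 = 0.5),
#'                  likelihoods = list(y1 = c(x = 0.8), y2 = c(x = 0.2)))
#' posterior(m, "y1", "x")
#' @export
bayes_model <- function(priors, likelihoods, evidence = NULL) {
  if (is.null(names(priors)) || any(!nzchar(names(priors)))) {
    sdm_stop("priors must be a named numeric vector")
  }
  if (any(priors < 0 | priors > 1)) sdm_stop("priors must lie in [0, 1]")
  if (abs(sum(priors) - 1) > 1e-9) {
    sdm_stop("priors must sum to 1 (got %.12f)", sum(priors))
  }
  if (!setequal(names(likelihoods), names(priors))) {
    sdm_stop("likelihoods must carry exactly the syndrome labels of priors")
  }
  for (y in names(likelihoods)) {
    p <- likelihoods[[y]]
    if (is.null(names(p)) || any(p < 0 | p > 1)) {
      sdm_stop("likelihoods[['%s']] must be a named vector with entries in [0, 1]", y)
    }
  }
  if (!is.null(evidence) && any(evidence < 0 | evidence > 1)) {
    sdm_stop("evidence probabilities must lie in [0, 1]")
  }
  labels <- sort(names(priors), method = "radix")
  structure(list(priors = priors[labels],
                 likelihoods = likelihoods[labels],
                 evidence = evidence),
            class = "bayes_model")
}

#' @export
print.bayes_model <- function(x, ...) {
  cat(sprintf("Bayes diagnostic model: %d syndrome(s), %d symptom label(s)%s\n",
              length(x$priors),
              length(unique(unlist(lapply(x$likelihoods, names)))),
              if (is.null(x$evidence)) ", evidence by marginalization" else ""))
  invisible(x)
}

model_likelihood <- function(model, y, x) {
  if (!y %in% names(model$priors)) {
    sdm_stop("unknown syndrome label '%s'", y, class = "sdm_lookup_error")
  }
  p <- model$likelihoods[[y]][x]
  if (any(is.na(p))) {
    sdm_stop("no likelihood P(x|y) for symptom '%s' under '%s'",
             x[which(is.na(p))[1]], y, class = "sdm_lookup_error")
  }
  unname(p)
}

symptom_evidence <- function(model, x) {
  if (!is.null(model$evidence)) {
    e <- model$evidence[x]
    if (is.na(e)) sdm_stop("no evidence probability for symptom '%s'", x,
                           class = "sdm_lookup_error")
    return(unname(e))
  }
  sum(vapply(names(model$priors), function(y)
    model_likelihood(model, y, x) * model$priors[[y]], numeric(1)))
}

#' Posterior probability of a syndrome given one symptom
#'
#' Bayes' rule P(y|x) = P(x|y) P(y) / P(x), with P(x) either supplied in
#' the model or computed by marginalization over the listed syndromes —
#' in which case the posteriors sum to 1 over syndromes for every symptom.
#'
#' @param model A [bayes_model()].
#' @param y Syndrome label.
#' @param x Symptom label.
#' @return The posterior probability.
#' @export
posterior <- function(model, y, x) {
  px <- symptom_evidence(model, x)
  if (px == 0) {
    sdm_stop("evidence P(x) is zero for symptom '%s': posterior undefined", x,
             class = "sdm_evidence_error")
  }
  model_likelihood(model, y, x) * model$priors[[y]] / px
}

#' Evidence from one diagnostic modality
#'
#' One of the four TCM diagnostic procedures (inspection, auscultation,
#' inquiry, palpation) together with the set of symptom labels it
#' established.
#'
#' @param modality One of `"inspection"`, `"auscultation"`, `"inquiry"`,
#'   `"palpation"`.
#' @param symptoms Character vector of symptom labels (may be empty; an
#'   empty modality contributes the prior).
#' @return An object of class `modality_evidence`.
#' @export
modality_evidence <- function(modality, symptoms = character(0)) {
  modality <- match.arg(modality,
                        c("inspection", "auscultation", "inquiry", "palpation"))
  structure(list(modality = modality, symptoms = as.character(symptoms)),
            class = "modality_evidence")
}

# naive-Bayes posterior over all syndromes for one modality's symptom set:
# P(y | s) proportional to P(y) * prod_{x in s} P(x|y), normalized over y
modality_posterior <- function(model, symptoms) {
  ys <- names(model$priors)
  unnorm <- vapply(ys, function(y) {
    p <- model$priors[[y]]
    if (length(symptoms)) p <- p * prod(model_likelihood(model, y, symptoms))
    p
  }, numeric(1))
  tot <- sum(unnorm)
  if (tot == 0) {
    sdm_stop("all syndromes have zero probability under this modality's evidence",
             class = "sdm_evidence_error")
  }
  unnorm / tot
}

#' Combine evidence across diagnostic modalities
#'
#' The four diagnostic procedures each yield a symptom set s_i; the
#' combined score for syndrome y is the sum of per-modality posteriors,
#' P(y | s1 u s2 u s3 u s4) = sum_i P(y | s_i), taken literally from the
#' framework. Each per-modality posterior is the naive-Bayes posterior
#' over that modality's symptom set under the stated independence
#' assumption. The plain sum is not a probability (it can exceed 1 and
#' sums to the number of modalities across syndromes); `normalize = TRUE`
#' rescales the scores to sum to 1 across syndromes, which never changes
#' the ranking.
#'
#' @param model A [bayes_model()].
#' @param evidence List of [modality_evidence()] objects, 1 to 4 distinct
#'   modalities.
#' @param y Optional syndrome label; when `NULL` the full named score
#'   vector over all syndromes is returned.
#' @param normalize Rescale scores to sum to 1 across syndromes.
#' @return A named numeric vector of scores (or a single score when `y`
#'   is given).
#' @examples
#' m <- bayes_model(priors = c(y1 = 0.5, y2 = 0.5),
#'                  likelihoods = list(y1 = c(x1 = 0.8, x2 = 0.3),
#'                                     y2 = c(x1 = 0.2, x2 = 0.7)))
#' combine_modalities(m, list(modality_evidence("inquiry", "x1"),
#'                            modality_evidence("palpation", "x2")))
#' @export
combine_modalities <- function(model, evidence, y = NULL, normalize = FALSE) {
  if (!length(evidence)) sdm_stop("evidence list must not be empty")
  if (length(evidence) > 4L) sdm_stop("at most four diagnostic modalities exist")
  mods <- vapply(evidence, function(e) e$modality, character(1))
  if (anyDuplicated(mods)) {
    sdm_stop("modalities must be distinct within one combination: %s",
             paste(unique(mods[duplicated(mods)]), collapse = ", "))
  }
  scores <- Reduce(`+`, lapply(evidence, function(e)
    modality_posterior(model, e$symptoms)))
  if (normalize) scores <- scores / sum(scores)
  if (is.null(y)) return(scores)
  if (!y %in% names(scores)) {
    sdm_stop("unknown syndrome label '%s'", y, class = "sdm_lookup_error")
  }
  unname(scores[[y]])
}

#' Map a knowledge base onto a Bayes model
#'
#' An exploratory bridge from the rule-based matcher to the probabilistic
#' framework: candidate syndromes get uniform priors, and each symptom
#' label "question/answer" gets likelihood `p_hit` under a syndrome whose
#' sequence contains that pair and `1 - p_hit` otherwise.
#'
#' @param kb An `inquiry_kb`.
#' @param candidates Candidate syndrome names.
#' @param p_hit Likelihood of a symptom belonging to the syndrome's
#'   sequence; default 0.9.
#' @return A [bayes_model()].
#' @export
kb_bayes_model <- function(kb, candidates, p_hit = 0.9) {
  candidates <- unique(norm_text(candidates))
  unknown <- setdiff(candidates, names(kb$syndromes))
  if (length(unknown)) {
    sdm_stop("unknown syndrome name(s): %s", paste(unknown, collapse = ", "),
             class = "sdm_lookup_error")
  }
  labels <- unique(unlist(lapply(candidates, function(n) {
    s <- syndrome_symptoms(kb, n)
    sprintf("%d/%s", s$question, s$answer)
  })))
  liks <- lapply(candidates, function(n) {
    s <- syndrome_symptoms(kb, n)
    mine <- sprintf("%d/%s", s$question, s$answer)
    stats::setNames(ifelse(labels %in% mine, p_hit, 1 - p_hit), labels)
  })
  names(liks) <- candidates
  bayes_model(priors = stats::setNames(rep(1 / length(candidates),
                                           length(candidates)), candidates),
              likelihoods = liks)
}
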