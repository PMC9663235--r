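two_syndrome_model <- function() {
  bayes_model(priors = c(y1 = 0.5, y2 = 0.5),
              likelihoods = list(y1 = c(x = 0.8), y2 = c(x = 0.2)))
}

test_that("Bayes' rule posteriors match hand arithmetic", {
  # P(x) = 0.5*0.8 + 0.5*0.2 = 0.5; P(y1|x) = 0.8*0.5/0.5 = 0.8
  m <- two_syndrome_model()
  expect_equal(posterior(m, "y1", "x"), 0.8)
  expect_equal(posterior(m, "y2", "x"), 0.2)

  # degenerate prior: a single syndrome always has posterior 1
  m1 <- bayes_model(priors = c(only = 1),
                    likelihoods = list(only = c(x = 0.37)))
  expect_equal(posterior(m1, "only", "x"), 1)

  # zero likelihood forces posterior 0 whatever the prior
  m0 <- bayes_model(priors = c(a = 0.9, b = 0.1),
                    likelihoods = list(a = c(x = 0), b = c(x = 0.5)))
  expect_equal(posterior(m0, "a", "x"), 0)
})

test_that("with marginalized evidence, posteriors sum to 1 over syndromes", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(2:5, 1)
    ys <- paste0("y", seq_len(n))
    pri <- runif(n); pri <- pri / sum(pri)
    xs <- paste0("x", 1:3)
    lik <- lapply(ys, function(y) stats::setNames(runif(3, 0.05, 0.95), xs))
    names(lik) <- ys
    m <- bayes_model(stats::setNames(pri, ys), lik)
    for (x in xs) {
      expect_equal(sum(vapply(ys, function(y) posterior(m, y, x), numeric(1))),
                   1, tolerance = 1e-9)
    }
  }
})

test_that("zero evidence and unknown labels are typed errors", {
  m0 <- bayes_model(priors = c(a = 1, b = 0),
                    likelihoods = list(a = c(x = 0), b = c(x = 0.5)))
  expect_error(posterior(m0, "a", "x"), class = "sdm_evidence_error")
  m <- two_syndrome_model()
  expect_error(posterior(m, "zz", "x"), class = "sdm_lookup_error")
  expect_error(posterior(m, "y1", "unknown"), class = "sdm_lookup_error")
  expect_error(bayes_model(c(y1 = 0.6, y2 = 0.6),
                           list(y1 = c(x = 1), y2 = c(x = 1))),
               "sum to 1")
})

test_that("modality combination is the plain sum of per-modality posteriors", {
  m <- bayes_model(
    priors = c(y1 = 0.5, y2 = 0.5),
    likelihoods = list(y1 = c(x1 = 0.8, x2 = 0.3, x3 = 0.6),
                       y2 = c(x1 = 0.2, x2 = 0.7, x3 = 0.6)))
  # one modality: the combined score is that modality's posterior
  one <- combine_modalities(m, list(modality_evidence("inquiry", "x1")))
  expect_equal(one[["y1"]], 0.8)

  # independent sum across modalities: per-modality posteriors for y1 are
  # 0.8 (x1), 0.3 (x2) and 0.5 (x3, symmetric), summing to 1.6
  ev <- list(modality_evidence("inspection", "x1"),
             modality_evidence("inquiry", "x2"),
             modality_evidence("palpation", "x3"))
  expect_equal(combine_modalities(m, ev, y = "y1"), 0.8 + 0.3 + 0.5)
  # the unnormalized scores sum to the number of modalities
  expect_equal(sum(combine_modalities(m, ev)), 3)
  expect_true(all(combine_modalities(m, ev) >= 0))
})

test_that("normalization yields a distribution and never reorders syndromes", {
  m <- bayes_model(
    priors = c(y1 = 0.3, y2 = 0.7),
    likelihoods = list(y1 = c(x1 = 0.9, x2 = 0.4),
                       y2 = c(x1 = 0.1, x2 = 0.8)))
  ev <- list(modality_evidence("inquiry", c("x1", "x2")),
             modality_evidence("palpation", "x1"))
  raw <- combine_modalities(m, ev)
  nrm <- combine_modalities(m, ev, normalize = TRUE)
  expect_equal(sum(nrm), 1, tolerance = 1e-12)
  expect_identical(order(raw), order(nrm))
})

test_that("symmetric models give symmetric evidence equal scores", {
  m <- bayes_model(priors = c(a = 0.5, b = 0.5),
                   likelihoods = list(a = c(xa = 0.8, xb = 0.2),
                                      b = c(xa = 0.2, xb = 0.8)))
  sc <- combine_modalities(m, list(modality_evidence("inquiry", c("xa", "xb"))))
  expect_equal(sc[["a"]], sc[["b"]])
})

test_that("evidence lists must be non-empty with distinct modalities", {
  m <- two_syndrome_model()
  expect_error(combine_modalities(m, list()), "must not be empty")
  expect_error(combine_modalities(m, list(modality_evidence("inquiry", "x"),
                                          modality_evidence("inquiry", "x"))),
               "distinct")
})

test_that("a KB maps onto a uniform-prior hit/miss Bayes model", {
  kb <- fixture_table2()
  m <- kb_bayes_model(kb, names(kb$syndromes), p_hit = 0.9)
  expect_equal(unname(m$priors), c(0.5, 0.5))
  waist <- "syndrome of cold and dampness invading the waist"
  expect_equal(unname(m$likelihoods[[waist]]["1/A5"]), 0.9)
  expect_equal(unname(m$likelihoods[[waist]]["1/A7"]), 0.1)
  # the patient's own symptoms favour the waist syndrome
  sc <- combine_modalities(m, list(modality_evidence("inquiry",
                                                     c("1/A5", "2/A11"))))
  expect_gt(sc[[waist]], sc[["syndrome of wind and cold and dampness impediment"]])
})
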