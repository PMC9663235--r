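Package: tcmsdm
Title: Knowledge-Driven Syndrome Differentiation by Simulated TCM Inquiry
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Represents Traditional Chinese Medicine (TCM) inquiry knowledge
    as question-answer pairs ordered by the classical Ten Brief Inquiries,
    deduces targeted question lists for candidate syndromes, simulates
    patient consultations under scripted, random or oracle answer policies,
    ranks candidates by symptom matching degree, and evaluates the whole
    consultation protocol on seeded synthetic knowledge bases. Also provides
    an optional Bayesian evidence-combination scorer over the four TCM
    diagnostic modalities and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
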