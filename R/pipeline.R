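#' Run the two-stage pipeline over a document corpus
#'
#' Convenience wrapper composing preprocessing, the selected engine and
#' patient aggregation:
#' * `"rule"` — stage-1 keyword rule classifier only;
#' * `"ml"` — TF-IDF linear classifier on preprocessed tokens;
#' * `"ml+post"` — ML decisions gated by the rule-based keyword check
#'   (default; the full two-stage design).
#'
#' @param docs Document data frame (`doc_id`, `patient_id`, `text`).
#' @param doc_labels For the ML engines: integer 0/1 vector of document
#'   training labels aligned with `docs` (e.g. the generator's
#'   `contains_self_service`). Ignored by the rule engine.
#' @param lexicons List of lexicons ([default_lexicons()]).
#' @param config An `msit_preprocess_config`
#'   ([default_preprocess_config()]).
#' @param engine `"ml+post"`, `"ml"` or `"rule"`.
#' @param model Optional pre-trained `msit_model`; when supplied the ML
#'   engines skip training.
#' @param seed Training seed.
#' @return List: `document_decisions`, `patient_decisions`, `model` (NULL
#'   for the rule engine), `streams` (preprocessed token streams).
#' @export
run_msit <- function(docs, doc_labels = NULL,
                     lexicons = default_lexicons(),
                     config = default_preprocess_config(),
                     engine = c("ml+post", "ml", "rule"),
                     model = NULL, seed = 42L) {
  engine <- match.arg(engine)
  if (engine == "rule") {
    dec <- rule_classify_corpus(docs, lexicons$military, lexicons$confounders,
                                lexicons$relations,
                                window = config$relation_window)
    return(list(document_decisions = dec,
                patient_decisions = aggregate_patients(dec, docs),
                model = NULL, streams = NULL))
  }
  streams <- preprocess_corpus(docs, config, lexicons)
  if (is.null(model)) {
    if (is.null(doc_labels)) {
      stop("doc_labels required to train the ML engine", call. = FALSE)
    }
    model <- train(streams, doc_labels, seed = seed)
  }
  dec <- predict_documents(model, streams)
  if (engine == "ml+post") {
    dec <- postprocess(dec, docs, lexicons$military, lexicons$confounders)
  }
  list(document_decisions = dec,
       patient_decisions = aggregate_patients(dec, docs),
       model = model, streams = streams)
}

#' Reference validation fixtures shipped with the package
#'
#' `reference_validation_counts()` returns the 2x2 contingency table of the
#' external validation survey (tool classification vs self-report, 146
#' patients) as an `msit_confusion`. `reference_cohort_flow()` returns the
#' recruitment flow counts of the same study.
#'
#' @return See above.
#' @export
reference_validation_counts <- function() {
  path <- system.file("extdata", "validation", "contingency_counts.csv",
                      package = "msitr", mustWork = TRUE)
  df <- utils::read.csv(path)
  cells <- stats::setNames(df$count, df$cell)
  confusion_matrix(a = cells[["a"]], b = cells[["b"]],
                   c = cells[["c"]], d = cells[["d"]])
}

#' @rdname reference_validation_counts
#' @export
reference_cohort_flow <- function() {
  path <- system.file("extdata", "validation", "cohort_flow.csv",
                      package = "msitr", mustWork = TRUE)
  utils::read.csv(path)
}

#' Expand a confusion matrix into patient-level truth and prediction tables
#'
#' Materializes one synthetic patient row per counted case, so file-based
#' evaluation paths (prediction/truth CSVs, [cross_tabulate()]) can be
#' exercised against a printed contingency table.
#'
#' @param m An `msit_confusion`.
#' @param prefix Patient-id prefix.
#' @return List with `truth` (`patient_id`, `self_report`) and
#'   `predictions` (`patient_id`, `label`, `n_documents`,
#'   `n_positive_documents`).
#' @export
expand_confusion_to_patients <- function(m, prefix = "V") {
  stopifnot(inherits(m, "msit_confusion"))
  lab_pred <- rep(c(0L, 0L, 1L, 1L), times = c(m$a, m$b, m$c, m$d))
  lab_true <- rep(c(0L, 1L, 0L, 1L), times = c(m$a, m$b, m$c, m$d))
  ids <- sprintf("%s%04d", prefix, seq_along(lab_pred))
  list(truth = data.frame(patient_id = ids, self_report = lab_true),
       predictions = data.frame(patient_id = ids, label = lab_pred,
                                n_documents = 1L,
                                n_positive_documents = lab_pred))
}
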