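#' Stage-1 keyword rule-based document classifier
#'
#' Classifies one document: after punctuation stripping and (by default)
#' removal of other people's service mentions, the document is labelled 1
#' (veteran evidence) iff it retains a military-lexicon match not contained
#' in a confounder span. Semantics match a LIKE-pattern keyword query over
#' the note text; no database is involved.
#'
#' @param doc One-row document data frame, or a list with `doc_id` and
#'   `text`.
#' @param military,confounders,relations `msit_lexicon` objects.
#' @param window Relation token window for other-person removal.
#' @param raw_keywords If `TRUE`, skip other-person removal and classify on
#'   raw keyword presence only.
#' @return One-row data frame: `doc_id`, `label` (0/1), `evidence`
#'   (semicolon-joined matched entries, `""` when none), `n_evidence`,
#'   `source = "rule"`.
#' @export
#' @examples
#' lex <- list(
#'   military = lexicon(c("veteran", "served in the forces", "army"), "military"),
#'   confounders = lexicon("salvation army", "confounder"),
#'   relations = lexicon(c("father", "husband"), "relation"))
#' rule_classify(list(doc_id = "d1", text = "patient served in the forces"),
#'               lex$military, lex$confounders, lex$relations)
rule_classify <- function(doc, military, confounders, relations,
                          window = 5L, raw_keywords = FALSE) {
  txt <- strip_punctuation(doc$text)
  if (!raw_keywords) {
    txt <- remove_other_person_service(txt, military, relations, window)
  }
  ev <- surviving_military_matches(txt, military, confounders)
  data.frame(doc_id = doc$doc_id,
             label = as.integer(nrow(ev) > 0L),
             evidence = paste(ev$entry, collapse = ";"),
             n_evidence = nrow(ev),
             source = "rule")
}

#' Rule-classify every document in a corpus
#'
#' @param docs Document data frame.
#' @inheritParams rule_classify
#' @return Data frame of document decisions, one row per document, in input
#'   order.
#' @export
rule_classify_corpus <- function(docs, military, confounders, relations,
                                 window = 5L, raw_keywords = FALSE) {
  rows <- lapply(seq_len(nrow(docs)), function(i) {
    rule_classify(docs[i, ], military, confounders, relations,
                  window = window, raw_keywords = raw_keywords)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
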