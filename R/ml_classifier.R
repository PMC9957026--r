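#' TF-IDF vectorizer
#'
#' Fits a term frequency-inverse document frequency representation over
#' token streams. Terms are unigrams and, optionally, bigrams
#' (space-joined adjacent tokens). IDF is smoothed:
#' `idf(t) = ln((1 + N) / (1 + df(t))) + 1`, and every document row is
#' L2-normalized, so feature values are non-negative and each non-empty row
#' has unit norm.
#'
#' @param streams Named list of token vectors (names = doc_ids).
#' @param ngram_max 1 = unigrams only, 2 = unigrams + bigrams (default).
#' @return List with `matrix` (sparse `dgCMatrix`, docs x terms),
#'   `vocabulary`, `idf`, `doc_ids`, `ngram_max`; class `msit_tfidf`.
#' @export
fit_tfidf <- function(streams, ngram_max = 2L) {
  if (length(streams) < 2L || sum(lengths(streams)) < 1L) {
    stop("empty corpus: TF-IDF requires at least 2 documents and 1 token",
         call. = FALSE)
  }
  terms <- lapply(streams, ngram_terms, ngram_max = ngram_max)
  vocab <- sort(unique(unlist(terms)))
  n <- length(streams)
  mat <- term_count_matrix(terms, vocab)
  df <- Matrix::colSums(mat > 0)
  idf <- stats::setNames(log((1 + n) / (1 + df)) + 1, vocab)
  tfidf <- l2_normalize_rows(mat %*% Matrix::Diagonal(x = idf))
  dimnames(tfidf) <- list(names(streams), vocab)
  structure(list(matrix = tfidf, vocabulary = vocab, idf = idf,
                 doc_ids = names(streams), ngram_max = as.integer(ngram_max)),
            class = "msit_tfidf")
}

ngram_terms <- function(tokens, ngram_max = 2L) {
  out <- tokens
  if (ngram_max >= 2L && length(tokens) >= 2L) {
    out <- c(out, paste(tokens[-length(tokens)], tokens[-1L]))
  }
  out
}

term_count_matrix <- function(terms, vocab) {
  idx <- lapply(terms, function(tt) {
    m <- match(tt, vocab)
    m[!is.na(m)]
  })
  ii <- rep(seq_along(idx), lengths(idx))
  jj <- unlist(idx, use.names = FALSE)
  if (length(jj) == 0L) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(length(terms), length(vocab))))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                       dims = c(length(terms), length(vocab)))
}

l2_normalize_rows <- function(m) {
  norms <- sqrt(Matrix::rowSums(m^2))
  norms[norms == 0] <- 1
  Matrix::Diagonal(x = 1 / norms) %*% m
}

#' Transform new token streams with a fitted vectorizer
#'
#' Tokens and bigrams absent from the fitted vocabulary are ignored (they
#' contribute nothing); fully out-of-vocabulary documents become zero rows.
#'
#' @param vectorizer An `msit_tfidf`.
#' @param streams Named list of token vectors.
#' @return Sparse matrix (docs x fitted vocabulary), rows L2-normalized.
#' @export
transform_tfidf <- function(vectorizer, streams) {
  terms <- lapply(streams, ngram_terms, ngram_max = vectorizer$ngram_max)
  mat <- term_count_matrix(terms, vectorizer$vocabulary)
  out <- l2_normalize_rows(mat %*% Matrix::Diagonal(x = vectorizer$idf))
  dimnames(out) <- list(names(streams), vectorizer$vocabulary)
  out
}

#' Train the stage-2 linear classifier
#'
#' Fits a ridge-penalized logistic regression (glmnet, alpha = 0) on TF-IDF
#' features of the supplied token streams. The fit is deterministic given
#' identical data and configuration; `seed` is stored in the model so any
#' stochastic extension stays reproducible.
#'
#' @param streams Named list of token vectors (names = doc_ids).
#' @param labels Integer vector of document labels (0/1) aligned with
#'   `streams`.
#' @param seed Integer training seed (recorded in the model). Default 42.
#' @param ngram_max Passed to [fit_tfidf()].
#' @param lambda Ridge penalty at which predictions are made. Default 1e-3.
#' @param threshold Decision threshold on predicted probability. Default 0.5.
#' @return An object of class `msit_model`.
#' @export
train <- function(streams, labels, seed = 42L, ngram_max = 2L,
                  lambda = 1e-3, threshold = 0.5) {
  if (length(streams) < 10L) {
    stop("insufficient data: need at least 10 labelled documents",
         call. = FALSE)
  }
  if (length(labels) != length(streams)) {
    stop("labels and streams must align", call. = FALSE)
  }
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("single-class labels: both classes must be present", call. = FALSE)
  }
  set.seed(seed)
  vec <- fit_tfidf(streams, ngram_max = ngram_max)
  # decreasing path down to the target lambda: glmnet's stable fitting mode
  path <- exp(seq(log(1), log(lambda), length.out = 30))
  fit <- glmnet::glmnet(vec$matrix, labels, family = "binomial",
                        alpha = 0, lambda = path, standardize = FALSE)
  structure(list(vectorizer = vec, fit = fit, lambda = lambda,
                 decision_threshold = threshold, training_seed = as.integer(seed)),
            class = "msit_model")
}

#' @export
print.msit_model <- function(x, ...) {
  cat(sprintf(
    "<msit_model> ridge logistic on TF-IDF: %d terms (ngram <= %d), lambda %.4g, threshold %.2f, seed %d\n",
    length(x$vectorizer$vocabulary), x$vectorizer$ngram_max, x$lambda,
    x$decision_threshold, x$training_seed))
  invisible(x)
}

#' Predict document decisions with a trained model
#'
#' One decision per stream. Empty token streams are labelled 0 directly
#' (no text, no evidence) rather than scored.
#'
#' @param model An `msit_model`.
#' @param streams Named list of token vectors.
#' @return Data frame: `doc_id`, `label`, `prob`, `source = "ml"`.
#' @export
predict_documents <- function(model, streams) {
  if (!inherits(model, "msit_model")) stop("unfitted model", call. = FALSE)
  x <- transform_tfidf(model$vectorizer, streams)
  prob <- as.numeric(stats::predict(model$fit, newx = x, s = model$lambda,
                                    type = "response"))
  label <- as.integer(prob >= model$decision_threshold)
  empty <- lengths(streams) == 0L
  label[empty] <- 0L
  prob[empty] <- 0
  data.frame(doc_id = names(streams), label = label, prob = prob,
             source = "ml")
}

#' Rule-based postprocessing gate on ML decisions
#'
#' Every ML positive whose document lacks surviving military evidence (a
#' military term not contained in a confounder phrase) is flipped to 0;
#' negatives are never changed. This reproduces the keyword check applied
#' to positive classifications to cut false positives.
#'
#' @param decisions Document decisions from [predict_documents()].
#' @param docs Document data frame covering every `doc_id` in `decisions`.
#' @param military,confounders `msit_lexicon` objects.
#' @return Decisions with `source = "ml_postprocessed"`, plus `evidence` and
#'   `n_evidence` columns.
#' @export
postprocess <- function(decisions, docs, military, confounders) {
  idx <- match(decisions$doc_id, docs$doc_id)
  if (anyNA(idx)) {
    stop("doc_id mismatch: decisions reference documents not supplied",
         call. = FALSE)
  }
  evidence <- character(nrow(decisions))
  n_ev <- integer(nrow(decisions))
  label <- decisions$label
  for (i in which(decisions$label == 1L)) {
    ev <- surviving_military_matches(docs$text[idx[i]], military, confounders)
    if (nrow(ev) == 0L) {
      label[i] <- 0L
    } else {
      evidence[i] <- paste(ev$entry, collapse = ";")
      n_ev[i] <- nrow(ev)
    }
  }
  out <- decisions
  out$label <- label
  out$evidence <- evidence
  out$n_evidence <- n_ev
  out$source <- "ml_postprocessed"
  out
}

#' Aggregate document decisions to patient level
#'
#' A patient is labelled veteran iff any of their documents is (logical OR);
#' order-invariant and idempotent.
#'
#' @param decisions Document decisions (`doc_id`, `label`).
#' @param doc_map Data frame mapping `doc_id` to `patient_id` (e.g. the
#'   document data frame itself).
#' @return Data frame: `patient_id`, `label`, `n_documents`,
#'   `n_positive_documents`; one row per patient, in first-appearance order.
#' @export
aggregate_patients <- function(decisions, doc_map) {
  idx <- match(decisions$doc_id, doc_map$doc_id)
  if (anyNA(idx)) {
    stop("unmapped doc_id: ",
         paste(utils::head(decisions$doc_id[is.na(idx)], 5L), collapse = ", "),
         call. = FALSE)
  }
  pid <- doc_map$patient_id[idx]
  ids <- unique(pid)
  n_doc <- as.integer(table(factor(pid, levels = ids)))
  n_pos <- as.integer(tapply(decisions$label, factor(pid, levels = ids), sum))
  data.frame(patient_id = ids,
             label = as.integer(n_pos >= 1L),
             n_documents = n_doc,
             n_positive_documents = n_pos)
}

#' Save / load a trained model bundle
#'
#' The bundle (vectorizer + classifier + configuration) round-trips
#' bit-stably: predictions before and after save/load are identical.
#'
#' @param model An `msit_model`.
#' @param path File path for the serialized bundle.
#' @return `save_model`: `path` invisibly; `load_model`: the `msit_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "msit_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "msit_model")) stop("not an msit_model bundle",
                                           call. = FALSE)
  model
}
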