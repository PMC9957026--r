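test_that("TF-IDF matches hand-computed values under the smoothed-idf formula", {
  streams <- list(d1 = c("a", "b", "a"), d2 = c("b", "c"),
                  d3 = c("c", "c", "c"))
  vec <- fit_tfidf(streams, ngram_max = 1L)
  expect_equal(vec$vocabulary, c("a", "b", "c"))
  # idf = ln((1+3)/(1+df)) + 1
  expect_equal(unname(vec$idf), c(log(4 / 2) + 1, log(4 / 3) + 1, log(4 / 3) + 1))
  m <- as.matrix(vec$matrix)
  # frozen values cross-checked against an independent TF-IDF implementation
  expect_equal(unname(m[1, ]), c(0.93470196, 0.35543247, 0), tolerance = 1e-7)
  expect_equal(unname(m[2, ]), c(0, 0.70710678, 0.70710678), tolerance = 1e-7)
  expect_equal(unname(m[3, ]), c(0, 0, 1), tolerance = 1e-7)
})

test_that("TF-IDF rows are L2-normalized and disjoint corpora are block-structured", {
  streams <- list(d1 = c("alpha", "beta"), d2 = c("gamma", "delta", "gamma"))
  vec <- fit_tfidf(streams)
  m <- as.matrix(vec$matrix)
  expect_equal(unname(sqrt(rowSums(m^2))), c(1, 1))
  expect_equal(sum(m[1, ] > 0 & m[2, ] > 0), 0L)
  expect_error(fit_tfidf(list(d1 = character(0))), "empty corpus")
})

test_that("a term present in every document gets the same idf weight everywhere", {
  streams <- list(d1 = c("common", "x"), d2 = c("common", "y"),
                  d3 = c("common", "z"))
  vec <- fit_tfidf(streams, ngram_max = 1L)
  expect_equal(unname(vec$idf["common"]), log(4 / 4) + 1)
})

separable_corpus <- function(n_patients = 80L, seed = 5L) {
  co <- generate(sim_config(n_patients = n_patients, p_disclosure = 1,
                            seed = seed))
  lex <- default_lexicons()
  streams <- preprocess_corpus(co$documents, default_preprocess_config(), lex)
  list(corpus = co, streams = streams,
       labels = as.integer(co$note_annotations$contains_self_service))
}

test_that("training on a separable synthetic corpus reaches near-perfect accuracy", {
  sc <- separable_corpus()
  model <- train(sc$streams, sc$labels, seed = 42L)
  dec <- predict_documents(model, sc$streams)
  expect_gte(mean(dec$label == sc$labels), 0.99)
})

test_that("train validates its inputs", {
  sc <- separable_corpus(n_patients = 10L)
  expect_error(train(sc$streams, rep(1L, length(sc$streams))), "single-class")
  expect_error(train(sc$streams[1:5], sc$labels[1:5]), "insufficient data")
  expect_error(train(sc$streams, sc$labels[-1]), "align")
})

test_that("retraining with identical seed, config and data reproduces predictions", {
  sc <- separable_corpus(n_patients = 40L)
  m1 <- train(sc$streams, sc$labels, seed = 42L)
  m2 <- train(sc$streams, sc$labels, seed = 42L)
  hold <- separable_corpus(n_patients = 20L, seed = 77L)
  expect_identical(predict_documents(m1, hold$streams),
                   predict_documents(m2, hold$streams))
})

test_that("prediction is total: one decision per stream, empty and unseen handled", {
  sc <- separable_corpus(n_patients = 40L)
  model <- train(sc$streams, sc$labels)
  newstreams <- list(e1 = character(0),
                     e2 = c("totally", "novel", "vocabulary"),
                     e3 = c("served", "army", "veteran"))
  dec <- predict_documents(model, newstreams)
  expect_equal(nrow(dec), 3L)
  expect_equal(dec$label[1], 0L)   # empty stream: decided behaviour
  expect_equal(dec$prob[1], 0)
  expect_equal(dec$label[2], 0L)   # fully out-of-vocabulary: zero row
})

test_that("postprocessing gates positives on military evidence and only flips 1 to 0", {
  lex <- tiny_lexicons()
  docs <- data.frame(doc_id = c("d1", "d2", "d3"), patient_id = "p",
                     text = c("supported by the salvation army",
                              "a veteran of the army",
                              "a veteran of the navy"))
  dec <- data.frame(doc_id = c("d1", "d2", "d3"), label = c(1L, 1L, 0L),
                    prob = c(0.9, 0.9, 0.2), source = "ml")
  out <- postprocess(dec, docs, lex$military, lex$confounders)
  expect_equal(out$label, c(0L, 1L, 0L))   # d3 stays 0 despite "veteran"
  expect_equal(out$source, rep("ml_postprocessed", 3))
  expect_true(out$n_evidence[2] > 0L)
  expect_error(postprocess(dec, docs[1:2, ], lex$military, lex$confounders),
               "doc_id mismatch")
})

test_that("postprocessed positives are a subset of ML positives on 1000 synthetic notes", {
  co <- generate(sim_config(n_patients = 220L, seed = 29L))
  expect_gte(nrow(co$documents), 1000L)
  lex <- default_lexicons()
  streams <- preprocess_corpus(co$documents, default_preprocess_config(), lex)
  model <- train(streams, as.integer(co$note_annotations$contains_self_service))
  ml <- predict_documents(model, streams)
  post <- postprocess(ml, co$documents, lex$military, lex$confounders)
  pos_ml <- ml$doc_id[ml$label == 1L]
  pos_post <- post$doc_id[post$label == 1L]
  expect_true(all(pos_post %in% pos_ml))
  expect_true(all(post$n_evidence[post$label == 1L] > 0L))
})

test_that("patient aggregation is an order-invariant logical OR", {
  dec <- data.frame(doc_id = c("d1", "d2", "d3", "d4", "d5"),
                    label = c(0L, 1L, 0L, 0L, 0L))
  docmap <- data.frame(doc_id = sprintf("d%d", 1:5),
                       patient_id = c("p1", "p1", "p1", "p2", "p2"))
  agg <- aggregate_patients(dec, docmap)
  expect_equal(agg$label[agg$patient_id == "p1"], 1L)
  expect_equal(agg$n_positive_documents[agg$patient_id == "p1"], 1L)
  expect_equal(agg$n_documents[agg$patient_id == "p1"], 3L)
  expect_equal(agg$label[agg$patient_id == "p2"], 0L)

  set.seed(37)
  for (i in 1:10) {
    perm <- sample(nrow(dec))
    agg2 <- aggregate_patients(dec[perm, ], docmap)
    agg2 <- agg2[order(agg2$patient_id), ]
    expect_equal(agg2$label, agg[order(agg$patient_id), ]$label)
  }
  expect_error(aggregate_patients(data.frame(doc_id = "zz", label = 1L),
                                  docmap), "unmapped doc_id")
})

test_that("a saved and reloaded model makes identical predictions", {
  sc <- separable_corpus(n_patients = 40L)
  model <- train(sc$streams, sc$labels)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  model2 <- load_model(path)
  expect_identical(predict_documents(model, sc$streams),
                   predict_documents(model2, sc$streams))
})
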