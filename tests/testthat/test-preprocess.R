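test_that("strip_punctuation lowercases, strips and collapses; idempotent on random strings", {
  expect_equal(strip_punctuation("He served, in 1990!"), "he served in 1990")
  expect_equal(strip_punctuation(""), "")
  set.seed(11)
  rand <- vapply(1:200, function(i) {
    rawToChar(as.raw(sample(c(32:126), sample(1:60, 1), replace = TRUE)))
  }, "")
  once <- strip_punctuation(rand)
  expect_equal(strip_punctuation(once), once)
})

test_that("other-person service mentions are deleted with the relation token", {
  lex <- tiny_lexicons()
  out <- remove_other_person_service("his father served in the army",
                                     lex$military, lex$relations, window = 5L)
  expect_false(grepl("army|served", out))
  expect_false(grepl("father", out))
  expect_equal(remove_other_person_service("patient is a veteran",
                                           lex$military, lex$relations, 5L),
               "patient is a veteran")
})

test_that("a relation word outside the window leaves the mention intact", {
  lex <- tiny_lexicons()
  txt <- strip_punctuation(
    "his father lives abroad and writes rarely these days but patient served in the army")
  out <- remove_other_person_service(txt, lex$military, lex$relations, 5L)
  expect_true(grepl("served in the army", out))
})

test_that("template-generated notes are cleaned exactly per the generator's truth", {
  co <- generate(sim_config(n_patients = 60L, seed = 9L))
  lex <- default_lexicons()
  for (i in seq_len(nrow(co$documents))) {
    t1 <- strip_punctuation(co$documents$text[i])
    t2 <- remove_other_person_service(t1, lex$military, lex$relations, 5L)
    ev <- has_military_evidence(t2, lex$military, lex$confounders)
    expect_equal(ev, co$note_annotations$contains_self_service[i],
                 info = co$documents$text[i])
  }
})

test_that("stop words and frequent terms are dropped; military tokens always survive", {
  lex <- tiny_lexicons()
  cfg <- preprocess_config(lex$stopwords, lex$confounders,
                           frequent_term_threshold = 0.5)
  streams <- list(d1 = c("was", "army", "clinic", "common"),
                  d2 = c("army", "common", "note"),
                  d3 = c("common", "army", "visit"))
  out <- remove_stop_and_frequent(streams, cfg, lex$military)
  # "was" is a stop word, "common" has df 1.0 > 0.5, "army" df 1.0 but military
  expect_equal(out$d1, c("army", "clinic"))
  expect_equal(out$d2, c("army", "note"))
  expect_equal(out$d3, c("army", "visit"))
  # a stop word that is part of a multi-word military entry is protected
  # ("the" is in "served in the forces"; "plan" exceeds the df threshold)
  out2 <- remove_stop_and_frequent(list(d1 = c("the", "plan")), cfg,
                                   lex$military)
  expect_equal(out2$d1, "the")
})

test_that("single-document corpus: df is 1 for all tokens, military survive", {
  lex <- tiny_lexicons()
  cfg <- preprocess_config(lex$stopwords, lex$confounders,
                           frequent_term_threshold = 0.85)
  out <- remove_stop_and_frequent(list(d1 = c("veteran", "clinic")), cfg,
                                  lex$military)
  expect_equal(out$d1, "veteran")  # df of "clinic" is 1.0 > 0.85, dropped
})

test_that("retained set matches brute-force document-frequency computation", {
  set.seed(21)
  vocabulary <- c(letters, "army", "veteran")
  streams <- lapply(1:50, function(i) sample(vocabulary, 12, replace = TRUE))
  names(streams) <- sprintf("d%02d", 1:50)
  lex <- tiny_lexicons()
  thr <- 0.4
  cfg <- preprocess_config(lex$stopwords, lex$confounders,
                           frequent_term_threshold = thr)
  out <- remove_stop_and_frequent(streams, cfg, lex$military)
  df <- sapply(unique(unlist(streams)), function(tok) {
    mean(vapply(streams, function(s) tok %in% s, TRUE))
  })
  protected <- unique(unlist(strsplit(lex$military$entries, " ")))
  for (id in names(streams)) {
    keep <- vapply(streams[[id]], function(tok) {
      tok %in% protected ||
        (!(tok %in% lex$stopwords$entries) && df[[tok]] <= thr)
    }, TRUE)
    expect_equal(out[[id]], unname(streams[[id]][keep]))
  }
})

test_that("confusion phrases are deleted as a unit", {
  lex <- tiny_lexicons()
  expect_equal(remove_confusion_terms(c("support", "from", "salvation", "army"),
                                      lex$confounders),
               c("support", "from"))
  expect_equal(remove_confusion_terms(c("plain", "note"), lex$confounders),
               c("plain", "note"))
})

test_that("full pipeline output contains no confusion-entry occurrences", {
  co <- generate(sim_config(n_patients = 80L, p_charity_confounder = 0.5,
                            p_metaphor = 0.5, seed = 13L))
  lex <- default_lexicons()
  cfg <- default_preprocess_config()
  streams <- preprocess_corpus(co$documents, cfg, lex)
  entry_tok <- strsplit(lex$confounders$entries, " ")
  for (s in streams) {
    for (et in entry_tok) {
      k <- length(et)
      if (k > length(s)) next
      hits <- vapply(seq_len(length(s) - k + 1L), function(i) {
        all(s[i:(i + k - 1L)] == et)
      }, TRUE)
      expect_false(any(hits))
    }
  }
})

test_that("pipeline composition handles both failure modes and degenerate input", {
  lex <- default_lexicons()
  cfg <- default_preprocess_config()
  docs <- data.frame(
    doc_id = c("d1", "d2", "d3", "d4"),
    patient_id = "p1",
    text = c("His father served in the Army; patient supported by Salvation Army.",
             "Patient is a veteran, served in the forces.",
             "",
             "Routine review, nothing of note."))
  streams <- preprocess_corpus(docs, cfg, lex)
  mil_tok <- unique(unlist(strsplit(lex$military$entries, " ")))
  expect_length(intersect(streams$d1, mil_tok), 0L)
  expect_true(all(c("veteran", "served", "forces") %in% streams$d2))
  expect_length(streams$d3, 0L)
  # determinism
  expect_identical(streams, preprocess_corpus(docs, cfg, lex))
})

test_that("military tokens are never removed by the frequency step", {
  co <- generate(sim_config(n_patients = 40L, veteran_prevalence = 0.9,
                            p_disclosure = 1, seed = 3L))
  lex <- default_lexicons()
  cfg <- default_preprocess_config(frequent_term_threshold = 0.05)
  streams <- preprocess_corpus(co$documents, cfg, lex)
  mil_tok <- unique(unlist(strsplit(lex$military$entries, " ")))
  vet_docs <- co$note_annotations$doc_id[co$note_annotations$contains_self_service]
  retained <- vapply(vet_docs, function(d) {
    length(intersect(streams[[d]], mil_tok)) > 0L
  }, TRUE)
  expect_true(all(retained))
})
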