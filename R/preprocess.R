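#' Preprocessing configuration
#'
#' Bundles the tunables of the four-step preprocessing pipeline:
#' punctuation stripping, removal of other people's service mentions,
#' stop-word / frequent-term removal (military terms exempt), and
#' confusion-phrase removal.
#'
#' @param stopwords Stop-word `msit_lexicon` (role `stopword`).
#' @param confusion_terms Confounder `msit_lexicon` whose token
#'   subsequences are deleted from token streams.
#' @param frequent_term_threshold Document-frequency proportion in (0, 1]
#'   above which a non-military token is dropped. Default 0.85.
#' @param relation_window Token distance (each side) within which a relation
#'   word attributes a military mention to another person. Default 5.
#' @return An object of class `msit_preprocess_config`.
#' @export
preprocess_config <- function(stopwords, confusion_terms,
                              frequent_term_threshold = 0.85,
                              relation_window = 5L) {
  stopifnot(frequent_term_threshold > 0, frequent_term_threshold <= 1,
            relation_window >= 1)
  structure(list(stopwords = stopwords,
                 confusion_terms = confusion_terms,
                 frequent_term_threshold = frequent_term_threshold,
                 relation_window = as.integer(relation_window)),
            class = "msit_preprocess_config")
}

#' Step 1: strip punctuation
#'
#' Replaces every character outside letters/digits/whitespace by a space,
#' collapses whitespace and lowercases. Idempotent.
#'
#' @param text Character vector.
#' @return Character vector of cleaned, lowercased text.
#' @export
#' @examples
#' strip_punctuation("He served, in 1990!")
strip_punctuation <- function(text) {
  normalize_text(text)
}

#' Step 2: remove mentions of another person's military service
#'
#' On punctuation-stripped text: any military-lexicon match with a
#' relation-lexicon match (e.g. "father", "husband") within `window` tokens
#' on either side is deleted together with the triggering relation tokens.
#' Military mentions with no nearby relation word are untouched.
#'
#' @param text A single punctuation-stripped string.
#' @param military Military `msit_lexicon`.
#' @param relations Relation `msit_lexicon`.
#' @param window Token distance on either side. Default 5.
#' @return The text with other-person service mentions deleted.
#' @export
#' @examples
#' ml <- lexicon(c("served in the army", "veteran"), "military")
#' rl <- lexicon(c("father", "husband"), "relation")
#' remove_other_person_service("his father served in the army", ml, rl)
remove_other_person_service <- function(text, military, relations, window = 5L) {
  tokens <- tokenize(text, normalized = TRUE)
  if (length(tokens) == 0L) return(text)
  mil <- match_token_spans(tokens, military)
  if (nrow(mil) == 0L) return(text)
  rel <- match_token_spans(tokens, relations)
  if (nrow(rel) == 0L) return(text)
  drop <- rep(FALSE, length(tokens))
  for (i in seq_len(nrow(mil))) {
    # token gap between the military span and each relation span
    gap <- ifelse(rel$i_end < mil$i_start[i], mil$i_start[i] - rel$i_end,
           ifelse(rel$i_start > mil$i_end[i], rel$i_start - mil$i_end[i], 0L))
    near <- gap <= window
    if (any(near)) {
      drop[mil$i_start[i]:mil$i_end[i]] <- TRUE
      for (j in which(near)) drop[rel$i_start[j]:rel$i_end[j]] <- TRUE
    }
  }
  paste(tokens[!drop], collapse = " ")
}

#' Step 3: remove stop words and frequently occurring terms
#'
#' Drops tokens in the stop-word set and tokens whose corpus document
#' frequency exceeds the configured threshold — except tokens that are part
#' of a military-lexicon entry, which are always retained. Document
#' frequency is computed over the supplied streams (two-pass).
#'
#' @param streams Named list of token vectors (names are doc_ids).
#' @param config An `msit_preprocess_config`.
#' @param military Military `msit_lexicon`.
#' @return Named list of filtered token vectors.
#' @export
remove_stop_and_frequent <- function(streams, config, military) {
  n <- length(streams)
  if (n == 0L) return(streams)
  protected <- unique(unlist(strsplit(military$entries, " ", fixed = TRUE)))
  df_tab <- table(unlist(lapply(streams, unique)))
  df_prop <- as.numeric(df_tab) / n
  frequent <- names(df_tab)[df_prop > config$frequent_term_threshold]
  bad <- setdiff(union(config$stopwords$entries, frequent), protected)
  lapply(streams, function(tok) tok[!tok %in% bad])
}

#' Step 4: remove confusion phrases
#'
#' Deletes token subsequences equal to a confusion-lexicon entry (e.g.
#' "salvation army") as a unit, scanning left to right with longest entry
#' first, before any military-term logic sees the stream.
#'
#' @param tokens Character vector of tokens.
#' @param confusion_terms Confounder `msit_lexicon`.
#' @return Token vector with confusion phrases removed.
#' @export
remove_confusion_terms <- function(tokens, confusion_terms) {
  n <- length(tokens)
  if (n == 0L || length(confusion_terms$entries) == 0L) return(tokens)
  entry_tok <- strsplit(confusion_terms$entries, " ", fixed = TRUE)
  entry_tok <- entry_tok[order(-lengths(entry_tok))]
  keep <- rep(TRUE, n)
  i <- 1L
  while (i <= n) {
    hit <- 0L
    for (et in entry_tok) {
      k <- length(et)
      if (i + k - 1L <= n && identical(tokens[i:(i + k - 1L)], et)) {
        hit <- k
        break
      }
    }
    if (hit > 0L) {
      keep[i:(i + hit - 1L)] <- FALSE
      i <- i + hit
    } else {
      i <- i + 1L
    }
  }
  tokens[keep]
}

#' Run the full preprocessing pipeline over a corpus
#'
#' Applies the four steps in order — (1) strip punctuation, (2) remove
#' other-person service mentions, (3) remove stop words and frequent terms
#' (military terms exempt), (4) remove confusion phrases — and emits one
#' token stream per document (possibly empty). Deterministic.
#'
#' @param docs Document data frame ([read_documents()]).
#' @param config An `msit_preprocess_config`.
#' @param lexicons List with `military` and `relations` lexicons (e.g.
#'   [default_lexicons()]).
#' @param other_person_removal Set `FALSE` to skip step 2 (raw keyword
#'   behaviour).
#' @return Named list of token vectors, names = `doc_id`, in input order.
#' @export
preprocess_corpus <- function(docs, config, lexicons,
                              other_person_removal = TRUE) {
  streams <- lapply(docs$text, function(txt) {
    t1 <- strip_punctuation(txt)
    t2 <- if (other_person_removal) {
      remove_other_person_service(t1, lexicons$military, lexicons$relations,
                                  window = config$relation_window)
    } else t1
    tokenize(t2, normalized = TRUE)
  })
  names(streams) <- docs$doc_id
  streams <- remove_stop_and_frequent(streams, config, lexicons$military)
  lapply(streams, remove_confusion_terms, confusion_terms = config$confusion_terms)
}

#' Default preprocessing configuration from packaged data files
#'
#' @inheritParams preprocess_config
#' @return An `msit_preprocess_config` using the packaged stop-word list and
#'   confounder lexicon.
#' @export
default_preprocess_config <- function(frequent_term_threshold = 0.85,
                                      relation_window = 5L) {
  lex <- default_lexicons()
  preprocess_config(stopwords = lex$stopwords,
                    confusion_terms = lex$confounders,
                    frequent_term_threshold = frequent_term_threshold,
                    relation_window = relation_window)
}
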