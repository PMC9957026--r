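# Independent brute-force oracles and tiny fixtures shared across tests.
# The oracles deliberately use a different mechanism (regex lookarounds on
# the normalized string) from the package's token-span matcher.

tiny_lexicons <- function() {
  list(
    military = lexicon(c("veteran", "army", "navy", "served in the forces",
                         "served in the army", "tour of duty"), "military"),
    confounders = lexicon(c("salvation army", "navy blue"), "confounder"),
    relations = lexicon(c("father", "husband", "brother", "son"), "relation"),
    stopwords = lexicon(c("the", "a", "in", "of", "is", "was", "and"),
                        "stopword")
  )
}

# All token-boundary occurrences of `entry` in normalized text, as 0-based
# half-open character spans; overlapping occurrences included.
oracle_entry_spans <- function(ntext, entry) {
  if (ntext == "") return(data.frame(start = integer(0), end = integer(0)))
  pat <- paste0("(?<=^| )", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", entry),
                "(?=$| )")
  m <- gregexpr(pat, ntext, perl = TRUE)[[1]]
  if (m[1] == -1L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) - 1L + attr(m, "match.length"))
}

# Brute-force equivalent of find_matches(): every entry at every position,
# longest wins at identical starts.
oracle_find_matches <- function(text, lex) {
  ntext <- normalize_text(text)
  res <- do.call(rbind, lapply(lex$entries, function(e) {
    sp <- oracle_entry_spans(ntext, e)
    if (nrow(sp) == 0L) return(NULL)
    data.frame(entry = e, start = sp$start, end = sp$end)
  }))
  if (is.null(res) || nrow(res) == 0L) {
    return(data.frame(entry = character(0), start = integer(0),
                      end = integer(0)))
  }
  res <- res[order(res$start, -(res$end - res$start)), , drop = FALSE]
  res <- res[!duplicated(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Independent re-derivation of the stage-1 rule decision: normalize,
# delete military spans with a relation token within `window` tokens,
# then require a military span not inside a confounder span.
oracle_rule_label <- function(text, military, confounders, relations,
                              window = 5L) {
  toks <- strsplit(normalize_text(text), " ", fixed = TRUE)[[1]]
  toks <- toks[toks != ""]
  if (length(toks) == 0L) return(0L)
  ent_spans <- function(entries) {
    out <- NULL
    for (e in entries) {
      et <- strsplit(e, " ", fixed = TRUE)[[1]]
      k <- length(et)
      if (k > length(toks)) next
      for (i in seq_len(length(toks) - k + 1L)) {
        if (all(toks[i:(i + k - 1L)] == et)) {
          out <- rbind(out, c(i, i + k - 1L))
        }
      }
    }
    out
  }
  mil <- ent_spans(military$entries)
  if (is.null(mil)) return(0L)
  rel <- ent_spans(relations$entries)
  keep_tok <- rep(TRUE, length(toks))
  if (!is.null(rel)) {
    for (r in seq_len(nrow(mil))) {
      gaps <- apply(rel, 1L, function(rv) {
        if (rv[2] < mil[r, 1]) mil[r, 1] - rv[2]
        else if (rv[1] > mil[r, 2]) rv[1] - mil[r, 2]
        else 0L
      })
      if (any(gaps <= window)) {
        keep_tok[mil[r, 1]:mil[r, 2]] <- FALSE
        for (j in which(gaps <= window)) keep_tok[rel[j, 1]:rel[j, 2]] <- FALSE
      }
    }
  }
  reduced <- paste(toks[keep_tok], collapse = " ")
  rtoks <- strsplit(reduced, " ", fixed = TRUE)[[1]]
  rtoks <- rtoks[rtoks != ""]
  if (length(rtoks) == 0L) return(0L)
  toks2 <- rtoks
  spans_in <- function(entries) {
    out <- NULL
    for (e in entries) {
      et <- strsplit(e, " ", fixed = TRUE)[[1]]
      k <- length(et)
      if (k > length(toks2)) next
      for (i in seq_len(length(toks2) - k + 1L)) {
        if (all(toks2[i:(i + k - 1L)] == et)) out <- rbind(out, c(i, i + k - 1L))
      }
    }
    out
  }
  mil2 <- spans_in(military$entries)
  if (is.null(mil2)) return(0L)
  conf <- spans_in(confounders$entries)
  if (is.null(conf)) return(1L)
  for (r in seq_len(nrow(mil2))) {
    inside <- any(conf[, 1] <= mil2[r, 1] & mil2[r, 2] <= conf[, 2])
    if (!inside) return(1L)
  }
  0L
}

# Random snippets mixing lexicon phrases, confounders and noise words.
random_texts <- function(n, seed = 101) {
  set.seed(seed)
  words <- c("the", "patient", "attended", "army", "veteran", "salvation",
             "navy", "blue", "father", "served", "in", "forces", "clinic",
             "review", "of", "duty", "tour", "a", "his")
  vapply(seq_len(n), function(i) {
    paste(sample(words, sample(3:25, 1L), replace = TRUE), collapse = " ")
  }, "")
}
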