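#' Normalize free text for matching
#'
#' Lowercases, replaces every character that is not a letter, digit or
#' whitespace by a space, collapses runs of whitespace to a single space and
#' trims. All phrase matching and tokenization in the package operate on
#' normalized text.
#'
#' @param x Character vector.
#' @return Character vector of the same length, normalized.
#' @export
#' @examples
#' normalize_text("He served, in 1990!")
normalize_text <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[^[:alnum:][:space:]]+", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Tokenize normalized text
#'
#' Splits on whitespace after [normalize_text()]. Returns a character vector
#' of tokens (possibly empty).
#'
#' @param x A single string.
#' @param normalized Set `TRUE` when `x` is already normalized.
#' @return Character vector of tokens.
#' @export
tokenize <- function(x, normalized = FALSE) {
  stopifnot(length(x) == 1L)
  if (!normalized) x <- normalize_text(x)
  if (is.na(x) || x == "") return(character(0))
  strsplit(x, " ", fixed = TRUE)[[1]]
}

#' Construct a lexicon
#'
#' A lexicon is a named set of normalized phrases with a role. Roles:
#' `military` (evidence of the patient's own service), `confounder`
#' (non-service uses of military vocabulary such as "Salvation Army"),
#' `relation` (words attributing service to another person, e.g. "father").
#'
#' @param entries Character vector of phrases; normalized internally.
#' @param role One of `"military"`, `"confounder"`, `"relation"`,
#'   `"stopword"`.
#' @param name Optional display name.
#' @return An object of class `msit_lexicon`.
#' @export
lexicon <- function(entries, role = c("military", "confounder", "relation", "stopword"),
                    name = role) {
  role <- match.arg(role)
  entries <- normalize_text(entries)
  entries <- unique(entries[!is.na(entries) & entries != ""])
  if (role == "military" && length(entries) == 0L) {
    stop("empty lexicon: role 'military' requires at least one entry", call. = FALSE)
  }
  structure(list(name = name, role = role, entries = entries),
            class = "msit_lexicon")
}

#' @export
print.msit_lexicon <- function(x, ...) {
  cat(sprintf("<msit_lexicon> %s (role: %s), %d entries\n",
              x$name, x$role, length(x$entries)))
  utils::head(x$entries, 10L) |> paste(collapse = ", ") |> cat("\n")
  invisible(x)
}

#' Load a lexicon from a plain-text file
#'
#' One phrase per line; blank lines and lines starting with `#` are ignored;
#' entries are normalized and de-duplicated.
#'
#' @param path Path to the file.
#' @inheritParams lexicon
#' @return An `msit_lexicon`.
#' @export
load_lexicon <- function(path, role = c("military", "confounder", "relation", "stopword"),
                         name = NULL) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("lexicon file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  lexicon(lines, role = role,
          name = if (is.null(name)) basename(path) else name)
}

#' Path to a packaged default lexicon or template file
#'
#' @param which One of `"military"`, `"confounders"`, `"relations"`,
#'   `"stopwords"`, `"templates"`.
#' @return File path inside the installed package.
#' @export
msit_data_file <- function(which = c("military", "confounders", "relations",
                                     "stopwords", "templates")) {
  which <- match.arg(which)
  fn <- switch(which,
    military = "lexicons/military.txt",
    confounders = "lexicons/confounders.txt",
    relations = "lexicons/relations.txt",
    stopwords = "lexicons/stopwords_en.txt",
    templates = "templates/note_templates.txt")
  system.file("extdata", fn, package = "msitr", mustWork = TRUE)
}

#' Load the packaged default lexicons
#'
#' @return Named list with elements `military`, `confounders`, `relations`,
#'   `stopwords`, each an `msit_lexicon`.
#' @export
default_lexicons <- function() {
  list(
    military = load_lexicon(msit_data_file("military"), "military"),
    confounders = load_lexicon(msit_data_file("confounders"), "confounder"),
    relations = load_lexicon(msit_data_file("relations"), "relation"),
    stopwords = load_lexicon(msit_data_file("stopwords"), "stopword")
  )
}

# Token start/end character offsets (0-based, half-open) in normalized text.
# Tokens in normalized text are separated by single spaces, so offsets are
# cumulative.
token_offsets <- function(tokens) {
  if (length(tokens) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  len <- nchar(tokens)
  start <- c(0L, cumsum(len + 1L)[-length(len)])
  data.frame(start = start, end = start + len)
}

# Match lexicon entries against a token vector. Returns token-index spans:
# data.frame(entry, i_start, i_end) with 1-based inclusive token indices.
match_token_spans <- function(tokens, lex) {
  n <- length(tokens)
  out <- list()
  if (n == 0L || length(lex$entries) == 0L) {
    return(data.frame(entry = character(0), i_start = integer(0),
                      i_end = integer(0)))
  }
  entry_tok <- strsplit(lex$entries, " ", fixed = TRUE)
  for (e in seq_along(entry_tok)) {
    et <- entry_tok[[e]]
    k <- length(et)
    if (k > n) next
    # candidate starts where the first token matches
    starts <- which(tokens == et[1L])
    starts <- starts[starts + k - 1L <= n]
    for (i in starts) {
      if (k == 1L || identical(tokens[i:(i + k - 1L)], et)) {
        out[[length(out) + 1L]] <- list(entry = lex$entries[e],
                                        i_start = i, i_end = i + k - 1L)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(entry = character(0), i_start = integer(0),
                      i_end = integer(0)))
  }
  data.frame(entry = vapply(out, `[[`, "", "entry"),
             i_start = vapply(out, `[[`, 0L, "i_start"),
             i_end = vapply(out, `[[`, 0L, "i_end"))
}

#' Find lexicon phrase matches in text
#'
#' Token-boundary, case-insensitive matching of every lexicon entry against
#' the normalized text. Offsets are 0-based half-open character positions in
#' the *normalized* text. When several entries match at the same start
#' position, only the longest is kept; matches starting at different
#' positions may overlap.
#'
#' @param text A single string (raw or normalized).
#' @param lex An `msit_lexicon`.
#' @return A data frame with columns `entry`, `start`, `end`, `role`, sorted
#'   by `start`.
#' @export
#' @examples
#' ml <- lexicon(c("veteran", "army", "served in the forces"), "military")
#' find_matches("He is a veteran of the army", ml)
find_matches <- function(text, lex) {
  stopifnot(inherits(lex, "msit_lexicon"))
  tokens <- tokenize(text)
  spans <- match_token_spans(tokens, lex)
  empty <- data.frame(entry = character(0), start = integer(0),
                      end = integer(0), role = character(0))
  if (nrow(spans) == 0L) return(empty)
  off <- token_offsets(tokens)
  res <- data.frame(entry = spans$entry,
                    start = off$start[spans$i_start],
                    end = off$end[spans$i_end],
                    role = lex$role)
  # longest entry wins at identical start
  res <- res[order(res$start, -(res$end - res$start)), , drop = FALSE]
  res <- res[!duplicated(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Military evidence with confounder suppression
#'
#' `TRUE` iff at least one military-lexicon match has a span not contained
#' within any confounder-lexicon match span: "army" inside "salvation army"
#' is suppressed, "army" standing alone is evidence.
#'
#' @param text A single string.
#' @param military Military `msit_lexicon`.
#' @param confounders Confounder `msit_lexicon` (may have zero entries).
#' @return Logical scalar.
#' @seealso [surviving_military_matches()] for the matches themselves.
#' @export
has_military_evidence <- function(text, military, confounders) {
  nrow(surviving_military_matches(text, military, confounders)) > 0L
}

#' Military matches surviving confounder suppression
#'
#' @inheritParams has_military_evidence
#' @return Data frame in the shape of [find_matches()], restricted to
#'   military matches whose spans are not contained in a confounder span.
#' @export
surviving_military_matches <- function(text, military, confounders) {
  m <- find_matches(text, military)
  if (nrow(m) == 0L) return(m)
  cf <- find_matches(text, confounders)
  if (nrow(cf) == 0L) return(m)
  contained <- vapply(seq_len(nrow(m)), function(i) {
    any(cf$start <= m$start[i] & m$end[i] <= cf$end)
  }, logical(1))
  out <- m[!contained, , drop = FALSE]
  rownames(out) <- NULL
  out
}
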