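#' Read clinical documents
#'
#' Reads a document corpus from JSONL (one object per line; canonical) or
#' CSV (RFC 4180, header row). Required keys/columns: `doc_id`,
#' `patient_id`, `text`; optional `created` (ISO-8601 date string).
#'
#' @param path File path.
#' @param format `"jsonl"` or `"csv"`; default guessed from the extension.
#' @return A data frame with columns `doc_id`, `patient_id`, `text`,
#'   `created`, rows in file order.
#' @export
read_documents <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "jsonl") {
    df <- jsonlite::stream_in(file(path), verbose = FALSE)
    if (nrow(df) == 0L) {
      df <- data.frame(doc_id = character(0), patient_id = character(0),
                       text = character(0))
    }
  } else {
    df <- utils::read.csv(path, colClasses = "character", encoding = "UTF-8")
  }
  required <- c("doc_id", "patient_id", "text")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$doc_id)) {
    dup <- unique(df$doc_id[duplicated(df$doc_id)])
    stop("duplicate doc_id: ", paste(utils::head(dup, 5L), collapse = ", "),
         call. = FALSE)
  }
  if (!"created" %in% names(df)) df$created <- rep(NA_character_, nrow(df))
  df$text[is.na(df$text)] <- ""
  df[, c("doc_id", "patient_id", "text", "created")]
}

#' Write clinical documents
#'
#' Inverse of [read_documents()]; JSONL is the canonical format because
#' free text with embedded newlines survives it trivially.
#'
#' @param docs Data frame with `doc_id`, `patient_id`, `text` and optionally
#'   `created`.
#' @inheritParams read_documents
#' @return `path`, invisibly.
#' @export
write_documents <- function(docs, path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (!"created" %in% names(docs)) docs$created <- NA_character_
  docs <- docs[, c("doc_id", "patient_id", "text", "created")]
  if (format == "jsonl") {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    jsonlite::stream_out(docs, con, verbose = FALSE)
  } else {
    utils::write.csv(docs, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read patient-level ground-truth labels
#'
#' CSV with columns `patient_id` and `self_report` (0 = non-veteran,
#' 1 = veteran).
#'
#' @param path CSV file path.
#' @return Data frame with `patient_id` (character) and `self_report`
#'   (integer 0/1).
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", encoding = "UTF-8")
  if (!all(c("patient_id", "self_report") %in% names(df))) {
    stop("labels CSV requires columns patient_id, self_report", call. = FALSE)
  }
  df$self_report <- as.integer(df$self_report)
  if (any(!df$self_report %in% c(0L, 1L))) {
    stop("self_report must be 0 or 1", call. = FALSE)
  }
  if (anyDuplicated(df$patient_id)) stop("duplicate patient_id in labels",
                                         call. = FALSE)
  df[, c("patient_id", "self_report")]
}

#' Write patient-level predictions
#'
#' CSV with columns `patient_id`, `msit_label`, `n_documents`,
#' `n_positive_documents`. With `coding = "12"` the label is emitted as
#' 1 = veteran / 2 = non-veteran instead of the internal 1/0.
#'
#' @param decisions Patient decisions from [aggregate_patients()].
#' @param path Output CSV path.
#' @param coding `"01"` (default) or `"12"`.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(decisions, path, coding = c("01", "12")) {
  coding <- match.arg(coding)
  out <- data.frame(patient_id = decisions$patient_id,
                    msit_label = decisions$label,
                    n_documents = decisions$n_documents,
                    n_positive_documents = decisions$n_positive_documents)
  if (coding == "12") out$msit_label <- ifelse(out$msit_label == 1L, 1L, 2L)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read patient-level predictions
#'
#' @param path CSV written by [write_predictions()] (or any CSV with
#'   `patient_id` and `msit_label`).
#' @param coding Label coding in the file: `"01"` or `"12"` (2 = non-veteran).
#' @return Data frame with `patient_id`, `label` and, when present,
#'   `n_documents`, `n_positive_documents`.
#' @export
read_predictions <- function(path, coding = c("01", "12")) {
  coding <- match.arg(coding)
  df <- utils::read.csv(path, colClasses = "character", encoding = "UTF-8")
  if (!all(c("patient_id", "msit_label") %in% names(df))) {
    stop("predictions CSV requires columns patient_id, msit_label",
         call. = FALSE)
  }
  lab <- as.integer(df$msit_label)
  if (coding == "12") lab <- ifelse(lab == 2L, 0L, lab)
  out <- data.frame(patient_id = df$patient_id, label = lab)
  for (col in c("n_documents", "n_positive_documents")) {
    if (col %in% names(df)) out[[col]] <- as.integer(df[[col]])
  }
  out
}

#' Read patient metadata for eligibility filtering
#'
#' CSV with `patient_id` plus the eligibility attributes consumed by
#' [filter_eligible()]: `alive`, `age`, `consent`, `dementia_psychosis`,
#' `has_contact`, `english_ok`, `active`, `coordinator_approved`. Boolean
#' columns accept TRUE/FALSE/1/0; empty cells become `NA` (conservatively
#' treated as failing the criterion).
#'
#' @param path CSV file path.
#' @return Data frame of patient records.
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", encoding = "UTF-8")
  if (!"patient_id" %in% names(df)) {
    stop("metadata CSV requires a patient_id column", call. = FALSE)
  }
  to_lgl <- function(x) {
    x <- tolower(trimws(x))
    out <- rep(NA, length(x))
    out[x %in% c("true", "t", "1", "yes")] <- TRUE
    out[x %in% c("false", "f", "0", "no")] <- FALSE
    out
  }
  for (col in c("alive", "consent", "dementia_psychosis", "has_contact",
                "english_ok", "active", "coordinator_approved")) {
    if (col %in% names(df)) df[[col]] <- to_lgl(df[[col]])
  }
  if ("age" %in% names(df)) df$age <- suppressWarnings(as.numeric(df$age))
  df
}

# The seven eligibility criteria, in screening order.
eligibility_stages <- c("alive", "age_18_plus", "consent_given",
                        "no_dementia_psychosis", "has_contact",
                        "english_without_interpreter", "coordinator_approved")

#' Apply the eligibility screen to patient metadata
#'
#' Retains patients passing all seven criteria, in order: (1) alive;
#' (2) aged 18 or older; (3) consent-for-contact given; (4) no
#' dementia/psychosis indicator; (5) has an email address or phone number;
#' (6) can communicate in English without an interpreter; (7) care
#' coordinator approval, required only for active patients. A missing
#' attribute fails its criterion (conservative exclusion). One flow stage is
#' recorded per criterion; the stages chain (stage k+1 `count_in` = stage k
#' `count_out`).
#'
#' @param patients Data frame from [read_metadata()] (or
#'   [generate_metadata()]).
#' @return List with `eligible` (row subset of `patients`, original order)
#'   and `flow` (data frame `stage_name`, `count_in`, `count_out`).
#' @export
filter_eligible <- function(patients) {
  get <- function(col, default = NA) {
    if (col %in% names(patients)) patients[[col]] else rep(default, nrow(patients))
  }
  isTRUE_v <- function(x) !is.na(x) & x
  alive <- isTRUE_v(get("alive"))
  age <- get("age")
  age_ok <- !is.na(age) & age >= 18
  consent <- isTRUE_v(get("consent"))
  dp <- get("dementia_psychosis")
  no_dp <- !is.na(dp) & !dp              # missing indicator = ineligible
  contact <- isTRUE_v(get("has_contact"))
  english <- isTRUE_v(get("english_ok"))
  active <- get("active")
  approved <- get("coordinator_approved")
  coord_ok <- ifelse(is.na(active), FALSE,
                     ifelse(active, !is.na(approved) & approved, TRUE))

  crit <- list(alive, age_ok, consent, no_dp, contact, english, coord_ok)
  keep <- rep(TRUE, nrow(patients))
  flow <- data.frame(stage_name = eligibility_stages,
                     count_in = NA_integer_, count_out = NA_integer_)
  for (k in seq_along(crit)) {
    flow$count_in[k] <- sum(keep)
    keep <- keep & crit[[k]]
    flow$count_out[k] <- sum(keep)
  }
  list(eligible = patients[keep, , drop = FALSE], flow = flow)
}
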