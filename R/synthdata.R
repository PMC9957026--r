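#' Simulation configuration for the synthetic note corpus
#'
#' Defaults emulate a psychiatric secondary-care corpus at the scale and
#' class balance of the validation setting: 400 patients with 3-7 notes
#' each (about 2000 documents) and a veteran prevalence of 0.233, the
#' proportion the tool classified as veterans in the validation sample.
#' Confounder rates govern how often non-veteran notes mention a family
#' member's service, the Salvation Army, or a military metaphor — the
#' documented false-positive modes.
#'
#' @param n_patients Number of patients (>= 2). Default 400.
#' @param docs_per_patient Integer range `c(min, max)` of notes per
#'   patient. Default `c(3, 7)`.
#' @param veteran_prevalence Probability a patient is a veteran.
#'   Default 0.233.
#' @param p_family_confounder Per-note probability (non-veterans) of an
#'   other-person service mention. Default 0.15.
#' @param p_charity_confounder Per-note probability of a Salvation Army
#'   mention. Default 0.10.
#' @param p_metaphor Per-note probability of a military metaphor.
#'   Default 0.10.
#' @param p_disclosure Per-note probability that a veteran's note mentions
#'   their own service. Default 0.8.
#' @param confounders_in_veterans Inject confounders into veterans' notes
#'   too. Default `FALSE` (confounders are the false-positive mechanism).
#' @param seed Integer master seed. Default 42.
#' @return An object of class `msit_sim_config`.
#' @export
sim_config <- function(n_patients = 400L, docs_per_patient = c(3L, 7L),
                       veteran_prevalence = 0.233,
                       p_family_confounder = 0.15,
                       p_charity_confounder = 0.10,
                       p_metaphor = 0.10,
                       p_disclosure = 0.8,
                       confounders_in_veterans = FALSE,
                       seed = 42L) {
  props <- c(veteran_prevalence, p_family_confounder, p_charity_confounder,
             p_metaphor, p_disclosure)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]",
                                       call. = FALSE)
  if (n_patients < 2L) stop("n_patients must be >= 2", call. = FALSE)
  if (length(docs_per_patient) != 2L ||
      docs_per_patient[1] > docs_per_patient[2] || docs_per_patient[1] < 1L) {
    stop("docs_per_patient must be c(min, max) with 1 <= min <= max",
         call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 docs_per_patient = as.integer(docs_per_patient),
                 veteran_prevalence = veteran_prevalence,
                 p_family_confounder = p_family_confounder,
                 p_charity_confounder = p_charity_confounder,
                 p_metaphor = p_metaphor,
                 p_disclosure = p_disclosure,
                 confounders_in_veterans = confounders_in_veterans,
                 seed = as.integer(seed)),
            class = "msit_sim_config")
}

# Stable 31-bit hash of (seed, string): drives one substream per patient so
# corpus edits are locally stable and generation is order-independent.
derive_seed <- function(seed, key) {
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(as.character(key))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

load_templates <- function(path = msit_data_file("templates")) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  m <- regmatches(lines, regexec("^([a-z_]+):\\s*(.*)$", lines))
  bad <- lengths(m) != 3L
  if (any(bad)) stop("malformed template line: ", lines[bad][1], call. = FALSE)
  cat_names <- vapply(m, `[[`, "", 2L)
  texts <- vapply(m, `[[`, "", 3L)
  split(texts, cat_names)
}

fill_slots <- function(template, tpl, relations) {
  if (grepl("{REL}", template, fixed = TRUE)) {
    template <- sub("{REL}", sample(relations$entries, 1L), template,
                    fixed = TRUE)
    template <- sub("{SERVICE}", sample(tpl$other_service_phrase, 1L),
                    template, fixed = TRUE)
  } else if (grepl("{SERVICE}", template, fixed = TRUE)) {
    template <- sub("{SERVICE}", sample(tpl$service_phrase, 1L), template,
                    fixed = TRUE)
  }
  template
}

#' Generate a labelled synthetic clinical-note corpus
#'
#' Notes are assembled from plain-text sentence templates: psychiatric-care
#' filler plus optional slotted sentences for the patient's own service,
#' another person's service, Salvation Army mentions and military
#' metaphors. Per-note and per-patient truth is recorded. Deterministic
#' given the config seed; each patient draws from a substream keyed by
#' `(seed, patient_id)`.
#'
#' @param config An `msit_sim_config`.
#' @return List of class `msit_corpus`: `documents` (doc_id, patient_id,
#'   text, created), `patients` (patient_id, self_report),
#'   `note_annotations` (doc_id, contains_self_service,
#'   contains_other_service, contains_confounder).
#' @export
generate <- function(config = sim_config()) {
  stopifnot(inherits(config, "msit_sim_config"))
  tpl <- load_templates()
  relations <- load_lexicon(msit_data_file("relations"), "relation")
  docs <- vector("list", config$n_patients)
  ann <- vector("list", config$n_patients)
  patient_ids <- sprintf("P%04d", seq_len(config$n_patients))
  self_report <- integer(config$n_patients)

  for (p in seq_len(config$n_patients)) {
    pid <- patient_ids[p]
    set.seed(derive_seed(config$seed, pid))
    is_vet <- stats::runif(1) < config$veteran_prevalence
    self_report[p] <- as.integer(is_vet)
    rng <- config$docs_per_patient
    n_docs <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
    ptexts <- character(n_docs)
    pann <- matrix(FALSE, n_docs, 3L)
    for (d in seq_len(n_docs)) {
      sentences <- sample(tpl$filler, sample(2:4, 1L))
      self_here <- is_vet && stats::runif(1) < config$p_disclosure
      if (self_here) {
        sentences <- append(sentences,
                            fill_slots(sample(tpl$self, 1L), tpl, relations),
                            after = sample(0:length(sentences), 1L))
      }
      inject <- !is_vet || config$confounders_in_veterans
      other_here <- inject && stats::runif(1) < config$p_family_confounder
      if (other_here) {
        sentences <- append(sentences,
                            fill_slots(sample(tpl$other, 1L), tpl, relations),
                            after = sample(0:length(sentences), 1L))
      }
      charity_here <- inject && stats::runif(1) < config$p_charity_confounder
      if (charity_here) {
        sentences <- append(sentences, sample(tpl$charity, 1L),
                            after = sample(0:length(sentences), 1L))
      }
      metaphor_here <- inject && stats::runif(1) < config$p_metaphor
      if (metaphor_here) {
        sentences <- append(sentences, sample(tpl$metaphor, 1L),
                            after = sample(0:length(sentences), 1L))
      }
      ptexts[d] <- paste(sentences, collapse = " ")
      pann[d, ] <- c(self_here, other_here, charity_here || metaphor_here)
    }
    doc_ids <- sprintf("%s-D%02d", pid, seq_len(n_docs))
    docs[[p]] <- data.frame(doc_id = doc_ids, patient_id = pid,
                            text = ptexts, created = NA_character_)
    ann[[p]] <- data.frame(doc_id = doc_ids,
                           contains_self_service = pann[, 1],
                           contains_other_service = pann[, 2],
                           contains_confounder = pann[, 3])
  }
  structure(list(documents = do.call(rbind, docs),
                 patients = data.frame(patient_id = patient_ids,
                                       self_report = self_report),
                 note_annotations = do.call(rbind, ann)),
            class = "msit_corpus")
}

#' @export
print.msit_corpus <- function(x, ...) {
  cat(sprintf("<msit_corpus> %d documents, %d patients (%.1f%% veteran)\n",
              nrow(x$documents), nrow(x$patients),
              100 * mean(x$patients$self_report)))
  invisible(x)
}

#' Generate synthetic patient metadata for the eligibility screen
#'
#' Samples each eligibility attribute independently at the stated exclusion
#' rate; all patients are marked active, so coordinator approval always
#' binds. Deterministic given the config seed.
#'
#' @param config An `msit_sim_config` (supplies `n_patients` and `seed`).
#' @param exclusion_rates Named numeric vector of per-criterion exclusion
#'   probabilities: `dead`, `under18`, `no_consent`, `dementia_psychosis`,
#'   `no_contact`, `no_english`, `not_approved`. Missing names default
#'   to 0.
#' @return Data frame of patient records consumable by [filter_eligible()].
#' @export
generate_metadata <- function(config = sim_config(), exclusion_rates = numeric()) {
  rates <- c(dead = 0, under18 = 0, no_consent = 0, dementia_psychosis = 0,
             no_contact = 0, no_english = 0, not_approved = 0)
  if (length(exclusion_rates) > 0) {
    bad <- setdiff(names(exclusion_rates), names(rates))
    if (length(bad) > 0) stop("unknown exclusion rate: ",
                              paste(bad, collapse = ", "), call. = FALSE)
    rates[names(exclusion_rates)] <- exclusion_rates
  }
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]",
                                       call. = FALSE)
  n <- config$n_patients
  set.seed(derive_seed(config$seed, "metadata"))
  data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    alive = stats::runif(n) >= rates["dead"],
    age = ifelse(stats::runif(n) < rates["under18"],
                 sample(12:17, n, replace = TRUE),
                 sample(18:90, n, replace = TRUE)),
    consent = stats::runif(n) >= rates["no_consent"],
    dementia_psychosis = stats::runif(n) < rates["dementia_psychosis"],
    has_contact = stats::runif(n) >= rates["no_contact"],
    english_ok = stats::runif(n) >= rates["no_english"],
    active = TRUE,
    coordinator_approved = stats::runif(n) >= rates["not_approved"],
    row.names = NULL
  )
}
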