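#' Construct a 2x2 confusion matrix of tool vs self-report
#'
#' Cell convention (fixed throughout the package):
#' `a` = tool non-veteran & true non-veteran, `b` = tool non-veteran & true
#' veteran, `c` = tool veteran & true non-veteran, `d` = tool veteran & true
#' veteran.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @return An object of class `msit_confusion`.
#' @export
confusion_matrix <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  structure(list(a = as.integer(a), b = as.integer(b),
                 c = as.integer(c), d = as.integer(d)),
            class = "msit_confusion")
}

#' @export
print.msit_confusion <- function(x, ...) {
  m <- rbind(`MSIT Non-veteran` = c(x$a, x$b, x$a + x$b),
             `MSIT Veteran` = c(x$c, x$d, x$c + x$d),
             Total = c(x$a + x$c, x$b + x$d, x$a + x$b + x$c + x$d))
  colnames(m) <- c("True Non-Veteran", "True Veteran", "Total")
  cat("MSIT classifications vs patient-reported classification\n")
  print(m)
  invisible(x)
}

#' Cross-tabulate patient predictions against ground truth
#'
#' Exact join on `patient_id`. Every predicted patient must have a truth
#' label; duplicates on either side are an error.
#'
#' @param predictions Data frame with `patient_id` and `label` (0/1),
#'   e.g. from [aggregate_patients()] or [read_predictions()].
#' @param truth Data frame with `patient_id` and `self_report` (0/1).
#' @return An `msit_confusion`.
#' @export
cross_tabulate <- function(predictions, truth) {
  if (anyDuplicated(predictions$patient_id)) {
    stop("duplicate patient_id in predictions", call. = FALSE)
  }
  if (anyDuplicated(truth$patient_id)) {
    stop("duplicate patient_id in truth", call. = FALSE)
  }
  idx <- match(predictions$patient_id, truth$patient_id)
  if (anyNA(idx)) {
    stop("missing truth for patient(s): ",
         paste(utils::head(predictions$patient_id[is.na(idx)], 5L),
               collapse = ", "), call. = FALSE)
  }
  pred <- as.integer(predictions$label)
  act <- as.integer(truth$self_report[idx])
  confusion_matrix(a = sum(pred == 0L & act == 0L),
                   b = sum(pred == 0L & act == 1L),
                   c = sum(pred == 1L & act == 0L),
                   d = sum(pred == 1L & act == 1L))
}

safe_ratio <- function(num, den) if (den > 0) num / den else NA_real_

#' Screening statistics from a confusion matrix
#'
#' Computes percent agreement, predictive values and two labelled
#' sensitivity/specificity conventions:
#'
#' * `paper` convention: sensitivity is the detection rate of
#'   *non-veterans* (`a/(a+c)`) and specificity the recovery of veterans
#'   (`d/(b+d)`) — the convention under which the published validation
#'   figures (0.83 / 0.92) reconcile with the printed contingency table.
#' * `veteran_positive`: the conventional epidemiological orientation,
#'   sensitivity `d/(b+d)`, specificity `a/(a+c)`.
#'
#' The Youden index is `sensitivity + specificity - 1` under the declared
#' convention (its value is convention-invariant). Percent agreement
#' `(a+d)/n` is reported as a distinct field and never conflated with the
#' Youden index. Statistics with zero denominators are `NA` (explicitly
#' undefined, never 0). Values are stored unrounded; rounding belongs to
#' the print method.
#'
#' @param m An `msit_confusion`.
#' @param convention `"paper"` (default) or `"veteran_positive"` — which
#'   orientation the `sensitivity`/`specificity`/`youden_j` fields use; both
#'   orientations are always present as suffixed fields.
#' @return An object of class `msit_report` (a list of named statistics).
#' @export
validation_report <- function(m, convention = c("paper", "veteran_positive")) {
  convention <- match.arg(convention)
  stopifnot(inherits(m, "msit_confusion"))
  n <- m$a + m$b + m$c + m$d
  if (n == 0L) stop("zero-total confusion matrix", call. = FALSE)
  sens_paper <- safe_ratio(m$a, m$a + m$c)
  spec_paper <- safe_ratio(m$d, m$b + m$d)
  rep <- list(
    n = n,
    agreement = (m$a + m$d) / n,
    ppv_veteran = safe_ratio(m$d, m$c + m$d),
    npv_veteran = safe_ratio(m$a, m$a + m$b),
    sensitivity_paper = sens_paper,
    specificity_paper = spec_paper,
    sensitivity_std = spec_paper,
    specificity_std = sens_paper,
    prop_tool_nonveteran = safe_ratio(m$a + m$b, n),
    prop_tool_veteran = safe_ratio(m$c + m$d, n),
    positive_class_convention = convention
  )
  if (convention == "paper") {
    rep$sensitivity <- rep$sensitivity_paper
    rep$specificity <- rep$specificity_paper
  } else {
    rep$sensitivity <- rep$sensitivity_std
    rep$specificity <- rep$specificity_std
  }
  rep$youden_j <- rep$sensitivity + rep$specificity - 1
  structure(rep, class = "msit_report")
}

#' @export
print.msit_report <- function(x, digits = 2, ...) {
  fmt <- function(v) ifelse(is.na(v), "undefined", formatC(v, digits = digits,
                                                           format = "f"))
  cat(sprintf("Validation report (n = %d, convention: %s)\n", x$n,
              x$positive_class_convention))
  cat(sprintf("  agreement    %s (%.1f%%)\n", fmt(x$agreement),
              100 * x$agreement))
  cat(sprintf("  sensitivity  %s\n", fmt(x$sensitivity)))
  cat(sprintf("  specificity  %s\n", fmt(x$specificity)))
  cat(sprintf("  PPV(veteran) %s   NPV(veteran) %s\n", fmt(x$ppv_veteran),
              fmt(x$npv_veteran)))
  cat(sprintf("  Youden J     %s\n", fmt(x$youden_j)))
  cat(sprintf("  tool classifications: %.1f%% non-veteran / %.1f%% veteran\n",
              100 * x$prop_tool_nonveteran, 100 * x$prop_tool_veteran))
  invisible(x)
}

#' Stage-by-stage retention percentages of a cohort flow
#'
#' For each stage, the percentage retained of the previous stage,
#' `100 * count_out / count_in`, rounded to 1 decimal place; stages with a
#' zero denominator are `NA` (undefined).
#'
#' @param flow Data frame with `stage_name`, `count_in`, `count_out`
#'   forming a chain (`count_in` of stage k+1 equals `count_out` of
#'   stage k).
#' @return `flow` with an added `pct_retained` column.
#' @export
#' @examples
#' flow <- data.frame(stage_name = c("invited", "responded"),
#'                    count_in = c(1684, 902), count_out = c(902, 149))
#' flow_percentages(flow)
flow_percentages <- function(flow) {
  stopifnot(all(c("stage_name", "count_in", "count_out") %in% names(flow)))
  if (any(flow$count_out > flow$count_in)) {
    stop("count_out exceeds count_in", call. = FALSE)
  }
  flow$pct_retained <- ifelse(flow$count_in > 0,
                              round(100 * flow$count_out / flow$count_in, 1),
                              NA_real_)
  flow
}
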