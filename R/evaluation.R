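# Precision evaluation: two-reviewer adjudication, precision arithmetic,
# gold-standard comparison on synthetic corpora, and review sampling.

#' Adjudicate two-reviewer decisions
#'
#' Each NLP-positive unit is reviewed by two domain experts
#' (`confirm` / `reject` / `unsure`). Agreement fixes the final label;
#' disagreement (including any `unsure`) falls to the third reviewer when
#' present, and is otherwise left `unresolved` and blocked from precision
#' computation. The final label is never one that both reviewers rejected.
#'
#' @param records tibble with columns `unit_id`, `reviewer1`, `reviewer2`,
#'   and optionally `reviewer3` (NA when not consulted)
#' @return `records` with a `final` column:
#'   `true_positive` / `false_positive` / `unresolved`
#' @export
adjudicate <- function(records) {
  stopifnot(all(c("unit_id", "reviewer1", "reviewer2") %in% names(records)))
  if (!"reviewer3" %in% names(records)) records$reviewer3 <- NA_character_
  decide <- function(r1, r2, r3) {
    as_final <- function(x) switch(x, confirm = "true_positive",
                                   reject = "false_positive", "unresolved")
    if (r1 == r2 && r1 %in% c("confirm", "reject")) return(as_final(r1))
    if (!is.na(r3) && r3 %in% c("confirm", "reject")) return(as_final(r3))
    "unresolved"
  }
  records$final <- mapply(decide, records$reviewer1, records$reviewer2,
                          records$reviewer3, USE.NAMES = FALSE)
  records
}

#' Precision from identified and confirmed counts
#'
#' Precision is the proportion of review-confirmed true positives among all
#' NLP-identified positives. With zero identified units the value is not
#' available (`NA`), never zero and never a division error.
#'
#' @param n_identified NLP-identified positive units
#' @param n_confirmed review-confirmed true positives
#'   (`n_confirmed <= n_identified`)
#' @return list with `value` (proportion, `NA` if undefined) and `pct`
#'   (string formatted to 1 decimal, half-up)
#' @export
#' @examples
#' can_precision(422, 396)  # 93.8%
#' can_precision(311, 222)  # 71.4%
can_precision <- function(n_identified, n_confirmed) {
  stopifnot(n_identified >= 0, n_confirmed >= 0)
  if (n_confirmed > n_identified) {
    stop_fmt("n_confirmed (%d) exceeds n_identified (%d)",
             n_confirmed, n_identified)
  }
  value <- if (n_identified == 0) NA_real_ else n_confirmed / n_identified
  list(value = value, pct = format_pct(value, 1))
}

prf <- function(tp, fp, fn) {
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}

#' Compare predicted labels against a gold standard
#'
#' Computes precision, recall and F1 at sentence level (units keyed by
#' `note_id` + `sentence_index`) and document level (keyed by `note_id`).
#' Both label sets must cover the same unit universe.
#'
#' @param predicted,gold tibbles with columns `note_id`, `sentence_index`
#'   (sentence level only), `positive`
#' @param level `"sentence"` or `"document"`
#' @return tibble: `level`, `n_units`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`
#' @export
evaluate_against_gold <- function(predicted, gold,
                                  level = c("sentence", "document")) {
  level <- match.arg(level)
  keyof <- function(d) {
    if (level == "sentence") paste(d$note_id, d$sentence_index)
    else d$note_id
  }
  pk <- keyof(predicted); gk <- keyof(gold)
  if (anyDuplicated(pk) || anyDuplicated(gk)) {
    stop_fmt("duplicate %s units in labels", level)
  }
  if (!setequal(pk, gk)) {
    stop_fmt("predicted and gold cover different %s units (%d vs %d)",
             level, length(pk), length(gk))
  }
  g <- gold$positive[match(pk, gk)]
  p <- predicted$positive
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g)
  m <- prf(tp, fp, fn)
  tibble(level = level, n_units = length(pk), tp = tp, fp = fp, fn = fn,
         precision = m$precision, recall = m$recall, f1 = m$f1)
}

#' Build a manual-review worksheet from a patient sample
#'
#' Samples `n_patients` patients (seeded, uniform, without replacement)
#' among patients having NLP-positive sentences or notes, then lists every
#' NLP-positive sentence of the sampled patients with a +/-1-sentence
#' context window and empty reviewer columns, ready for adjudication.
#'
#' @param ann `can_annotations` object
#' @param notes corpus tibble (to map notes to patients)
#' @param n_patients number of patients to sample
#' @param seed integer seed
#' @return tibble: `unit_id`, `note_id`, `patient_id`, `sentence_index`,
#'   `context`, `sentence`, `reviewer1`, `reviewer2`, `reviewer3`
#' @export
sample_for_review <- function(ann, notes, n_patients, seed) {
  stopifnot(inherits(ann, "can_annotations"))
  patients <- sort(unique(notes$patient_id))
  if (n_patients > length(patients)) {
    stop_fmt("requested %d patients but corpus has %d", n_patients,
             length(patients))
  }
  chosen <- withr::with_seed(seed, sample(patients, n_patients))
  note_ids <- notes$note_id[notes$patient_id %in% chosen]
  sl <- ann$sentence_labels
  pos <- sl[sl$positive & sl$note_id %in% note_ids, , drop = FALSE]
  if (nrow(pos) == 0) {
    return(tibble(unit_id = character(), note_id = character(),
                  patient_id = character(), sentence_index = integer(),
                  context = character(), sentence = character(),
                  reviewer1 = character(), reviewer2 = character(),
                  reviewer3 = character()))
  }
  sent <- ann$sentences
  skey <- paste(sent$note_id, sent$index)
  ctx <- function(nid, idx) {
    window <- match(paste(nid, (idx - 1):(idx + 1)), skey)
    paste(sent$text[window[!is.na(window)]], collapse = " ")
  }
  tibble(
    unit_id = paste0(pos$note_id, ":", pos$sentence_index),
    note_id = pos$note_id,
    patient_id = notes$patient_id[match(pos$note_id, notes$note_id)],
    sentence_index = pos$sentence_index,
    context = mapply(ctx, pos$note_id, pos$sentence_index,
                     USE.NAMES = FALSE),
    sentence = sent$text[match(paste(pos$note_id, pos$sentence_index),
                               skey)],
    reviewer1 = "", reviewer2 = "", reviewer3 = ""
  )
}

#' Precision table from adjudicated review records
#'
#' Aggregates adjudicated records into identified / confirmed counts and a
#' formatted precision, mirroring the standard evaluation-table layout
#' (Resource, Sample, NLP identified, Manual confirmed, Precision).
#' Unresolved records are an error: resolve them before computing precision.
#'
#' @param records adjudicated records ([adjudicate()] output)
#' @param level label for the table row (e.g. `"sentence"`)
#' @param n_sample size of the reviewed sample (defaults to row count)
#' @return one-row tibble: `level`, `n_sample`, `n_identified`,
#'   `n_confirmed`, `precision`, `precision_pct`
#' @export
review_precision <- function(records, level = "sentence",
                             n_sample = nrow(records)) {
  if (any(records$final == "unresolved")) {
    stop_fmt("%d unresolved record(s); resolve before computing precision",
             sum(records$final == "unresolved"))
  }
  n_identified <- nrow(records)
  n_confirmed <- sum(records$final == "true_positive")
  p <- can_precision(n_identified, n_confirmed)
  tibble(level = level, n_sample = n_sample, n_identified = n_identified,
         n_confirmed = n_confirmed, precision = p$value,
         precision_pct = p$pct)
}
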