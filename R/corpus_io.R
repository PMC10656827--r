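# Corpus ingestion, cleaning and patient-level partitioning.

CORPUS_COLUMNS <- c("note_id", "patient_id", "note_type",
                    "provider_category", "date", "text")

PROVIDER_CATEGORIES <- c("physician", "nurse", "social_worker", "other",
                         "unknown")

#' Read a clinical-note corpus
#'
#' Accepts JSON Lines (one note object per line) or CSV with columns
#' `note_id`, `patient_id`, `note_type`, `provider_category`, `date`,
#' `text`. Records lacking `note_id` or `patient_id` ("orphan" records) are
#' rejected but do not stop the run: they are collected, with line numbers
#' and a reason, in the `rejected` attribute of the result. Unknown
#' note types pass through relabelled "Not Specified"; unknown provider
#' categories become "unknown".
#'
#' @param path file path
#' @param format `"auto"` (by extension), `"jsonl"`, or `"csv"`
#' @return tibble of valid notes; attribute `rejected` is a tibble
#'   (`line`, `reason`)
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl"
              else "csv"
  }
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- vector("list", length(lines))
    rejected <- list()
    for (i in seq_along(lines)) {
      obj <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
      if (is.null(obj) || !is.list(obj)) {
        rejected[[length(rejected) + 1]] <-
          tibble(line = i, reason = "malformed JSON")
        next
      }
      recs[[i]] <- obj
    }
    keep <- !vapply(recs, is.null, TRUE)
    df <- dplyr::bind_rows(lapply(recs[keep], function(o) {
      o <- o[intersect(names(o), CORPUS_COLUMNS)]
      as_tibble(lapply(o, as.character))
    }))
    df$.line <- which(keep)
  } else {
    raw <- utils::read.csv(path, colClasses = "character", na.strings = NULL,
                           fileEncoding = "UTF-8")
    df <- as_tibble(raw)
    df$.line <- seq_len(nrow(df)) + 1L  # header is line 1
    rejected <- list()
  }
  for (col in CORPUS_COLUMNS) if (is.null(df[[col]])) df[[col]] <- ""
  df[CORPUS_COLUMNS] <- lapply(df[CORPUS_COLUMNS],
                               function(x) ifelse(is.na(x), "", x))
  bad <- !nzchar(df$note_id) | !nzchar(df$patient_id)
  if (any(bad)) {
    rejected <- c(rejected, list(tibble(
      line = df$.line[bad],
      reason = ifelse(!nzchar(df$note_id[bad]), "missing note_id",
                      "missing patient_id (orphan)"))))
  }
  notes <- df[!bad, CORPUS_COLUMNS, drop = FALSE]
  if (anyDuplicated(notes$note_id)) {
    stop_fmt("duplicate note_id in corpus: '%s'",
             notes$note_id[duplicated(notes$note_id)][1])
  }
  notes$note_type <- ifelse(nzchar(trimws(notes$note_type)),
                            trimws(notes$note_type), "Not Specified")
  notes$provider_category <- ifelse(
    notes$provider_category %in% PROVIDER_CATEGORIES,
    notes$provider_category, "unknown")
  rej <- if (length(rejected) > 0) dplyr::bind_rows(rejected)
         else tibble(line = integer(), reason = character())
  attr(notes, "rejected") <- rej
  notes
}

#' Write a corpus to JSONL or CSV
#'
#' @param notes corpus tibble
#' @param path output path
#' @param format `"auto"` (by extension), `"jsonl"`, or `"csv"`
#' @return `path`, invisibly
#' @export
write_corpus <- function(notes, path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl"
              else "csv"
  }
  out <- notes[CORPUS_COLUMNS]
  if (format == "jsonl") {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(out))) {
      writeLines(jsonlite::toJSON(as.list(out[i, ]), auto_unbox = TRUE), con)
    }
  } else {
    utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Remove duplicated notes
#'
#' Notes with identical (`patient_id`, `note_type`, `text`) are collapsed to
#' the earliest-dated instance (ties broken by `note_id` for determinism).
#' The number of removals is attached as attribute `n_removed` and reported
#' via `message()`.
#'
#' @param notes corpus tibble
#' @return deduplicated tibble, original order preserved
#' @export
deduplicate_notes <- function(notes) {
  if (nrow(notes) == 0) {
    attr(notes, "n_removed") <- 0L
    return(notes)
  }
  key <- paste(notes$patient_id, notes$note_type, notes$text, sep = "\r")
  ord <- order(key, notes$date, notes$note_id)
  keep_ids <- notes$note_id[ord][!duplicated(key[ord])]
  out <- notes[notes$note_id %in% keep_ids, , drop = FALSE]
  n_removed <- nrow(notes) - nrow(out)
  attr(out, "n_removed") <- n_removed
  message(n_removed, " duplicate note(s) removed")
  out
}

#' Partition a corpus by patient
#'
#' Patients are shuffled with the given seed and the first
#' `ceiling(train_frac * P)` assigned to the training partition; every note
#' follows its patient, so no patient ever appears in both sets.
#'
#' @param notes corpus tibble (at least 2 patients)
#' @param train_frac fraction of patients for training (default 0.75)
#' @param seed integer seed
#' @return object of class `corpus_split`: list with `train_patients`,
#'   `test_patients`, `seed`
#' @export
split_by_patient <- function(notes, train_frac = 0.75, seed) {
  if (train_frac <= 0 || train_frac >= 1) {
    stop_fmt("train_frac must be in (0, 1), got %s", train_frac)
  }
  patients <- sort(unique(notes$patient_id))
  if (length(patients) < 2) stop_fmt("need at least 2 patients to split")
  shuffled <- withr::with_seed(seed, sample(patients))
  n_train <- ceiling(train_frac * length(patients))
  structure(list(train_patients = sort(shuffled[seq_len(n_train)]),
                 test_patients = sort(shuffled[-seq_len(n_train)]),
                 seed = seed),
            class = "corpus_split")
}

#' @export
print.corpus_split <- function(x, ...) {
  cat("<corpus_split>", length(x$train_patients), "train /",
      length(x$test_patients), "test patients (seed", paste0(x$seed, ")\n"))
  invisible(x)
}

#' Notes belonging to one side of a split
#'
#' @param notes corpus tibble
#' @param split `corpus_split` object
#' @param which `"train"` or `"test"`
#' @return subset of `notes`
#' @export
split_notes <- function(notes, split, which = c("train", "test")) {
  which <- match.arg(which)
  ids <- if (which == "train") split$train_patients else split$test_patients
  notes[notes$patient_id %in% ids, , drop = FALSE]
}

#' Sample patients and return all their notes
#'
#' Seeded uniform sample of `n` patients without replacement; the result
#' contains every note of each sampled patient.
#'
#' @param notes corpus tibble
#' @param n number of patients
#' @param seed integer seed
#' @return subset of `notes`
#' @export
sample_patients <- function(notes, n, seed) {
  patients <- sort(unique(notes$patient_id))
  if (n > length(patients)) {
    stop_fmt("requested %d patients but corpus has only %d", n,
             length(patients))
  }
  chosen <- withr::with_seed(seed, sample(patients, n))
  notes[notes$patient_id %in% chosen, , drop = FALSE]
}
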