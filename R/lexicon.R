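#' Normalize a lexicon term or suggestion
#'
#' Lowercases, treats hyphens as token separators, strips leading/trailing
#' punctuation, and collapses internal whitespace. Clinical text is
#' typographically noisy; all dictionary surfaces and free-text suggestions
#' pass through this before comparison.
#'
#' @param x character vector
#' @return normalized character vector
#' @export
#' @examples
#' normalize_term("  Child--Protective  Services. ")
normalize_term <- function(x) {
  x <- tolower(x)
  x <- gsub("[-/]+", " ", x)
  x <- gsub("^[[:punct:][:space:]]+|[[:punct:][:space:]]+$", "", x)
  x <- gsub("[[:space:]]+", " ", x)
  x
}

#' Summarize expert survey ratings per term
#'
#' Experts rate each candidate term on a 3-point importance scale
#' (1 = not important, 2 = somewhat important, 3 = critical for inclusion).
#' For each term this computes the number of raters, the mean rating over
#' raters who rated it, and the fraction of those raters giving a score of
#' at least `min_rating`.
#'
#' @param ratings data frame with columns `respondent_id`, `term`, `rating`
#'   (integer 1-3); one row per (respondent, term)
#' @param min_rating score counted as an endorsement (default 2)
#' @return tibble with columns `term`, `n_raters`, `mean_rating`,
#'   `prop_at_least_2`, in first-appearance order of `term`
#' @export
aggregate_ratings <- function(ratings, min_rating = 2) {
  stopifnot(all(c("respondent_id", "term", "rating") %in% names(ratings)))
  if (nrow(ratings) == 0) stop_fmt("no ratings supplied")
  if (!all(ratings$rating %in% 1:3)) {
    stop_fmt("ratings must be integers in {1, 2, 3}")
  }
  ratings %>%
    dplyr::mutate(term = factor(.data$term, levels = unique(.data$term))) %>%
    dplyr::group_by(term = .data$term) %>%
    dplyr::summarise(
      n_raters = dplyr::n(),
      mean_rating = mean(.data$rating),
      prop_at_least_2 = mean(.data$rating >= min_rating),
      .groups = "drop"
    ) %>%
    dplyr::mutate(term = as.character(.data$term))
}

#' Apply the lexicon retention rule to a rating summary
#'
#' A term is retained when at least `min_prop` (default 80%) of its raters
#' scored it `min_rating` (default 2) or higher. Ties at exactly the
#' threshold are retained ("at least 80%"). Order is preserved and the
#' decision is deterministic.
#'
#' @param summary output of [aggregate_ratings()]
#' @param min_rating documented endorsement threshold (informational; the
#'   proportion in `summary` was computed against it)
#' @param min_prop minimum endorsing fraction (default 0.80)
#' @return `summary` filtered to retained terms
#' @export
retain_terms <- function(summary, min_rating = 2, min_prop = 0.80) {
  stopifnot(all(c("term", "prop_at_least_2") %in% names(summary)))
  summary[!is.na(summary$prop_at_least_2) &
            summary$prop_at_least_2 >= min_prop, , drop = FALSE]
}

#' Collect free-text term suggestions endorsed by enough respondents
#'
#' Suggestions are normalized (see [normalize_term()]) and merged by exact
#' string equality; a suggestion becomes a candidate for the next survey
#' round when the number of distinct endorsing respondents reaches
#' `min_frac` of the round's respondents. Empty suggestions are ignored.
#'
#' @param suggestions data frame with columns `respondent_id`, `suggestion`
#' @param n_respondents number of respondents in the round (denominator)
#' @param min_frac minimum endorsing fraction (default 0.10)
#' @return tibble with columns `term`, `n_endorsers`, `frac`, candidates only,
#'   in first-appearance order
#' @export
collect_suggestions <- function(suggestions, n_respondents, min_frac = 0.10) {
  stopifnot(all(c("respondent_id", "suggestion") %in% names(suggestions)),
            n_respondents >= 1)
  s <- suggestions
  s$term <- normalize_term(s$suggestion)
  s <- s[nzchar(s$term), , drop = FALSE]
  if (nrow(s) == 0) {
    return(tibble(term = character(), n_endorsers = integer(), frac = double()))
  }
  s <- s[!duplicated(s[c("respondent_id", "term")]), , drop = FALSE]
  out <- s %>%
    dplyr::mutate(term = factor(.data$term, levels = unique(.data$term))) %>%
    dplyr::count(term = .data$term, name = "n_endorsers") %>%
    dplyr::mutate(term = as.character(.data$term),
                  frac = .data$n_endorsers / n_respondents)
  out[out$frac >= min_frac, , drop = FALSE]
}

LEXICON_COLUMNS <- c("term", "variants", "subtype", "specificity", "source",
                     "mean_rating", "prop_at_least_2")

validate_lexicon <- function(lex, where = "lexicon") {
  missing <- setdiff(LEXICON_COLUMNS, names(lex))
  if (length(missing) > 0) {
    stop_fmt("%s is missing columns: %s", where, paste(missing, collapse = ", "))
  }
  bad <- which(!lex$subtype %in% can_subtypes())
  if (length(bad) > 0) {
    stop_fmt("%s row %d: unknown subtype '%s' (allowed: %s)",
             where, bad[1], lex$subtype[bad[1]],
             paste(can_subtypes(), collapse = ", "))
  }
  bad <- which(!lex$specificity %in% c("standard", "low"))
  if (length(bad) > 0) {
    stop_fmt("%s row %d: specificity must be 'standard' or 'low', got '%s'",
             where, bad[1], lex$specificity[bad[1]])
  }
  key <- paste(lex$term, lex$subtype, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- lex$term[duplicated(key)][1]
    stop_fmt("%s: duplicate (term, subtype) entry '%s'", where, dup)
  }
  if (any(!nzchar(normalize_term(lex$term)))) {
    stop_fmt("%s: empty term after normalization", where)
  }
  if (any(!is.na(lex$mean_rating) & is.na(lex$prop_at_least_2))) {
    stop_fmt("%s: mean_rating present without prop_at_least_2", where)
  }
  invisible(lex)
}

#' Read a CAN lexicon from a tab-separated file
#'
#' The TSV has a header row with columns `term`, `variants` (|-separated
#' alternative surfaces, may be empty), `subtype` (one of the five CAN
#' subtypes), `specificity` (`standard`, or `low` for terms that require
#' corroboration), `source`, `mean_rating`, `prop_at_least_2` (last two may
#' be empty). Unknown subtypes and duplicate (term, subtype) pairs are hard
#' errors naming the offending row.
#'
#' @param path TSV file path
#' @return tibble, one row per lexicon term
#' @seealso [write_lexicon()], [starter_lexicon()]
#' @export
read_lexicon <- function(path) {
  lex <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = NULL,
                           quote = "", fileEncoding = "UTF-8")
  lex <- as_tibble(lex)
  lex$mean_rating <- suppressWarnings(as.numeric(lex$mean_rating))
  lex$prop_at_least_2 <- suppressWarnings(as.numeric(lex$prop_at_least_2))
  validate_lexicon(lex, where = basename(path))
}

#' Write a CAN lexicon to a tab-separated file
#'
#' @param lexicon tibble as returned by [read_lexicon()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_lexicon <- function(lexicon, path) {
  validate_lexicon(lexicon)
  out <- lexicon[LEXICON_COLUMNS]
  out$mean_rating <- ifelse(is.na(out$mean_rating), "",
                            format(out$mean_rating, trim = TRUE))
  out$prop_at_least_2 <- ifelse(is.na(out$prop_at_least_2), "",
                                format(out$prop_at_least_2, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' The bundled starter CAN lexicon
#'
#' The expert-validated lexicon used in the original screening study is not
#' published in full; this starter dictionary is the union of all surfaces
#' printed in that study's report (subtype examples, the most frequent
#' entities, and the five low-specificity terms flagged during evaluation).
#' It is a starting point: the TSV format is the extension mechanism for
#' site-specific dictionaries.
#'
#' @return lexicon tibble (see [read_lexicon()])
#' @export
starter_lexicon <- function() {
  read_lexicon(system.file("extdata", "starter_lexicon.tsv",
                           package = "canscreen", mustWork = TRUE))
}

#' Compile a lexicon into a token-boundary matcher
#'
#' Builds the lookup structure used for dictionary named-entity recognition.
#' Every canonical surface and every variant becomes a token-sequence
#' pattern. Matching is case-insensitive, except that all-uppercase variants
#' of up to 4 characters (clinical abbreviations such as "SA") match
#' case-sensitively, so lowercase homographs ("sa") do not fire.
#'
#' @param lexicon lexicon tibble
#' @return object of class `can_matcher`
#' @seealso [match_entities()]
#' @export
compile_matcher <- function(lexicon) {
  validate_lexicon(lexicon)
  if (nrow(lexicon) == 0) stop_fmt("cannot compile an empty lexicon")
  entries <- list()
  for (i in seq_len(nrow(lexicon))) {
    surfaces <- c(lexicon$term[i],
                  strsplit(lexicon$variants[i], "|", fixed = TRUE)[[1]])
    surfaces <- surfaces[nzchar(trimws(surfaces))]
    for (s in surfaces) {
      s <- trimws(s)
      case_sensitive <- nchar(s) <= 4 && s == toupper(s) && grepl("[A-Z]", s)
      toks <- word_tokens(if (case_sensitive) s else normalize_term(s))
      if (length(toks) == 0) next
      entries[[length(entries) + 1]] <- list(
        tokens = toks,
        case_sensitive = case_sensitive,
        lexicon_surface = lexicon$term[i],
        subtype = lexicon$subtype[i],
        specificity = lexicon$specificity[i],
        priority = subtype_priority(lexicon$subtype[i])
      )
    }
  }
  # index entries by first token for O(1) candidate retrieval
  index <- new.env(parent = emptyenv())
  for (e in entries) {
    key <- if (e$case_sensitive) e$tokens[1] else tolower(e$tokens[1])
    index[[key]] <- c(index[[key]], list(e))
  }
  structure(list(index = index, n_terms = nrow(lexicon)),
            class = "can_matcher")
}

#' @export
print.can_matcher <- function(x, ...) {
  cat("<can_matcher> compiled from", x$n_terms, "lexicon terms\n")
  invisible(x)
}

# word tokens of a phrase (no punctuation tokens), preserving case
word_tokens <- function(x) {
  toks <- regmatches(x, gregexpr("[A-Za-z0-9]+", x))[[1]]
  toks
}
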