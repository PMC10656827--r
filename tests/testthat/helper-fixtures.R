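# Shared fixtures: tiny lexicons, note builders, and an independent
# brute-force matching oracle used to validate the compiled matcher.

make_lexicon <- function(terms, subtypes = "ABUSE", specificity = "standard",
                         variants = "") {
  tibble::tibble(
    term = terms,
    variants = rep_len(variants, length(terms)),
    subtype = rep_len(subtypes, length(terms)),
    specificity = rep_len(specificity, length(terms)),
    source = "investigator",
    mean_rating = NA_real_,
    prop_at_least_2 = NA_real_
  )
}

make_note <- function(text, note_id = "n1", patient_id = "p1",
                      note_type = "Progress Notes",
                      provider_category = "physician",
                      date = "2015-06-01") {
  tibble::tibble(note_id = note_id, patient_id = patient_id,
                 note_type = note_type,
                 provider_category = provider_category,
                 date = date, text = text)
}

# Brute-force oracle: enumerate EVERY (position, phrase) match over word
# tokens, then select left to right, longest first, subtype priority on
# ties — written independently of the compiled-matcher code path.
oracle_match <- function(lexicon, tokens) {
  wt <- tokens[tokens$is_word, , drop = FALSE]
  words <- wt$token
  prio <- c(SEXUAL_ABUSE = 1, PHYSICAL_INDICATION = 2,
            EMOTIONAL_INDICATION = 3, ABUSE = 4, SERVICE = 5)
  cands <- list()
  for (i in seq_len(nrow(lexicon))) {
    surfaces <- c(lexicon$term[i],
                  strsplit(lexicon$variants[i], "|", fixed = TRUE)[[1]])
    surfaces <- trimws(surfaces[nzchar(trimws(surfaces))])
    for (s in surfaces) {
      cs <- nchar(s) <= 4 && s == toupper(s) && grepl("[A-Z]", s)
      ptoks <- regmatches(gsub("[-/]+", " ", s),
                          gregexpr("[A-Za-z0-9]+", gsub("[-/]+", " ", s)))[[1]]
      k <- length(ptoks)
      if (k == 0) next
      for (p in seq_len(max(0, length(words) - k + 1))) {
        seg <- words[p:(p + k - 1)]
        ok <- if (cs) identical(seg, ptoks)
              else identical(tolower(seg), tolower(ptoks))
        if (ok) {
          cands[[length(cands) + 1]] <- list(
            pos = p, k = k, surface = lexicon$term[i],
            subtype = lexicon$subtype[i], prio = prio[[lexicon$subtype[i]]])
        }
      }
    }
  }
  # leftmost-longest non-overlapping selection
  picked <- list()
  pos <- 1
  while (pos <= length(words)) {
    here <- Filter(function(c) c$pos == pos, cands)
    if (length(here) == 0) { pos <- pos + 1; next }
    ks <- vapply(here, function(c) c$k, 0)
    here <- here[ks == max(ks)]
    ps <- vapply(here, function(c) c$prio, 0)
    best <- here[[which.min(ps)]]
    picked[[length(picked) + 1]] <- best
    pos <- pos + best$k
  }
  tibble::tibble(
    begin = vapply(picked, function(h) wt$begin[h$pos], 0L),
    end = vapply(picked, function(h) wt$end[h$pos + h$k - 1], 0L),
    lexicon_surface = vapply(picked, function(h) h$surface, ""),
    subtype = vapply(picked, function(h) h$subtype, "")
  )
}

# word pool for fuzzing lexicon/text pairs
FUZZ_WORDS <- c("abuse", "rape", "neglect", "care", "foster", "child",
                "protective", "services", "bruise", "visit", "clinic",
                "home", "report", "exam", "team", "SA", "burn", "police",
                "history", "note")

random_fuzz_case <- function() {
  n_terms <- sample(1:5, 1)
  terms <- unique(replicate(n_terms, paste(
    sample(tolower(FUZZ_WORDS), sample(1:3, 1)), collapse = " ")))
  lex <- make_lexicon(terms,
                      subtypes = sample(can_subtypes(), length(terms),
                                        replace = TRUE))
  text <- paste(sample(FUZZ_WORDS, sample(3:12, 1), replace = TRUE),
                collapse = " ")
  list(lexicon = lex, text = text)
}
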