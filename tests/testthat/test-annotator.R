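test_that("sentence splitting follows clinical punctuation rules", {
  s <- split_sentences("Pt doing well. Denies abuse.")
  expect_equal(nrow(s), 2)
  expect_equal(s$text, c("Pt doing well.", "Denies abuse."))
  expect_equal(nrow(split_sentences("")), 0)
  # colon does not split agrammatical header language
  one <- split_sentences(paste("sexual abuse health since last visit:",
                               "No illnesses, ER visits, or hospitalizations"))
  expect_equal(nrow(one), 1)
  # abbreviations suppress the period boundary
  expect_equal(nrow(split_sentences("Seen by Dr. Smith today.")), 1)
  expect_equal(nrow(split_sentences("Takes 5 mg. daily. Doing well.")), 2)
  # blank-line runs and list markers split
  expect_equal(nrow(split_sentences("Plan\n\nFollow up")), 2)
  expect_equal(nrow(split_sentences("Plan:\n- rest\n- fluids")), 3)
})

test_that("sentence spans reconstruct the note text", {
  texts <- c("Pt doing well. Denies abuse. Follow up in 2 wk.",
             "A?! B.\n\nC: d e f.  G yes.",
             "one\n- two\n- three")
  for (tx in texts) {
    s <- split_sentences(tx, note_id = "n")
    for (i in seq_len(nrow(s))) {
      expect_equal(substr(tx, s$begin[i] + 1, s$end[i]), s$text[i])
    }
    expect_true(all(diff(s$begin) > 0))
    expect_true(all(s$end <= nchar(tx)))
  }
})

test_that("tokenization yields alphanumeric runs with exact spans", {
  t1 <- can_tokenize("child protective services")
  expect_equal(t1$token, c("child", "protective", "services"))
  t2 <- can_tokenize("2nd-degree burn")
  expect_equal(t2$token, c("2nd", "-", "degree", "burn"))
  expect_equal(t2$is_word, c(TRUE, FALSE, TRUE, TRUE))
  # span contract under fuzzing
  set.seed(1)
  for (i in 1:50) {
    tx <- paste(sample(c(FUZZ_WORDS, ".", ",", "-", "2nd", "a/b"),
                       sample(1:10, 1), replace = TRUE), collapse = " ")
    tk <- can_tokenize(tx, offset = 0L)
    for (j in seq_len(nrow(tk))) {
      expect_equal(substr(tx, tk$begin[j] + 1, tk$end[j]), tk$token[j])
    }
  }
})

test_that("entity matching is leftmost-longest with subtype priority", {
  lex <- make_lexicon(c("abuse", "physical abuse"),
                      subtypes = c("ABUSE", "ABUSE"))
  m <- compile_matcher(lex)
  hit <- match_entities(can_tokenize("history of physical abuse"), m)
  expect_equal(hit$lexicon_surface, "physical abuse")

  hit2 <- match_entities(
    can_tokenize("referred to child protective services today"),
    compile_matcher(starter_lexicon()))
  expect_equal(hit2$lexicon_surface, "child protective services")
  expect_equal(hit2$subtype, "SERVICE")

  expect_equal(nrow(match_entities(can_tokenize("no lexicon words here"),
                                   m)), 0)
})

test_that("compiled matcher agrees with the brute-force oracle", {
  set.seed(99)
  for (i in 1:500) {
    case <- random_fuzz_case()
    toks <- can_tokenize(case$text)
    got <- match_entities(toks, compile_matcher(case$lexicon))
    want <- oracle_match(case$lexicon, toks)
    expect_equal(got$begin, want$begin, info = case$text)
    expect_equal(got$end, want$end, info = case$text)
    expect_equal(got$lexicon_surface, want$lexicon_surface,
                 info = case$text)
    expect_equal(got$subtype, want$subtype, info = case$text)
  }
})

annotate_one <- function(text, lexicon = starter_lexicon(), ...) {
  annotate_corpus(make_note(text), lexicon, ...)
}

test_that("negation triggers and terminators behave as specified", {
  m <- compile_matcher(starter_lexicon())
  run <- function(text) {
    toks <- can_tokenize(text)
    detect_negation(match_entities(toks, m), toks)
  }
  expect_true(run("denies any abuse at home")$negated)
  expect_true(run("no signs of neglect")$negated)
  expect_true(run("patient is negative for bruise today")$negated)
  # terminator blocks the scope
  r <- run("denies pain but reports abuse by stepfather")
  expect_false(r$negated)
  # beyond the 6-token scope the trigger does not reach
  far <- run("no acute distress was observed at the visit since abuse")
  expect_true(nrow(far) == 1 && !far$negated)
  expect_false(run("pt discloses abuse by neighbor")$negated)
})

test_that("exclusion rules fire on their false-positive patterns only", {
  ann <- annotate_one("Abbreviations: AV = alleged victim, AO = alleged offender.")
  expect_true(all(ann$mentions$excluded))
  expect_true(all(ann$mentions$exclusion_rule_id == "r2"))

  ann <- annotate_one(paste("First Aid: Burns Call 911 immediately if the",
                            "victim has any burn over a large area."))
  expect_true(all(ann$mentions$excluded))
  expect_equal(unique(ann$mentions$exclusion_rule_id), "r3")

  ann <- annotate_one(paste("sexual abuse health since last visit: No",
                            "illnesses, ER visits, or hospitalizations"))
  expect_true(all(ann$mentions$excluded))
  expect_equal(unique(ann$mentions$exclusion_rule_id), "r4")

  ann <- annotate_one("Per the mother a history of rape was reported years ago.")
  expect_true(all(ann$mentions$excluded))
  expect_equal(unique(ann$mentions$exclusion_rule_id), "r1")

  ann <- annotate_one("Pt was screened for STD (sexually transmitted disease at the visit.")
  expect_true(all(ann$mentions$excluded))
  expect_equal(unique(ann$mentions$exclusion_rule_id), "r5")

  # a genuine disclosure is untouched
  ann <- annotate_one("pt discloses abuse by neighbor")
  expect_false(any(ann$mentions$excluded))
  expect_true(ann$document_labels$positive)
})

test_that("unknown exclusion rule kinds are a load-time error", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("rules:", "  - rule_id: rx", "    kind: regex_magic",
               "    scope: sentence"), path)
  expect_error(read_exclusion_rules(path), "unknown kind")
})

test_that("low-specificity terms require a corroborating standard mention", {
  # lone low-specificity mention -> excluded -> document negative
  ann <- annotate_one("The police were called to the school.")
  expect_true(all(ann$mentions$excluded))
  expect_equal(unique(ann$mentions$exclusion_rule_id), "low_specificity")
  expect_false(ann$document_labels$positive)

  # corroborated within the window -> retained
  txt <- paste("Filler sentence one. Filler sentence two. Filler three.",
               "The police were called. Referred to child protective",
               "services today.")
  ann <- annotate_corpus(make_note(txt))
  pol <- ann$mentions[ann$mentions$lexicon_surface == "police", ]
  expect_false(pol$excluded)

  # window 0: corroboration must be in the same sentence
  ann0 <- annotate_corpus(make_note(txt), corroboration_window = 0)
  pol0 <- ann0$mentions[ann0$mentions$lexicon_surface == "police", ]
  expect_true(pol0$excluded)
  # negated standard mentions do not corroborate
  ann_neg <- annotate_corpus(make_note(
    "The police were called. Pt denies abuse at this time."))
  poln <- ann_neg$mentions[ann_neg$mentions$lexicon_surface == "police", ]
  expect_true(poln$excluded)
})

test_that("sentence and document classification follow the any-mention rule", {
  ann <- annotate_one("Referred to child protective services today.")
  expect_true(ann$sentence_labels$positive)
  expect_equal(ann$sentence_labels$active_subtypes, "SERVICE")
  expect_true(ann$document_labels$positive)

  # only a negated mention -> negative
  ann <- annotate_one("Pt denies abuse at this time.")
  expect_false(any(ann$sentence_labels$positive))
  expect_false(ann$document_labels$positive)

  # one positive among many sentences flips the document
  filler <- paste(rep("Routine follow up visit.", 39), collapse = " ")
  ann <- annotate_one(paste(filler, "Pt discloses abuse by neighbor."))
  expect_equal(sum(ann$sentence_labels$positive), 1)
  expect_true(ann$document_labels$positive)
  expect_equal(ann$document_labels$n_positive_sentences, 1L)

  # empty note -> zero sentences, negative document
  ann <- annotate_one("")
  expect_equal(nrow(ann$sentences), 0)
  expect_false(ann$document_labels$positive)
})

test_that("planting a denial flips a positive sentence to negative", {
  set.seed(7)
  lex <- starter_lexicon()
  terms <- lex$term[lex$specificity == "standard"]
  for (term in sample(terms, 10)) {
    base <- paste0("Pt reports ", term, " at home.")
    negd <- paste0("Pt reports denies ", term, " at home.")
    a1 <- annotate_one(base)
    a2 <- annotate_one(negd)
    expect_true(a1$sentence_labels$positive, info = term)
    expect_false(a2$sentence_labels$positive, info = term)
  }
})

test_that("adding exclusion rules never increases positive sentences", {
  gen <- generate_corpus(synth_spec(seed = 21, n_patients = 40,
                                    positive_note_rate = 0.15,
                                    trap_rates = c(trap_r1 = 0.05,
                                                   trap_r2 = 0.05,
                                                   trap_r3 = 0.05,
                                                   trap_r4 = 0.05,
                                                   trap_r5 = 0.05)))
  rules <- default_exclusion_rules()
  n_pos <- vapply(0:5, function(k) {
    ann <- annotate_corpus(gen$notes, exclusions = TRUE,
                           exclusion_rules = rules[seq_len(k)])
    sum(ann$sentence_labels$positive)
  }, 0)
  expect_true(all(diff(n_pos) <= 0))
})

test_that("annotation output is deterministic and serializable", {
  gen <- generate_corpus(synth_spec(seed = 5, n_patients = 10,
                                    positive_note_rate = 0.3))
  a1 <- annotate_corpus(gen$notes)
  a2 <- annotate_corpus(gen$notes)
  expect_identical(a1$mentions, a2$mentions)
  expect_identical(a1$document_labels, a2$document_labels)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_annotations(a1, d1)
  write_annotations(a2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # BRAT standoff spans slice back to the matched surface
  bd <- withr::local_tempdir()
  write_brat(a1, bd)
  ann_files <- list.files(bd, pattern = "\\.ann$", full.names = TRUE)
  expect_gt(length(ann_files), 0)
  t_lines <- grep("^T", readLines(ann_files[1]), value = TRUE)
  parts <- strsplit(t_lines, "\t")
  nid <- sub("\\.ann$", "", basename(ann_files[1]))
  note_text <- gen$notes$text[gen$notes$note_id == nid]
  for (p in parts) {
    span <- as.integer(strsplit(p[2], " ")[[1]][2:3])
    expect_equal(substr(note_text, span[1] + 1, span[2]), p[3])
  }
})
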