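test_that("generation is byte-identical for a fixed spec and seed", {
  spec <- synth_spec(seed = 101, n_patients = 20)
  g1 <- generate_corpus(spec)
  g2 <- generate_corpus(spec)
  expect_identical(g1$notes$text, g2$notes$text)
  expect_identical(g1$gold, g2$gold)
})

test_that("zero positive rate yields zero gold-positive sentences", {
  gen <- generate_corpus(synth_spec(seed = 7, n_patients = 30,
                                    positive_note_rate = 0))
  expect_equal(sum(gen$gold$planted_kind == "positive"), 0)
  gl <- gold_labels(gen$notes, gen$gold)
  expect_false(any(gl$sentence$positive))
})

test_that("planted subtype proportions track the requested mixture", {
  mix <- c(SERVICE = 0.67, ABUSE = 0.22, SEXUAL_ABUSE = 0.06,
           PHYSICAL_INDICATION = 0.05, EMOTIONAL_INDICATION = 0)
  gen <- generate_corpus(synth_spec(seed = 23, n_patients = 1500,
                                    notes_per_patient = c(2, 3),
                                    positive_note_rate = 1,
                                    negation_rate = 0,
                                    trap_rates = c(trap_r1 = 0, trap_r2 = 0,
                                                   trap_r3 = 0, trap_r4 = 0,
                                                   trap_r5 = 0)))
  plants <- gen$gold[gen$gold$planted_kind == "positive", ]
  expect_gt(nrow(plants), 4000)
  emp <- prop.table(table(factor(plants$subtype, levels = names(mix))))
  expect_true(all(abs(as.numeric(emp) - mix) <= 0.02))
})

test_that("gold spans slice to the planted lexicon surface", {
  gen <- generate_corpus(synth_spec(seed = 3, n_patients = 60,
                                    positive_note_rate = 0.3,
                                    negation_rate = 0.2,
                                    trap_rates = c(trap_r1 = 0.05,
                                                   trap_r2 = 0.05,
                                                   trap_r3 = 0.05,
                                                   trap_r4 = 0.05,
                                                   trap_r5 = 0.05)))
  expect_gt(nrow(gen$gold), 30)
  for (i in seq_len(nrow(gen$gold))) {
    tx <- gen$notes$text[gen$notes$note_id == gen$gold$note_id[i]]
    expect_equal(substr(tx, gen$gold$begin[i] + 1, gen$gold$end[i]),
                 gen$gold$surface[i])
  }
})

test_that("every negated plant is flagged negated by the default rules", {
  gen <- generate_corpus(synth_spec(seed = 29, n_patients = 100,
                                    positive_note_rate = 0.3,
                                    negation_rate = 1))
  negs <- gen$gold[gen$gold$planted_kind == "negated", ]
  expect_gt(nrow(negs), 10)
  ann <- annotate_corpus(gen$notes)
  key <- paste(ann$mentions$note_id, ann$mentions$begin)
  hit <- match(paste(negs$note_id, negs$begin), key)
  expect_false(anyNA(hit))
  expect_true(all(ann$mentions$negated[hit]))
})

test_that("corpus statistics are exact bookkeeping", {
  spec <- synth_spec(seed = 37, n_patients = 200, duplicate_rate = 0.1,
                     positive_note_rate = 0.1)
  gen <- generate_corpus(spec)
  st <- corpus_stats(gen$notes, gen$gold)
  expect_equal(st$n_notes, nrow(gen$notes))
  expect_equal(st$n_patients, 200)
  expect_equal(sum(st$notes_per_type$n), nrow(gen$notes))
  expect_equal(sum(st$plants_per_kind$n), nrow(gen$gold))
  # duplicate count within the binomial 99% interval around rate * notes
  n_orig <- nrow(gen$notes) - st$n_duplicates
  bounds <- qbinom(c(0.005, 0.995), n_orig, 0.1)
  expect_gte(st$n_duplicates, bounds[1])
  expect_lte(st$n_duplicates, bounds[2])
  # orphan gold records are an error
  bad_gold <- gen$gold
  bad_gold$note_id[1] <- "missing-note"
  expect_error(corpus_stats(gen$notes, bad_gold), "missing-note")
})

test_that("the generator spec validates its probability inputs", {
  expect_error(synth_spec(seed = 1, subtype_mix = c(SERVICE = 0.5,
                                                    ABUSE = 0.3,
                                                    SEXUAL_ABUSE = 0.1,
                                                    PHYSICAL_INDICATION = 0,
                                                    EMOTIONAL_INDICATION = 0)),
               "sum to 1")
  expect_error(synth_spec(seed = 1, positive_note_rate = 1.5), "rates")
  # mass on a subtype with no standard lexicon terms is an error
  lex <- make_lexicon("police", subtypes = "SERVICE", specificity = "low")
  expect_error(generate_corpus(synth_spec(seed = 1), lexicon = lex),
               "no standard term")
})

test_that("spec YAML round-trips through read/write", {
  spec <- synth_spec(seed = 77, n_patients = 12, negation_rate = 0.25)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_synth_spec(spec, path)
  back <- read_synth_spec(path)
  expect_equal(back$seed, spec$seed)
  expect_equal(back$negation_rate, spec$negation_rate)
  expect_equal(back$subtype_mix, spec$subtype_mix)
  expect_identical(generate_corpus(back)$notes$text,
                   generate_corpus(spec)$notes$text)
})

test_that("survey-round simulators hit their construction targets", {
  r1 <- simulate_survey_round1(seed = 5)
  s <- aggregate_ratings(r1$ratings)
  expect_equal(nrow(s), 90)
  grand_mean <- mean(r1$ratings$rating)
  expect_equal(grand_mean, 2.58, tolerance = 0.005)
  # when every rater rates every term, the grand mean equals the mean of
  # per-term means
  expect_equal(mean(s$mean_rating), grand_mean)
  expect_equal(nrow(retain_terms(s)), 90)  # round 1 retains everything

  cand <- collect_suggestions(r1$suggestions, r1$n_respondents)
  expect_equal(nrow(cand), 58)

  r2 <- simulate_survey_round2(seed = 6, terms = cand$term)
  s2 <- aggregate_ratings(r2)
  kept2 <- retain_terms(s2)
  expect_equal(nrow(s2) - nrow(kept2), 15)
  expect_equal(nrow(kept2), 43)
})
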