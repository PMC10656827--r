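# Seeded generator of artificial pediatric clinical-note corpora with gold
# annotations. Notes are assembled from synthetic well-child boilerplate
# plus planted CAN sentences (positive, negated, and the five
# false-positive trap categories), so every pipeline stage is testable
# without any protected health data.

FILLER_TEMPLATES <- c(
  "Patient is a well appearing child in no acute distress.",
  "Growth parameters are tracking along the 50th percentile.",
  "Immunizations are up to date per the state registry.",
  "Diet includes a variety of fruits and vegetables.",
  "Sleeping through the night in own bed.",
  "Lungs clear to auscultation bilaterally.",
  "Heart regular rate and rhythm without murmur.",
  "Developmental milestones are appropriate for age.",
  "Follow up in clinic in 6 months for routine care.",
  "Tympanic membranes pearly gray bilaterally.",
  "Skin warm and dry with good turgor.",
  "Denies fever, cough, or congestion.",
  "School attendance has been regular this semester.",
  "Weight gain is appropriate since the last visit."
)

POSITIVE_TEMPLATES <- c(
  "Pt discloses {term} involving a neighbor.",
  "Documentation of {term} was provided to the clinic team.",
  "The care team discussed {term} with the patient today.",
  "Concern for {term} was raised during today's visit.",
  "Pt reports {term} occurring at home last month.",
  "Records indicate {term} documented by the referring clinic."
)

NEGATED_TEMPLATES <- c(
  "Denies {term} at home.",
  "No {term} reported by the patient.",
  "No signs of {term} on exam today.",
  "Pt denies {term} at this time."
)

# parameterized variants of the five false-positive categories; each embeds
# a dictionary surface that the default exclusion rules must suppress
TRAP_TEMPLATES <- list(
  trap_r1 = "Per the mother a history of {term} was reported years ago.",
  trap_r2 = "Abbreviations: AV = alleged victim, AO = alleged offender.",
  trap_r3 = "First Aid: Burns Call 911 immediately if the victim has any burn over a large area.",
  trap_r4 = "{term} health since last visit: No illnesses, ER visits, or hospitalizations.",
  trap_r5 = "Pt was screened for STD (sexually transmitted disease at the visit."
)
# surface recorded as gold for the fixed-surface traps
TRAP_SURFACE <- list(trap_r2 = "alleged", trap_r3 = "burn",
                     trap_r5 = "sexually transmitted disease")

#' Note-type profile of a pediatric outpatient corpus
#'
#' The 22 note types of a multi-clinic pediatric EHR corpus with their
#' relative frequencies, used as the default note-type mix of the
#' generator.
#'
#' @return tibble: `note_type`, `n_notes` (reference counts), `weight`
#' @export
note_type_profile <- function() {
  t <- tibble(
    note_type = c("Plan of Care", "Not Specified", "Nursing",
                  "Emergency Department Notes", "Patient Instructions",
                  "ED AVS Snapshot", "Telephone Encounter",
                  "MR AVS Snapshot", "Letter", "Medical Student",
                  "Discharge Instructions - Other Orders", "Sticky Note",
                  "Emergency Department Provider Notes", "Progress Notes",
                  "IP AVS Snapshot", "Discharge Summaries", "H&P",
                  "Lactation Note", "Consults", "Consult NW",
                  "Social Worker/Case Management", "Treatment Plan"),
    n_notes = c(333L, 1813L, 134L, 518L, 1149L, 472L, 2051L, 1571L, 127L,
                60L, 58L, 27L, 281L, 3859L, 66L, 788L, 677L, 192L, 458L,
                112L, 51L, 5L)
  )
  t$weight <- t$n_notes / sum(t$n_notes)
  t
}

#' Specification for a synthetic clinical-note corpus
#'
#' Defaults mirror the statistical structure the pipeline assumes in a real
#' pediatric corpus: a SERVICE-heavy subtype mixture (.67/.22/.06/.05/.00
#' over SERVICE, ABUSE, SEXUAL_ABUSE, PHYSICAL_INDICATION,
#' EMOTIONAL_INDICATION), a low positive-note rate (~3%), and note types
#' drawn from [note_type_profile()].
#'
#' @param seed integer seed; the corpus is fully deterministic given it
#' @param n_patients number of patients (default 200)
#' @param notes_per_patient integer range, default `c(2, 6)`
#' @param sentence_count sentences per note, default `c(4, 10)`
#' @param positive_note_rate fraction of notes carrying at least one
#'   planted CAN sentence (default 0.03)
#' @param subtype_mix named probability vector over the five subtypes
#' @param negation_rate fraction of planted mentions wrapped in a negation
#'   trigger (default 0.1)
#' @param trap_rates named per-note probabilities for the five
#'   false-positive trap categories (default 0.01 each)
#' @param duplicate_rate fraction of notes duplicated verbatim (default 0)
#' @param note_type_mix tibble with `note_type`, `weight`
#' @return object of class `synth_spec`
#' @export
synth_spec <- function(seed,
                       n_patients = 200,
                       notes_per_patient = c(2, 6),
                       sentence_count = c(4, 10),
                       positive_note_rate = 0.03,
                       subtype_mix = c(SERVICE = 0.67, ABUSE = 0.22,
                                       SEXUAL_ABUSE = 0.06,
                                       PHYSICAL_INDICATION = 0.05,
                                       EMOTIONAL_INDICATION = 0),
                       negation_rate = 0.1,
                       trap_rates = c(trap_r1 = 0.01, trap_r2 = 0.01,
                                      trap_r3 = 0.01, trap_r4 = 0.01,
                                      trap_r5 = 0.01),
                       duplicate_rate = 0,
                       note_type_mix = note_type_profile()) {
  stopifnot(length(seed) == 1, n_patients >= 1,
            length(notes_per_patient) == 2, length(sentence_count) == 2)
  if (abs(sum(subtype_mix) - 1) > 1e-9) {
    stop_fmt("subtype_mix must sum to 1 (got %g)", sum(subtype_mix))
  }
  if (!setequal(names(subtype_mix), can_subtypes())) {
    stop_fmt("subtype_mix must be named by the five subtypes")
  }
  rates <- c(positive_note_rate, negation_rate, trap_rates, duplicate_rate)
  if (any(rates < 0 | rates > 1)) stop_fmt("rates must be in [0, 1]")
  structure(list(seed = as.integer(seed), n_patients = n_patients,
                 notes_per_patient = notes_per_patient,
                 sentence_count = sentence_count,
                 positive_note_rate = positive_note_rate,
                 subtype_mix = subtype_mix, negation_rate = negation_rate,
                 trap_rates = trap_rates, duplicate_rate = duplicate_rate,
                 note_type_mix = note_type_mix),
            class = "synth_spec")
}

#' Read / write a generator specification as YAML
#'
#' @param path YAML file
#' @return `synth_spec` object (`read_synth_spec`); `path` invisibly
#'   (`write_synth_spec`)
#' @export
read_synth_spec <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), "note_type_mix")]
  args$subtype_mix <- unlist(args$subtype_mix)
  args$trap_rates <- unlist(args$trap_rates)
  if (!is.null(y$note_type_mix)) {
    args$note_type_mix <- dplyr::bind_rows(y$note_type_mix)
  }
  do.call(synth_spec, args)
}

#' @rdname read_synth_spec
#' @param spec `synth_spec` object
#' @export
write_synth_spec <- function(spec, path) {
  y <- unclass(spec)
  y$subtype_mix <- as.list(y$subtype_mix)
  y$trap_rates <- as.list(y$trap_rates)
  y$note_type_mix <- lapply(seq_len(nrow(spec$note_type_mix)), function(i) {
    as.list(spec$note_type_mix[i, ])
  })
  yaml::write_yaml(y, path)
  invisible(path)
}

# sampling weights for plantable (standard-specificity) terms of a subtype;
# "child protective services" is up-weighted to dominate SERVICE plants,
# mirroring its dominance in real corpora
plantable_terms <- function(lexicon, subtype) {
  terms <- lexicon$term[lexicon$subtype == subtype &
                          lexicon$specificity == "standard"]
  w <- rep(1, length(terms))
  cps <- terms == "child protective services"
  if (any(cps)) w[cps] <- length(terms) - 1
  list(terms = terms, weights = w / sum(w))
}

fill_template <- function(template, term) {
  sub("{term}", term, template, fixed = TRUE)
}

# locate the planted surface in the instantiated sentence (word-boundary,
# first occurrence); returns 0-based half-open character span
surface_span <- function(sentence, surface) {
  m <- regexpr(paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", surface),
                      "\\b"), sentence)
  if (m[1] == -1) stop_fmt("planted surface '%s' not found", surface)
  c(begin = m[1] - 1L, end = m[1] - 1L + attr(m, "match.length"))
}

#' Generate a synthetic annotated corpus
#'
#' Builds `n_patients` patients' worth of notes from well-child filler
#' sentences interleaved with planted CAN sentences: positives embed a
#' standard-specificity lexicon surface of a sampled subtype, negated
#' plants wrap the surface in a negation trigger, and trap plants
#' instantiate the five false-positive patterns. Every plant is recorded as
#' gold. Fully deterministic given `spec$seed`.
#'
#' @param spec `synth_spec` object
#' @param lexicon lexicon tibble; every subtype with positive mass in
#'   `subtype_mix` must have at least one standard-specificity term
#' @return list with `notes` (corpus tibble) and `gold` (tibble: `note_id`,
#'   `sentence_index`, `begin`, `end`, `surface`, `subtype`,
#'   `planted_kind`); attribute `n_duplicates` on `notes`
#' @export
generate_corpus <- function(spec, lexicon = starter_lexicon()) {
  stopifnot(inherits(spec, "synth_spec"))
  for (st in names(spec$subtype_mix)[spec$subtype_mix > 0]) {
    if (length(plantable_terms(lexicon, st)$terms) == 0) {
      stop_fmt("subtype_mix puts mass on %s but lexicon has no standard term for it", st)
    }
  }
  withr::with_seed(spec$seed, {
    notes <- list(); gold <- list()
    note_counter <- 0L
    base_date <- as.Date("2012-01-01")
    for (p in seq_len(spec$n_patients)) {
      pid <- sprintf("P%04d", p)
      n_notes <- sample(spec$notes_per_patient[1]:spec$notes_per_patient[2], 1)
      for (k in seq_len(n_notes)) {
        note_counter <- note_counter + 1L
        nid <- sprintf("N%06d", note_counter)
        n_sent <- sample(spec$sentence_count[1]:spec$sentence_count[2], 1)
        sents <- sample(FILLER_TEMPLATES, n_sent, replace = TRUE)
        plants <- list()  # sentence_index -> list(surface, subtype, kind)
        if (stats::runif(1) < spec$positive_note_rate) {
          n_plants <- sample(1:2, 1)
          pos_idx <- sample(seq_len(n_sent), min(n_plants, n_sent))
          for (si in pos_idx) {
            st <- sample(names(spec$subtype_mix), 1,
                         prob = spec$subtype_mix)
            pt <- plantable_terms(lexicon, st)
            term <- sample(pt$terms, 1, prob = pt$weights)
            negated <- stats::runif(1) < spec$negation_rate
            tmpl <- if (negated) sample(NEGATED_TEMPLATES, 1)
                    else sample(POSITIVE_TEMPLATES, 1)
            sents[si] <- fill_template(tmpl, term)
            plants[[as.character(si)]] <- list(
              surface = term, subtype = st,
              kind = if (negated) "negated" else "positive")
          }
        }
        for (trap in names(spec$trap_rates)) {
          if (stats::runif(1) >= spec$trap_rates[[trap]]) next
          free <- setdiff(seq_len(n_sent), as.integer(names(plants)))
          if (length(free) == 0) next
          si <- free[sample.int(length(free), 1)]
          if (trap %in% names(TRAP_SURFACE)) {
            surface <- TRAP_SURFACE[[trap]]
            st <- lexicon$subtype[match(surface, lexicon$term)]
            sents[si] <- TRAP_TEMPLATES[[trap]]
          } else {
            st <- sample(c("ABUSE", "SEXUAL_ABUSE"), 1)
            pt <- plantable_terms(lexicon, st)
            surface <- sample(pt$terms, 1, prob = pt$weights)
            sents[si] <- fill_template(TRAP_TEMPLATES[[trap]], surface)
          }
          plants[[as.character(si)]] <- list(surface = surface,
                                             subtype = st, kind = trap)
        }
        text <- paste(sents, collapse = " ")
        offsets <- c(0L, cumsum(nchar(sents) + 1L))
        for (si_chr in names(plants)) {
          si <- as.integer(si_chr)
          pl <- plants[[si_chr]]
          sp <- surface_span(sents[si], pl$surface)
          gold[[length(gold) + 1]] <- tibble(
            note_id = nid, sentence_index = si - 1L,
            begin = offsets[si] + sp[["begin"]],
            end = offsets[si] + sp[["end"]],
            surface = pl$surface, subtype = pl$subtype,
            planted_kind = pl$kind)
        }
        notes[[note_counter]] <- tibble(
          note_id = nid, patient_id = pid,
          note_type = sample(spec$note_type_mix$note_type, 1,
                             prob = spec$note_type_mix$weight),
          provider_category = sample(c("physician", "nurse",
                                       "social_worker", "other"), 1,
                                     prob = c(0.5, 0.3, 0.1, 0.1)),
          date = as.character(base_date + sample.int(2500, 1)),
          text = text)
      }
    }
    notes <- dplyr::bind_rows(notes)
    gold <- if (length(gold) > 0) dplyr::bind_rows(gold) else
      tibble(note_id = character(), sentence_index = integer(),
             begin = integer(), end = integer(), surface = character(),
             subtype = character(), planted_kind = character())
    n_dup <- 0L
    if (spec$duplicate_rate > 0 && nrow(notes) > 0) {
      dup_rows <- which(stats::runif(nrow(notes)) < spec$duplicate_rate)
      n_dup <- length(dup_rows)
      if (n_dup > 0) {
        dups <- notes[dup_rows, ]
        dup_gold <- gold[gold$note_id %in% dups$note_id, ]
        new_ids <- sprintf("N%06d", note_counter + seq_len(n_dup))
        dup_gold$note_id <- new_ids[match(dup_gold$note_id, dups$note_id)]
        dups$note_id <- new_ids
        dups$date <- as.character(as.Date(dups$date) + 1L)
        notes <- dplyr::bind_rows(notes, dups)
        gold <- dplyr::bind_rows(gold, dup_gold)
      }
    }
    attr(notes, "n_duplicates") <- n_dup
    list(notes = notes, gold = gold)
  })
}

#' Gold sentence and document labels from planted annotations
#'
#' A sentence is gold-positive exactly when a `positive`-kind plant sits in
#' it; a note is gold-positive when any of its sentences is.
#'
#' @param notes corpus tibble from [generate_corpus()]
#' @param gold gold tibble from [generate_corpus()]
#' @return list of tibbles `sentence` (`note_id`, `sentence_index`,
#'   `positive`) and `document` (`note_id`, `positive`)
#' @export
gold_labels <- function(notes, gold) {
  sent <- dplyr::bind_rows(lapply(seq_len(nrow(notes)), function(i) {
    split_sentences(notes$text[i], note_id = notes$note_id[i])
  }))
  pos_key <- paste(gold$note_id[gold$planted_kind == "positive"],
                   gold$sentence_index[gold$planted_kind == "positive"])
  sentence <- tibble(note_id = sent$note_id, sentence_index = sent$index,
                     positive = paste(sent$note_id, sent$index) %in% pos_key)
  document <- sentence %>%
    dplyr::group_by(note_id = .data$note_id) %>%
    dplyr::summarise(positive = any(.data$positive), .groups = "drop")
  list(sentence = sentence, document = document)
}

#' Summary statistics of a generated corpus
#'
#' @param notes,gold output of [generate_corpus()]
#' @return list: `n_notes`, `n_patients`, `notes_per_type`,
#'   `plants_per_kind`, `gold_positive_note_rate`, `n_duplicates`
#' @export
corpus_stats <- function(notes, gold) {
  orphan <- setdiff(gold$note_id, notes$note_id)
  if (length(orphan) > 0) {
    stop_fmt("gold annotation references unknown note '%s'", orphan[1])
  }
  gl <- gold_labels(notes, gold)
  list(
    n_notes = nrow(notes),
    n_patients = length(unique(notes$patient_id)),
    notes_per_type = notes %>% dplyr::count(note_type = .data$note_type),
    plants_per_kind = gold %>%
      dplyr::count(planted_kind = .data$planted_kind),
    gold_positive_note_rate = mean(gl$document$positive),
    n_duplicates = attr(notes, "n_duplicates") %||% NA_integer_
  )
}

#' Synthetic labeled sentence dataset for the SVM classifier
#'
#' Generates a linearly separable sentence-classification dataset: CAN
#' sentences embed a standard-specificity lexicon surface, non-CAN
#' sentences are well-child boilerplate. Class balance defaults to the
#' 71.4% / 28.6% CAN / non-CAN split of a manually labeled review set.
#'
#' @param n number of sentences
#' @param seed integer seed
#' @param pos_frac CAN fraction (default 0.714)
#' @param lexicon lexicon tibble
#' @return tibble: `sentence`, `label` (1 = CAN)
#' @export
simulate_sentence_dataset <- function(n, seed, pos_frac = 0.714,
                                      lexicon = starter_lexicon()) {
  stopifnot(n >= 2)
  withr::with_seed(seed, {
    n_pos <- max(1L, min(n - 1L, round(pos_frac * n)))
    terms <- lexicon$term[lexicon$specificity == "standard"]
    pos <- vapply(seq_len(n_pos), function(i) {
      fill_template(sample(POSITIVE_TEMPLATES, 1), sample(terms, 1))
    }, "")
    neg <- sample(FILLER_TEMPLATES, n - n_pos, replace = TRUE)
    out <- tibble(sentence = c(pos, neg),
                  label = c(rep(1L, n_pos), rep(0L, n - n_pos)))
    out[sample.int(nrow(out)), , drop = FALSE]
  })
}

#' Simulate an expert rating round over an initial term pool
#'
#' Builds a round of 3-point importance ratings whose grand mean hits
#' `target_mean` exactly (achievable to 1/(n_terms*n_respondents)
#' resolution) while every term clears the 80% retention rule, emulating a
#' first validation round in which the whole investigator pool is endorsed.
#' Also fabricates free-text suggestions: `n_candidates` terms endorsed by
#' at least `endorse_frac` of respondents plus `n_noise` under-endorsed
#' ones.
#'
#' @param seed integer seed
#' @param n_terms terms in the pool (default 90)
#' @param n_respondents raters (default 25)
#' @param target_mean desired grand mean rating (default 2.58)
#' @param n_candidates suggestions that should clear the 10% bar
#'   (default 58)
#' @param n_noise suggestions that should not (default 12)
#' @param endorse_frac endorsement fraction for candidates (default 0.12)
#' @return list: `ratings` (respondent_id, term, rating), `suggestions`
#'   (respondent_id, suggestion), `n_respondents`
#' @export
simulate_survey_round1 <- function(seed, n_terms = 90, n_respondents = 25,
                                   target_mean = 2.58, n_candidates = 58,
                                   n_noise = 12, endorse_frac = 0.12) {
  n_cells <- n_terms * n_respondents
  total <- round(target_mean * n_cells)
  # start from all 3s, walk down to the target sum with 2s and 1s;
  # ones are dealt round-robin so no term collects enough to fail retention
  deficit <- 3L * n_cells - total
  max_ones_per_term <- floor(0.2 * n_respondents)
  n_ones <- min(deficit %/% 2L %/% 2L, max_ones_per_term * n_terms)
  n_twos <- deficit - 2L * n_ones
  stopifnot(n_twos >= 0, n_ones + n_twos <= n_cells)
  terms <- sprintf("term %02d", seq_len(n_terms))
  ratings <- matrix(3L, nrow = n_terms, ncol = n_respondents)
  one_terms <- rep(seq_len(n_terms), length.out = n_ones)
  for (t in seq_len(n_terms)) {
    k <- sum(one_terms == t)
    if (k > 0) ratings[t, seq_len(k)] <- 1L
  }
  # place 2s after the 1s, column-major so they spread over terms evenly
  flat <- as.vector(t(ratings))
  threes <- which(flat == 3L)
  flat[threes[seq_len(n_twos)]] <- 2L
  ratings_df <- withr::with_seed(seed, {
    df <- tibble(
      term = rep(terms, each = n_respondents),
      respondent_id = rep(sprintf("R%02d", seq_len(n_respondents)),
                          times = n_terms),
      rating = flat)
    # shuffle which respondent holds which rating within each term
    df %>% dplyr::group_by(.data$term) %>%
      dplyr::mutate(rating = sample(.data$rating)) %>%
      dplyr::ungroup()
  })
  n_endorse <- ceiling(endorse_frac * n_respondents)
  cand <- sprintf("suggested term %02d", seq_len(n_candidates))
  noise <- sprintf("rare term %02d", seq_len(n_noise))
  suggestions <- dplyr::bind_rows(
    tibble(respondent_id = rep(sprintf("R%02d", seq_len(n_endorse)),
                               times = n_candidates),
           suggestion = rep(cand, each = n_endorse)),
    tibble(respondent_id = rep("R01", n_noise), suggestion = noise)
  )
  list(ratings = ratings_df[c("respondent_id", "term", "rating")],
       suggestions = suggestions, n_respondents = n_respondents)
}

#' Simulate a second rating round over suggested terms
#'
#' Rates `terms` so that exactly `n_fail` of them miss the 80% retention
#' rule (the last `n_fail` in order) and the rest clear it unanimously.
#'
#' @param seed integer seed
#' @param terms candidate terms from round 1
#' @param n_respondents raters (default 12)
#' @param n_fail terms that must fail retention (default 15)
#' @return ratings tibble (`respondent_id`, `term`, `rating`)
#' @export
simulate_survey_round2 <- function(seed, terms, n_respondents = 12,
                                   n_fail = 15) {
  stopifnot(n_fail <= length(terms))
  fail_set <- utils::tail(terms, n_fail)
  # failing terms: just over half the raters endorse (< 80%)
  n_low <- n_respondents - floor(0.58 * n_respondents)
  withr::with_seed(seed, dplyr::bind_rows(lapply(terms, function(tm) {
    r <- if (tm %in% fail_set) {
      c(rep(1L, n_low), sample(2:3, n_respondents - n_low, replace = TRUE))
    } else {
      sample(2:3, n_respondents, replace = TRUE)
    }
    tibble(respondent_id = sprintf("R%02d", seq_len(n_respondents)),
           term = tm, rating = sample(r))
  })))
}
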