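test_that("note-type table reproduces half-up percentage formatting", {
  notes <- tibble::tibble(
    note_id = sprintf("n%02d", 1:56),
    patient_id = "p1",
    note_type = c(rep("Treatment Plan", 5),
                  rep("Social Worker/Case Management", 51)),
    provider_category = "social_worker", date = "2015-01-01", text = "x")
  labels <- tibble::tibble(
    note_id = notes$note_id,
    positive = c(rep(TRUE, 3), rep(FALSE, 2),
                 rep(TRUE, 26), rep(FALSE, 25)))
  tab <- note_type_table(labels, notes)
  expect_equal(tab$positive_pct[tab$note_type == "Treatment Plan"], 60.00)
  expect_equal(
    tab$positive_pct[tab$note_type == "Social Worker/Case Management"],
    50.98)
  # rows sum to corpus size; positives sum to document positives
  expect_equal(sum(tab$n_notes), nrow(notes))
  expect_equal(sum(tab$n_positive), sum(labels$positive))
  # sorted ascending by percentage
  expect_true(!is.unsorted(tab$positive_pct))
  # label without a note is an error
  expect_error(note_type_table(
    tibble::tibble(note_id = "zz", positive = TRUE), notes), "zz")
})

test_that("all-negative corpora give all-zero percentages", {
  notes <- make_note("x", note_id = c("a", "b"),
                     note_type = c("Nursing", "Consults"))
  labels <- tibble::tibble(note_id = c("a", "b"), positive = FALSE)
  expect_true(all(note_type_table(labels, notes)$positive_pct == 0))
})

mention_stub <- function(subtype, surface = subtype, negated = FALSE,
                         excluded = FALSE) {
  tibble::tibble(note_id = "n1", sentence_index = 0L, begin = 0L, end = 1L,
                 matched_surface = surface, lexicon_surface = surface,
                 subtype = subtype, specificity = "standard",
                 negated = negated, excluded = excluded,
                 exclusion_rule_id = NA_character_)
}

test_that("subtype distribution covers all five subtypes and sums to one", {
  ments <- dplyr::bind_rows(
    lapply(rep(c("SERVICE", "ABUSE", "SEXUAL_ABUSE", "PHYSICAL_INDICATION"),
               c(67, 22, 6, 5)), mention_stub))
  d <- subtype_distribution(ments)
  expect_equal(nrow(d), 5)
  expect_equal(sum(d$proportion), 1, tolerance = 1e-9)
  expect_equal(d$proportion[d$subtype == "SERVICE"], 0.67)
  expect_equal(d$proportion[d$subtype == "ABUSE"], 0.22)
  expect_equal(d$proportion[d$subtype == "EMOTIONAL_INDICATION"], 0)
  # invariant under reordering
  d2 <- subtype_distribution(ments[sample(nrow(ments)), ])
  expect_equal(d, d2, ignore_attr = TRUE)
  # negated/excluded mentions do not count
  with_neg <- dplyr::bind_rows(mention_stub("ABUSE"),
                               mention_stub("SERVICE", negated = TRUE))
  expect_equal(subtype_distribution(with_neg)$proportion[
    subtype_distribution(with_neg)$subtype == "ABUSE"], 1)
  # zero qualifying mentions: flagged empty, no division error
  empty <- subtype_distribution(mention_stub("ABUSE", negated = TRUE))
  expect_true(attr(empty, "empty"))
  expect_true(all(empty$proportion == 0))
})

test_that("top entities rank by count with alphabetical ties", {
  ments <- dplyr::bind_rows(
    lapply(rep(c("b term", "a term", "c term"), c(3, 1, 1)),
           function(s) mention_stub("SERVICE", surface = s)))
  top <- top_entities(ments, 3)
  expect_equal(top$lexicon_surface, c("b term", "a term", "c term"))
  expect_equal(top$n, c(3L, 1L, 1L))
})

test_that("the dominant planted entity ranks first in a generated corpus", {
  gen <- generate_corpus(synth_spec(seed = 31, n_patients = 150,
                                    positive_note_rate = 0.2))
  ann <- annotate_corpus(gen$notes)
  top <- top_entities(ann$mentions, 5)
  expect_equal(top$lexicon_surface[1], "child protective services")
})

test_that("highlight rendering round-trips the note text", {
  txt <- "Pt discloses abuse by neighbor. Follow up <soon> & review."
  ann <- annotate_corpus(make_note(txt))
  html <- render_highlights(txt, ann$mentions, "html")
  expect_equal(strip_highlights(html, "html"), txt)
  expect_equal(length(gregexpr("<span", html, fixed = TRUE)[[1]]), 1)
  ansi <- render_highlights(txt, ann$mentions, "ansi")
  expect_equal(strip_highlights(ansi, "ansi"), txt)
  # zero mentions: identity after strip
  none <- render_highlights("No mentions here & <tags>.",
                            ann$mentions[0, ], "html")
  expect_equal(strip_highlights(none, "html"), "No mentions here & <tags>.")
  # span outside the note is an error
  bad <- ann$mentions
  bad$end[1] <- nchar(txt) + 10L
  expect_error(render_highlights(txt, bad), "outside")
  # produced HTML parses
  page <- render_note_html(txt, ann$mentions)
  doc <- xml2::read_html(paste(page, collapse = "\n"))
  expect_equal(length(xml2::xml_find_all(doc, "//span")), 1)
})

test_that("render/strip is the identity over fuzzed generated notes", {
  gen <- generate_corpus(synth_spec(seed = 41, n_patients = 15,
                                    positive_note_rate = 0.5))
  ann <- annotate_corpus(gen$notes)
  for (i in seq_len(nrow(gen$notes))) {
    m <- ann$mentions[ann$mentions$note_id == gen$notes$note_id[i], ]
    h <- render_highlights(gen$notes$text[i], m, "html")
    expect_equal(strip_highlights(h, "html"), gen$notes$text[i])
  }
})
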