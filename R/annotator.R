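# Rule-based annotation pipeline: sentence detection, tokenization,
# dictionary NER, negation scope, exclusion rules, low-specificity
# corroboration, and sentence/document classification.
#
# All character offsets are 0-based, half-open, in note coordinates
# (BRAT-compatible standoff convention).

# abbreviations whose trailing period does not end a sentence
SENTENCE_ABBREVS <- c("dr", "mr", "mrs", "ms", "vs", "e.g", "i.e", "mg",
                      "ml", "yo", "mo", "wk", "pt")

#' Split note text into sentences
#'
#' Rule-based sentence detection for clinical text. Boundaries occur after
#' `.`, `!`, `?` (when followed by whitespace and not preceded by a bundled
#' abbreviation such as "Dr." or "e.g."), at runs of two or more newlines,
#' and before list-item markers at the start of a line. Colons never split:
#' agrammatical header-style constructions stay in one sentence. Each
#' sentence's `text` equals the note slice `[begin, end)`, so the note is
#' reconstructable from the spans.
#'
#' @param text single note body (may be empty)
#' @param note_id optional id carried into the output
#' @return tibble with columns `note_id`, `index` (0-based), `begin`, `end`
#'   (0-based half-open character offsets), `text`
#' @export
split_sentences <- function(text, note_id = NA_character_) {
  stopifnot(length(text) == 1)
  empty <- tibble(note_id = character(), index = integer(),
                  begin = integer(), end = integer(), text = character())
  if (is.na(text) || !nzchar(text)) return(empty)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  is_space <- chars %in% c(" ", "\t", "\n", "\r", "\f", "\v")
  # boundary[i] = TRUE means a sentence ends after character i
  boundary <- logical(n)
  cand <- which(chars %in% c(".", "!", "?", "\n"))
  for (i in cand) {
    ch <- chars[i]
    if (ch %in% c("!", "?")) {
      if (i == n || is_space[i + 1]) boundary[i] <- TRUE
    } else if (ch == ".") {
      if (i == n || is_space[i + 1]) {
        # word since last whitespace, excluding this period
        j <- i - 1
        while (j >= 1 && !is_space[j]) j <- j - 1
        word <- tolower(substr(text, j + 1, i - 1))
        if (!(word %in% SENTENCE_ABBREVS)) boundary[i] <- TRUE
      }
    } else {
      # newline run >= 2, or single newline followed by a list-item marker
      run_end <- i
      while (run_end < n && is_space[run_end + 1]) run_end <- run_end + 1
      n_newlines <- sum(chars[i:run_end] == "\n")
      after <- if (run_end < n) chars[run_end + 1] else ""
      list_marker <- after %in% c("-", "*", "•") ||
        (grepl("[0-9]", after) && run_end + 2 <= n &&
           chars[run_end + 2] %in% c(".", ")"))
      if ((n_newlines >= 2 || list_marker) && i > 1) boundary[i - 1] <- TRUE
    }
  }
  boundary[n] <- TRUE
  ends <- which(boundary)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  sv <- integer(); ev <- integer()
  for (k in seq_along(ends)) {
    s <- starts[k]; e <- ends[k]
    # trim surrounding whitespace from the span
    while (s <= e && is_space[s]) s <- s + 1
    while (e >= s && is_space[e]) e <- e - 1
    if (s > e) next
    sv <- c(sv, s); ev <- c(ev, e)
  }
  if (length(sv) == 0) return(empty)
  tibble(note_id = note_id, index = seq_along(sv) - 1L,
         begin = sv - 1L, end = ev,  # 0-based half-open
         text = substring(text, sv, ev))
}

#' Tokenize text into alphanumeric and punctuation tokens
#'
#' Tokens are maximal alphanumeric runs plus standalone punctuation
#' characters; hyphen and slash therefore split words ("2nd-degree" becomes
#' `2nd`, `-`, `degree`). Spans are 0-based half-open and, when `offset` is
#' the sentence's `begin`, lie in note coordinates.
#'
#' @param text character scalar (usually a sentence)
#' @param offset character offset added to all spans (default 0)
#' @return tibble with columns `token`, `begin`, `end`, `is_word`
#' @export
can_tokenize <- function(text, offset = 0L) {
  stopifnot(length(text) == 1)
  if (is.na(text) || !nzchar(text)) {
    return(tibble(token = character(), begin = integer(),
                  end = integer(), is_word = logical()))
  }
  m <- gregexpr("[A-Za-z0-9]+|[^A-Za-z0-9[:space:]]", text)[[1]]
  if (m[1] == -1) {
    return(tibble(token = character(), begin = integer(),
                  end = integer(), is_word = logical()))
  }
  len <- attr(m, "match.length")
  tok <- substring(text, m, m + len - 1)
  tibble::new_tibble(list(token = tok,
                          begin = as.integer(m - 1L + offset),
                          end = as.integer(m - 1L + len + offset),
                          is_word = grepl("^[A-Za-z0-9]", tok)),
                     nrow = length(tok))
}

# try to match compiled entries at word position `pos` of word-token vector;
# returns best entry (longest, then subtype priority) and its length, or NULL
match_at <- function(words, pos, matcher) {
  w <- words[pos]
  cands <- c(matcher$index[[tolower(w)]], matcher$index[[w]])
  if (length(cands) == 0) return(NULL)
  best <- NULL
  for (e in cands) {
    k <- length(e$tokens)
    if (pos + k - 1 > length(words)) next
    seg <- words[pos:(pos + k - 1)]
    ok <- if (e$case_sensitive) identical(seg, e$tokens)
          else identical(tolower(seg), tolower(e$tokens))
    if (!ok) next
    if (is.null(best) || k > best$k ||
        (k == best$k && e$priority < best$entry$priority)) {
      best <- list(entry = e, k = k)
    }
  }
  best
}

#' Dictionary named-entity recognition over one sentence
#'
#' Leftmost-longest, non-overlapping matching of lexicon surfaces against
#' the sentence's word tokens (punctuation tokens are transparent: "foster-
#' care" matches "foster care"). When two surfaces of equal token length
#' match at the same position, the more clinically specific subtype wins
#' (SEXUAL_ABUSE > PHYSICAL_INDICATION > EMOTIONAL_INDICATION > ABUSE >
#' SERVICE). Mentions never span sentence boundaries.
#'
#' @param tokens tibble from [can_tokenize()] (spans in note coordinates)
#' @param matcher compiled matcher from [compile_matcher()]
#' @param note_id,sentence_index carried into the output
#' @return tibble of mentions: `note_id`, `sentence_index`, `begin`, `end`,
#'   `matched_surface`, `lexicon_surface`, `subtype`, `specificity`,
#'   `negated`, `excluded`, `exclusion_rule_id` (flags initialized FALSE)
#' @export
match_entities <- function(tokens, matcher, note_id = NA_character_,
                           sentence_index = NA_integer_) {
  stopifnot(inherits(matcher, "can_matcher"))
  wt <- tokens[tokens$is_word, , drop = FALSE]
  words <- wt$token
  hits <- list()
  pos <- 1
  while (pos <= length(words)) {
    hit <- match_at(words, pos, matcher)
    if (is.null(hit)) { pos <- pos + 1; next }
    hits[[length(hits) + 1]] <- list(b = wt$begin[pos],
                                     e = wt$end[pos + hit$k - 1],
                                     entry = hit$entry)
    pos <- pos + hit$k
  }
  n <- length(hits)
  tibble::new_tibble(list(
    note_id = rep(note_id, n),
    sentence_index = rep(sentence_index, n),
    begin = vapply(hits, function(h) as.integer(h$b), 0L),
    end = vapply(hits, function(h) as.integer(h$e), 0L),
    matched_surface = rep(NA_character_, n),  # filled by caller
    lexicon_surface = vapply(hits, function(h) h$entry$lexicon_surface, ""),
    subtype = vapply(hits, function(h) h$entry$subtype, ""),
    specificity = vapply(hits, function(h) h$entry$specificity, ""),
    negated = rep(FALSE, n), excluded = rep(FALSE, n),
    exclusion_rule_id = rep(NA_character_, n)
  ), nrow = n)
}

#' Default negation rules
#'
#' NegEx-style trigger list: a mention is negated when a pre-trigger occurs
#' within `scope_tokens` word tokens before it (or a post-trigger within
#' scope after it) with no terminator in between. The defaults use a scope
#' of 6 tokens, the published community convention.
#'
#' @return list with `scope_tokens`, `terminators`, and a `triggers` tibble
#'   (`phrase`, `direction`)
#' @export
default_negation_rules <- function() {
  list(
    scope_tokens = 6L,
    terminators = c("but", "however", "although", "except"),
    triggers = tibble(
      phrase = c("no", "not", "denies", "deny", "denied", "without",
                 "negative for", "no evidence of", "no signs of", "never"),
      direction = "pre"
    )
  )
}

#' Read negation rules from a YAML file
#'
#' Expected keys: `scope_tokens` (integer >= 1), `terminators` (list of
#' words), `triggers` (list of `{phrase, direction}` with direction `pre` or
#' `post`).
#'
#' @param path YAML file
#' @return rules list as in [default_negation_rules()]
#' @export
read_negation_rules <- function(path) {
  y <- yaml::read_yaml(path)
  trig <- dplyr::bind_rows(lapply(y$triggers, function(t) {
    tibble(phrase = t$phrase, direction = t$direction %||% "pre")
  }))
  if (any(!trig$direction %in% c("pre", "post"))) {
    stop_fmt("negation trigger direction must be 'pre' or 'post'")
  }
  scope <- as.integer(y$scope_tokens %||% 6L)
  if (scope < 1) stop_fmt("scope_tokens must be >= 1")
  list(scope_tokens = scope,
       terminators = unlist(y$terminators) %||% character(),
       triggers = trig)
}

# positions (first, last) of every occurrence of a phrase in a word vector
phrase_positions <- function(words_lower, phrase) {
  ptoks <- tolower(word_tokens(phrase))
  k <- length(ptoks)
  if (k == 0 || length(words_lower) < k) return(NULL)
  hits <- list()
  for (p in seq_len(length(words_lower) - k + 1)) {
    if (identical(words_lower[p:(p + k - 1)], ptoks)) {
      hits[[length(hits) + 1]] <- c(first = p, last = p + k - 1)
    }
  }
  hits
}

#' Flag negated mentions
#'
#' Applies the trigger/scope/terminator rules to each mention of one
#' sentence. Distances are counted in word tokens; a terminator anywhere
#' strictly between trigger and mention blocks the negation.
#'
#' @param mentions mentions of one sentence ([match_entities()] output)
#' @param tokens the sentence's tokens (note coordinates)
#' @param rules negation rules (default [default_negation_rules()])
#' @return `mentions` with `negated` updated
#' @export
detect_negation <- function(mentions, tokens, rules = default_negation_rules()) {
  if (nrow(mentions) == 0) return(mentions)
  wt <- tokens[tokens$is_word, , drop = FALSE]
  words_lower <- tolower(wt$token)
  term_pos <- which(words_lower %in% tolower(rules$terminators))
  for (i in seq_len(nrow(mentions))) {
    # word index range of the mention
    m_first <- which(wt$begin >= mentions$begin[i])[1]
    m_last <- utils::tail(which(wt$end <= mentions$end[i]), 1)
    if (is.na(m_first) || length(m_last) == 0) next
    neg <- FALSE
    for (r in seq_len(nrow(rules$triggers))) {
      occ <- phrase_positions(words_lower, rules$triggers$phrase[r])
      for (o in occ) {
        if (rules$triggers$direction[r] == "pre") {
          gap <- m_first - o["last"]
          if (gap >= 1 && gap <= rules$scope_tokens &&
              !any(term_pos > o["last"] & term_pos < m_first)) neg <- TRUE
        } else {
          gap <- o["first"] - m_last
          if (gap >= 1 && gap <= rules$scope_tokens &&
              !any(term_pos > m_last & term_pos < o["first"])) neg <- TRUE
        }
      }
      if (neg) break
    }
    mentions$negated[i] <- neg
  }
  mentions
}

# verbs used to decide whether a pre-colon fragment is a section header
HEADER_VERBS <- c("is", "was", "are", "were", "has", "had", "have", "be",
                  "been", "reports", "reported", "denies", "denied",
                  "states", "stated", "discloses", "disclosed", "says",
                  "said", "notes", "noted", "presents", "presented")

#' Default exclusion rules
#'
#' Five shipped rules approximating the false-positive categories observed
#' when screening real pediatric notes:
#' \describe{
#'   \item{r1 (non_patient_subject)}{a third-party kin token within 6 word
#'     tokens before the mention plus a history marker in the sentence —
#'     the event concerns a relative, not the patient}
#'   \item{r2 (template_pattern)}{abbreviation-legend boilerplate such as
#'     "AV = alleged victim"}
#'   \item{r3 (template_pattern)}{first-aid / instruction templates
#'     ("First Aid:", "Call 911")}
#'   \item{r4 (section_header)}{mention inside a header fragment ending in
#'     ":" that contains no verb}
#'   \item{r5 (template_pattern)}{parenthetical abbreviation expansions
#'     ("STD (sexually transmitted disease"); only mentions after the
#'     expansion point are suppressed}
#' }
#' Rules are data: ship your own YAML via [read_exclusion_rules()].
#'
#' @return list of rule definitions
#' @export
default_exclusion_rules <- function() {
  read_exclusion_rules(system.file("extdata", "exclusion_rules.yaml",
                                   package = "canscreen", mustWork = TRUE))
}

#' Read exclusion rules from a YAML file
#'
#' Each rule has `rule_id`, `kind` (one of `phrase_blacklist`,
#' `template_pattern`, `section_header`, `non_patient_subject`), `scope`
#' (`sentence` or `note`), and kind-specific parameters. An unknown kind is
#' a configuration error at load time.
#'
#' @param path YAML file
#' @return list of rules
#' @export
read_exclusion_rules <- function(path) {
  y <- yaml::read_yaml(path)
  rules <- y$rules
  ids <- vapply(rules, function(r) r$rule_id, "")
  if (anyDuplicated(ids)) stop_fmt("duplicate exclusion rule_id")
  kinds <- c("phrase_blacklist", "template_pattern", "section_header",
             "non_patient_subject")
  for (r in rules) {
    if (!r$kind %in% kinds) {
      stop_fmt("exclusion rule '%s': unknown kind '%s' (allowed: %s)",
               r$rule_id, r$kind, paste(kinds, collapse = ", "))
    }
  }
  rules
}

# does rule `r` fire for mention row `m` (note coords) in sentence `sent`?
exclusion_fires <- function(r, m, sent) {
  rel_begin <- m$begin - sent$begin  # 0-based offset within sentence
  stext <- sent$text
  switch(r$kind,
    phrase_blacklist = {
      any(vapply(r$phrases, function(p) {
        grepl(p, stext, ignore.case = TRUE, fixed = FALSE)
      }, TRUE))
    },
    template_pattern = {
      for (p in r$patterns) {
        mt <- regexpr(p, stext, ignore.case = !isTRUE(r$case_sensitive),
                      perl = TRUE)
        if (mt[1] == -1) next
        if (isTRUE(r$mention_after_match)) {
          if (rel_begin >= mt[1] - 1 + attr(mt, "match.length")) return(TRUE)
        } else {
          return(TRUE)
        }
      }
      FALSE
    },
    section_header = {
      # colon at/after mention end; fragment from sentence start (or the
      # previous colon) up to it must contain no verb
      colons <- gregexpr(":", stext, fixed = TRUE)[[1]]
      if (colons[1] == -1) return(FALSE)
      rel_end <- m$end - sent$begin
      colon <- colons[colons >= rel_end + 1][1]
      if (is.na(colon)) return(FALSE)
      prev <- colons[colons < rel_begin]
      frag_start <- if (length(prev) > 0) max(prev) + 1 else 1
      frag <- substr(stext, frag_start, colon - 1)
      fw <- tolower(word_tokens(frag))
      !any(fw %in% HEADER_VERBS)
    },
    non_patient_subject = {
      toks <- can_tokenize(stext)
      wt <- toks[toks$is_word, , drop = FALSE]
      words <- tolower(wt$token)
      if (!any(words %in% tolower(unlist(r$history_markers)))) return(FALSE)
      m_first <- which(wt$begin + sent$begin >= m$begin)[1]
      if (is.na(m_first)) return(FALSE)
      kin <- which(words %in% tolower(unlist(r$kin_tokens)))
      window <- r$window_tokens %||% 6
      any(kin < m_first & m_first - kin <= window)
    },
    FALSE
  )
}

#' Apply exclusion rules to mentions
#'
#' Runs every rule against every mention (negation flags are expected to be
#' set already); the first firing rule's id is recorded. Exclusions are
#' monotone: they only ever turn mentions off.
#'
#' @param mentions mention tibble (any number of sentences/notes)
#' @param sentences sentence tibble covering those mentions
#' @param rules list of rules (default [default_exclusion_rules()])
#' @return `mentions` with `excluded` / `exclusion_rule_id` updated
#' @export
apply_exclusions <- function(mentions, sentences,
                             rules = default_exclusion_rules()) {
  if (nrow(mentions) == 0 || length(rules) == 0) return(mentions)
  skey <- paste(sentences$note_id, sentences$index)
  for (i in seq_len(nrow(mentions))) {
    if (mentions$excluded[i]) next
    si <- match(paste(mentions$note_id[i], mentions$sentence_index[i]), skey)
    if (is.na(si)) next
    sent <- sentences[si, ]
    for (r in rules) {
      if (exclusion_fires(r, mentions[i, ], sent)) {
        mentions$excluded[i] <- TRUE
        mentions$exclusion_rule_id[i] <- r$rule_id
        break
      }
    }
  }
  mentions
}

#' Corroborate low-specificity mentions
#'
#' Terms such as "police" or "case manager" indicate CAN only when stronger
#' evidence appears nearby: a low-specificity mention is excluded unless a
#' standard-specificity, non-negated, non-excluded mention occurs within
#' `window_sentences` sentences of it in the same note.
#'
#' @param mentions full-document mention set (negation and exclusions
#'   already applied)
#' @param window_sentences corroboration window (default 3; 0 = same
#'   sentence only)
#' @return `mentions` with uncorroborated low-specificity mentions excluded
#'   (`exclusion_rule_id` = `"low_specificity"`)
#' @export
corroborate_low_specificity <- function(mentions, window_sentences = 3) {
  if (nrow(mentions) == 0) return(mentions)
  for (nid in unique(mentions$note_id)) {
    in_note <- mentions$note_id == nid
    anchor_idx <- mentions$sentence_index[in_note &
      mentions$specificity == "standard" &
      !mentions$negated & !mentions$excluded]
    low <- which(in_note & mentions$specificity == "low" &
                   !mentions$negated & !mentions$excluded)
    for (i in low) {
      if (!any(abs(anchor_idx - mentions$sentence_index[i]) <=
                 window_sentences)) {
        mentions$excluded[i] <- TRUE
        mentions$exclusion_rule_id[i] <- "low_specificity"
      }
    }
  }
  mentions
}

#' Classify sentences from their finalized mentions
#'
#' A sentence is CAN-positive when it contains at least one mention that is
#' neither negated nor excluded; its active subtypes are the subtypes of
#' those qualifying mentions.
#'
#' @param mentions finalized mention tibble
#' @param sentences sentence tibble (every sentence gets a label)
#' @return tibble: `note_id`, `sentence_index`, `positive`,
#'   `active_subtypes` (comma-joined), `n_mentions`
#' @export
classify_sentences <- function(mentions, sentences) {
  qual <- mentions[!mentions$negated & !mentions$excluded, , drop = FALSE]
  key <- paste(sentences$note_id, sentences$index)
  qkey <- paste(qual$note_id, qual$sentence_index)
  labels <- tibble(
    note_id = sentences$note_id,
    sentence_index = sentences$index,
    positive = key %in% qkey,
    active_subtypes = vapply(key, function(k) {
      st <- sort(unique(qual$subtype[qkey == k]))
      paste(st, collapse = ",")
    }, "", USE.NAMES = FALSE),
    n_mentions = vapply(key, function(k) sum(qkey == k), 0L,
                        USE.NAMES = FALSE)
  )
  labels
}

#' Classify notes from their sentence labels
#'
#' A note is CAN-positive when at least one of its sentences is positive.
#'
#' @param sentence_labels output of [classify_sentences()]
#' @return tibble: `note_id`, `positive`, `n_positive_sentences`, plus one
#'   count column per subtype
#' @export
classify_document <- function(sentence_labels) {
  by_note <- split(sentence_labels, sentence_labels$note_id)
  rows <- lapply(by_note, function(d) {
    st <- unlist(strsplit(d$active_subtypes[d$positive], ","))
    counts <- as.list(as.integer(table(factor(st, levels = can_subtypes()))))
    names(counts) <- can_subtypes()
    dplyr::bind_cols(
      tibble(note_id = d$note_id[1],
             positive = any(d$positive),
             n_positive_sentences = sum(d$positive)),
      as_tibble(counts)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(note_id = character(), positive = logical(),
                  n_positive_sentences = integer())
    for (s in can_subtypes()) out[[s]] <- integer()
  }
  out[order(out$note_id), , drop = FALSE]
}

#' Annotate a corpus end to end
#'
#' Runs the full rule-based pipeline over every note: sentence detection,
#' tokenization, dictionary NER, negation, exclusion rules, low-specificity
#' corroboration, and sentence/document classification. The full
#' configuration (all stages on, corroboration window 3) is the default;
#' stages can be toggled for ablation.
#'
#' @param notes corpus tibble (see [read_corpus()])
#' @param lexicon lexicon tibble, or an already-compiled `can_matcher`
#' @param negation apply negation detection (default TRUE)
#' @param exclusions apply exclusion rules (default TRUE)
#' @param corroboration_window sentences; `NULL` disables corroboration
#' @param negation_rules,exclusion_rules rule sets (defaults shipped)
#' @return object of class `can_annotations`: list of tibbles `mentions`,
#'   `sentences`, `sentence_labels`, `document_labels`, plus `config`
#' @export
annotate_corpus <- function(notes, lexicon = starter_lexicon(),
                            negation = TRUE, exclusions = TRUE,
                            corroboration_window = 3,
                            negation_rules = default_negation_rules(),
                            exclusion_rules = default_exclusion_rules()) {
  matcher <- if (inherits(lexicon, "can_matcher")) lexicon
             else compile_matcher(lexicon)
  all_sent <- vector("list", nrow(notes))
  all_ment <- vector("list", nrow(notes))
  for (i in seq_len(nrow(notes))) {
    nid <- notes$note_id[i]
    sents <- split_sentences(notes$text[i], note_id = nid)
    all_sent[[i]] <- sents
    if (nrow(sents) == 0) next
    ments <- vector("list", nrow(sents))
    for (j in seq_len(nrow(sents))) {
      toks <- can_tokenize(sents$text[j], offset = sents$begin[j])
      m <- match_entities(toks, matcher, note_id = nid,
                          sentence_index = sents$index[j])
      if (nrow(m) > 0) {
        m$matched_surface <- substring(notes$text[i], m$begin + 1, m$end)
        if (negation) m <- detect_negation(m, toks, negation_rules)
      }
      ments[[j]] <- m
    }
    all_ment[[i]] <- dplyr::bind_rows(ments)
  }
  sentences <- dplyr::bind_rows(all_sent)
  mentions <- dplyr::bind_rows(all_ment)
  if (ncol(mentions) == 0) {
    mentions <- match_entities(can_tokenize(""), matcher)  # empty frame
  }
  if (nrow(mentions) > 0) {
    if (exclusions) {
      mentions <- apply_exclusions(mentions, sentences, exclusion_rules)
    }
    if (!is.null(corroboration_window)) {
      mentions <- corroborate_low_specificity(mentions, corroboration_window)
    }
  }
  sentence_labels <- classify_sentences(mentions, sentences)
  document_labels <- classify_document(sentence_labels)
  # notes with no sentences still need a (negative) document label
  missing <- setdiff(notes$note_id, document_labels$note_id)
  if (length(missing) > 0) {
    extra <- tibble(note_id = missing, positive = FALSE,
                    n_positive_sentences = 0L)
    for (s in can_subtypes()) extra[[s]] <- 0L
    document_labels <- dplyr::bind_rows(document_labels, extra)
    document_labels <- document_labels[order(document_labels$note_id), ]
  }
  structure(
    list(mentions = mentions, sentences = sentences,
         sentence_labels = sentence_labels,
         document_labels = document_labels,
         config = list(negation = negation, exclusions = exclusions,
                       corroboration_window = corroboration_window)),
    class = "can_annotations"
  )
}

#' @export
print.can_annotations <- function(x, ...) {
  cat("<can_annotations>\n",
      " notes:             ", nrow(x$document_labels), "\n",
      " sentences:         ", nrow(x$sentences), "\n",
      " mentions:          ", nrow(x$mentions), "\n",
      " positive sentences:", sum(x$sentence_labels$positive), "\n",
      " positive notes:    ", sum(x$document_labels$positive), "\n")
  invisible(x)
}

#' Write annotations as JSON Lines
#'
#' One JSON object per record; files `mentions.jsonl`,
#' `sentence_labels.jsonl`, `document_labels.jsonl` under `dir`.
#'
#' @param ann `can_annotations` object
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_annotations <- function(ann, dir) {
  stopifnot(inherits(ann, "can_annotations"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dump <- function(df, file) {
    con <- file(file.path(dir, file), open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(df))) {
      writeLines(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE,
                                  na = "null"), con)
    }
  }
  dump(ann$mentions, "mentions.jsonl")
  dump(ann$sentence_labels, "sentence_labels.jsonl")
  dump(ann$document_labels, "document_labels.jsonl")
  invisible(dir)
}

#' Write BRAT-style standoff annotation files
#'
#' One `.ann` file per note: `T` lines carry the subtype and span of each
#' mention, `A` lines mark Negated / Excluded attributes.
#'
#' @param ann `can_annotations` object
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_brat <- function(ann, dir) {
  stopifnot(inherits(ann, "can_annotations"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nid in unique(ann$mentions$note_id)) {
    m <- ann$mentions[ann$mentions$note_id == nid, ]
    lines <- character()
    a <- 0
    for (i in seq_len(nrow(m))) {
      lines <- c(lines, sprintf("T%d\t%s %d %d\t%s", i, m$subtype[i],
                                m$begin[i], m$end[i], m$matched_surface[i]))
      if (m$negated[i]) {
        a <- a + 1
        lines <- c(lines, sprintf("A%d\tNegated T%d", a, i))
      }
      if (m$excluded[i]) {
        a <- a + 1
        lines <- c(lines, sprintf("A%d\tExcluded T%d %s", a, i,
                                  m$exclusion_rule_id[i]))
      }
    }
    writeLines(lines, file.path(dir, paste0(nid, ".ann")))
  }
  invisible(dir)
}
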