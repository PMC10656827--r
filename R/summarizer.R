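# Descriptive outputs: note-type positivity tables, subtype distributions,
# top-entity rankings, and highlighted renderings of annotated notes.

#' CAN positivity by note type
#'
#' One row per note type present in the corpus, with the number of notes,
#' the number flagged CAN-positive, and the positive percentage (rounded
#' half-up to 2 decimals), sorted ascending by percentage.
#'
#' @param document_labels document labels (from [classify_document()] or
#'   [annotate_corpus()])
#' @param notes corpus tibble; every label must join to a note
#' @return tibble: `note_type`, `n_notes`, `n_positive`, `positive_pct`
#' @export
note_type_table <- function(document_labels, notes) {
  i <- match(document_labels$note_id, notes$note_id)
  if (anyNA(i)) {
    stop_fmt("document label without matching note: '%s'",
             document_labels$note_id[which(is.na(i))[1]])
  }
  d <- tibble(note_type = notes$note_type[i],
              positive = document_labels$positive)
  out <- d %>%
    dplyr::group_by(note_type = .data$note_type) %>%
    dplyr::summarise(n_notes = dplyr::n(),
                     n_positive = sum(.data$positive), .groups = "drop") %>%
    dplyr::mutate(positive_pct =
                    round_half_up(100 * .data$n_positive / .data$n_notes, 2))
  out[order(out$positive_pct, out$note_type), , drop = FALSE]
}

#' Distribution of CAN hits by subtype
#'
#' Proportions over qualifying mentions (non-negated, non-excluded). All
#' five subtypes are reported, zeros included; proportions sum to 1. With
#' zero qualifying mentions an empty-flagged zero distribution is returned
#' rather than a division error.
#'
#' @param mentions finalized mention tibble
#' @return tibble: `subtype`, `n`, `proportion`; attribute `empty` is TRUE
#'   when there were no qualifying mentions
#' @export
subtype_distribution <- function(mentions) {
  qual <- mentions[!mentions$negated & !mentions$excluded, , drop = FALSE]
  counts <- table(factor(qual$subtype, levels = can_subtypes()))
  out <- tibble(subtype = can_subtypes(), n = as.integer(counts))
  if (nrow(qual) == 0) {
    out$proportion <- 0
    attr(out, "empty") <- TRUE
  } else {
    out$proportion <- out$n / sum(out$n)
    attr(out, "empty") <- FALSE
  }
  out
}

#' Most frequent CAN entities
#'
#' Qualifying mentions counted by canonical lexicon surface, descending by
#' count with alphabetical tie-break.
#'
#' @param mentions finalized mention tibble
#' @param k number of entities to return
#' @return tibble: `lexicon_surface`, `n`
#' @export
top_entities <- function(mentions, k = 10) {
  stopifnot(k >= 1)
  qual <- mentions[!mentions$negated & !mentions$excluded, , drop = FALSE]
  if (nrow(qual) == 0) return(tibble(lexicon_surface = character(),
                                     n = integer()))
  counts <- qual %>% dplyr::count(lexicon_surface = .data$lexicon_surface)
  counts <- counts[order(-counts$n, counts$lexicon_surface), , drop = FALSE]
  utils::head(counts, k)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render a note with CAN mentions highlighted
#'
#' Wraps each qualifying (non-negated, non-excluded) mention in
#' subtype-tagged markup: HTML `<span class="can-SUBTYPE">` or ANSI terminal
#' color. Stripping the markup reproduces the original note text exactly
#' (HTML output entity-escapes the text; unescaping restores it).
#'
#' @param text note body
#' @param mentions mentions of this note, spans in note coordinates
#' @param format `"html"` or `"ansi"`
#' @return character scalar of marked-up text
#' @export
render_highlights <- function(text, mentions, format = c("html", "ansi")) {
  format <- match.arg(format)
  if (nrow(mentions) > 0 &&
      (min(mentions$begin) < 0 || max(mentions$end) > nchar(text))) {
    stop_fmt("mention span outside note text")
  }
  qual <- mentions[!mentions$negated & !mentions$excluded, , drop = FALSE]
  qual <- qual[order(qual$begin), , drop = FALSE]
  esc <- if (format == "html") html_escape else identity
  colors <- c(SEXUAL_ABUSE = 31, PHYSICAL_INDICATION = 33,
              EMOTIONAL_INDICATION = 35, ABUSE = 91, SERVICE = 36)
  pieces <- character()
  cursor <- 0L
  for (i in seq_len(nrow(qual))) {
    b <- qual$begin[i]; e <- qual$end[i]
    pieces <- c(pieces, esc(substring(text, cursor + 1, b)))
    seg <- esc(substring(text, b + 1, e))
    pieces <- c(pieces, if (format == "html") {
      sprintf('<span class="can-%s">%s</span>', qual$subtype[i], seg)
    } else {
      sprintf("\033[%dm%s\033[0m", colors[[qual$subtype[i]]], seg)
    })
    cursor <- e
  }
  paste0(paste(pieces, collapse = ""), esc(substring(text, cursor + 1)))
}

#' Remove highlight markup
#'
#' Inverse of [render_highlights()]: strips the span / ANSI wrappers (and,
#' for HTML, unescapes entities), recovering the original note text.
#'
#' @param marked output of [render_highlights()]
#' @param format `"html"` or `"ansi"`
#' @return character scalar
#' @export
strip_highlights <- function(marked, format = c("html", "ansi")) {
  format <- match.arg(format)
  if (format == "html") {
    x <- gsub('<span class="can-[A-Z_]+">', "", marked)
    x <- gsub("</span>", "", x, fixed = TRUE)
    x <- gsub("&lt;", "<", x, fixed = TRUE)
    x <- gsub("&gt;", ">", x, fixed = TRUE)
    gsub("&amp;", "&", x, fixed = TRUE)
  } else {
    gsub("\033\\[[0-9]+m", "", marked)
  }
}

#' Render a full note as a standalone HTML page
#'
#' @param text note body
#' @param mentions mentions of this note
#' @param title page title
#' @return character vector of HTML lines
#' @export
render_note_html <- function(text, mentions, title = "Annotated note") {
  body <- render_highlights(text, mentions, format = "html")
  c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
    sprintf("<title>%s</title>", html_escape(title)),
    "<style>",
    ".can-ABUSE{background:#ffd9b3}.can-SEXUAL_ABUSE{background:#ffb3b3}",
    ".can-PHYSICAL_INDICATION{background:#fff0a0}",
    ".can-EMOTIONAL_INDICATION{background:#e6ccff}",
    ".can-SERVICE{background:#b3e6ff}",
    "body{font-family:monospace;white-space:pre-wrap}",
    "</style></head><body>", body, "</body></html>")
}
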