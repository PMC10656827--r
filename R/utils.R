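#' @importFrom dplyr %>%
#' @importFrom tibble tibble as_tibble
NULL

# round-half-up; base round() is banker's rounding, which disagrees with the
# half-up convention used in the report tables
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a proportion as a percentage string
#'
#' Rounds half-up (so 0.605 becomes "60.5%", not "60.4%") to match the
#' formatting conventions of clinical evaluation tables.
#'
#' @param p proportion in \[0, 1\] (or `NA`)
#' @param digits decimal places (default 1)
#' @return character; `"NA"` for missing input
#' @export
format_pct <- function(p, digits = 1) {
  ifelse(is.na(p), "NA",
         paste0(formatC(round_half_up(100 * p, digits),
                        format = "f", digits = digits), "%"))
}

# the five CAN mention subtypes, in tie-break priority order (most clinically
# specific first); SERVICE last
CAN_SUBTYPES <- c("SEXUAL_ABUSE", "PHYSICAL_INDICATION",
                  "EMOTIONAL_INDICATION", "ABUSE", "SERVICE")

#' CAN mention subtypes
#'
#' The five categories a lexicon term (and hence a mention) can carry:
#' `ABUSE`, `SEXUAL_ABUSE`, `PHYSICAL_INDICATION`, `EMOTIONAL_INDICATION`,
#' `SERVICE`.
#'
#' @return character vector of the five subtype codes
#' @export
can_subtypes <- function() {
  c("ABUSE", "SEXUAL_ABUSE", "PHYSICAL_INDICATION",
    "EMOTIONAL_INDICATION", "SERVICE")
}

subtype_priority <- function(subtype) match(subtype, CAN_SUBTYPES)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
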