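#' Alphanumeric tokenization
#'
#' Splits text into tokens defined as maximal runs of consecutive
#' alphanumeric characters (Unicode letters and decimal digits). All other
#' characters — punctuation, whitespace, symbols — delimit tokens. This is
#' the unit of scoring everywhere in the package: gold annotations,
#' predictions and confusion counts are all projected onto these tokens.
#'
#' Offsets are 0-based, half-open, counted in Unicode code points.
#'
#' @param text A single character string (UTF-8). `NA` is an error.
#' @return A data.frame with columns `text`, `start`, `end`, one row per
#'   token, ordered by `start`. Zero rows for empty input.
#' @examples
#' tokenize("Stevens-Johnson syndrome")
#' tokenize("Mr J.B., aged 60")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- enc2utf8(text)
  empty <- data.frame(text = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  if (nchar(text, type = "chars") == 0L) return(empty)
  # gregexpr on a UTF-8 string reports character (code point) positions
  m <- gregexpr("[\\p{L}\\p{Nd}]+", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  data.frame(text = substring(text, start + 1L, start + len),
             start = start, end = start + as.integer(len),
             stringsAsFactors = FALSE)
}

#' Project gold spans onto tokens
#'
#' A token is labelled `NAME` if it overlaps any gold span by at least one
#' character, otherwise `NON_NAME`. Any-overlap is deliberate: a token only
#' partially covered by an annotation is still a name fragment and must be
#' treated as sensitive.
#'
#' @param tokens Token data.frame from [tokenize()].
#' @param gold_spans Span data.frame (columns `start`, `end`) or `NULL`.
#' @return Character vector of labels (`"NAME"`/`"NON_NAME"`), one per token.
#' @export
project_gold <- function(tokens, gold_spans = NULL) {
  n <- nrow(tokens)
  labels <- rep("NON_NAME", n)
  if (n == 0L || is.null(gold_spans) || nrow(gold_spans) == 0L) return(labels)
  for (i in seq_len(nrow(gold_spans))) {
    hit <- tokens$start < gold_spans$end[i] & tokens$end > gold_spans$start[i]
    labels[hit] <- "NAME"
  }
  labels
}

#' Short-token predicate
#'
#' Tokens of three or fewer characters ("short") proxy for initials and are
#' evaluated separately from longer tokens, which proxy for full name words.
#'
#' @param token Character vector of token texts, or a token data.frame.
#' @return Logical vector: `TRUE` where the token has <= 3 characters.
#' @export
is_short <- function(token) {
  if (is.data.frame(token)) token <- token$text
  nchar(token, type = "chars") <= 3L
}
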