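#' Rule lexicons for the regex name classifier
#'
#' Three families of triggers capture names from their context:
#' salutations that precede a name ("dr", "mr", "sister"), report labels
#' ending in a colon ("name:", "patient:"), and post-positioned credential
#' titles ("m.d.", "rn"). Between one and three words adjacent to a trigger
#' are captured; how many depends on capitalisation (see [rule_classify()]).
#'
#' @param salutations,labels,titles Character vectors of triggers
#'   (case-insensitive). `NULL` keeps the shipped defaults.
#' @param max_window Maximum number of words captured per trigger (3).
#' @return A list of class `ruleset`.
#' @export
ruleset <- function(salutations = NULL, labels = NULL, titles = NULL,
                    max_window = 3L) {
  def <- default_ruleset_lexicons()
  rs <- list(
    salutations = tolower(if (is.null(salutations)) def$salutations else salutations),
    labels = tolower(if (is.null(labels)) def$labels else labels),
    titles = tolower(if (is.null(titles)) def$titles else titles),
    max_window = as.integer(max_window))
  stopifnot(length(rs$salutations) > 0L, length(rs$labels) > 0L,
            length(rs$titles) > 0L, rs$max_window == 3L)
  class(rs) <- "ruleset"
  rs
}

default_ruleset_lexicons <- function() {
  read_ruleset(system.file("extdata", "ruleset.txt",
                           package = "redactnames", mustWork = TRUE),
               as_list = TRUE)
}

#' Read / write a rule lexicon file
#'
#' Plain-text format: `[salutations]`, `[labels]`, `[titles]` section
#' headers, one trigger per line, `#` comments.
#'
#' @param path File path.
#' @param as_list Return a bare list instead of a `ruleset` (internal).
#' @return A `ruleset` (or list).
#' @export
read_ruleset <- function(path, as_list = FALSE) {
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- NA_character_
  out <- list(salutations = character(0), labels = character(0),
              titles = character(0))
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      if (!section %in% names(out))
        stop(sprintf("unknown ruleset section '[%s]'", section), call. = FALSE)
    } else {
      if (is.na(section)) stop("trigger before any [section] header", call. = FALSE)
      out[[section]] <- c(out[[section]], tolower(ln))
    }
  }
  if (as_list) return(out)
  ruleset(out$salutations, out$labels, out$titles)
}

#' @rdname read_ruleset
#' @param rs A `ruleset`.
#' @export
write_ruleset <- function(rs, path) {
  lines <- c("[salutations]", rs$salutations,
             "[labels]", rs$labels,
             "[titles]", rs$titles)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# A trigger like "m.d." or "name:" is matched against consecutive
# alphanumeric tokens; trailing '.'/':' in the lexicon entry are decoration.
trigger_token_seq <- function(trigger) {
  toks <- regmatches(trigger, gregexpr("[\\p{L}\\p{Nd}]+", trigger, perl = TRUE))[[1]]
  tolower(toks)
}

starts_upper <- function(word) {
  grepl("^\\p{Lu}", word, perl = TRUE)
}

# TRUE if the raw text between code-point offsets [from, to) contains a
# sentence-terminating character or newline. Used to stop capture extension.
gap_has_boundary <- function(text, from, to) {
  if (to <= from) return(FALSE)
  gap <- substring(text, from + 1L, to)
  grepl("[.!?\n\r;]", gap)
}

#' Rule-based name classifier
#'
#' Flags candidate name spans from three context patterns over the
#' alphanumeric token stream:
#' \itemize{
#'   \item R1 salutation: one to three words following a salutation trigger.
#'   \item R2 label: one to three words following a label trigger (the
#'     trigger token must be immediately followed by a colon in the text).
#'   \item R3 title: one to three words preceding a credential title.
#' }
#' The first adjacent word is always captured; the second and third are
#' captured only while each additional word starts with an uppercase letter.
#' Capture never crosses a sentence-terminating character or newline, and
#' never exceeds three words. Triggers match whole tokens,
#' case-insensitively ("dr" fires as its own token, never inside "drug").
#' Overlapping captures are merged; output spans are trimmed to whole
#' tokens. By construction at least one word is always captured, which is
#' why the rules alone have low precision ("the doctor said" flags "said");
#' they exist to backstop the neural classifier on blatant contexts.
#'
#' @param text Narrative text.
#' @param rs A [ruleset()].
#' @return Span data.frame (`start`, `end`, `label`, `subtype`), sorted,
#'   non-overlapping, within text bounds.
#' @export
rule_classify <- function(text, rs = ruleset()) {
  stopifnot(inherits(rs, "ruleset"))
  toks <- tokenize(text)
  n <- nrow(toks)
  if (n == 0L) return(empty_spans())
  low <- tolower(toks$text)

  sal_seqs <- lapply(rs$salutations, trigger_token_seq)
  lab_seqs <- lapply(rs$labels, trigger_token_seq)
  tit_seqs <- lapply(rs$titles, trigger_token_seq)

  # match a trigger token sequence ending/starting at token index i;
  # between consecutive trigger tokens only punctuation ('.', '-') may occur
  match_seq_at <- function(seq, i) {
    k <- length(seq)
    if (k == 0L || i + k - 1L > n) return(FALSE)
    for (j in seq_len(k)) {
      if (low[i + j - 1L] != seq[j]) return(FALSE)
      if (j > 1L) {
        gap <- substring(text, toks$end[i + j - 2L] + 1L, toks$start[i + j - 1L])
        if (!grepl("^[.\\-]*$", gap)) return(FALSE)
      }
    }
    TRUE
  }

  capture_forward <- function(after_idx, skip_colon = FALSE) {
    # after_idx: index of last trigger token; capture words after_idx+1 ...
    first <- after_idx + 1L
    if (first > n) return(NULL)
    gap_from <- toks$end[after_idx]
    # a '.' or ':' immediately after the trigger belongs to the trigger
    gap <- substring(text, gap_from + 1L, toks$start[first])
    gap <- sub("^[.:]", "", gap)
    if (grepl("[.!?\n\r;:]", gap)) return(NULL)
    last <- first
    while (last - first + 1L < rs$max_window && last + 1L <= n &&
           starts_upper(toks$text[last + 1L]) &&
           !gap_has_boundary(text, toks$end[last], toks$start[last + 1L])) {
      last <- last + 1L
    }
    c(first, last)
  }

  capture_backward <- function(before_idx) {
    last <- before_idx - 1L
    if (last < 1L) return(NULL)
    if (gap_has_boundary(text, toks$end[last], toks$start[before_idx]))
      return(NULL)
    first <- last
    while (last - first + 1L < rs$max_window && first - 1L >= 1L &&
           starts_upper(toks$text[first - 1L]) &&
           !gap_has_boundary(text, toks$end[first - 1L], toks$start[first]))
      first <- first - 1L
    c(first, last)
  }

  spans <- list()
  add_capture <- function(rng) {
    if (!is.null(rng))
      spans[[length(spans) + 1L]] <<- c(toks$start[rng[1]], toks$end[rng[2]])
  }

  for (i in seq_len(n)) {
    for (seq in sal_seqs) {
      if (match_seq_at(seq, i))
        add_capture(capture_forward(i + length(seq) - 1L))
    }
    for (seq in lab_seqs) {
      if (match_seq_at(seq, i)) {
        last_tok <- i + length(seq) - 1L
        # label triggers require the colon in the running text
        rest <- substring(text, toks$end[last_tok] + 1L,
                          nchar(text, type = "chars"))
        if (startsWith(rest, ":"))
          add_capture(capture_forward(last_tok))
      }
    }
    for (seq in tit_seqs) {
      if (match_seq_at(seq, i))
        add_capture(capture_backward(i))
    }
  }
  if (length(spans) == 0L) return(empty_spans())
  df <- do.call(rbind, spans)
  normalize_spans(data.frame(start = df[, 1], end = df[, 2]),
                  nchar(text, type = "chars"))
}

#' Token labels from rule spans
#'
#' Convenience projection: label each alphanumeric token `NAME` when it is
#' covered by a rule span.
#'
#' @inheritParams rule_classify
#' @return Character label vector aligned with `tokenize(text)`.
#' @export
rule_classify_tokens <- function(text, rs = ruleset()) {
  project_gold(tokenize(text), rule_classify(text, rs))
}
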