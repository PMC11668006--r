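#' OR-combination of two token label vectors
#'
#' The ensemble's final label is `NAME` if either the neural classifier or
#' the rule classifier says `NAME`, and `NON_NAME` only when both agree on
#' `NON_NAME`. The OR can only add flags: ensemble recall and false-positive
#' rate are both at least each component's.
#'
#' @param labels_a,labels_b Character label vectors of equal length
#'   (`"NAME"`/`"NON_NAME"`).
#' @return Combined label vector.
#' @export
ensemble_or <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors differ in length", call. = FALSE)
  ifelse(labels_a == "NAME" | labels_b == "NAME", "NAME", "NON_NAME")
}

#' Redact flagged spans with a placeholder
#'
#' Every flagged span is replaced by the placeholder string; all characters
#' outside the spans are preserved exactly. No character of any flagged span
#' survives into the output. Spans must be non-overlapping (merge upstream,
#' e.g. via [normalize_spans()] or [labels_to_spans()]).
#'
#' @param text Narrative text.
#' @param spans Span data.frame (`start`, `end`), non-overlapping.
#' @param placeholder Non-empty replacement string (default `"NAME"`).
#' @return Redacted text.
#' @export
redact <- function(text, spans, placeholder = "NAME") {
  stopifnot(is.character(placeholder), length(placeholder) == 1L,
            nzchar(placeholder))
  if (is.null(spans) || NROW(spans) == 0L) return(text)
  o <- order(spans$start)
  s <- as.integer(spans$start[o]); e <- as.integer(spans$end[o])
  n <- nchar(text, type = "chars")
  if (any(s < 0L) || any(e > n) || any(s >= e))
    stop("span outside text bounds", call. = FALSE)
  if (any(s[-1] < e[-length(e)]))
    stop("overlapping spans: merge before redacting", call. = FALSE)
  pieces <- character(0)
  cursor <- 0L
  for (i in seq_along(s)) {
    pieces <- c(pieces, substring(text, cursor + 1L, s[i]), placeholder)
    cursor <- e[i]
  }
  paste0(paste(pieces, collapse = ""), substring(text, cursor + 1L, n))
}

#' De-identify one narrative
#'
#' Runs the neural classifier (and, unless disabled, the rule classifier on
#' the original-cased text), OR-combines the token labels, merges runs of
#' NAME tokens into spans, and redacts them with the placeholder.
#'
#' @param text Narrative text.
#' @param classifier A trained `redact_classifier`.
#' @param rs A [ruleset()], or `NULL` to disable the rule arm.
#' @param placeholder Replacement string.
#' @param threshold Optional override of the neural decision threshold.
#' @return List with `redacted` (text), `spans` (merged predicted spans),
#'   `labels` (per-token ensemble labels) and `tokens`.
#' @export
deidentify_narrative <- function(text, classifier, rs = ruleset(),
                                 placeholder = "NAME", threshold = NULL) {
  toks <- tokenize(text)
  labels <- predict_tokens(text, classifier, threshold)
  if (!is.null(rs)) labels <- ensemble_or(labels, rule_classify_tokens(text, rs))
  spans <- labels_to_spans(toks, labels)
  list(redacted = redact(text, spans, placeholder), spans = spans,
       labels = labels, tokens = toks)
}

#' De-identify a corpus and build the review queue
#'
#' Applies [deidentify_narrative()] to every narrative and collects the
#' review queue: the ids of narratives with at least one suspected name,
#' ordered by flagged-token count (descending) for triage. On data with the
#' low name prevalence typical of spontaneous reports this queue is a small
#' fraction of the corpus, which is what makes flag-and-review workflows
#' practical.
#'
#' @param corpus List of narratives ([annotated_narrative()] or lists with
#'   `id`, `text`).
#' @inheritParams deidentify_narrative
#' @return List with `predictions` (named list of span data.frames),
#'   `redacted` (named character vector), `review_queue` (character ids) and
#'   `flagged_tokens` (named integer vector for queue members).
#' @export
deidentify_corpus <- function(corpus, classifier, rs = ruleset(),
                              placeholder = "NAME", threshold = NULL) {
  res <- lapply(corpus, function(nar)
    deidentify_narrative(nar$text, classifier, rs, placeholder, threshold))
  ids <- vapply(corpus, function(nar) nar$id, character(1))
  names(res) <- ids
  predictions <- lapply(res, `[[`, "spans")
  redacted <- vapply(res, `[[`, character(1), "redacted")
  n_flagged <- vapply(res, function(r) sum(r$labels == "NAME"), integer(1))
  queue <- flag_for_review(predictions, n_flagged)
  list(predictions = predictions, redacted = redacted,
       review_queue = queue, flagged_tokens = n_flagged[queue])
}

#' Review queue from per-narrative predictions
#'
#' @param predictions Named list of predicted span data.frames by id.
#' @param n_flagged Optional named count of flagged tokens per id, used to
#'   order the queue (descending); unordered otherwise.
#' @return Character vector of narrative ids with >= 1 predicted span.
#' @export
flag_for_review <- function(predictions, n_flagged = NULL) {
  has <- vapply(predictions, function(p) !is.null(p) && NROW(p) > 0L,
                logical(1))
  ids <- names(predictions)[has]
  if (!is.null(n_flagged))
    ids <- ids[order(n_flagged[ids], decreasing = TRUE)]
  ids
}

#' Replace a gold name with a surrogate
#'
#' Substitutes the text of one existing gold span by a replacement name and
#' shifts all downstream gold spans by the length difference, preserving the
#' narrative's invariants. This is the building block of the sensitivity
#' protocol: re-running prediction after injecting surrogate names of
#' different origins probes whether detection depends on the specific name.
#'
#' @param narrative An [annotated_narrative()].
#' @param replacement_name Non-empty replacement string.
#' @param target_span A row (`start`, `end`) identifying an existing gold
#'   span; defaults to the first gold span.
#' @return A new [annotated_narrative()].
#' @export
inject_name <- function(narrative, replacement_name, target_span = NULL) {
  stopifnot(inherits(narrative, "annotated_narrative"),
            nzchar(replacement_name))
  spans <- narrative$spans
  if (nrow(spans) == 0L) stop("narrative has no gold spans", call. = FALSE)
  if (is.null(target_span))
    target_span <- spans[1L, ]
  hit <- which(spans$start == target_span$start & spans$end == target_span$end)
  if (length(hit) != 1L)
    stop("target_span is not a gold span of this narrative", call. = FALSE)
  s <- spans$start[hit]; e <- spans$end[hit]
  n <- nchar(narrative$text, type = "chars")
  new_len <- nchar(replacement_name, type = "chars")
  delta <- new_len - (e - s)
  text <- paste0(substring(narrative$text, 1L, s),
                 replacement_name,
                 substring(narrative$text, e + 1L, n))
  spans$end[hit] <- s + new_len
  after <- spans$start >= e & seq_len(nrow(spans)) != hit
  spans$start[after] <- spans$start[after] + delta
  spans$end[after] <- spans$end[after] + delta
  annotated_narrative(narrative$id, text, spans)
}

#' Name-injection sensitivity protocol
#'
#' For each surrogate name, injects it in place of a gold span, re-runs the
#' classifier, and records whether every token of the injected name was
#' fully covered by a predicted span (covering mode). A name only partially
#' flagged (e.g. surname caught, first name leaked) counts as not flagged.
#'
#' @param narrative An [annotated_narrative()] with at least one gold span.
#' @param names Character vector of surrogate full names.
#' @param classifier A trained `redact_classifier`.
#' @param rs A [ruleset()] or `NULL` (neural classifier alone).
#' @param target_span Gold span to replace; defaults to the first.
#' @return Data.frame with columns `name` and `flagged` (logical).
#' @export
sensitivity_analysis <- function(narrative, names, classifier, rs = NULL,
                                 target_span = NULL) {
  if (is.null(target_span)) target_span <- narrative$spans[1L, ]
  flagged <- vapply(names, function(nm) {
    nar <- inject_name(narrative, nm, target_span)
    toks <- tokenize(nar$text)
    labels <- predict_tokens(nar$text, classifier)
    if (!is.null(rs))
      labels <- ensemble_or(labels, rule_classify_tokens(nar$text, rs))
    pred <- labels_to_spans(toks, labels)
    # score only the injected span: it must leak no token
    probe <- annotated_narrative(nar$id, nar$text, data.frame(
      start = target_span$start,
      end = target_span$start + nchar(nm, type = "chars")))
    cc <- evaluate_covering(probe, pred)
    cc["all", "fn"] == 0L
  }, logical(1))
  data.frame(name = names, flagged = unname(flagged),
             stringsAsFactors = FALSE)
}
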