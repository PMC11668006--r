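#' Covering-mode confusion counts for one narrative
#'
#' Scores predicted NAME spans against gold annotations at the level of
#' alphanumeric tokens, in "covering" mode:
#' \itemize{
#'   \item A gold NAME token is a true positive only if some predicted span
#'     completely encapsulates it; partial coverage is a false negative
#'     (a leak).
#'   \item A gold NON-NAME token partially covered by any predicted span is
#'     a false positive.
#'   \item A gold NON-NAME token fully covered by a predicted span is
#'     forgiven (a true negative) when that same span also fully covers at
#'     least one gold NAME token — over-extension around a real name does
#'     not hurt precision — and a false positive otherwise (a spurious
#'     flag).
#'   \item All remaining NON-NAME tokens are true negatives.
#' }
#' Counts are kept separately for long (> 3 characters) and short (<= 3)
#' tokens; the `all` stratum is their componentwise sum.
#'
#' @param gold An [annotated_narrative()] (its `spans` are the gold
#'   standard).
#' @param predicted Predicted span data.frame (`start`, `end`); overlapping
#'   predictions are merged before scoring.
#' @return A `confusion_counts` object: a 3 x 4 integer matrix with rows
#'   `all`, `long`, `short` and columns `tp`, `fp`, `fn`, `tn`.
#' @export
evaluate_covering <- function(gold, predicted) {
  toks <- tokenize(gold$text)
  pred <- normalize_spans(predicted, nchar(gold$text, type = "chars"),
                          id = gold$id)
  labels <- project_gold(toks, gold$spans)
  n <- nrow(toks)
  if (n == 0L) return(confusion_counts_zero())
  ts <- toks$start; te <- toks$end
  if (nrow(pred) == 0L) {
    full <- rep(FALSE, n); partial <- rep(FALSE, n)
    forgiven <- rep(FALSE, n)
  } else {
    ps <- pred$start; pe <- pred$end
    # spans are disjoint and sorted: the only span that can fully cover
    # token t is the last one starting at or before t's start
    idx <- findInterval(ts, ps)
    has <- idx >= 1L
    full <- has & pe[pmax(idx, 1L)] >= te
    # overlap with span idx (starts at/before token) or span idx + 1
    ov1 <- has & pe[pmax(idx, 1L)] > ts
    nxt <- idx + 1L
    ov2 <- nxt <= length(ps) & ps[pmin(nxt, length(ps))] < te
    partial <- (ov1 | ov2) & !full
    # a span forgives fully covered NON-NAME tokens iff it fully covers
    # at least one gold NAME token
    span_forgives <- rep(FALSE, length(ps))
    cov_name <- full & labels == "NAME"
    if (any(cov_name)) span_forgives[unique(idx[cov_name])] <- TRUE
    forgiven <- full & span_forgives[pmax(idx, 1L)]
  }
  is_name <- labels == "NAME"
  tp <- is_name & full
  fn <- is_name & !full
  fp <- !is_name & (partial | (full & !forgiven))
  tn <- !is_name & !partial & !fp
  short <- is_short(toks)
  cell <- function(v, s) sum(v & s)
  m <- rbind(
    long = c(cell(tp, !short), cell(fp, !short), cell(fn, !short), cell(tn, !short)),
    short = c(cell(tp, short), cell(fp, short), cell(fn, short), cell(tn, short)))
  m <- rbind(all = colSums(m), m)
  colnames(m) <- c("tp", "fp", "fn", "tn")
  storage.mode(m) <- "integer"
  structure(m, class = c("confusion_counts", class(m)))
}

#' @export
print.confusion_counts <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}

confusion_counts_zero <- function() {
  m <- matrix(0L, 3L, 4L, dimnames = list(c("all", "long", "short"),
                                          c("tp", "fp", "fn", "tn")))
  structure(m, class = c("confusion_counts", class(m)))
}

#' Build a confusion-count table directly from cell values
#'
#' @param long,short Named numeric vectors with entries `tp`, `fp`, `fn`,
#'   `tn` for each stratum; the `all` stratum is their sum.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(long, short) {
  cells <- c("tp", "fp", "fn", "tn")
  stopifnot(all(cells %in% names(long)), all(cells %in% names(short)),
            all(long[cells] >= 0), all(short[cells] >= 0))
  m <- rbind(all = long[cells] + short[cells],
             long = long[cells], short = short[cells])
  colnames(m) <- cells
  storage.mode(m) <- "integer"
  structure(m, class = c("confusion_counts", class(m)))
}

#' Sum confusion counts over narratives
#'
#' @param counts_list List of `confusion_counts`.
#' @return Componentwise sum, a `confusion_counts`.
#' @export
sum_counts <- function(counts_list) {
  out <- Reduce(`+`, lapply(counts_list, unclass),
                unclass(confusion_counts_zero()))
  structure(out, class = c("confusion_counts", class(out)))
}

#' Score a whole corpus in covering mode
#'
#' @param gold_corpus List of [annotated_narrative()] objects.
#' @param predictions Named list of predicted span data.frames, one per
#'   narrative id (missing entries mean "no spans predicted").
#' @return A `confusion_counts` over the corpus.
#' @export
evaluate_corpus <- function(gold_corpus, predictions) {
  sum_counts(lapply(gold_corpus, function(nar) {
    evaluate_covering(nar, predictions[[nar$id]])
  }))
}

# round-half-up, matching how the reported percentages are printed
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Derived metrics from confusion counts
#'
#' Precision, recall and F1 are percentages rounded to the nearest whole
#' percent (half up); the false-positive rate — the share of gold NON-NAME
#' tokens flagged — is rounded to two decimals. F1 is the harmonic mean of
#' the unrounded precision and recall. A metric whose denominator is zero is
#' undefined and reported as `NA`, never as 0.
#'
#' @param counts A `confusion_counts`.
#' @return Data.frame with one row per stratum (`all`, `long`, `short`) and
#'   columns `precision`, `recall`, `f1`, `fpr`.
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"), all(counts >= 0))
  safe <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
  tp <- counts[, "tp"]; fp <- counts[, "fp"]
  fn <- counts[, "fn"]; tn <- counts[, "tn"]
  data.frame(
    stratum = rownames(counts),
    precision = round_half_up(safe(tp, tp + fp)),
    recall = round_half_up(safe(tp, tp + fn)),
    f1 = round_half_up(safe(2 * tp, 2 * tp + fp + fn)),
    fpr = round_half_up(safe(fp, fp + tn), 2L),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Narrative-level recall
#'
#' The fraction of name-bearing narratives in which no NAME token of the
#' chosen stratum leaked: denominator = narratives with at least one gold
#' NAME token of the stratum, numerator = those with zero false negatives
#' in the stratum. Rounded to a whole percent; `NA` when no narrative
#' qualifies.
#'
#' @param gold_corpus List of [annotated_narrative()] objects.
#' @param predictions Named list of predicted span data.frames by id.
#' @param stratum `"all"`, `"long"` or `"short"`.
#' @return Percentage (0-100) or `NA`.
#' @export
narrative_recall <- function(gold_corpus, predictions, stratum = "all") {
  stratum <- match.arg(stratum, c("all", "long", "short"))
  per <- vapply(gold_corpus, function(nar) {
    cc <- evaluate_covering(nar, predictions[[nar$id]])
    c(names = cc[stratum, "tp"] + cc[stratum, "fn"], fn = cc[stratum, "fn"])
  }, numeric(2))
  bearing <- per["names", ] > 0
  if (!any(bearing)) return(NA_real_)
  round_half_up(100 * sum(bearing & per["fn", ] == 0) / sum(bearing))
}

#' Full evaluation report for a corpus
#'
#' Combines covering-mode confusion counts, the derived stratified metrics,
#' narrative-level recall per stratum, and the count of narratives touched
#' by at least one predicted span.
#'
#' @inheritParams narrative_recall
#' @return List with elements `counts`, `metrics`, `narrative_recall`
#'   (named vector over strata) and `touched_narratives`.
#' @export
evaluation_report <- function(gold_corpus, predictions) {
  counts <- evaluate_corpus(gold_corpus, predictions)
  touched <- sum(vapply(gold_corpus, function(nar) {
    p <- predictions[[nar$id]]
    !is.null(p) && NROW(p) > 0L
  }, logical(1)))
  list(counts = counts,
       metrics = compute_metrics(counts),
       narrative_recall = c(
         all = narrative_recall(gold_corpus, predictions, "all"),
         long = narrative_recall(gold_corpus, predictions, "long"),
         short = narrative_recall(gold_corpus, predictions, "short")),
       touched_narratives = touched)
}

#' Construct a corpus and predictions realizing given confusion counts
#'
#' Builds a synthetic gold corpus plus prediction set whose covering-mode
#' evaluation reproduces the target counts exactly, per stratum. Used to
#' verify the evaluator against any published confusion table: every token
#' is an isolated word so each contributes exactly one independent cell
#' (tp: gold and exact prediction; fn: gold only; fp: spurious exact
#' prediction; tn: untouched). Long cells use 4-character words, short
#' cells 2-character words.
#'
#' @param target A `confusion_counts` (its `all` row must equal
#'   `long + short`).
#' @param tokens_per_narrative Number of tokens per generated narrative.
#' @return List with `corpus` (list of [annotated_narrative()]) and
#'   `predictions` (named list of span data.frames).
#' @export
make_confusion_fixture <- function(target, tokens_per_narrative = 5000L) {
  stopifnot(inherits(target, "confusion_counts"), all(target >= 0))
  if (!all(target["all", ] == target["long", ] + target["short", ]))
    stop("inconsistent target: 'all' stratum must equal long + short",
         call. = FALSE)
  words <- c(long_tp = "Abcd", long_fp = "drug", long_fn = "Efgh",
             long_tn = "dose", short_tp = "Ab", short_fp = "rx",
             short_fn = "Cd", short_tn = "mg")
  kinds <- c(rep(names(words)[1:4], times = target["long", c("tp", "fp", "fn", "tn")]),
             rep(names(words)[5:8], times = target["short", c("tp", "fp", "fn", "tn")]))
  if (length(kinds) == 0L) {
    nar <- annotated_narrative("fix0001", "")
    return(list(corpus = list(nar),
                predictions = stats::setNames(list(empty_spans()), nar$id)))
  }
  corpus <- list()
  predictions <- list()
  groups <- split(kinds, (seq_along(kinds) - 1L) %/% tokens_per_narrative)
  for (take in groups) {
    w <- words[take]
    nw <- nchar(w, type = "chars")
    end <- cumsum(nw + 1L) - 1L        # tokens separated by single spaces
    start <- end - nw
    text <- paste(w, collapse = " ")
    id <- sprintf("fix%04d", length(corpus) + 1L)
    is_gold <- grepl("tp|fn", take)
    is_pred <- grepl("tp|fp", take)
    gold <- if (any(is_gold)) data.frame(start = start[is_gold],
                                         end = end[is_gold]) else NULL
    corpus[[length(corpus) + 1L]] <- annotated_narrative(id, text, gold)
    predictions[[id]] <- if (any(is_pred))
      data.frame(start = start[is_pred], end = end[is_pred],
                 label = "NAME", subtype = "unspecified") else empty_spans()
  }
  list(corpus = corpus, predictions = predictions)
}
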