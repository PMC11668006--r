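#' Construct a narrative, optionally with gold NAME spans
#'
#' The package's working unit is the annotated narrative: a free-text case
#' narrative plus zero or more gold-standard NAME spans. Spans use 0-based,
#' half-open character offsets counted in Unicode code points. Overlapping
#' or touching spans are merged on construction: names are a single binary
#' class here, so span identity below the merged extent carries no meaning.
#'
#' @param id Non-empty string identifier, unique within a corpus.
#' @param text Narrative text (may be empty).
#' @param spans `NULL`, or a data.frame with columns `start`, `end` and
#'   optionally `label` (always `"NAME"`) and `subtype` (one of `doctor`,
#'   `patient`, `username`, `unspecified`).
#' @return A list of class `annotated_narrative` with elements `id`, `text`,
#'   `spans` (a normalized span data.frame, possibly 0-row).
#' @export
annotated_narrative <- function(id, text, spans = NULL) {
  stopifnot(is.character(id), length(id) == 1L, !is.na(id), nzchar(id),
            is.character(text), length(text) == 1L, !is.na(text))
  text <- enc2utf8(text)
  spans <- normalize_spans(spans, nchar(text, type = "chars"), id = id)
  structure(list(id = id, text = text, spans = spans),
            class = "annotated_narrative")
}

#' @export
print.annotated_narrative <- function(x, ...) {
  cat(sprintf("<annotated_narrative '%s': %d chars, %d NAME span(s)>\n",
              x$id, nchar(x$text, type = "chars"), nrow(x$spans)))
  invisible(x)
}

empty_spans <- function() {
  data.frame(start = integer(0), end = integer(0),
             label = character(0), subtype = character(0),
             stringsAsFactors = FALSE)
}

#' Validate, sort and merge a span table
#'
#' Bounds-checks spans against the text length and merges overlapping or
#' touching intervals into one. Subtypes survive merging only when a merged
#' group is homogeneous; otherwise the merged span is `unspecified`.
#'
#' @param spans A data.frame with `start`/`end` (and optional `label`,
#'   `subtype` columns), or `NULL`.
#' @param text_length Length of the narrative text in code points.
#' @param id Narrative id used in error messages.
#' @return Normalized span data.frame sorted by `start`.
#' @export
normalize_spans <- function(spans, text_length, id = "<unknown>") {
  if (is.null(spans) || NROW(spans) == 0L) return(empty_spans())
  spans <- as.data.frame(spans, stringsAsFactors = FALSE)
  stopifnot(all(c("start", "end") %in% names(spans)))
  start <- as.integer(spans$start)
  end <- as.integer(spans$end)
  if (any(is.na(start)) || any(is.na(end)))
    stop(sprintf("narrative '%s': non-integer span offsets", id))
  if (any(start < 0L) || any(end > text_length) || any(start >= end))
    stop(sprintf(
      "narrative '%s': span outside text bounds (text length %d)",
      id, text_length))
  subtype <- if ("subtype" %in% names(spans)) as.character(spans$subtype)
             else rep(NA_character_, length(start))
  subtype[is.na(subtype)] <- "unspecified"
  ok_sub <- c("doctor", "patient", "username", "unspecified")
  if (!all(subtype %in% ok_sub))
    stop(sprintf("narrative '%s': unknown span subtype", id))
  o <- order(start, end)
  start <- start[o]; end <- end[o]; subtype <- subtype[o]
  # merge overlapping/touching intervals
  ms <- start[1]; me <- end[1]; msub <- subtype[1]
  out_s <- integer(0); out_e <- integer(0); out_sub <- character(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
      if (!identical(subtype[i], msub)) msub <- "unspecified"
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me); out_sub <- c(out_sub, msub)
      ms <- start[i]; me <- end[i]; msub <- subtype[i]
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me); out_sub <- c(out_sub, msub)
  data.frame(start = out_s, end = out_e,
             label = rep("NAME", length(out_s)), subtype = out_sub,
             stringsAsFactors = FALSE)
}

#' Read a corpus from JSONL standoff format
#'
#' One JSON object per line: `{"id": str, "text": str, "spans": [{"start":
#' int, "end": int, "label": "NAME", "subtype": str?}]}`. The `spans` field
#' is optional. Offsets are Unicode code points.
#'
#' @param path Path to a JSONL file.
#' @return List of [annotated_narrative()] objects, in file order.
#' @export
read_jsonl_corpus <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
      error = function(e) stop(sprintf(
        "malformed JSON on line %d of '%s': %s", i, path, conditionMessage(e)),
        call. = FALSE))
    if (is.null(rec$id) || is.null(rec$text))
      stop(sprintf("line %d of '%s': missing 'id' or 'text'", i, path),
           call. = FALSE)
    spans <- rec$spans
    if (!is.null(spans) && !is.data.frame(spans) && length(spans) == 0L)
      spans <- NULL
    out[[i]] <- annotated_narrative(as.character(rec$id),
                                    as.character(rec$text), spans)
    ids[i] <- out[[i]]$id
  }
  if (anyDuplicated(ids))
    stop(sprintf("duplicate narrative id(s) in '%s': %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  out
}

#' Write a corpus in JSONL standoff format
#'
#' Inverse of [read_jsonl_corpus()]: reading the written file reproduces the
#' corpus exactly (ids, texts, normalized spans), including under multi-byte
#' text.
#'
#' @param corpus List of [annotated_narrative()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_jsonl_corpus <- function(corpus, path) {
  lines <- vapply(corpus, function(nar) {
    rec <- list(id = nar$id, text = nar$text)
    if (nrow(nar$spans) > 0L) {
      rec$spans <- lapply(seq_len(nrow(nar$spans)), function(i) list(
        start = nar$spans$start[i], end = nar$spans$end[i],
        label = nar$spans$label[i], subtype = nar$spans$subtype[i]))
    }
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, useBytes = FALSE)
  invisible(path)
}

#' Read one record of the i2b2 2014 de-identification XML dialect
#'
#' A record holds the document text in a `TEXT` element (CDATA) and typed
#' PHI annotations as children of a `TAGS` element, each carrying `start`,
#' `end` and `TYPE` attributes. Only person names are in scope here: `NAME`
#' tags of type `DOCTOR`, `PATIENT` or `USERNAME` become gold NAME spans
#' (subtype retained, but collapsed to the single NAME class for modelling
#' and scoring). All other PHI categories (DATE, LOCATION, AGE, ...) are
#' ignored, i.e. treated as NON-NAME.
#'
#' @param path Path to one i2b2 2014 XML record.
#' @param id Narrative id; defaults to the file name without extension.
#' @return An [annotated_narrative()].
#' @export
read_i2b2_xml <- function(path, id = NULL) {
  stopifnot(file.exists(path))
  if (is.null(id)) id <- sub("\\.[Xx][Mm][Ll]$", "", basename(path))
  doc <- xml2::read_xml(path)
  text_node <- xml2::xml_find_first(doc, ".//TEXT")
  tags_node <- xml2::xml_find_first(doc, ".//TAGS")
  if (inherits(text_node, "xml_missing") || inherits(tags_node, "xml_missing"))
    stop(sprintf("'%s': not an i2b2 2014 record (missing TEXT or TAGS)", path),
         call. = FALSE)
  text <- xml2::xml_text(text_node)
  name_tags <- xml2::xml_find_all(tags_node, "./NAME")
  if (length(name_tags) == 0L)
    return(annotated_narrative(id, text))
  start <- as.integer(xml2::xml_attr(name_tags, "start"))
  end <- as.integer(xml2::xml_attr(name_tags, "end"))
  type <- toupper(xml2::xml_attr(name_tags, "TYPE"))
  keep <- type %in% c("DOCTOR", "PATIENT", "USERNAME")
  spans <- data.frame(start = start[keep], end = end[keep],
                      label = "NAME", subtype = tolower(type[keep]),
                      stringsAsFactors = FALSE)
  annotated_narrative(id, text, spans)
}

#' Select narratives likely to contain names
#'
#' Spontaneous-report corpora have a very low prevalence of names, so
#' training sets are enriched by selecting candidate narratives whose text
#' matches context patterns (salutation-adjacent contexts, initial-like
#' uppercase pairs, sign-offs). Deterministic; preserves input order.
#'
#' @param corpus List of narratives ([annotated_narrative()] objects or
#'   plain lists with `id` and `text`).
#' @param patterns Character vector of PCRE regular expressions; defaults to
#'   the lexicon shipped with the package ([default_candidate_patterns()]).
#' @return The matching sub-corpus, with an attribute `pattern_hits`: a
#'   named integer vector of per-pattern narrative hit counts.
#' @export
select_candidates <- function(corpus, patterns = default_candidate_patterns()) {
  stopifnot(is.character(patterns), length(patterns) > 0L)
  for (p in patterns) {
    ok <- tryCatch({grepl(p, "probe", perl = TRUE); TRUE},
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop(sprintf("invalid candidate regex: '%s'", p), call. = FALSE)
  }
  texts <- vapply(corpus, function(n) n$text, character(1))
  hit_mat <- vapply(patterns, function(p) grepl(p, texts, perl = TRUE),
                    logical(length(texts)))
  if (length(texts) == 1L) hit_mat <- matrix(hit_mat, nrow = 1L)
  selected <- corpus[rowSums(hit_mat) > 0L]
  hits <- colSums(hit_mat)
  names(hits) <- patterns
  attr(selected, "pattern_hits") <- as.integer(hits) |> stats::setNames(patterns)
  selected
}

#' Default candidate-selection patterns
#'
#' Shipped as an editable plain-text lexicon (`extdata/candidate_patterns.txt`,
#' one PCRE per line, `#` comments). The patterns target contexts around
#' names — salutations, report labels, sign-offs — and uppercase initial
#' pairs, rather than names themselves.
#'
#' @param path Optional path to an alternative pattern file.
#' @return Character vector of regular expressions.
#' @export
default_candidate_patterns <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "candidate_patterns.txt",
                        package = "redactnames", mustWork = TRUE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
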