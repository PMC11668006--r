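#' Name lexicons for generation and sensitivity probes
#'
#' Shipped as editable plain-text lists under `extdata/` (one entry per
#' line, `#` comments): first names and last names (all longer than 3
#' characters, mixed origins so fairness probes like comparing South Asian
#' and common English names are expressible) and short tokens (<= 3
#' characters: initials and very short given names).
#'
#' @param dir Optional directory holding `names_first.txt`,
#'   `names_last.txt`, `names_initials.txt`; defaults to the shipped files.
#' @return List with character vectors `first`, `last`, `initials`.
#' @export
name_lexicon <- function(dir = NULL) {
  read_list <- function(fname) {
    path <- if (is.null(dir))
      system.file("extdata", fname, package = "redactnames", mustWork = TRUE)
    else file.path(dir, fname)
    lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
    lines[nzchar(lines) & !startsWith(lines, "#")]
  }
  list(first = read_list("names_first.txt"),
       last = read_list("names_last.txt"),
       initials = read_list("names_initials.txt"))
}

#' Default surrogate full names for the sensitivity protocol
#'
#' Ten full names of mixed origin drawn from the shipped lexicon.
#'
#' @return Character vector of length 10.
#' @export
surrogate_names <- function() {
  c("Ramesh Patel", "John Smith", "Jane Smith", "Hanna Rosling",
    "Priya Sharma", "Amara Okafor", "Fatima Hussain", "Lars Nilsson",
    "Keiko Tanaka", "Kwame Mensah")
}

# sentence inventories -------------------------------------------------------

filler_sentences <- function() c(
  "The patient took DRUG on DATE and developed a severe rash.",
  "Symptoms started two days after the second dose of DRUG.",
  "She reported nausea, dizziness and a persistent headache.",
  "The reaction resolved after the medication was withdrawn.",
  "He was admitted to hospital on DATE for observation.",
  "No previous history of allergy to this class of medicines.",
  "The rash spread to the arms and torso within 24 hours.",
  "Blood tests on DATE showed elevated liver enzymes.",
  "The event was considered serious and medically significant.",
  "Patient recovered fully within one week of stopping DRUG.",
  "Concomitant medication included DRUG for hypertension.",
  "The doctor said the symptoms had resolved by DATE.",
  "Her doctor suggested stopping DRUG immediately.",
  "Discussed with the nurse during the home visit.",
  "Swelling of the face and lips was observed on DATE.",
  "The injection site remained painful for several days.",
  "Fever of 39 degrees was recorded the following morning.",
  "The reporter considered the reaction related to DRUG.")

distractor_sentences <- function() c(
  "Stevens-Johnson syndrome was suspected on clinical review.",
  "Presentation was consistent with Parkinson disease.",
  "Thyroid tests excluded Graves disease.",
  "A Colles fracture was sustained in the fall.",
  "Bell palsy was considered in the differential diagnosis.",
  "Person A administered the first dose.",
  "Treated at Riverside General Hospital on DATE.",
  "The Yellow Card was submitted via the website.",
  "Hodgkin lymphoma had been diagnosed in 2015.",
  "Crohn disease is part of the medical history.")

# name-mention context templates; {N} marks the injected name
context_templates <- function() list(
  salutation = c("Reviewed by Dr {N} at the surgery.",
                 "Spoke to Mr {N} regarding the reaction.",
                 "Nurse {N} administered the vaccine.",
                 "Referred by Dr {N} on DATE."),
  label = c("Reporter: {N}.",
            "Patient: {N} experienced the symptoms below.",
            "Consultant: {N} reviewed the case."),
  title = c("Assessed by {N} MD.",
            "Report countersigned by {N} PhD.",
            "Case discussed with {N} MBBS."),
  bare = c("{N} developed hives shortly after the infusion.",
           "According to {N} the symptoms began overnight.",
           "{N} has since made a full recovery."),
  signature = c("Kind regards {N}",
                "Many thanks {N}",
                "Yours sincerely {N}"))

#' Configuration for the synthetic narrative generator
#'
#' Defaults emulate the structural characteristics of a held-out
#' spontaneous-report test set: 5,042 narratives of which 71 contain names,
#' 179 NAME tokens in total, 71 of them short (<= 3 characters, mostly
#' initials), name mentions appearing in salutation, label, title, bare and
#' signature contexts, and medical-eponym distractors sprinkled through the
#' text. Realized counts are exact, not merely expected: narratives and
#' tokens are partitioned before sampling.
#'
#' @param n_narratives Number of narratives (>= 0).
#' @param frac_with_names Fraction of narratives containing >= 1 name.
#' @param total_name_tokens Exact total number of NAME tokens, or `NULL` to
#'   draw per-narrative counts from `names_per_narrative`.
#' @param names_per_narrative Probability weights over 1, 2, 3, ... NAME
#'   tokens per name-bearing narrative (used when `total_name_tokens` is
#'   `NULL`, and as the allocation bias otherwise).
#' @param frac_initials Share of NAME tokens that are short (<= 3 chars).
#' @param context_mix Named weights over the five mention contexts
#'   `salutation`, `label`, `title`, `bare`, `signature`; must sum to 1.
#' @param distractor_rate Expected number of distractor sentences (medical
#'   eponyms, pseudo-identifiers, capitalized non-names) per narrative.
#' @param lowercase_rate Probability that a name token is typed in lower
#'   case (informal reporter style).
#' @param seed Integer seed; generation is fully deterministic given the
#'   config.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_narratives = 5042L,
                             frac_with_names = 71 / 5042,
                             total_name_tokens = 179L,
                             names_per_narrative = c(0.35, 0.40, 0.15, 0.10),
                             frac_initials = 71 / 179,
                             context_mix = c(salutation = 0.30, label = 0.15,
                                             title = 0.10, bare = 0.30,
                                             signature = 0.15),
                             distractor_rate = 0.05,
                             lowercase_rate = 0.03,
                             seed = 20201125L) {
  cfg <- list(n_narratives = as.integer(n_narratives),
              frac_with_names = frac_with_names,
              total_name_tokens = if (is.null(total_name_tokens)) NULL
                                  else as.integer(total_name_tokens),
              names_per_narrative = names_per_narrative / sum(names_per_narrative),
              frac_initials = frac_initials,
              context_mix = context_mix / sum(context_mix),
              distractor_rate = distractor_rate,
              lowercase_rate = lowercase_rate,
              seed = as.integer(seed))
  stopifnot(cfg$n_narratives >= 0L,
            cfg$frac_with_names >= 0, cfg$frac_with_names <= 1,
            cfg$frac_initials >= 0, cfg$frac_initials <= 1,
            cfg$distractor_rate >= 0, cfg$lowercase_rate >= 0,
            setequal(names(cfg$context_mix),
                     c("salutation", "label", "title", "bare", "signature")))
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generator conditions emulating an enriched training corpus
#'
#' Corpora used to fine-tune the classifier are enriched for names by
#' machine-assisted candidate selection, so their name prevalence is far
#' above the raw reporting stream: roughly 64 of every 100 narratives carry
#' at least one name, about 2.3 NAME tokens per narrative overall, and
#' about a quarter of NAME tokens are short. This helper scales those
#' anchor rates (299/467 name-bearing, 1,080 NAME tokens of which 267
#' short) to a corpus of `n_narratives`, realizing integer counts exactly.
#'
#' @param n_narratives Corpus size.
#' @param seed Integer seed.
#' @return A [synthetic_config()].
#' @export
training_config <- function(n_narratives, seed = 20201125L) {
  total <- max(1L, as.integer(round(n_narratives * 1080 / 467)))
  n_with <- max(1L, as.integer(round(n_narratives * 299 / 467)))
  total <- max(total, n_with)
  n_short <- as.integer(round(total * 267 / 1080))
  synthetic_config(n_narratives = n_narratives,
                   frac_with_names = n_with / n_narratives,
                   total_name_tokens = total,
                   frac_initials = n_short / total,
                   seed = seed)
}

#' Generate an annotated synthetic corpus
#'
#' Produces adverse-event-style narratives (drug and date mentions as
#' placeholder tokens, reaction vocabulary, eponym distractors) with gold
#' NAME spans exactly delimiting the injected names. The number of
#' name-bearing narratives, the total NAME token count and the short-token
#' share are realized exactly as configured. Deterministic given the seed.
#'
#' @param config A [synthetic_config()].
#' @param lexicon A [name_lexicon()].
#' @return List of [annotated_narrative()] objects.
#' @export
generate_corpus <- function(config = synthetic_config(),
                            lexicon = name_lexicon()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_narratives
  if (n == 0L) return(list())
  n_with_exact <- config$frac_with_names * n
  n_with <- as.integer(round(n_with_exact))
  if (abs(n_with_exact - n_with) > 1e-9)
    warning(sprintf("frac_with_names * n = %.3f is not an integer; using %d",
                    n_with_exact, n_with))
  with_names <- sort(sample.int(n, n_with))

  # exact token budget, partitioned across name-bearing narratives
  npn <- config$names_per_narrative
  if (n_with > 0L) {
    if (!is.null(config$total_name_tokens)) {
      total <- config$total_name_tokens
      if (total < n_with)
        stop("total_name_tokens must be >= number of name-bearing narratives",
             call. = FALSE)
      tokens_per <- rep(1L, n_with)
      extra <- total - n_with
      if (extra > 0L) {
        recipients <- sample.int(n_with, extra, replace = TRUE)
        tab <- tabulate(recipients, nbins = n_with)
        tokens_per <- tokens_per + tab
      }
    } else {
      tokens_per <- sample.int(length(npn), n_with, replace = TRUE, prob = npn)
      total <- sum(tokens_per)
    }
    n_short_exact <- config$frac_initials * total
    n_short <- as.integer(round(n_short_exact))
    if (abs(n_short_exact - n_short) > 1e-9)
      warning(sprintf("frac_initials * tokens = %.3f is not an integer; using %d",
                      n_short_exact, n_short))
    short_flags <- sample(c(rep(TRUE, n_short), rep(FALSE, total - n_short)))
  }

  fillers <- filler_sentences()
  distractors <- distractor_sentences()
  templates <- context_templates()
  ctx_names <- names(config$context_mix)

  draw_name_token <- function(short, position) {
    w <- if (short) sample(lexicon$initials, 1L)
         else if (position == 1L) sample(lexicon$first, 1L)
         else sample(lexicon$last, 1L)
    if (stats::runif(1) < config$lowercase_rate) w <- tolower(w)
    w
  }

  out <- vector("list", n)
  tok_cursor <- 0L
  widx <- 0L
  for (i in seq_len(n)) {
    sentences <- sample(fillers, sample(2:4, 1L))
    n_dis <- stats::rpois(1L, config$distractor_rate)
    if (n_dis > 0L)
      sentences <- append(sentences,
                          sample(distractors, min(n_dis, length(distractors))),
                          after = sample(0:length(sentences), 1L))
    mention_sentences <- character(0)
    mention_names <- character(0)
    if (i %in% with_names) {
      widx <- widx + 1L
      left <- tokens_per[widx]
      while (left > 0L) {
        m <- min(left, sample.int(3L, 1L, prob = c(0.3, 0.55, 0.15)))
        words <- vapply(seq_len(m), function(pos)
          draw_name_token(short_flags[tok_cursor + pos], pos), character(1))
        tok_cursor <- tok_cursor + m
        left <- left - m
        ctx <- sample(ctx_names, 1L, prob = config$context_mix)
        tpl <- sample(templates[[ctx]], 1L)
        mention_sentences <- c(mention_sentences, tpl)
        mention_names <- c(mention_names, paste(words, collapse = " "))
      }
      pos <- sort(sample.int(length(sentences) + 1L,
                             length(mention_sentences), replace = TRUE))
      for (k in seq_along(mention_sentences))
        sentences <- append(sentences, mention_sentences[k],
                            after = pos[k] + k - 1L)
    }
    # assemble text, replacing {N} and tracking span offsets
    text <- ""
    starts <- integer(0); ends <- integer(0)
    mi <- 0L
    for (s in sentences) {
      if (nzchar(text)) text <- paste0(text, " ")
      hit <- regexpr("{N}", s, fixed = TRUE)
      if (hit > 0L) {
        mi <- mi + 1L
        prefix <- substring(s, 1L, hit - 1L)
        suffix <- substring(s, hit + 3L, nchar(s))
        starts <- c(starts, nchar(text, type = "chars") +
                      nchar(prefix, type = "chars"))
        ends <- c(ends, nchar(text, type = "chars") +
                    nchar(prefix, type = "chars") +
                    nchar(mention_names[mi], type = "chars"))
        text <- paste0(text, prefix, mention_names[mi], suffix)
      } else {
        text <- paste0(text, s)
      }
    }
    spans <- if (length(starts)) data.frame(start = starts, end = ends) else NULL
    out[[i]] <- annotated_narrative(sprintf("syn%06d", i), text, spans)
  }
  out
}
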