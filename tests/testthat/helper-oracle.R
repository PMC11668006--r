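# Independent brute-force reference for covering-mode scoring.
# Works character by character, with no shared code with the package:
# tokens are found by scanning, predicted coverage is a per-character mask,
# and effective spans are the maximal runs of covered characters.
oracle_covering <- function(text, gold_spans, pred_spans) {
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  is_alnum <- grepl("[\\p{L}\\p{Nd}]", chars, perl = TRUE)
  gold_mask <- rep(FALSE, n)
  if (!is.null(gold_spans) && NROW(gold_spans) > 0)
    for (i in seq_len(NROW(gold_spans)))
      gold_mask[seq(gold_spans$start[i] + 1, gold_spans$end[i])] <- TRUE
  pred_mask <- rep(FALSE, n)
  if (!is.null(pred_spans) && NROW(pred_spans) > 0)
    for (i in seq_len(NROW(pred_spans)))
      pred_mask[seq(pred_spans$start[i] + 1, pred_spans$end[i])] <- TRUE
  # effective predicted spans: maximal runs of covered characters
  run_id <- cumsum(c(pred_mask[1], diff(pred_mask) == 1)) * pred_mask

  # scan tokens
  toks <- list()
  i <- 1
  while (i <= n) {
    if (is_alnum[i]) {
      j <- i
      while (j + 1 <= n && is_alnum[j + 1]) j <- j + 1
      toks[[length(toks) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  tok_info <- lapply(toks, function(t) {
    pos <- seq(t[1], t[2])
    list(len = length(pos),
         name = any(gold_mask[pos]),
         full = all(pred_mask[pos]),
         some = any(pred_mask[pos]),
         run = if (all(pred_mask[pos])) run_id[pos[1]] else NA)
  })
  # which runs fully cover at least one NAME token
  forgiving <- unique(unlist(lapply(tok_info, function(t)
    if (t$name && t$full) t$run else NULL)))
  cell <- function(t) {
    if (t$name) { if (t$full) "tp" else "fn" }
    else if (t$full) { if (t$run %in% forgiving) "tn" else "fp" }
    else if (t$some) "fp"
    else "tn"
  }
  m <- matrix(0L, 3, 4, dimnames = list(c("all", "long", "short"),
                                        c("tp", "fp", "fn", "tn")))
  for (t in tok_info) {
    stratum <- if (t$len <= 3) "short" else "long"
    m[stratum, cell(t)] <- m[stratum, cell(t)] + 1L
    m["all", cell(t)] <- m["all", cell(t)] + 1L
  }
  m
}

# random scoring instance: a short narrative of random words plus random
# non-overlapping gold and predicted spans (both may be empty)
random_instance <- function(max_tokens = 20) {
  n_tok <- sample.int(max_tokens, 1)
  words <- replicate(n_tok, paste(sample(c(letters, LETTERS, 0:9),
                                         sample.int(6, 1), replace = TRUE),
                                  collapse = ""))
  seps <- c(" ", ", ", ". ", "-", " ... ")
  text <- words[1]
  if (n_tok > 1)
    for (w in words[-1]) text <- paste0(text, sample(seps, 1), w)
  n <- nchar(text)
  rand_spans <- function(k) {
    if (k == 0 || n < 2) return(NULL)
    cuts <- sort(sample.int(n + 1, min(2 * k, n + 1)) - 1)
    s <- cuts[seq(1, length(cuts) - 1, by = 2)]
    e <- cuts[seq(2, length(cuts), by = 2)]
    keep <- s < e
    if (!any(keep)) return(NULL)
    data.frame(start = s[keep], end = e[keep])
  }
  list(text = text,
       gold = rand_spans(sample(0:3, 1)),
       pred = rand_spans(sample(0:3, 1)))
}

make_corpus_predictions <- function(corpus, classifier, rs = NULL,
                                    threshold = NULL) {
  preds <- lapply(corpus, function(nar) {
    toks <- tokenize(nar$text)
    labels <- predict_tokens(nar$text, classifier, threshold)
    if (!is.null(rs))
      labels <- ensemble_or(labels, rule_classify_tokens(nar$text, rs))
    labels_to_spans(toks, labels)
  })
  names(preds) <- vapply(corpus, `[[`, character(1), "id")
  preds
}

# small fast model for unit tests (not the study conditions)
fast_config <- function(seed = 1L, epochs = 3L, lr = 1e-3) {
  model_config(epochs = epochs, learning_rate = lr, seed = seed,
               hidden_size = 16L, vocab_size = 256L,
               max_sequence_length = 128L)
}
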