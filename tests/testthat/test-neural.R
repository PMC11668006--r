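test_that("sequence splitting respects the unit budget and word groups", {
  one <- split_sequences(as.list(1:100), 512)
  expect_length(one, 1L)

  two <- split_sequences(as.list(1:1000), 512)
  expect_length(two, 2L)
  expect_lte(length(unlist(two[[1]])), 510L)
  expect_identical(unlist(two), 1:1000)

  # groups are never split across chunks
  groups <- list(1:4, 5:10, 11:12, 13:19, 20:20)
  chunks <- split_sequences(groups, 10)   # capacity 8 content units
  expect_identical(unlist(chunks), 1:20)
  for (ch in chunks) {
    expect_lte(length(unlist(ch)), 8L)
    for (g in ch) expect_true(all(diff(g) == 1))  # each group intact
  }

  # an oversized single word is truncated with a warning
  expect_warning(tr <- split_sequences(list(1:50), 10), "truncated")
  expect_length(unlist(tr), 8L)
})

test_that("analytic gradients match finite differences", {
  cfg <- model_config(seed = 5, hidden_size = 8L, vocab_size = 32L,
                      max_sequence_length = 16L)
  params <- redactnames:::init_params(cfg)
  ids <- c(1L, 7L, 12L, 7L, 30L, 2L)
  shapes <- c(1L, 2L, 10L, 2L, 1L, 1L)
  labels <- c(NA, 2L, 1L, 2L, 2L, NA)
  loss_at <- function(p) {
    fw <- redactnames:::tiny_forward(p, cfg, ids, shapes, keep = TRUE)
    redactnames:::tiny_backward(p, cfg, ids, shapes, fw, labels)$loss
  }
  fw <- redactnames:::tiny_forward(params, cfg, ids, shapes, keep = TRUE)
  grads <- redactnames:::tiny_backward(params, cfg, ids, shapes, fw, labels)$grads
  eps <- 1e-6
  set.seed(2)
  for (nm in c("Wq", "Wk", "Wv", "Wo", "Wf1", "Wf2", "Wc", "bc",
               "ln1_g", "ln2_b", "shape", "pos", "emb")) {
    idx <- sample.int(length(params[[nm]]), min(3L, length(params[[nm]])))
    for (k in idx) {
      up <- params; up[[nm]][k] <- up[[nm]][k] + eps
      dn <- params; dn[[nm]][k] <- dn[[nm]][k] - eps
      num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      expect_lt(abs(grads[[nm]][k] - num), 1e-5 + 1e-3 * abs(num))
    }
  }
})

test_that("zero-epoch training returns the initialized backend, training is reproducible", {
  corp <- generate_corpus(training_config(30, seed = 8))
  cfg <- fast_config(seed = 9, epochs = 0L)
  expect_identical(train(corp, cfg), init_classifier(cfg))

  cfg <- fast_config(seed = 9, epochs = 2L)
  clf1 <- suppressMessages(train(corp, cfg))
  clf2 <- suppressMessages(train(corp, cfg))
  probe <- "Reviewed by Dr Hanna Rosling after the DRUG infusion"
  expect_identical(predict_scores(probe, clf1), predict_scores(probe, clf2))
  expect_true(all(is.finite(attr(clf1, "epoch_loss"))))

  # degenerate one-class corpus warns
  flat <- list(annotated_narrative("f1", "no names at all here"))
  expect_warning(suppressMessages(train(flat, fast_config(epochs = 1L))),
                 "one token class")
  expect_error(train(list(), fast_config()), "length")
})

test_that("score pairs align one-to-one with tokens, also across chunks", {
  cfg <- model_config(seed = 3, hidden_size = 8L, vocab_size = 64L,
                      max_sequence_length = 12L)   # force many chunks
  clf <- init_classifier(cfg)
  set.seed(31)
  for (rep in 1:10) {
    words <- sample(c("pain", "DRUG", "Hanna", "J", "extraordinarily",
                      "dizziness", "b12", "Patel"), sample(1:60, 1),
                    replace = TRUE)
    text <- paste(words, collapse = " ")
    sc <- predict_scores(text, clf)
    expect_equal(nrow(sc), nrow(tokenize(text)))
    expect_true(all(abs(sc$p_name + sc$p_non_name - 1) < 1e-6))
  }
  expect_equal(nrow(predict_scores("", clf)), 0L)
})

test_that("threshold rule is strict and monotone in the threshold", {
  clf <- init_classifier(fast_config(seed = 12))
  text <- "Spoke to Mr Tariq Hussain about DRUG and the rash on DATE"
  sc <- predict_scores(text, clf)
  # strictness: at threshold exactly equal to a token's NON-NAME score,
  # that token must be NAME
  thr <- sc$p_non_name[1]
  expect_equal(predict_tokens(text, clf, threshold = thr)[1], "NAME")
  # monotonicity: lowering the threshold never adds NAME labels
  thresholds <- sort(c(0.1, 0.5, 0.9, 0.99, sc$p_non_name))
  prev <- NULL
  for (t in thresholds) {
    cur <- predict_tokens(text, clf, threshold = t) == "NAME"
    if (!is.null(prev)) expect_true(all(cur >= prev))
    prev <- cur
  }
})

test_that("a separable marker feature is learned to high recall", {
  # every name is preceded by a unique marker word: with a workable
  # learning rate the tiny backend must pick this up quickly
  set.seed(6)
  mk <- function(i, with_name) {
    if (with_name) {
      nm <- sample(c("Patel", "Rosling", "Hussain", "Tanaka", "Smith"), 1)
      text <- sprintf("report %d zqxj %s had a rash after DRUG", i, nm)
      s <- regexpr(nm, text, fixed = TRUE)
      annotated_narrative(sprintf("m%03d", i), text,
                          data.frame(start = s - 1, end = s - 1 + nchar(nm)))
    } else {
      annotated_narrative(sprintf("m%03d", i),
                          sprintf("report %d described nausea after DRUG", i))
    }
  }
  corp <- lapply(1:80, function(i) mk(i, i %% 2 == 0))
  clf <- suppressMessages(train(corp, fast_config(seed = 4, epochs = 8L,
                                                  lr = 5e-3)))
  held <- lapply(81:120, function(i) mk(i, i %% 2 == 0))
  preds <- make_corpus_predictions(held, clf)
  cc <- evaluate_corpus(held, preds)
  rec <- cc["all", "tp"] / (cc["all", "tp"] + cc["all", "fn"])
  expect_gte(rec, 0.9)
})

test_that("classifier save/load round-trips predictions exactly", {
  corp <- generate_corpus(training_config(20, seed = 14))
  clf <- suppressMessages(train(corp, fast_config(seed = 15, epochs = 1L)))
  d <- tempfile("clf")
  save_classifier(clf, d)
  clf2 <- load_classifier(d)
  probe <- "Reporter: K Chowdhury noted swelling on DATE"
  expect_equal(predict_scores(probe, clf2), predict_scores(probe, clf))
  expect_equal(clf2$config, clf$config)
  unlink(d, recursive = TRUE)
})

test_that("the pretrained backend is refused without shipped weights", {
  cfg <- model_config(backend = "pretrained_uncased_transformer")
  expect_error(init_classifier(cfg), "pretrained")
})
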