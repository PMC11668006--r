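# text laid out so token offsets are easy to read:
# "told that Agnes was unwell" -> told(0,4) that(5,9) Agnes(10,15)
# was(16,19) unwell(20,26)
eval_one <- function(gold, pred) {
  nar <- annotated_narrative("e1", "told that Agnes was unwell",
                             if (is.null(gold)) NULL else gold)
  evaluate_covering(nar, pred)
}

test_that("full encapsulation scores tp; partial coverage of a name is fn", {
  # predicted span over-extends around the gold NAME token: still a tp
  cc <- eval_one(data.frame(start = 10, end = 15),
                 data.frame(start = 5, end = 19))
  expect_equal(unname(cc["all", c("tp", "fn")]), c(1L, 0L))

  # incomplete coverage of the NAME token is a leak (fn)
  cc <- eval_one(data.frame(start = 10, end = 15),
                 data.frame(start = 10, end = 13))
  expect_equal(unname(cc["all", c("tp", "fn")]), c(0L, 1L))
})

test_that("covered NON-NAME tokens are forgiven only beside a covered name", {
  # span (5,19) fully covers NON-NAME "that"(5,9) and "was"(16,19) but also
  # fully covers NAME "Agnes": both forgiven, no fp
  cc <- eval_one(data.frame(start = 10, end = 15),
                 data.frame(start = 5, end = 19))
  expect_equal(unname(cc["all", "fp"]), 0L)
  expect_equal(unname(cc["all", "tn"]), 4L)

  # same span with no gold at all: fully covered NON-NAME tokens become fps
  cc <- eval_one(NULL, data.frame(start = 5, end = 19))
  expect_equal(unname(cc["all", "fp"]), 3L)

  # partially covered NON-NAME token is always an fp, even next to a tp:
  # span (5,22) covers "Agnes" fully but cuts "unwell"(20,26)
  cc <- eval_one(data.frame(start = 10, end = 15),
                 data.frame(start = 5, end = 22))
  expect_equal(unname(cc["all", c("tp", "fp")]), c(1L, 1L))
})

test_that("metrics derive from counts with half-up rounding and NA when undefined", {
  cc <- confusion_counts(long = c(tp = 102, fp = 73, fn = 6, tn = 1000),
                         short = c(tp = 53, fp = 54, fn = 18, tn = 500))
  m <- compute_metrics(cc)
  expect_equal(m$recall[m$stratum == "all"], 87)      # 155/179
  expect_equal(m$precision[m$stratum == "all"], 55)   # 155/282
  expect_equal(m$recall[m$stratum == "long"], 94)     # 102/108
  expect_equal(m$precision[m$stratum == "long"], 58)  # 102/175
  # 53/107 = 49.53: rounds up to 50 under half-up
  expect_equal(m$precision[m$stratum == "short"], 50)

  # half-up at exactly .5 (banker's rounding would give 86)
  cc2 <- confusion_counts(long = c(tp = 173, fp = 0, fn = 27, tn = 0),
                          short = c(tp = 0, fp = 0, fn = 0, tn = 0))
  expect_equal(compute_metrics(cc2)$recall[1], 87)    # 173/200 = 86.5

  # undefined metrics are NA, never zero
  cc3 <- confusion_counts(long = c(tp = 0, fp = 0, fn = 0, tn = 5),
                          short = c(tp = 0, fp = 0, fn = 0, tn = 0))
  m3 <- compute_metrics(cc3)
  expect_true(is.na(m3$precision[1]))
  expect_true(is.na(m3$recall[1]))
  expect_equal(m3$fpr[1], 0)
})

test_that("narrative recall counts leak-free name-bearing narratives", {
  mk <- function(id, leak) {
    nar <- annotated_narrative(id, "seen by Agnes Miller today",
                               data.frame(start = 8, end = 20))
    pred <- if (leak) redactnames:::empty_spans()
            else data.frame(start = 8, end = 20)
    list(nar = nar, pred = pred)
  }
  items <- c(lapply(1:3, function(i) mk(sprintf("leak%d", i), TRUE)),
             lapply(1:7, function(i) mk(sprintf("ok%d", i), FALSE)))
  corpus <- lapply(items, `[[`, "nar")
  preds <- lapply(items, `[[`, "pred")
  names(preds) <- vapply(corpus, `[[`, character(1), "id")
  expect_equal(narrative_recall(corpus, preds, "all"), 70)
  expect_equal(narrative_recall(corpus, preds, "long"), 70)
  # no narrative has short name tokens: undefined
  expect_true(is.na(narrative_recall(corpus, preds, "short")))

  # all leak -> 0
  all_leak <- lapply(preds, function(p) redactnames:::empty_spans())
  expect_equal(narrative_recall(corpus, all_leak, "all"), 0)
})

test_that("evaluator matches the brute-force oracle on random instances", {
  set.seed(123)
  for (i in 1:300) {
    inst <- random_instance()
    nar <- annotated_narrative("r", inst$text, inst$gold)
    got <- evaluate_covering(nar, inst$pred)
    want <- oracle_covering(inst$text, nar$spans, inst$pred)
    expect_identical(unclass(got), want,
                     label = sprintf("case %d: %s", i, inst$text))
  }
})

test_that("more predictions never raise fn; strata always sum to all", {
  set.seed(321)
  for (i in 1:100) {
    inst <- random_instance()
    nar <- annotated_narrative("r", inst$text, inst$gold)
    base <- evaluate_covering(nar, inst$pred)
    expect_equal(base["all", ], base["long", ] + base["short", ])
    # add one more predicted span
    n <- nchar(inst$text)
    extra <- sort(sample.int(n + 1, 2) - 1)
    if (extra[1] < extra[2]) {
      pred2 <- rbind(if (is.null(inst$pred)) NULL else inst$pred[, c("start", "end")],
                     data.frame(start = extra[1], end = extra[2]))
      more <- evaluate_covering(nar, pred2)
      expect_lte(more["all", "fn"], base["all", "fn"])
      expect_gte(more["all", "tp"], base["all", "tp"])
    }
  }
})

test_that("fixtures round-trip through the evaluator", {
  set.seed(55)
  for (i in 1:25) {
    target <- confusion_counts(
      long = c(tp = sample(0:20, 1), fp = sample(0:20, 1),
               fn = sample(0:20, 1), tn = sample(0:200, 1)),
      short = c(tp = sample(0:20, 1), fp = sample(0:20, 1),
                fn = sample(0:20, 1), tn = sample(0:200, 1)))
    fx <- make_confusion_fixture(target, tokens_per_narrative = 37L)
    got <- evaluate_corpus(fx$corpus, fx$predictions)
    expect_identical(unclass(got), unclass(target))
  }
  # inconsistent target rejected
  bad <- confusion_counts(long = c(tp = 1, fp = 0, fn = 0, tn = 0),
                          short = c(tp = 0, fp = 0, fn = 0, tn = 0))
  bad["all", "tp"] <- 5L
  expect_error(make_confusion_fixture(bad), "inconsistent")
})
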