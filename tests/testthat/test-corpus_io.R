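test_that("JSONL reader maps fields, validates bounds and names lines", {
  f <- tempfile(fileext = ".jsonl")
  writeLines(paste0('{"id":"n1","text":"seen by Dr Brown",',
                    '"spans":[{"start":11,"end":16,"label":"NAME"}]}'), f)
  corp <- read_jsonl_corpus(f)
  expect_length(corp, 1L)
  expect_equal(corp[[1]]$id, "n1")
  expect_equal(substring(corp[[1]]$text, corp[[1]]$spans$start + 1,
                         corp[[1]]$spans$end), "Brown")

  # empty file -> empty corpus
  writeLines(character(0), f)
  expect_length(read_jsonl_corpus(f), 0L)

  # span beyond the 16-char text -> validation error naming the narrative
  writeLines(paste0('{"id":"nbad","text":"seen by Dr Brown",',
                    '"spans":[{"start":11,"end":99}]}'), f)
  expect_error(read_jsonl_corpus(f), "nbad")

  # malformed JSON -> parse error naming the line
  writeLines(c('{"id":"a","text":"ok"}', "{broken"), f)
  expect_error(read_jsonl_corpus(f), "line 2")

  # duplicate ids rejected
  writeLines(rep('{"id":"dup","text":"x"}', 2), f)
  expect_error(read_jsonl_corpus(f), "dup")
})

test_that("JSONL round-trip is the identity, including multi-byte text", {
  set.seed(7)
  alphabet <- c(letters, LETTERS, " ", ".", ",", "é", "ñ", "ß", "中", "'")
  for (rep in 1:20) {
    corpus <- lapply(seq_len(sample.int(5, 1)), function(i) {
      text <- paste(sample(alphabet, sample(10:60, 1), replace = TRUE),
                    collapse = "")
      n <- nchar(text, type = "chars")
      k <- sample(0:2, 1)
      spans <- if (k > 0 && n >= 4) {
        cuts <- sort(sample.int(n, 2 * k))
        s <- cuts[seq(1, 2 * k - 1, 2)]; e <- cuts[seq(2, 2 * k, 2)]
        keep <- s < e
        if (any(keep)) data.frame(start = s[keep], end = e[keep]) else NULL
      } else NULL
      annotated_narrative(sprintf("r%d_%d", rep, i), text, spans)
    })
    f <- tempfile(fileext = ".jsonl")
    write_jsonl_corpus(corpus, f)
    expect_identical(read_jsonl_corpus(f), corpus)
    unlink(f)
  }
})

test_that("overlapping gold spans are merged on construction", {
  nar <- annotated_narrative("m1", "Anna Maria Svensson was seen",
                             data.frame(start = c(0, 5, 11), end = c(10, 19, 19)))
  expect_equal(nrow(nar$spans), 1L)
  expect_equal(nar$spans$start, 0L)
  expect_equal(nar$spans$end, 19L)
})

test_that("i2b2 reader keeps the three name subtypes and drops other PHI", {
  p <- system.file("extdata", "synthetic_i2b2_record.xml",
                   package = "redactnames")
  nar <- read_i2b2_xml(p)
  expect_s3_class(nar, "annotated_narrative")
  expect_equal(nar$spans$subtype, c("doctor", "patient", "username"))
  expect_equal(substring(nar$text, nar$spans$start + 1, nar$spans$end),
               c("Okafor", "Jane Mills", "jmills99"))
  # the record carries DATE and AGE tags: none may surface as spans
  expect_equal(nrow(nar$spans), 3L)

  # a record with only non-name PHI yields zero spans
  f <- tempfile(fileext = ".xml")
  writeLines(paste0('<deIdi2b2><TEXT><![CDATA[admitted on 2010-01-02]]></TEXT>',
                    '<TAGS><DATE id="P0" start="12" end="22" TYPE="DATE"/>',
                    '</TAGS></deIdi2b2>'), f)
  expect_equal(nrow(read_i2b2_xml(f)$spans), 0L)

  # missing TAGS is a format error
  writeLines('<deIdi2b2><TEXT><![CDATA[x]]></TEXT></deIdi2b2>', f)
  expect_error(read_i2b2_xml(f), "TAGS")
  unlink(f)
})

test_that("candidate selection returns an ordered, idempotent subset", {
  corp <- list(annotated_narrative("a", "spoke to dr. Jones about rash"),
               annotated_narrative("b", "no identifying context at all"),
               annotated_narrative("c", "Reporter: H Smith"))
  sel <- select_candidates(corp)
  expect_equal(vapply(sel, `[[`, character(1), "id"), c("a", "c"))
  sel2 <- select_candidates(sel)
  expect_equal(vapply(sel2, `[[`, character(1), "id"), c("a", "c"))
  hits <- attr(sel, "pattern_hits")
  expect_true(sum(hits) >= 2)
  expect_error(select_candidates(corp, "(unclosed"), "invalid")
})

test_that("candidate selection enriches name prevalence on synthetic data", {
  cfg <- synthetic_config(n_narratives = 1000, frac_with_names = 0.02,
                          total_name_tokens = 45, frac_initials = 9 / 45,
                          seed = 99)
  corp <- generate_corpus(cfg)
  sel <- select_candidates(corp)
  prev <- function(x) mean(vapply(x, function(n) nrow(n$spans) > 0, logical(1)))
  expect_lt(length(sel), length(corp))
  expect_gt(prev(sel), prev(corp))
})
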