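# Corpus schema, round-tripping and the CRF training-file layouts.

make_demo_corpus <- function() {
  a1 <- pico_abstract("A1", "Aspirin in stroke patients",
    sentence_table(
      c("Stroke is a leading cause of disability.",
        "We enrolled 200 adult patients with prior stroke.",
        "Patients received aspirin or placebo.",
        "Mortality was reduced in the aspirin group.",
        "Aspirin appears beneficial."),
      raw_header = c("OBJECTIVE", "METHODS", "METHODS", "RESULTS", "CONCLUSIONS"),
      labels = list("BACKGROUND", "POPULATION",
                    c("INTERVENTION", "POPULATION"), "OUTCOME", "OTHER")),
    keywords = c("aspirin", "stroke"))
  a2 <- pico_abstract("A2", "Therapy for diabetes",
    sentence_table(
      c("Diabetes affects many adults.",
        "Intensive therapy was compared with standard care.",
        "Outcomes improved with intensive therapy.",
        "These findings warrant replication.",
        "Further trials are needed."),
      labels = list("BACKGROUND", "INTERVENTION", "OUTCOME", "OTHER", "OTHER")))
  pico_corpus(list(a1, a2), provenance = "demo")
}

test_that("JSON round trip preserves structure and is byte-stable", {
  corp <- make_demo_corpus()
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_corpus(corp, f1, "json")
  back <- read_corpus(f1)
  expect_length(back$abstracts, 2)
  expect_equal(vapply(back$abstracts, function(a) nrow(a$sentences), integer(1)),
               c(5L, 5L))
  expect_equal(back$abstracts[[1]]$sentences$index, 1:5)
  expect_true(back$abstracts[[1]]$is_structured)
  expect_false(back$abstracts[[2]]$is_structured)
  expect_equal(back$abstracts[[1]]$sentences$labels[[3]],
               c("INTERVENTION", "POPULATION"))
  # canonical form: write(read(write(x))) is byte-identical to write(x)
  write_corpus(back, f2, "json")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("CSV round trip preserves sentences, labels and keywords", {
  corp <- make_demo_corpus()
  f <- tempfile(fileext = ".csv")
  write_corpus(corp, f, "csv")
  back <- read_corpus(f)
  expect_equal(corpus_summary <- length(back$abstracts), 2)
  expect_equal(back$abstracts[[1]]$keywords, c("aspirin", "stroke"))
  expect_equal(back$abstracts[[1]]$sentences$text,
               corp$abstracts[[1]]$sentences$text)
  expect_equal(back$abstracts[[1]]$sentences$labels,
               corp$abstracts[[1]]$sentences$labels)
})

test_that("schema violations are rejected with informative errors", {
  expect_error(
    pico_abstract("B1", "t", sentence_table("One sentence.",
                                            labels = list("PICO"))),
    "unknown label 'PICO'")
  expect_error(
    pico_abstract("B2", "", sentence_table("One sentence.")),
    "title")
  bad <- sentence_table(c("First.", "Second."))
  bad$index <- c(1L, 3L)
  expect_error(pico_abstract("B3", "t", bad), "indices")
  expect_error(pico_corpus(list(
    pico_abstract("X", "t", sentence_table("One.")),
    pico_abstract("X", "t", sentence_table("Two.")))),
    "duplicate")
  expect_error(read_corpus(tempfile()), "not found")
})

test_that("split_train_test partitions by id with no overlap", {
  corp <- generate_corpus(generator_spec(n_abstracts = 10, seed = 3))
  ids <- vapply(corp$abstracts, function(a) a$abstract_id, character(1))
  parts <- split_train_test(corp, ids[1:8])
  expect_length(parts$train$abstracts, 8)
  expect_length(parts$test$abstracts, 2)
  tr <- vapply(parts$train$abstracts, function(a) a$abstract_id, character(1))
  te <- vapply(parts$test$abstracts, function(a) a$abstract_id, character(1))
  expect_length(intersect(tr, te), 0)
  expect_setequal(c(tr, te), ids)
  # degenerate: empty training set
  parts0 <- split_train_test(corp, character())
  expect_length(parts0$train$abstracts, 0)
  expect_length(parts0$test$abstracts, 10)
  expect_error(split_train_test(corp, "NOPE"), "unknown abstract id")
})

test_that("feature-file layouts emit the documented row counts", {
  corp <- make_demo_corpus()
  corp <- standardize_headers(corp)
  vectors <- extract_corpus_features(corp, tiny_lexicons())
  f_std <- tempfile(); f_red <- tempfile()
  write_feature_file(corp, vectors, f_std, "standard")
  write_feature_file(corp, vectors, f_red, "redundant")

  std <- readLines(f_std); std <- std[nzchar(std)]
  red <- readLines(f_red); red <- red[nzchar(red)]
  n_gold <- sum(unlist(lapply(corp$abstracts,
                              function(a) lengths(a$sentences$labels))))
  n_sent <- sum(vapply(corp$abstracts, function(a) nrow(a$sentences), integer(1)))
  expect_length(std, n_gold)
  expect_length(red, n_sent * length(PICO_LABELS))

  # standard layout: a single-gold-label sentence yields one row ending in
  # that label; a two-label sentence yields two rows
  last_tok <- vapply(strsplit(std, " +"), function(x) x[length(x)], character(1))
  expect_equal(sum(last_tok == "POPULATION"), 2)  # A1 s2 and A1 s3
  expect_equal(sum(last_tok == "INTERVENTION"), 2)

  # redundant layout: per sentence, exactly one positive row per gold label
  flags <- vapply(strsplit(red, " +"), function(x) x[length(x)], character(1))
  expect_setequal(unique(flags), c("0", "1"))
  expect_equal(sum(flags == "1"), n_gold)

  expect_error(write_feature_file(corp, vectors["A1"], tempfile()),
               "no feature vectors for abstract A2")
})
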