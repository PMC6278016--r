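# Text rectification, segmentation, header normalization, pseudo
# structuring and relative position.

test_that("rectification protects abbreviations and decimals from segmentation", {
  out <- segment_sentences(rectify_text(
    "Group A vs. group B received 2.5 mg daily."))
  expect_length(out, 1)
  expect_identical(out, "Group A vs. group B received 2.5 mg daily.")

  out2 <- segment_sentences(rectify_text(
    "Dosing was flexible, e.g. 2.5 mg or 5.0 mg. Outcomes were similar."))
  expect_length(out2, 2)
  expect_match(out2[1], "e\\.g\\. 2\\.5 mg")

  expect_identical(rectify_text(""), "")
  expect_identical(segment_sentences("A. B? C!"), c("A.", "B?", "C!"))
})

test_that("segmenting injected abbreviation text recovers the true boundaries", {
  set.seed(41)
  fillers <- c("patients improved", "therapy e.g. aspirin was given",
               "doses of 2.5 mg were used", "results i.e. outcomes were stable",
               "groups differed vs. control")
  for (rep in 1:10) {
    n_true <- sample(2:8, 1)
    sents <- paste0(toupper(letters[seq_len(n_true)]), " ",
                    sample(fillers, n_true, replace = TRUE), ".")
    text <- paste(sents, collapse = " ")
    got <- segment_sentences(rectify_text(text))
    expect_length(got, n_true)
    # concatenation preserves the text modulo whitespace
    expect_identical(gsub("\\s+", " ", paste(got, collapse = " ")),
                     gsub("\\s+", " ", text))
  }
})

test_that("published header variants normalize to their common header", {
  variants <- list(
    OBJECTIVE = c("AIM", "OBJECTIVE", "BACKGROUND AND OBJECTIVES", "CONTEXT"),
    METHOD = c("DESIGN", "DESIGN AND METHODS", "PATIENT(S)", "INTERVENTION"),
    RESULTS = c("FINDINGS", "MAIN RESULTS", "OUTCOME MEASURES"),
    CONCLUSION = c("CONCLUSION", "DISCUSSION", "IMPLICATIONS", "SUMMARY"))
  for (common in names(variants))
    for (v in variants[[common]])
      expect_identical(standardize_header(v), common)
  # lookup is case-insensitive and trims punctuation
  expect_identical(standardize_header(" aims: "), "OBJECTIVE")
  expect_identical(standardize_header("Findings"), "RESULTS")
  # unknown headers degrade with a warning, never an error
  expect_warning(got <- standardize_header("ZANY SECTION"), "unknown")
  expect_identical(got, "NOHEADING")
})

test_that("standardize_header is idempotent on fuzzed inputs", {
  set.seed(7)
  pool <- c(names(default_header_map()),
            replicate(50, paste(sample(LETTERS, 6), collapse = "")))
  fuzz <- sample(pool, 1000, replace = TRUE)
  flip <- runif(1000) < 0.5
  fuzz[flip] <- tolower(fuzz[flip])
  once <- suppressWarnings(standardize_header(fuzz))
  twice <- suppressWarnings(standardize_header(once))
  expect_identical(twice, once)
  expect_true(all(once %in% PICO_HEADERS))
})

test_that("pseudo_structure maps gold labels to sections and touches nothing else", {
  a <- pico_abstract("U1", "t", sentence_table(
    c("Background sentence here.", "Population sentence here.",
      "Outcome sentence here.", "Design sentence here.", "Closing sentence."),
    labels = list("BACKGROUND", c("POPULATION", "INTERVENTION"),
                  "OUTCOME", "STUDYDESIGN", "OTHER")))
  ps <- pseudo_structure(a)
  expect_equal(ps$sentences$header,
               c("OBJECTIVE", "METHOD", "RESULTS", "METHOD", "CONCLUSION"))
  # text, labels and structuredness untouched
  expect_identical(ps$sentences$text, a$sentences$text)
  expect_identical(ps$sentences$labels, a$sentences$labels)
  expect_false(ps$is_structured)

  s <- pico_abstract("S1", "t", sentence_table(
    "Headed sentence.", raw_header = "METHODS", labels = list("POPULATION")))
  expect_warning(same <- pseudo_structure(s), "structured")
  expect_identical(same$sentences$header, s$sentences$header)

  unlabeled <- pico_abstract("U2", "t", sentence_table("No labels here."))
  expect_error(pseudo_structure(unlabeled), "gold labels")
})

test_that("relative position follows ceiling thirds", {
  expect_identical(relative_position(1, 9), "FIRST_THIRD")
  expect_identical(relative_position(9, 9), "LAST_THIRD")
  # length-10 abstract splits (4, 3, 3) under the ceiling convention
  pos10 <- vapply(1:10, relative_position, character(1), abstract_len = 10)
  expect_equal(as.vector(table(factor(pos10, c("FIRST_THIRD", "MIDDLE_THIRD",
                                               "LAST_THIRD")))), c(4, 3, 3))
  # short abstracts are all first-third; out-of-range errors
  expect_identical(relative_position(2, 2), "FIRST_THIRD")
  expect_error(relative_position(5, 4), "out of range")
  # agreement with the arithmetic oracle over many shapes
  for (n in 1:15)
    for (i in seq_len(n))
      expect_identical(relative_position(i, n), oracle_third(i, n))
})
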