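# Metric formulas, both evaluation granularities, cross-validation.

test_that("precision/recall/F follow the formulas on fixed counts", {
  got <- picosift:::metrics_from_counts(3, 1, 1)
  expect_equal(got$precision, 0.75)
  expect_equal(got$recall, 0.75)
  expect_equal(got$f_score, 0.75)
  # undefined denominators flag as NA, never 0 or NaN
  und <- picosift:::metrics_from_counts(0, 0, 2)
  expect_true(is.na(und$precision))
  expect_equal(und$recall, 0)
  expect_true(is.na(und$f_score))
})

test_that("metrics agree with the re-computation oracle on random counts", {
  set.seed(29)
  for (i in 1:50) {
    tp <- sample(0:40, 1); fp <- sample(0:40, 1); fn <- sample(0:40, 1)
    got <- picosift:::metrics_from_counts(tp, fp, fn)
    want <- oracle_prf(tp, fp, fn)
    expect_equal(unlist(got), want, tolerance = 1e-12)
    # F lies between min and max of P and R, and equals both when equal
    if (!is.na(want["f_score"])) {
      expect_lte(got$f_score, max(want[1:2]) + 1e-12)
      expect_gte(got$f_score, min(want[1:2]) - 1e-12)
    }
    if (!is.na(want["precision"]) && !is.na(want["recall"]) &&
        isTRUE(all.equal(want[["precision"]], want[["recall"]])) &&
        want[["precision"]] > 0)
      expect_equal(got$f_score, got$precision)
  }
})

eval_fixture <- function() {
  a1 <- pico_abstract("E1", "t", sentence_table(
    c("First sentence text.", "Second sentence text.", "Third sentence text."),
    labels = list("POPULATION", "INTERVENTION", "OUTCOME")))
  a2 <- pico_abstract("E2", "t", sentence_table(
    c("First sentence text.", "Second sentence text."),
    labels = list("OUTCOME", "OTHER")))
  pico_corpus(list(a1, a2))
}

test_that("sentence-level counting covers every sentence/element pair", {
  gold <- eval_fixture()
  preds <- list(
    E1 = list("POPULATION", c("INTERVENTION", "POPULATION"), "OTHER"),
    E2 = list("OUTCOME", "OUTCOME"))
  rep <- evaluate(preds, gold, mode = "sentence_level")
  p_row <- rep[rep$element == "P", ]
  expect_equal(c(p_row$tp, p_row$fp, p_row$fn), c(1, 1, 0))
  o_row <- rep[rep$element == "O", ]
  expect_equal(c(o_row$tp, o_row$fp, o_row$fn), c(1, 1, 1))
  expect_error(evaluate(preds["E1"], gold, mode = "sentence_level"),
               "missing")
})

test_that("abstract-level counting treats the selected sentence as the claim", {
  gold <- eval_fixture()
  sel <- list(E1 = list(P = 1L, I = 3L, O = NA_integer_),
              E2 = list(P = NA_integer_, I = NA_integer_, O = 1L))
  rep <- evaluate(sel, gold, mode = "abstract_level")
  # P: right sentence in E1 (TP), no gold P in E2 and none claimed
  expect_equal(rep[rep$element == "P", c("tp", "fp", "fn")],
               data.frame(tp = 1L, fp = 0L, fn = 0L), ignore_attr = TRUE)
  # I: wrong sentence selected in E1 -> FP and FN
  expect_equal(rep[rep$element == "I", c("tp", "fp", "fn")],
               data.frame(tp = 0L, fp = 1L, fn = 1L), ignore_attr = TRUE)
  # O: missed in E1 (FN), hit in E2 (TP)
  expect_equal(rep[rep$element == "O", c("tp", "fp", "fn")],
               data.frame(tp = 1L, fp = 0L, fn = 1L), ignore_attr = TRUE)
  # TP + FN per element equals the number of gold-bearing abstracts
  for (el in c("P", "I", "O")) {
    lab <- PICO_ELEMENTS[[el]]
    n_gold <- sum(vapply(gold$abstracts, function(a)
      any(vapply(a$sentences$labels, function(l) lab %in% l, logical(1))),
      logical(1)))
    row <- rep[rep$element == el, ]
    expect_equal(row$tp + row$fn, n_gold)
  }
  expect_equal(attr(rep, "missed_abstracts")$O, 1L)
})

test_that("cross-validation partitions abstracts and reports stable folds", {
  corp <- generate_corpus(generator_spec(n_abstracts = 10, seed = 2))
  assignment <- picosift:::with_seed(4, sample(rep_len(1:5, 10)))
  expect_equal(as.vector(table(assignment)), rep(2, 5))

  cv <- cross_validate(
    generate_corpus(generator_spec(n_abstracts = 60, signal_strength = 1,
                                   seed = 10)),
    k = 5, config = fast_config(), seed = 4)
  expect_length(cv$folds, 5)
  f_o <- vapply(cv$folds, function(r) r$f_score[r$element == "O"], numeric(1))
  # strong-signal corpus: the Outcome F-score is stable across folds
  expect_lt(sd(f_o), 0.1)
  expect_error(cross_validate(corp, k = 20, config = fast_config()),
               "more folds")
  expect_error(cross_validate(corp, k = 1, config = fast_config()),
               "at least 2")
})
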