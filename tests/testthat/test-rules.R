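# Fallback rules: printed examples, monotonicity, threshold relaxation
# and application to missed abstracts.

fv_rule <- function(f1 = 0, f2 = 0, f3 = 0, header = "NOHEADING", index = 1L) {
  structure(list(f1 = f1, f2 = f2, f3 = f3, f4 = 0, f5 = 0, f6 = 0,
                 f7 = header, f8 = 10L, f9 = 1L, f10 = character(),
                 categorical = character(), index = as.integer(index),
                 abstract_len = 9L),
            class = "pico_features")
}

test_that("the Population rule fires per its three clauses", {
  expect_true(rule_population(fv_rule(f1 = 3, header = "CONCLUSION")))
  expect_true(rule_population(fv_rule(f1 = 1, header = "METHOD")))
  expect_false(rule_population(fv_rule(f2 = 1, header = "NOHEADING",
                                       index = 5)))
  expect_true(rule_population(fv_rule(f2 = 1, header = "NOHEADING",
                                      index = 3)))
})

test_that("the Intervention rule fires per its three clauses", {
  expect_true(rule_intervention(fv_rule(f3 = 3, header = "CONCLUSION")))
  expect_false(rule_intervention(fv_rule(f3 = 0, header = "METHOD")))
  expect_true(rule_intervention(fv_rule(f3 = 1, header = "METHOD")))
  expect_false(rule_intervention(fv_rule(f3 = 1, header = "RESULTS",
                                         index = 2)))
})

test_that("rules are monotone in their semantic counts", {
  headers <- c("METHOD", "NOHEADING", "RESULTS")
  for (h in headers)
    for (idx in c(1L, 5L))
      for (f in 0:4) {
        if (rule_population(fv_rule(f1 = f, f2 = f, header = h, index = idx)))
          expect_true(rule_population(fv_rule(f1 = f + 1, f2 = f + 1,
                                              header = h, index = idx)))
        if (rule_intervention(fv_rule(f3 = f, header = h, index = idx)))
          expect_true(rule_intervention(fv_rule(f3 = f + 1, header = h,
                                                index = idx)))
      }
})

test_that("relaxing the strong-evidence threshold never shrinks the hit set", {
  strict <- rbm_thresholds(high = 3)
  relaxed <- rbm_thresholds(high = 2)
  for (f1 in 0:4) for (f2 in 0:4) for (h in c("METHOD", "NOHEADING", "RESULTS")) {
    fv <- fv_rule(f1 = f1, f2 = f2, f3 = f1, header = h, index = 2L)
    if (rule_population(fv, thresholds = strict))
      expect_true(rule_population(fv, thresholds = relaxed))
    if (rule_intervention(fv, thresholds = strict))
      expect_true(rule_intervention(fv, thresholds = relaxed))
  }
  expect_error(rbm_thresholds(high = 1, low = 2), "high >= low")
})

test_that("apply_rbm fills missed elements from rule hits and never overrides", {
  wf <- generate_worked_fixture()
  a <- wf$corpus$abstracts[[1]]  # gold P at sentence 1
  vecs <- lapply(seq_len(nrow(a$sentences)), function(i)
    extract_features(a$sentences[i, ], a, wf$lexicons))
  got <- apply_rbm(a, "P", vecs)
  expect_equal(got$P, 1L)
  # no sentence fires the I rule in this abstract: stays missed
  got_i <- apply_rbm(a, "I", vecs)
  expect_true(is.na(got_i$I))
  expect_error(apply_rbm(a, "O", vecs), "only for P and I")
  expect_error(apply_rbm(a, "P", vecs, mlm_selected = list(P = 2L)),
               "not override")
})

test_that("each worked-fixture sentence fires exactly its own rule", {
  wf <- generate_worked_fixture()
  expected <- list(`WF-P1` = "P", `WF-P2` = "P", `WF-I1` = c("P", "I"),
                   `WF-I2` = "I")
  for (a in wf$corpus$abstracts) {
    vecs <- lapply(seq_len(nrow(a$sentences)), function(i)
      extract_features(a$sentences[i, ], a, wf$lexicons))
    gold_idx <- which(vapply(a$sentences$labels, function(l)
      any(l %in% c("POPULATION", "INTERVENTION")), logical(1)))
    p_hits <- which(vapply(vecs, rule_population, logical(1)))
    i_hits <- which(vapply(vecs, rule_intervention, logical(1)))
    exp_el <- expected[[a$abstract_id]]
    if ("P" %in% exp_el) expect_equal(p_hits, gold_idx)
    if ("I" %in% exp_el) expect_equal(i_hits, gold_idx)
    # agreement with the independent truth table
    for (i in seq_along(vecs)) {
      fv <- vecs[[i]]
      expect_equal(rule_population(fv),
                   oracle_rule_p(fv$f1, fv$f2, fv$f7, fv$index))
      expect_equal(rule_intervention(fv),
                   oracle_rule_i(fv$f3, fv$f7, fv$index))
    }
  }
})
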