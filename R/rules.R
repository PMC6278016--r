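# Rule-based fallback stage. The rules are disjunctions of three
# conjunctive clauses: strong semantic evidence anywhere; weak evidence in
# a METHOD section; weak evidence in the first three sentences of an
# unstructured abstract. The high threshold (3) is the average semantic
# count observed in Population sentences; it can be relaxed through the
# thresholds argument, which never shrinks the rule's hit set.

#' Thresholds for the fallback rules
#'
#' @param high Count treated as strong semantic evidence (default 3).
#' @param low Count treated as weak evidence needing positional support
#'   (default 1).
#' @return A named list.
#' @export
rbm_thresholds <- function(high = 3L, low = 1L) {
  stopifnot(high >= low, low >= 0L)
  list(high = as.integer(high), low = as.integer(low))
}

#' Population fallback rule
#'
#' Fires when `f1 >= high` or `f2 >= high`; or `(f1 >= low or f2 >= low)`
#' and the sentence is in a METHOD section; or `f2 >= low`, the abstract
#' is unstructured (NOHEADING) and the sentence is among the first three.
#'
#' @param fv A `pico_features` vector (or any list with `f1`, `f2`).
#' @param header Normalized header; defaults to `fv$f7`.
#' @param index 1-based sentence index; defaults to `fv$index`.
#' @param thresholds From [rbm_thresholds()].
#' @return Logical scalar.
#' @export
rule_population <- function(fv, header = fv$f7, index = fv$index,
                            thresholds = rbm_thresholds()) {
  (fv$f1 >= thresholds$high || fv$f2 >= thresholds$high) ||
    ((fv$f1 >= thresholds$low || fv$f2 >= thresholds$low) &&
       header == "METHOD") ||
    (fv$f2 >= thresholds$low && header == "NOHEADING" && index < 4L)
}

#' Intervention fallback rule
#'
#' Fires when `f3 >= high`; or `f3 >= low` in a METHOD section; or
#' `f3 >= low` among the first three sentences of an unstructured
#' abstract.
#'
#' @inheritParams rule_population
#' @return Logical scalar.
#' @export
rule_intervention <- function(fv, header = fv$f7, index = fv$index,
                              thresholds = rbm_thresholds()) {
  fv$f3 >= thresholds$high ||
    (fv$f3 >= thresholds$low && header == "METHOD") ||
    (fv$f3 >= thresholds$low && header == "NOHEADING" && index < 4L)
}

#' Apply the fallback rules to an abstract the CRF stage missed
#'
#' For each missed element (P and/or I) the element's rule is evaluated on
#' every sentence; among rule-satisfying sentences the one with the
#' highest assessment total wins (the rule hits act as the candidate set,
#' so P/I coexistence still earns `wCo`), ties going to the earliest
#' index. When no sentence fires, the element stays missed (a
#' not-applicable outcome). The fallback never overrides a stage-1
#' selection: passing an element that was not missed is an error.
#'
#' @param abstract A [pico_abstract].
#' @param missed_elements Subset of `c("P", "I")`.
#' @param vectors The abstract's feature vectors.
#' @param thresholds From [rbm_thresholds()].
#' @param mlm_selected Optional stage-1 selection list; when given, a
#'   non-`NA` entry for a supposedly missed element raises an error.
#' @param position_weight,coexistence_weight Assessment weights.
#' @return Named list over `missed_elements`: winning sentence index or
#'   `NA_integer_`.
#' @export
apply_rbm <- function(abstract, missed_elements, vectors,
                      thresholds = rbm_thresholds(), mlm_selected = NULL,
                      position_weight = 2, coexistence_weight = 2) {
  bad <- setdiff(missed_elements, c("P", "I"))
  if (length(bad)) stop("fallback rules exist only for P and I, not: ", bad[1])
  if (!is.null(mlm_selected)) {
    for (el in missed_elements)
      if (!is.na(mlm_selected[[el]] %||% NA_integer_))
        stop("element ", el, " was not missed by the CRF stage; ",
             "the fallback must not override it")
  }
  n <- length(vectors)
  fires <- list(
    P = vapply(vectors, rule_population, logical(1), thresholds = thresholds),
    I = vapply(vectors, rule_intervention, logical(1), thresholds = thresholds))
  out <- list()
  for (el in missed_elements) {
    idx <- which(fires[[el]])
    if (!length(idx)) { out[[el]] <- NA_integer_; next }
    totals <- vapply(idx, function(i) {
      cand <- c(if (fires$P[i]) "POPULATION", if (fires$I[i]) "INTERVENTION")
      score_sentence(el, vectors[[i]], cand, abstract$is_structured,
                     position_weight = position_weight,
                     coexistence_weight = coexistence_weight)$total
    }, numeric(1))
    out[[el]] <- select_best(el, data.frame(index = idx, total = totals))
  }
  out
}
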