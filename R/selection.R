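#' Score a candidate sentence for one PICO element
#'
#' Implements the weighted sentence-assessment total
#' `wTotal = wPoM + wPoT + wCo + wSe` used to arbitrate between sentences
#' the CRF stage proposed for the same element:
#' * `wPoM` (position): for P and I, `position_weight` when the sentence
#'   sits in the METHOD section of a structured abstract, or in the first
#'   third of an unstructured one; for O, when it sits in RESULTS or the
#'   last third; otherwise 0.
#' * `wPoT` (title overlap): the value of `f5`.
#' * `wCo` (coexistence): `coexistence_weight` when both POPULATION and
#'   INTERVENTION are in the sentence's candidate set (P and I scoring
#'   only; 0 for O).
#' * `wSe` (semantic evidence): `f1 + f2` for P, `f3` for I, `f4` for O.
#'
#' @param element `"P"`, `"I"` or `"O"`.
#' @param fv The sentence's `pico_features` vector.
#' @param candidates Candidate label set of the sentence (from
#'   [predict_with_repetition()] or the fallback rules); must contain the
#'   element's label.
#' @param is_structured Whether the abstract is structured.
#' @param abstract_len Number of sentences in the abstract (for the thirds
#'   rule); defaults to the value recorded in `fv`.
#' @param position_weight,coexistence_weight The two 2-or-0 weights.
#' @return A `pico_score` list with `wPoM`, `wPoT`, `wCo`, `wSe`, `total`.
#' @export
score_sentence <- function(element, fv, candidates, is_structured,
                           abstract_len = fv$abstract_len,
                           position_weight = 2, coexistence_weight = 2) {
  element <- match.arg(element, c("P", "I", "O"))
  if (!PICO_ELEMENTS[[element]] %in% candidates)
    stop("sentence ", fv$index, " is not a candidate for element ", element)
  rel <- relative_position(fv$index, abstract_len)
  wPoM <- if (element %in% c("P", "I")) {
    if ((is_structured && fv$f7 == "METHOD") ||
        (!is_structured && rel == "FIRST_THIRD")) position_weight else 0
  } else {
    if ((is_structured && fv$f7 == "RESULTS") ||
        (!is_structured && rel == "LAST_THIRD")) position_weight else 0
  }
  wPoT <- fv$f5
  wCo <- if (element %in% c("P", "I") &&
             all(c("POPULATION", "INTERVENTION") %in% candidates))
    coexistence_weight else 0
  wSe <- switch(element, P = fv$f1 + fv$f2, I = fv$f3, O = fv$f4)
  structure(list(wPoM = wPoM, wPoT = wPoT, wCo = wCo, wSe = wSe,
                 total = wPoM + wPoT + wCo + wSe),
            class = "pico_score")
}

#' Select the most plausible sentence for an element
#'
#' Argmax of the assessment totals; ties go to the earliest sentence
#' index. With no candidates the element is *missed* (the signal the
#' rule-based fallback stage consumes).
#'
#' @param element `"P"`, `"I"` or `"O"` (recorded on the result).
#' @param scores A `data.frame` with columns `index` and `total`, one row
#'   per candidate sentence (possibly zero rows).
#' @return The winning sentence index, or `NA_integer_` when missed.
#' @export
select_best <- function(element, scores) {
  if (is.null(scores) || nrow(scores) == 0L) return(NA_integer_)
  best <- max(scores$total)
  as.integer(min(scores$index[scores$total == best]))
}

# Stage-1 selection for one abstract: score each element's CRF candidates
# and pick a winner (or NA) per element.
select_abstract <- function(abstract, vectors, candidate_sets,
                            position_weight = 2, coexistence_weight = 2) {
  out <- list()
  score_tabs <- list()
  for (el in names(PICO_ELEMENTS)) {
    lab <- PICO_ELEMENTS[[el]]
    idx <- which(vapply(candidate_sets, function(s) lab %in% s, logical(1)))
    if (length(idx)) {
      totals <- vapply(idx, function(i)
        score_sentence(el, vectors[[i]], candidate_sets[[i]],
                       abstract$is_structured,
                       position_weight = position_weight,
                       coexistence_weight = coexistence_weight)$total,
        numeric(1))
      tab <- data.frame(index = idx, total = totals)
    } else tab <- data.frame(index = integer(), total = numeric())
    score_tabs[[el]] <- tab
    out[[el]] <- select_best(el, tab)
  }
  list(selected = out, scores = score_tabs)
}
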