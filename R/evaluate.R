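# Precision / recall / F per PICO element, at two granularities:
# sentence level (every sentence/label pair counts) and abstract level
# (one selected sentence per element per abstract).

metrics_from_counts <- function(tp, fp, fn) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f_score <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(precision = precision, recall = recall, f_score = f_score)
}

make_report <- function(counts, mode, missed = NULL) {
  rows <- lapply(names(counts), function(el) {
    m <- metrics_from_counts(counts[[el]]$tp, counts[[el]]$fp, counts[[el]]$fn)
    data.frame(element = el, tp = counts[[el]]$tp, fp = counts[[el]]$fp,
               fn = counts[[el]]$fn, precision = m$precision,
               recall = m$recall, f_score = m$f_score)
  })
  rep <- do.call(rbind, rows)
  attr(rep, "mode") <- mode
  if (!is.null(missed)) attr(rep, "missed_abstracts") <- missed
  class(rep) <- c("pico_eval", "data.frame")
  rep
}

#' @export
print.pico_eval <- function(x, ...) {
  cat("<pico_eval> mode:", attr(x, "mode"), "\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  mi <- attr(x, "missed_abstracts")
  if (!is.null(mi))
    cat("missed abstracts:",
        paste(sprintf("%s=%d", names(mi), unlist(mi)), collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate predictions against gold labels
#'
#' `mode = "sentence_level"`: `predictions` is a named list (by abstract
#' id) of per-sentence predicted label sets; every (sentence, element)
#' pair counts one TP / FP / FN. `mode = "abstract_level"`: `predictions`
#' is a named list of per-abstract selections `list(P =, I =, O =)`
#' (sentence index or `NA`); an abstract with gold sentences for an
#' element counts a TP when the selected sentence carries that gold label
#' and an FN when the element is missed or a wrong sentence is selected;
#' selecting a sentence that lacks the gold label counts an FP. A
#' selected sentence with several gold labels is a TP for each matching
#' element. Undefined precision/recall (zero denominator) is reported as
#' `NA`, never coerced to 0.
#'
#' @param predictions See above.
#' @param gold A [pico_corpus] carrying the gold labels.
#' @param mode `"sentence_level"` or `"abstract_level"`.
#' @param elements Which elements to report (default P, I, O).
#' @return A `pico_eval` data.frame with one row per element (columns
#'   `tp`, `fp`, `fn`, `precision`, `recall`, `f_score`); abstract-level
#'   reports also carry a `missed_abstracts` attribute.
#' @export
evaluate <- function(predictions, gold,
                     mode = c("sentence_level", "abstract_level"),
                     elements = names(PICO_ELEMENTS)) {
  mode <- match.arg(mode)
  ids <- corpus_ids(gold)
  if (!all(ids %in% names(predictions)))
    stop("predictions missing for abstract(s): ",
         paste(head(setdiff(ids, names(predictions)), 3), collapse = ", "))
  counts <- lapply(elements, function(el) list(tp = 0L, fp = 0L, fn = 0L))
  names(counts) <- elements
  missed <- stats::setNames(rep(0L, length(elements)), elements)

  for (a in gold$abstracts) {
    pred <- predictions[[a$abstract_id]]
    if (mode == "sentence_level") {
      if (length(pred) != nrow(a$sentences))
        stop("prediction length mismatch for abstract ", a$abstract_id)
      for (i in seq_len(nrow(a$sentences))) {
        g <- a$sentences$labels[[i]]
        p <- pred[[i]]
        for (el in elements) {
          lab <- PICO_ELEMENTS[[el]]
          in_g <- lab %in% g; in_p <- lab %in% p
          if (in_g && in_p) counts[[el]]$tp <- counts[[el]]$tp + 1L
          else if (in_p) counts[[el]]$fp <- counts[[el]]$fp + 1L
          else if (in_g) counts[[el]]$fn <- counts[[el]]$fn + 1L
        }
      }
    } else {
      for (el in elements) {
        lab <- PICO_ELEMENTS[[el]]
        has_gold <- any(vapply(a$sentences$labels, function(l) lab %in% l,
                               logical(1)))
        sel <- pred[[el]] %||% NA_integer_
        if (is.na(sel)) {
          if (has_gold) counts[[el]]$fn <- counts[[el]]$fn + 1L
          missed[[el]] <- missed[[el]] + 1L
        } else {
          hit <- lab %in% a$sentences$labels[[sel]]
          if (hit) counts[[el]]$tp <- counts[[el]]$tp + 1L
          else {
            counts[[el]]$fp <- counts[[el]]$fp + 1L
            if (has_gold) counts[[el]]$fn <- counts[[el]]$fn + 1L
          }
        }
      }
    }
  }
  make_report(counts, mode, if (mode == "abstract_level") as.list(missed))
}

#' Macro-averaged F-score of a report
#'
#' @param report A `pico_eval` report.
#' @param na_as_zero Treat undefined per-element F as 0 (useful for chance
#'   baselines where an element may never be predicted).
#' @return Numeric scalar.
#' @export
macro_f <- function(report, na_as_zero = TRUE) {
  f <- report$f_score
  if (na_as_zero) f[is.na(f)] <- 0
  mean(f)
}

#' k-fold cross-validation of the full pipeline
#'
#' Folds are drawn at the abstract level (no abstract straddles folds),
#' deterministically from `seed`. Each fold trains the complete pipeline
#' on the remaining abstracts and evaluates on the held-out fold.
#'
#' @param corpus A labeled [pico_corpus].
#' @param k Number of folds (default 5).
#' @param config A [pico_config()].
#' @param seed Integer seed controlling the fold assignment.
#' @param mode Evaluation mode passed to [evaluate()].
#' @return A list with `folds` (per-fold `pico_eval` reports) and
#'   `summary` (mean and sd of precision/recall/F per element across
#'   folds).
#' @export
cross_validate <- function(corpus, k = 5L, config = pico_config(),
                           seed = 1L, mode = "sentence_level") {
  n <- length(corpus$abstracts)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("more folds (", k, ") than abstracts (", n, ")")
  assignment <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  reports <- lapply(seq_len(k), function(fold) {
    test_idx <- which(assignment == fold)
    train <- pico_corpus(corpus$abstracts[-test_idx], corpus$provenance)
    test <- pico_corpus(corpus$abstracts[test_idx], corpus$provenance)
    fitted <- train_pipeline(train, config)
    res <- run_hybrid(test, fitted)
    if (mode == "sentence_level") res$reports$sentence_level
    else res$reports$combined
  })
  per_el <- lapply(names(PICO_ELEMENTS), function(el) {
    vals <- sapply(reports, function(r) unlist(r[r$element == el,
                                                 c("precision", "recall", "f_score")]))
    data.frame(element = el,
               metric = c("precision", "recall", "f_score"),
               mean = rowMeans(vals, na.rm = TRUE),
               sd = apply(vals, 1, stats::sd, na.rm = TRUE),
               row.names = NULL)
  })
  list(folds = reports, summary = do.call(rbind, per_el))
}
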