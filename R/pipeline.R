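#' Pipeline configuration
#'
#' One object governs the whole hybrid run: lexicons, header map, CRF
#' settings, assessment weights, fallback thresholds and whether the
#' fallback stage runs at all.
#'
#' @param lexicons A `pico_lexicons` bundle.
#' @param header_map Header map (named character vector).
#' @param crf A [crf_config()].
#' @param position_weight,coexistence_weight The 2-or-0 assessment
#'   weights.
#' @param rbm [rbm_thresholds()] for the fallback rules.
#' @param use_rbm Run the fallback stage (stage 2)?
#' @return A `pico_config` object.
#' @export
pico_config <- function(lexicons = default_lexicons(),
                        header_map = default_header_map(),
                        crf = crf_config(),
                        position_weight = 2, coexistence_weight = 2,
                        rbm = rbm_thresholds(), use_rbm = TRUE) {
  structure(list(lexicons = lexicons, header_map = header_map, crf = crf,
                 position_weight = position_weight,
                 coexistence_weight = coexistence_weight,
                 rbm = rbm, use_rbm = use_rbm),
            class = "pico_config")
}

#' Train the full pipeline on a labeled corpus
#'
#' Normalizes headers, pseudo-structures unstructured training abstracts
#' (their gold labels stand in for section headers), extracts feature
#' vectors and fits the CRF.
#'
#' @param train_corpus A labeled [pico_corpus].
#' @param config A [pico_config()].
#' @return A `pico_pipeline` object holding the fitted CRF and the config.
#' @export
train_pipeline <- function(train_corpus, config = pico_config()) {
  corp <- standardize_headers(train_corpus, config$header_map)
  corp$abstracts <- lapply(corp$abstracts, function(a)
    if (a$is_structured) a else pseudo_structure(a))
  vectors <- extract_corpus_features(corp, config$lexicons)
  model <- crf_train(corp, vectors, config$crf)
  structure(list(model = model, config = config), class = "pico_pipeline")
}

#' @export
print.pico_pipeline <- function(x, ...) {
  cat("<pico_pipeline>\n")
  print(x$model)
  invisible(x)
}

#' Run the two-stage hybrid extraction on a test corpus
#'
#' Stage 1 (statistical, coarse-grained): normalize headers (unstructured
#' abstracts keep NOHEADING at test time), extract features, decode
#' candidate label sets with test-sentence repetition, and select the
#' best-scoring sentence per element per abstract. Stage 2 (rules,
#' fine-grained): for abstracts where stage 1 produced no P or I
#' selection, the fallback rules propose one; a stage-1 selection is
#' never overridden.
#'
#' @param test_corpus A [pico_corpus] (gold labels optional; needed for
#'   the evaluation reports).
#' @param pipeline A fitted `pico_pipeline` from [train_pipeline()].
#' @param reps Test-sentence repetitions (default from the CRF config).
#' @return A `pico_extraction` list: `selections` (per-abstract, per
#'   element, `mlm` and `combined` sentence indices), `candidates`
#'   (per-sentence label sets), and `reports` (`sentence_level`,
#'   `mlm`, `combined` `pico_eval` reports when gold labels are present).
#' @export
run_hybrid <- function(test_corpus, pipeline,
                       reps = pipeline$config$crf$test_repetitions) {
  config <- pipeline$config
  corp <- standardize_headers(test_corpus, config$header_map)
  vectors <- extract_corpus_features(corp, config$lexicons)

  candidates <- list(); mlm_sel <- list(); combined_sel <- list()
  for (a in corp$abstracts) {
    vecs <- vectors[[a$abstract_id]]
    cand <- predict_with_repetition(pipeline$model, a, vecs, reps = reps)
    sel <- select_abstract(a, vecs, cand,
                           position_weight = config$position_weight,
                           coexistence_weight = config$coexistence_weight)
    comb <- sel$selected
    if (config$use_rbm) {
      missed <- names(PICO_ELEMENTS)[vapply(sel$selected, is.na, logical(1))]
      missed <- intersect(missed, c("P", "I"))
      if (length(missed)) {
        fills <- apply_rbm(a, missed, vecs, thresholds = config$rbm,
                           mlm_selected = sel$selected,
                           position_weight = config$position_weight,
                           coexistence_weight = config$coexistence_weight)
        for (el in missed) comb[[el]] <- fills[[el]]
      }
    }
    candidates[[a$abstract_id]] <- cand
    mlm_sel[[a$abstract_id]] <- sel$selected
    combined_sel[[a$abstract_id]] <- comb
  }

  has_gold <- all(vapply(corp$abstracts, function(a)
    all(lengths(a$sentences$labels) > 0L), logical(1)))
  reports <- if (has_gold) list(
    sentence_level = evaluate(candidates, corp, mode = "sentence_level"),
    mlm = evaluate(mlm_sel, corp, mode = "abstract_level"),
    combined = evaluate(combined_sel, corp, mode = "abstract_level"))
  else NULL

  structure(list(selections = list(mlm = mlm_sel, combined = combined_sel),
                 candidates = candidates, reports = reports,
                 reps = reps),
            class = "pico_extraction")
}

#' @export
print.pico_extraction <- function(x, ...) {
  cat("<pico_extraction> ", length(x$selections$combined), " abstracts, ",
      x$reps, " repetitions\n", sep = "")
  if (!is.null(x$reports)) {
    cat("\ncombined (MLM + rules), abstract level:\n")
    print(x$reports$combined)
  }
  invisible(x)
}

#' Per-abstract extraction table
#'
#' @param x A `pico_extraction`.
#' @param stage `"combined"` or `"mlm"`.
#' @return A data.frame with columns `abstract_id`, `P`, `I`, `O`
#'   (selected sentence indices, `NA` = missed).
#' @export
extraction_table <- function(x, stage = c("combined", "mlm")) {
  stage <- match.arg(stage)
  sel <- x$selections[[stage]]
  data.frame(abstract_id = names(sel),
             P = vapply(sel, function(s) as.integer(s$P), integer(1)),
             I = vapply(sel, function(s) as.integer(s$I), integer(1)),
             O = vapply(sel, function(s) as.integer(s$O), integer(1)),
             row.names = NULL)
}
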