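# Independent oracles and tiny fixture builders shared across tests.
# Each oracle is written as a direct transcription of the definition it
# checks, kept deliberately separate from the package's code paths.

# brute-force truth table for the Population fallback rule
oracle_rule_p <- function(f1, f2, header, index, high = 3, low = 1) {
  clause1 <- (f1 >= high) | (f2 >= high)
  clause2 <- ((f1 >= low) | (f2 >= low)) & (header == "METHOD")
  clause3 <- (f2 >= low) & (header == "NOHEADING") & (index < 4)
  clause1 | clause2 | clause3
}

# brute-force truth table for the Intervention fallback rule
oracle_rule_i <- function(f3, header, index, high = 3, low = 1) {
  (f3 >= high) |
    ((f3 >= low) & (header == "METHOD")) |
    ((f3 >= low) & (header == "NOHEADING") & (index < 4))
}

# spreadsheet-style recomputation of the selection total
oracle_score_total <- function(element, f1, f2, f3, f4, f5, header,
                               coexists, is_structured, rel_pos) {
  wPoM <- 0
  if (element %in% c("P", "I")) {
    if (is_structured && header == "METHOD") wPoM <- 2
    if (!is_structured && rel_pos == "FIRST_THIRD") wPoM <- 2
  } else {
    if (is_structured && header == "RESULTS") wPoM <- 2
    if (!is_structured && rel_pos == "LAST_THIRD") wPoM <- 2
  }
  wCo <- if (element != "O" && coexists) 2 else 0
  wSe <- switch(element, P = f1 + f2, I = f3, O = f4)
  wPoM + f5 + wCo + wSe
}

# direct transcription of the precision/recall/F formulas
oracle_prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  r <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f <- if (!is.na(p) && !is.na(r) && p + r > 0) 2 * p * r / (p + r) else NA_real_
  c(precision = p, recall = r, f_score = f)
}

# arithmetic thirds oracle (floor-counting alternative formulation)
oracle_third <- function(index, n) {
  if (n < 3) return("FIRST_THIRD")
  b1 <- ceiling(n / 3); b2 <- ceiling(2 * n / 3)
  if (index <= b1) "FIRST_THIRD" else if (index <= b2) "MIDDLE_THIRD" else "LAST_THIRD"
}

# a minimal lexicon bundle for unit tests
tiny_lexicons <- function() {
  as_lexicons(list(
    PATIENT_DEMOGRAPHIC = c("patients", "women", "adults"),
    DISORDERS = c("diabetes", "stroke", "heart failure"),
    PROCEDURES_DRUGS = c("aspirin", "surgery", "therapy"),
    OUTCOME_CUES = c("mortality", "improvement", "reduction")))
}

# a small fully separable corpus: each label owns a disjoint vocabulary,
# so a CRF that learns anything at all classifies it perfectly
separable_corpus <- function(n_abstracts = 8) {
  vocab <- list(POPULATION = c("alpha", "alef", "aleph"),
                INTERVENTION = c("beta", "bet", "beth"),
                OUTCOME = c("gamma", "gimel", "gml"),
                BACKGROUND = c("delta", "dalet", "dlt"),
                STUDYDESIGN = c("epsilon", "he", "hey"),
                OTHER = c("zeta", "waw", "vav"))
  abstracts <- lapply(seq_len(n_abstracts), function(i) {
    labs <- names(vocab)
    texts <- vapply(labs, function(l)
      paste0(paste(rep(vocab[[l]], 2), collapse = " "), "."), character(1))
    pico_abstract(sprintf("SEP%02d", i), "A separable fixture title",
                  sentence_table(unname(texts), labels = as.list(labs)))
  })
  pico_corpus(abstracts, provenance = "separable fixture")
}

# small configs so unit tests stay quick
fast_crf <- function(...) crf_config(max_iterations = 60L, ...)
fast_config <- function(...) pico_config(crf = fast_crf(), ...)
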