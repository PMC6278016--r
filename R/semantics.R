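# Lexicon-based semantic tagging. The four categories mirror the coarse
# semantic groups the feature set counts: demographic cues for the Patient
# element, disorder terms, procedure/drug terms for the Intervention
# element, and outcome cue words. Each category is a flat term list
# (single words or phrases); a bundle must keep categories disjoint so a
# token can count toward at most one category.

LEXICON_CATEGORIES <- c("PATIENT_DEMOGRAPHIC", "DISORDERS",
                        "PROCEDURES_DRUGS", "OUTCOME_CUES")

#' Read one lexicon file
#'
#' One lowercase term (word or phrase) per line, UTF-8, `#` starts a
#' comment.
#'
#' @param path File path.
#' @return Character vector of unique terms.
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- tolower(trimws(lines))
  unique(lines[nzchar(lines)])
}

#' Load a lexicon bundle
#'
#' @param paths Named character vector or list mapping each category in
#'   `PATIENT_DEMOGRAPHIC, DISORDERS, PROCEDURES_DRUGS, OUTCOME_CUES` to a
#'   lexicon file.
#' @return A `pico_lexicons` object (named list of term vectors).
#' @export
load_lexicons <- function(paths) {
  missing <- setdiff(LEXICON_CATEGORIES, names(paths))
  if (length(missing))
    stop("lexicon bundle incomplete; missing: ", paste(missing, collapse = ", "))
  lex <- lapply(paths[LEXICON_CATEGORIES], read_lexicon)
  as_lexicons(lex)
}

#' Assemble a lexicon bundle from term vectors
#'
#' @param terms Named list of character vectors, one per category.
#' @return A `pico_lexicons` object.
#' @export
as_lexicons <- function(terms) {
  missing <- setdiff(LEXICON_CATEGORIES, names(terms))
  if (length(missing))
    stop("lexicon bundle incomplete; missing: ", paste(missing, collapse = ", "))
  lex <- lapply(terms[LEXICON_CATEGORIES], function(x) unique(tolower(x)))
  if (any(vapply(lex, length, integer(1)) == 0L))
    stop("every lexicon category must contain at least one term")
  all_terms <- unlist(lex, use.names = FALSE)
  if (anyDuplicated(all_terms))
    stop("lexicon categories must be disjoint; duplicated term: ",
         all_terms[duplicated(all_terms)][1])
  structure(lex, class = "pico_lexicons")
}

#' The lexicon bundle shipped with the package
#'
#' Compact, hand-curated stand-ins for licensed medical vocabularies:
#' demographic cues, common disorder terms, procedure/drug terms, and an
#' outcome cue list of the package's own construction. Intended for
#' synthetic corpora and desk-scale experiments; real deployments should
#' supply richer lexicons through [load_lexicons()].
#'
#' @return A `pico_lexicons` object.
#' @export
default_lexicons <- function() {
  dir <- system.file("extdata", "lexicons", package = "picosift")
  load_lexicons(c(
    PATIENT_DEMOGRAPHIC = file.path(dir, "patient_demographic.txt"),
    DISORDERS = file.path(dir, "disorders.txt"),
    PROCEDURES_DRUGS = file.path(dir, "procedures_drugs.txt"),
    OUTCOME_CUES = file.path(dir, "outcome_cues.txt")))
}

#' @export
print.pico_lexicons <- function(x, ...) {
  cat("<pico_lexicons>",
      paste(sprintf("%s: %d", names(x), lengths(x)), collapse = ", "), "\n")
  invisible(x)
}

#' Tag a tokenized sentence against a lexicon bundle
#'
#' Greedy longest-match, left to right: at each position the longest
#' lexicon phrase starting there (in any category) is consumed and counts
#' one hit for its category; covered tokens cannot match again, so a token
#' contributes to at most one category.
#'
#' @param tokens Character vector of lowercased tokens.
#' @param lexicons A `pico_lexicons` bundle.
#' @return A `pico_semtags` list with per-token `category` assignments
#'   (`NA` for unmatched tokens) and counts `n_demographic`, `n_disorder`,
#'   `n_intervention`, `n_outcome`.
#' @export
tag_sentence <- function(tokens, lexicons) {
  if (!inherits(lexicons, "pico_lexicons"))
    stop("lexicons must be a pico_lexicons bundle (see load_lexicons)")
  n <- length(tokens)
  category <- rep(NA_character_, n)
  counts <- c(PATIENT_DEMOGRAPHIC = 0L, DISORDERS = 0L,
              PROCEDURES_DRUGS = 0L, OUTCOME_CUES = 0L)
  if (n > 0L) {
    phrase_cat <- phrase_index(lexicons)
    max_len <- attr(phrase_cat, "max_len")
    i <- 1L
    while (i <= n) {
      matched <- FALSE
      for (len in seq(min(max_len, n - i + 1L), 1L)) {
        phrase <- paste(tokens[i:(i + len - 1L)], collapse = " ")
        cat_hit <- phrase_cat[[phrase]]
        if (!is.null(cat_hit)) {
          category[i:(i + len - 1L)] <- cat_hit
          counts[[cat_hit]] <- counts[[cat_hit]] + 1L
          i <- i + len
          matched <- TRUE
          break
        }
      }
      if (!matched) i <- i + 1L
    }
  }
  structure(list(category = category,
                 n_demographic = counts[["PATIENT_DEMOGRAPHIC"]],
                 n_disorder = counts[["DISORDERS"]],
                 n_intervention = counts[["PROCEDURES_DRUGS"]],
                 n_outcome = counts[["OUTCOME_CUES"]]),
            class = "pico_semtags")
}

# term -> category hash, cached on the bundle
phrase_index <- function(lexicons) {
  idx <- attr(lexicons, "phrase_index")
  if (!is.null(idx)) return(idx)
  env <- new.env(parent = emptyenv(), hash = TRUE)
  max_len <- 1L
  for (cat_name in names(lexicons)) {
    for (term in lexicons[[cat_name]]) {
      assign(term, cat_name, envir = env)
      max_len <- max(max_len, length(strsplit(term, " ", fixed = TRUE)[[1]]))
    }
  }
  attr(env, "max_len") <- max_len
  env
}

#' Categorical encoding of semantic counts
#'
#' Encodes the per-sentence semantic category frequencies as categorical
#' tokens: `MPt_k` (Patient/demographic cues), `MP_k` (disorder terms,
#' the Problem part), `MI_k` (procedure/drug terms, the Intervention part)
#' and `MT_k` (overlap with the title). Zero counts emit nothing.
#'
#' @param tags A `pico_semtags` object from [tag_sentence()].
#' @param in_title_count Number of sentence words also present in the title.
#' @return Character vector of categorical tokens (possibly empty).
#' @export
categorical_encoding <- function(tags, in_title_count = 0L) {
  counts <- c(MPt = tags$n_demographic, MP = tags$n_disorder,
              MI = tags$n_intervention, MT = as.integer(in_title_count))
  counts <- counts[counts > 0L]
  if (!length(counts)) return(character())
  sprintf("%s_%d", names(counts), counts)
}
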