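#' Tokenize a sentence into words
#'
#' Alphanumeric runs, keeping internal hyphens, apostrophes and decimal
#' points (`2.5`, `low-back-pain`, `scd-heft` stay single tokens).
#'
#' @param text Character scalar.
#' @return Character vector of tokens (original case).
#' @export
tokenize_words <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- gregexpr("[[:alnum:]]+(?:[-'.][[:alnum:]]+)*", text)
  toks <- regmatches(text, m)[[1]]
  toks[nzchar(toks)]
}

# small closed-class word lists for the heuristic POS tagger
POS_CLOSED <- list(
  DT = c("the", "a", "an", "this", "that", "these", "those", "each",
         "every", "all", "both", "some", "any", "no"),
  IN = c("in", "on", "at", "of", "to", "from", "with", "without", "by",
         "for", "during", "after", "before", "between", "among", "against",
         "under", "over", "into", "through", "within", "versus", "vs"),
  CC = c("and", "or", "but", "nor", "plus"),
  PRP = c("we", "they", "it", "he", "she", "i", "you", "them", "us", "its",
          "their", "our"),
  VB = c("is", "are", "was", "were", "be", "been", "being", "has", "have",
         "had", "do", "does", "did", "can", "could", "may", "might",
         "should", "would", "will"))

#' Heuristic part-of-speech tagging
#'
#' A lightweight suffix-and-closed-class tagger emitting Penn-style tags
#' (CD, DT, IN, CC, PRP, VB, VBD, VBG, RB, JJ, NN, NNS). It exists to feed
#' the word/POS bag-of-words feature, not to be a reference tagger.
#'
#' @param tokens Character vector of tokens.
#' @return Character vector of tags, same length.
#' @export
pos_tag <- function(tokens) {
  vapply(tokens, function(tok) {
    low <- tolower(tok)
    if (grepl("^[0-9]+([.,][0-9]+)*%?$", low)) return("CD")
    for (tag in names(POS_CLOSED))
      if (low %in% POS_CLOSED[[tag]]) return(tag)
    if (grepl("ly$", low)) return("RB")
    if (grepl("ing$", low) && nchar(low) > 4) return("VBG")
    if (grepl("ed$", low) && nchar(low) > 3) return("VBD")
    if (grepl("(ous|ive|ical|able|ible|al|ic)$", low) && nchar(low) > 4)
      return("JJ")
    if (grepl("(tion|sion|ment|ness|ity|ism)s?$", low)) return("NN")
    if (grepl("s$", low) && !grepl("(ss|us|is)$", low) && nchar(low) > 3)
      return("NNS")
    "NN"
  }, character(1), USE.NAMES = FALSE)
}

#' Combine words and POS tags into bag-of-words tokens
#'
#' One `word|POS` token per input token, words lowercased.
#'
#' @param tokens Character vector of words.
#' @param pos_tags Character vector of tags, same length.
#' @return Character vector of `word|POS` tokens.
#' @export
build_bow <- function(tokens, pos_tags) {
  if (length(tokens) != length(pos_tags))
    stop("tokens and pos_tags must have the same length (",
         length(tokens), " vs ", length(pos_tags), ")")
  if (!length(tokens)) return(character())
  paste(tolower(tokens), pos_tags, sep = "|")
}

#' Grouped structural position code
#'
#' Aligns the section header with the sentence number so that every
#' sentence of a section shares one positional code: OBJECTIVE sections
#' code 3, METHOD 6, RESULTS 12, CONCLUSION 14 (arbitrary codes near the
#' cumulative average section sizes, chosen to cluster the structural
#' features). Sentences without a header keep their raw index, capped at
#' 14, so position information survives in unstructured abstracts.
#'
#' @param header Normalized header, one of [PICO_HEADERS].
#' @param index 1-based sentence index (used only for NOHEADING).
#' @param abstract_len Unused except for validation; kept for symmetry.
#' @return Integer code.
#' @export
group_structural <- function(header, index = 1L, abstract_len = index) {
  codes <- c(OBJECTIVE = 3L, METHOD = 6L, RESULTS = 12L, CONCLUSION = 14L)
  if (!header %in% PICO_HEADERS) stop("unknown header: ", header)
  if (header == "NOHEADING") return(min(as.integer(index), 14L))
  unname(codes[header])
}

#' Extract the per-sentence feature vector
#'
#' Builds the ten-feature representation of one sentence:
#' * `f1`..`f4`: semantic counts (demographic, disorder, procedure/drug,
#'   outcome-cue hits) from [tag_sentence()];
#' * `f5`: number of sentence words also in the title; `f6`: same over the
#'   abstract keywords;
#' * `f7`: normalized section header; `f8`: sentence length in words;
#'   `f9`: grouped structural code from [group_structural()];
#' * `f10`: `word|POS` bag-of-words tokens;
#' * `categorical`: the `MPt_k`/`MP_k`/`MI_k`/`MT_k` encoding.
#'
#' @param sentence One row of an abstract's sentence table (or a list with
#'   `index`, `text`, `header`).
#' @param abstract The [pico_abstract] the sentence belongs to.
#' @param lexicons A `pico_lexicons` bundle.
#' @return A `pico_features` object.
#' @export
extract_features <- function(sentence, abstract, lexicons) {
  text <- sentence$text
  if (is.null(text) || !nzchar(text)) stop("cannot extract features from an empty sentence")
  index <- as.integer(sentence$index)
  header <- sentence$header %||% "NOHEADING"
  n_sent <- nrow(abstract$sentences)

  toks <- tokenize_words(text)
  if (!length(toks)) stop("sentence has no tokens: ", substr(text, 1, 40))
  low <- tolower(toks)
  pos <- pos_tag(toks)
  tags <- tag_sentence(low, lexicons)

  title_words <- tolower(tokenize_words(abstract$title))
  kw_words <- tolower(unlist(lapply(abstract$keywords, tokenize_words)))
  f5 <- sum(low %in% title_words)
  f6 <- sum(low %in% kw_words)
  f8 <- length(toks)

  structure(list(
    f1 = tags$n_demographic, f2 = tags$n_disorder,
    f3 = tags$n_intervention, f4 = tags$n_outcome,
    f5 = f5, f6 = f6, f7 = header, f8 = f8,
    f9 = group_structural(header, index, n_sent),
    f10 = build_bow(toks, pos),
    categorical = categorical_encoding(tags, f5),
    index = index, abstract_len = n_sent),
    class = "pico_features")
}

#' @export
print.pico_features <- function(x, ...) {
  cat(sprintf("<pico_features> s%d f1-f4=%d,%d,%d,%d f5=%d f6=%d f7=%s f8=%d f9=%d\n",
              x$index, x$f1, x$f2, x$f3, x$f4, x$f5, x$f6, x$f7, x$f8, x$f9))
  invisible(x)
}

# bin sentence length so it stays a small categorical alphabet
length_bin <- function(f8) {
  if (f8 <= 10L) "SHORT" else if (f8 <= 18L) "MED" else "LONG"
}

#' Observation tokens a feature vector contributes to the CRF
#'
#' Flattens a `pico_features` object into the categorical token set the
#' sequence model consumes: the `MPt/MP/MI/MT` encodings, an outcome-count
#' token, a keyword-overlap token, header, grouped position, binned length
#' and the `word|POS` bag-of-words.
#'
#' @param fv A `pico_features` object.
#' @return Character vector of observation tokens.
#' @export
feature_tokens <- function(fv) {
  c(fv$categorical,
    if (fv$f4 > 0L) sprintf("MO_%d", fv$f4),
    if (fv$f6 > 0L) sprintf("KW_%d", fv$f6),
    paste0("HDR=", fv$f7),
    paste0("POS=", fv$f9),
    paste0("LEN=", length_bin(fv$f8)),
    fv$f10)
}

#' Extract feature vectors for a whole corpus
#'
#' @param corpus A [pico_corpus] whose headers are already normalized (and,
#'   for training, pseudo-structured).
#' @param lexicons A `pico_lexicons` bundle.
#' @return Named list (by abstract id) of lists of `pico_features`, one per
#'   sentence.
#' @export
extract_corpus_features <- function(corpus, lexicons) {
  out <- lapply(corpus$abstracts, function(a)
    lapply(seq_len(nrow(a$sentences)), function(i)
      extract_features(a$sentences[i, ], a, lexicons)))
  names(out) <- corpus_ids(corpus)
  out
}
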