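# Periods that must not end a sentence (abbreviations, decimals) are
# swapped for ONE DOT LEADER while segmenting and restored afterwards.
DOT_SENTINEL <- "․"

ABBREV_PATTERN <- paste0(
  "\\b(?:vs|etc|e\\.g|i\\.e|et\\s+al|cf|ca|approx|resp|no|fig|figs|ref|",
  "dr|mr|mrs|ms|prof|st)\\.")

#' Rectify text before sentence segmentation
#'
#' Protects characters that a naive segmenter would confuse with the end of
#' a sentence: periods inside common abbreviations (`vs.`, `e.g.`, `i.e.`,
#' `et al.` and similar) and decimal points (`2.5`). Protected periods are
#' replaced by a same-width sentinel character that
#' [segment_sentences()] restores, so rectified text is an internal
#' intermediate form of the same length as the input.
#'
#' @param raw Character scalar (may be empty).
#' @return The rectified string.
#' @export
rectify_text <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (!nzchar(raw)) return(raw)
  x <- raw
  # decimal numbers: digit '.' digit
  x <- gsub("(?<=[0-9])\\.(?=[0-9])", DOT_SENTINEL, x, perl = TRUE)
  # known abbreviations, case-insensitively, preserving their own case
  m <- gregexpr(ABBREV_PATTERN, x, perl = TRUE, ignore.case = TRUE)
  regmatches(x, m) <- lapply(regmatches(x, m), function(hits)
    gsub(".", DOT_SENTINEL, hits, fixed = TRUE))
  x
}

#' Segment rectified text into sentences
#'
#' Splits at `.`, `?` or `!` followed by whitespace (or end of text) and
#' restores any periods [rectify_text()] protected. Joining the returned
#' sentences with single spaces reproduces the original text modulo
#' whitespace.
#'
#' @param text A string, normally the output of [rectify_text()].
#' @return Character vector of non-empty sentences.
#' @export
segment_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) return(character())
  parts <- strsplit(text, "(?<=[.?!])\\s+", perl = TRUE)[[1]]
  parts <- gsub(DOT_SENTINEL, ".", parts, fixed = TRUE)
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

#' The header map shipped with the package
#'
#' A two-column mapping from raw header variants (upper-cased, trimmed) to
#' the four common headers OBJECTIVE / METHOD / RESULTS / CONCLUSION. It
#' covers the published variant exemplars plus common synonyms and is
#' user-extensible through [load_header_map()].
#'
#' @return A named character vector: `names` are variants, values common
#'   headers.
#' @export
default_header_map <- function() {
  path <- system.file("extdata", "header_map.csv", package = "picosift")
  load_header_map(path)
}

#' Load a header map from a two-column CSV
#'
#' @param path CSV with columns `variant, common`; `common` must be one of
#'   OBJECTIVE, METHOD, RESULTS, CONCLUSION.
#' @return Named character vector as in [default_header_map()].
#' @export
load_header_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("variant", "common") %in% names(df)))
    stop("header map needs columns 'variant' and 'common'")
  bad <- setdiff(unique(df$common), setdiff(PICO_HEADERS, "NOHEADING"))
  if (length(bad)) stop("unknown common header in map: ", bad[1])
  stats::setNames(df$common, toupper(trimws(df$variant)))
}

#' Normalize a raw section header
#'
#' Case-insensitive lookup (after trimming and stripping trailing
#' punctuation) of a raw header variant against a header map. Unknown
#' variants degrade to `NOHEADING` with a warning rather than failing.
#' Idempotent: the four common headers and `NOHEADING` map to themselves.
#'
#' @param raw_header Character vector of raw headers (`NA` allowed, treated
#'   as `NOHEADING`).
#' @param map Header map, by default [default_header_map()].
#' @return Character vector over [PICO_HEADERS].
#' @export
standardize_header <- function(raw_header, map = default_header_map()) {
  vapply(raw_header, function(h) {
    if (is.na(h)) return("NOHEADING")
    key <- toupper(trimws(gsub("[:.]+$", "", trimws(h))))
    if (!nzchar(key) || key == "NOHEADING") return("NOHEADING")
    hit <- unname(map[key])
    if (is.na(hit)) {
      warning("unknown section header '", h, "'; using NOHEADING",
              call. = FALSE)
      return("NOHEADING")
    }
    hit
  }, character(1), USE.NAMES = FALSE)
}

#' Normalize the headers of every sentence in a corpus
#'
#' @param corpus A [pico_corpus].
#' @param map Header map.
#' @return The corpus with each sentence's `header` field set from its
#'   `raw_header`.
#' @export
standardize_headers <- function(corpus, map = default_header_map()) {
  corpus$abstracts <- lapply(corpus$abstracts, function(a) {
    a$sentences$header <- standardize_header(a$sentences$raw_header, map)
    a
  })
  corpus
}

#' Pseudo-structure an unstructured training abstract
#'
#' Training-time only: assigns normalized section headers to the sentences
#' of an unstructured abstract from their gold labels, so the structural
#' features of unstructured training abstracts carry the same information
#' as those of structured ones. The mapping is BACKGROUND to OBJECTIVE;
#' POPULATION / INTERVENTION / STUDYDESIGN to METHOD; OUTCOME to RESULTS;
#' OTHER to CONCLUSION. Sentences with several labels take the first match
#' in that priority order (METHOD first, since Population and Intervention
#' are the scarce classes). Text, labels and `raw_header` are untouched, so
#' the abstract still identifies as unstructured.
#'
#' @param abstract A [pico_abstract] with gold labels on every sentence.
#' @return The abstract with `header` set; a structured abstract is
#'   returned unchanged with a warning.
#' @export
pseudo_structure <- function(abstract) {
  if (abstract$is_structured) {
    warning("pseudo_structure called on a structured abstract; no-op",
            call. = FALSE)
    return(abstract)
  }
  labs <- abstract$sentences$labels
  if (any(vapply(labs, length, integer(1)) == 0L))
    stop("pseudo_structure requires gold labels on every sentence ",
         "(training-time use only)")
  abstract$sentences$header <- vapply(labs, function(l) {
    if (any(l %in% c("POPULATION", "INTERVENTION", "STUDYDESIGN"))) "METHOD"
    else if ("OUTCOME" %in% l) "RESULTS"
    else if ("BACKGROUND" %in% l) "OBJECTIVE"
    else "CONCLUSION"
  }, character(1))
  abstract
}

#' Relative position of a sentence within its abstract
#'
#' Thirds are computed with ceiling boundaries: a sentence at 1-based
#' `index` of an abstract of `abstract_len` sentences is in the first third
#' when `index <= ceiling(n/3)`, the middle third when
#' `index <= ceiling(2n/3)`, and the last third otherwise. Abstracts
#' shorter than three sentences place everything in the first third.
#'
#' @param index 1-based sentence index.
#' @param abstract_len Number of sentences in the abstract.
#' @return One of `"FIRST_THIRD"`, `"MIDDLE_THIRD"`, `"LAST_THIRD"`.
#' @export
relative_position <- function(index, abstract_len) {
  stopifnot(length(index) == 1L, length(abstract_len) == 1L)
  if (index < 1L || index > abstract_len)
    stop("sentence index ", index, " out of range 1..", abstract_len)
  if (abstract_len < 3L) return("FIRST_THIRD")
  if (index <= ceiling(abstract_len / 3)) "FIRST_THIRD"
  else if (index <= ceiling(2 * abstract_len / 3)) "MIDDLE_THIRD"
  else "LAST_THIRD"
}
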