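#' Construct an abstract record
#'
#' An abstract is an ordered collection of sentences, each carrying an
#' optional raw section header, a normalized header and zero or more gold
#' labels. An abstract is *structured* when at least one sentence has a raw
#' header.
#'
#' @param abstract_id Unique identifier (character scalar).
#' @param title Non-empty title string.
#' @param sentences A `data.frame` with columns `index` (1-based, contiguous),
#'   `text` (non-empty), `raw_header` (character, `NA` when the sentence has
#'   no header), `header` (one of [PICO_HEADERS]), `labels` (list column of
#'   character vectors drawn from [PICO_LABELS]).
#' @param keywords Character vector of abstract keywords (possibly empty).
#' @return A `pico_abstract` object.
#' @export
pico_abstract <- function(abstract_id, title, sentences, keywords = character()) {
  stopifnot(is.character(abstract_id), length(abstract_id) == 1L, nzchar(abstract_id))
  if (!is.character(title) || length(title) != 1L || !nzchar(title))
    stop("abstract ", abstract_id, ": title must be a non-empty string")
  req <- c("index", "text", "raw_header", "header", "labels")
  if (!all(req %in% names(sentences)))
    stop("abstract ", abstract_id, ": sentence table lacks columns ",
         paste(setdiff(req, names(sentences)), collapse = ", "))
  n <- nrow(sentences)
  if (n == 0L) stop("abstract ", abstract_id, ": no sentences")
  if (!identical(as.integer(sentences$index), seq_len(n)))
    stop("abstract ", abstract_id, ": sentence indices must be 1..", n, " in order")
  if (any(!nzchar(sentences$text)))
    stop("abstract ", abstract_id, ": empty sentence text")
  bad_hdr <- setdiff(unique(sentences$header), PICO_HEADERS)
  if (length(bad_hdr))
    stop("abstract ", abstract_id, ": unknown normalized header ", bad_hdr[1])
  for (i in seq_len(n)) {
    lab <- sentences$labels[[i]]
    bad <- setdiff(lab, PICO_LABELS)
    if (length(bad))
      stop("abstract ", abstract_id, ", sentence ", i, ": unknown label '",
           bad[1], "'")
  }
  structure(
    list(abstract_id = abstract_id,
         title = title,
         keywords = as.character(keywords),
         is_structured = any(!is.na(sentences$raw_header)),
         sentences = sentences),
    class = "pico_abstract")
}

#' Construct a labeled corpus
#'
#' @param abstracts List of [pico_abstract] objects with unique ids.
#' @param provenance Free-text metadata about where the corpus came from.
#' @return A `pico_corpus` object.
#' @export
pico_corpus <- function(abstracts, provenance = "") {
  ids <- vapply(abstracts, function(a) a$abstract_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate abstract_id: ", ids[duplicated(ids)][1])
  structure(list(abstracts = abstracts, provenance = provenance),
            class = "pico_corpus")
}

#' @export
print.pico_corpus <- function(x, ...) {
  ns <- vapply(x$abstracts, function(a) nrow(a$sentences), integer(1))
  nstr <- sum(vapply(x$abstracts, function(a) a$is_structured, logical(1)))
  cat("<pico_corpus> ", length(x$abstracts), " abstracts (",
      nstr, " structured), ", sum(ns), " sentences\n", sep = "")
  invisible(x)
}

#' @export
print.pico_abstract <- function(x, ...) {
  cat("<pico_abstract> ", x$abstract_id, ": ", nrow(x$sentences),
      " sentences, ", if (x$is_structured) "structured" else "unstructured",
      "\n", sep = "")
  invisible(x)
}

corpus_ids <- function(corpus)
  vapply(corpus$abstracts, function(a) a$abstract_id, character(1))

# assemble the sentence data.frame used inside pico_abstract
sentence_table <- function(text, raw_header = NA_character_,
                           header = "NOHEADING", labels = NULL) {
  n <- length(text)
  if (is.null(labels)) labels <- rep(list(character()), n)
  data.frame(index = seq_len(n), text = text,
             raw_header = rep_len(raw_header, n),
             header = rep_len(header, n),
             labels = I(labels),
             stringsAsFactors = FALSE)
}

#' Read a corpus file
#'
#' Two on-disk forms are supported. The JSON form holds one object per
#' abstract: `{"abstract_id", "title", "keywords": [...], "sentences":
#' [{"index", "text", "header" (string or null), "labels": [...]}]}` under a
#' top-level `{"provenance", "abstracts"}` object. The CSV form holds one row
#' per sentence with columns `abstract_id, title, keywords, index, text,
#' header, labels`, where `keywords` and `labels` are `;`-separated and an
#' empty `header` means no header. Headers read from file are raw strings;
#' [standardize_headers()] normalizes them.
#'
#' @param path File path.
#' @param format `"json"` or `"csv"`; the default guesses from the extension.
#' @return A [pico_corpus].
#' @export
read_corpus <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  if (!file.exists(path)) stop("corpus file not found: ", path)
  if (format == "json") read_corpus_json(path) else read_corpus_csv(path)
}

read_corpus_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$abstracts)) stop("malformed corpus: no 'abstracts' array in ", path)
  abstracts <- lapply(doc$abstracts, function(a) {
    id <- as.character(a$abstract_id %||% stop("abstract without abstract_id"))
    sen <- a$sentences
    if (is.null(sen) || !length(sen))
      stop("abstract ", id, ": no sentences")
    txt <- vapply(sen, function(s) as.character(s$text), character(1))
    hdr <- vapply(sen, function(s)
      if (is.null(s$header) || !nzchar(s$header)) NA_character_
      else as.character(s$header), character(1))
    labs <- lapply(sen, function(s) as.character(unlist(s$labels)))
    pico_abstract(id, as.character(a$title),
                  sentence_table(txt, raw_header = hdr, labels = labs),
                  keywords = as.character(unlist(a$keywords)))
  })
  pico_corpus(abstracts, provenance = as.character(doc$provenance %||% ""))
}

read_corpus_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  req <- c("abstract_id", "title", "keywords", "index", "text", "header", "labels")
  if (!all(req %in% names(df)))
    stop("malformed corpus CSV: need columns ", paste(req, collapse = ", "))
  split_multi <- function(x) {
    x <- trimws(unlist(strsplit(x, ";", fixed = TRUE)))
    x[nzchar(x)]
  }
  abstracts <- lapply(split(df, factor(df$abstract_id, levels = unique(df$abstract_id))),
    function(d) {
      d <- d[order(as.integer(d$index)), , drop = FALSE]
      hdr <- ifelse(nzchar(d$header), d$header, NA_character_)
      pico_abstract(d$abstract_id[1], d$title[1],
                    sentence_table(d$text, raw_header = hdr,
                                   labels = lapply(d$labels, split_multi)),
                    keywords = split_multi(d$keywords[1]))
    })
  pico_corpus(unname(abstracts))
}

#' Write a corpus file
#'
#' Writes the canonical form of the schema documented in [read_corpus()];
#' `write_corpus(read_corpus(f))` of a canonical file is byte-identical.
#'
#' @param corpus A [pico_corpus].
#' @param path Output path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    doc <- list(
      provenance = jsonlite::unbox(corpus$provenance),
      abstracts = lapply(corpus$abstracts, function(a) {
        list(abstract_id = jsonlite::unbox(a$abstract_id),
             title = jsonlite::unbox(a$title),
             keywords = a$keywords,
             sentences = lapply(seq_len(nrow(a$sentences)), function(i) {
               s <- a$sentences[i, ]
               list(index = jsonlite::unbox(s$index),
                    text = jsonlite::unbox(s$text),
                    header = if (is.na(s$raw_header)) NULL
                             else jsonlite::unbox(s$raw_header),
                    labels = s$labels[[1]])
             }))
      }))
    writeLines(jsonlite::toJSON(doc, pretty = TRUE, null = "null"), path,
               useBytes = TRUE)
  } else {
    rows <- do.call(rbind, lapply(corpus$abstracts, function(a) {
      data.frame(abstract_id = a$abstract_id, title = a$title,
                 keywords = paste(a$keywords, collapse = ";"),
                 index = a$sentences$index, text = a$sentences$text,
                 header = ifelse(is.na(a$sentences$raw_header), "",
                                 a$sentences$raw_header),
                 labels = vapply(a$sentences$labels, paste, character(1),
                                 collapse = ";"),
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(rows, path, row.names = FALSE)
  }
  invisible(path)
}

#' Split a corpus into train and test parts by abstract id
#'
#' @param corpus A [pico_corpus].
#' @param train_ids Character vector of abstract ids to place in the
#'   training part; must all exist in `corpus`.
#' @return A list with elements `train` and `test`, both [pico_corpus].
#' @export
split_train_test <- function(corpus, train_ids) {
  ids <- corpus_ids(corpus)
  unknown <- setdiff(train_ids, ids)
  if (length(unknown)) stop("unknown abstract id(s): ",
                            paste(head(unknown, 3), collapse = ", "))
  in_train <- ids %in% train_ids
  list(train = pico_corpus(corpus$abstracts[in_train], corpus$provenance),
       test = pico_corpus(corpus$abstracts[!in_train], corpus$provenance))
}

#' Write a CRF training/test file in one of two layouts
#'
#' One whitespace-separated row per entry, feature tokens first. The
#' *standard* layout emits one row per (sentence, gold label), the label
#' last. The *redundant* layout emits one row per (sentence, candidate
#' label) with the candidate label followed by a final `1` (the sentence
#' carries that gold label) or `0`. Abstracts are separated by a blank line,
#' the sequence convention of CRF toolkits.
#'
#' @param corpus A [pico_corpus] with gold labels.
#' @param vectors Corpus feature set from [extract_corpus_features()].
#' @param path Output path.
#' @param layout `"standard"` or `"redundant"`.
#' @param candidate_labels Labels enumerated by the redundant layout.
#' @return `path`, invisibly.
#' @export
write_feature_file <- function(corpus, vectors, path,
                               layout = c("standard", "redundant"),
                               candidate_labels = PICO_LABELS) {
  layout <- match.arg(layout)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (a in corpus$abstracts) {
    fvs <- vectors[[a$abstract_id]]
    if (is.null(fvs)) stop("no feature vectors for abstract ", a$abstract_id)
    for (i in seq_len(nrow(a$sentences))) {
      fv <- fvs[[i]]
      if (is.null(fv)) stop("no feature vector for abstract ", a$abstract_id,
                            " sentence ", i)
      toks <- paste(feature_tokens(fv), collapse = " ")
      gold <- a$sentences$labels[[i]]
      if (layout == "standard") {
        for (lab in gold) writeLines(paste(toks, lab), con)
      } else {
        for (lab in candidate_labels)
          writeLines(paste(toks, lab, as.integer(lab %in% gold)), con)
      }
    }
    writeLines("", con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
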