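# Synthetic-corpus generator. Emulates the statistical structure the
# pipeline assumes -- skewed label distribution, a mix of structured and
# unstructured abstracts, header variants, class-conditional vocabulary --
# with a tunable signal strength, so every downstream stage is testable
# without any external corpus.

# Neutral connective/academic vocabulary; kept disjoint from the shipped
# lexicons so that at signal strength 0 the labels carry no lexical signal.
FILLER_VOCAB <- c(
  "the", "a", "an", "this", "that", "these", "of", "in", "on", "to",
  "with", "for", "from", "by", "as", "at", "was", "were", "is", "are",
  "be", "been", "has", "have", "had", "not", "we", "our", "their", "its",
  "study", "studies", "analysis", "analyses", "data", "evidence",
  "research", "report", "approach", "model", "design", "protocol",
  "baseline", "period", "phase", "stage", "group", "groups", "arm",
  "arms", "site", "sites", "center", "centers", "record", "records",
  "assessment", "assessed", "measured", "measure", "measures",
  "collected", "obtained", "observed", "performed", "conducted",
  "randomized", "controlled", "trial", "trials", "clinical", "medical",
  "primary", "secondary", "present", "current", "previous", "recent",
  "further", "several", "various", "overall", "total", "average",
  "compared", "comparison", "relation", "association", "examined",
  "investigated", "evaluated", "considered", "included", "excluded",
  "criteria", "methodology", "procedure", "described", "reported",
  "shown", "found", "suggested", "indicated", "may", "might", "could",
  "should", "however", "therefore", "moreover", "although", "whether",
  "between", "among", "during", "within", "across", "about", "after",
  "before", "using", "based", "according", "regarding", "respectively")

#' Specification of a synthetic corpus
#'
#' Defaults reproduce the study conditions the pipeline targets: the
#' skewed label mix of the reference training corpus (Population 6.8%,
#' Intervention 5.8%, Outcome 36.6%, Other 27.9%, Study Design 2.0%,
#' Background 20.9%) and its 314/800 structured fraction.
#'
#' @param n_abstracts Number of abstracts.
#' @param structured_fraction Probability an abstract is structured.
#' @param label_distribution Named probabilities over [PICO_LABELS];
#'   must sum to 1.
#' @param signal_strength `s` in `[0, 1]`: probability that a sentence of
#'   a class draws terms from its class lexicon and sits in its typical
#'   position; at 0 labels are independent of the text.
#' @param sentences_range Range (min, max) of sentences per abstract.
#' @param words_range Range of words per sentence.
#' @param header_variant_noise Probability a structured section carries a
#'   raw variant header (e.g. `AIM`) instead of its common header.
#' @param multilabel_rate Probability a Population sentence also carries
#'   the Intervention label (and vice versa).
#' @param seed Integer seed; the corpus is a pure function of the spec.
#' @return A `generator_spec` object.
#' @export
generator_spec <- function(n_abstracts = 800L,
                           structured_fraction = 314 / 800,
                           label_distribution = c(
                             POPULATION = 0.068, INTERVENTION = 0.058,
                             OUTCOME = 0.366, OTHER = 0.279,
                             STUDYDESIGN = 0.020, BACKGROUND = 0.209),
                           signal_strength = 0.7,
                           sentences_range = c(6L, 12L),
                           words_range = c(8L, 25L),
                           header_variant_noise = 0.3,
                           multilabel_rate = 0.05,
                           seed = 1L) {
  if (!setequal(names(label_distribution), PICO_LABELS))
    stop("label_distribution must name exactly the six labels")
  if (abs(sum(label_distribution) - 1) > 1e-6)
    stop("label_distribution must sum to 1 (got ",
         format(sum(label_distribution)), ")")
  if (signal_strength < 0 || signal_strength > 1)
    stop("signal_strength must be in [0, 1]")
  stopifnot(n_abstracts >= 1L, sentences_range[1] >= 1L,
            sentences_range[2] >= sentences_range[1],
            words_range[1] >= 3L, words_range[2] >= words_range[1])
  structure(list(n_abstracts = as.integer(n_abstracts),
                 structured_fraction = structured_fraction,
                 label_distribution = label_distribution[PICO_LABELS],
                 signal_strength = signal_strength,
                 sentences_range = as.integer(sentences_range),
                 words_range = as.integer(words_range),
                 header_variant_noise = header_variant_noise,
                 multilabel_rate = multilabel_rate,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

# draw k distinct terms from a lexicon category
draw_terms <- function(lexicons, category, k)
  sample(lexicons[[category]], min(k, length(lexicons[[category]])))

# section a label's sentences typically live in
label_section <- function(label) {
  switch(label,
         POPULATION = , INTERVENTION = , STUDYDESIGN = "METHOD",
         OUTCOME = "RESULTS", BACKGROUND = "OBJECTIVE", "CONCLUSION")
}

#' Generate a labeled synthetic corpus
#'
#' Each sentence draws a label from the spec's distribution; with
#' probability `signal_strength` it is *informative*: it contains terms
#' from its class's lexicon (demographic and disorder terms for
#' Population, procedure/drug terms for Intervention, outcome cues for
#' Outcome) and sits in its typical location (its section in structured
#' abstracts; the first three sentences for Population/Intervention and
#' the last third for Outcome in unstructured ones). Titles are built
#' from the abstract's Population/Intervention terms so title overlap is
#' informative. Ten percent of sentences gain one random lexicon term
#' irrespective of their label, so lexicon hits are never perfectly
#' class-pure.
#'
#' @param spec A [generator_spec()].
#' @param lexicons Term bank; defaults to the shipped lexicons.
#' @return A labeled [pico_corpus], a pure function of `spec`.
#' @export
generate_corpus <- function(spec, lexicons = default_lexicons()) {
  stopifnot(inherits(spec, "generator_spec"))
  variant_pool <- split(names(default_header_map()),
                        unname(default_header_map()))
  with_seed(spec$seed, {
    abstracts <- lapply(seq_len(spec$n_abstracts), function(ai) {
      generate_abstract(sprintf("SYN%04d", ai), spec, lexicons, variant_pool)
    })
    pico_corpus(abstracts,
                provenance = sprintf("picosift synthetic corpus (seed %d, s = %g)",
                                     spec$seed, spec$signal_strength))
  })
}

generate_abstract <- function(id, spec, lexicons, variant_pool) {
  s <- spec$signal_strength
  n_sent <- sample(spec$sentences_range[1]:spec$sentences_range[2], 1L)
  structured <- runif(1) < spec$structured_fraction

  sent <- lapply(seq_len(n_sent), function(i) {
    label <- sample(PICO_LABELS, 1L, prob = spec$label_distribution)
    labels <- label
    informative <- runif(1) < s
    terms <- character()
    if (informative) {
      terms <- switch(label,
        POPULATION = c(draw_terms(lexicons, "PATIENT_DEMOGRAPHIC", sample(2:4, 1L)),
                       draw_terms(lexicons, "DISORDERS", sample(1:3, 1L))),
        INTERVENTION = draw_terms(lexicons, "PROCEDURES_DRUGS", sample(2:4, 1L)),
        OUTCOME = draw_terms(lexicons, "OUTCOME_CUES", sample(2:4, 1L)),
        character())
      if (label == "POPULATION" && runif(1) < spec$multilabel_rate) {
        labels <- c(labels, "INTERVENTION")
        terms <- c(terms, draw_terms(lexicons, "PROCEDURES_DRUGS", sample(1:2, 1L)))
      } else if (label == "INTERVENTION" && runif(1) < spec$multilabel_rate) {
        labels <- c(labels, "POPULATION")
        terms <- c(terms, draw_terms(lexicons, "PATIENT_DEMOGRAPHIC", sample(1:2, 1L)))
      }
    }
    # label-independent lexical noise
    if (runif(1) < 0.1)
      terms <- c(terms, sample(unlist(lexicons, use.names = FALSE), 1L))
    list(labels = labels, terms = terms, informative = informative,
         section = if (informative) label_section(label)
                   else sample(c("OBJECTIVE", "METHOD", "RESULTS", "CONCLUSION"), 1L))
  })

  # ordering: structured abstracts sort by section; unstructured place
  # informative P/I early and informative O late
  if (structured) {
    ord <- order(match(vapply(sent, `[[`, character(1), "section"),
                       c("OBJECTIVE", "METHOD", "RESULTS", "CONCLUSION")))
    sent <- sent[ord]
  } else {
    early <- which(vapply(sent, function(x)
      x$informative && any(x$labels %in% c("POPULATION", "INTERVENTION")),
      logical(1)))
    late <- which(vapply(sent, function(x)
      x$informative && "OUTCOME" %in% x$labels, logical(1)))
    late <- setdiff(late, early)
    early <- head(early, 3L)
    last_third_size <- n_sent - ceiling(2 * n_sent / 3)
    late <- head(late, last_third_size)
    rest <- setdiff(seq_len(n_sent), c(early, late))
    mid <- if (length(rest)) sample(rest) else integer()
    sent <- sent[c(early, head(mid, n_sent - length(early) - length(late)), late)]
  }

  texts <- vapply(sent, function(x) render_sentence(x$terms, spec), character(1))
  labels <- lapply(sent, `[[`, "labels")

  if (structured) {
    sections <- vapply(sent, `[[`, character(1), "section")
    raw_hdr <- vapply(unique(sections), function(sec) {
      if (runif(1) < spec$header_variant_noise)
        sample(variant_pool[[sec]], 1L) else sec
    }, character(1))
    raw_header <- unname(raw_hdr[sections])
    header <- sections
  } else {
    raw_header <- NA_character_
    header <- "NOHEADING"
  }

  # title from the abstract's P/I terms so title overlap is informative
  pi_terms <- unique(unlist(lapply(sent, function(x)
    if (any(x$labels %in% c("POPULATION", "INTERVENTION")) && x$informative)
      x$terms)))
  title_terms <- head(pi_terms, 4L)
  title_words <- c(title_terms, sample(FILLER_VOCAB, 3L))
  title <- to_sentence_case(paste(title_words, collapse = " "), final = "")
  keywords <- if (length(pi_terms) && runif(1) < 0.7)
    head(pi_terms, sample(1:3, 1L)) else character()

  pico_abstract(id, title,
                sentence_table(texts, raw_header = raw_header,
                               header = header, labels = labels),
                keywords = keywords)
}

render_sentence <- function(terms, spec) {
  n_words <- sample(spec$words_range[1]:spec$words_range[2], 1L)
  term_words <- sum(lengths(strsplit(terms, " ", fixed = TRUE)))
  n_fill <- max(3L, n_words - term_words)
  words <- sample(FILLER_VOCAB, n_fill, replace = TRUE)
  if (length(terms)) {
    slots <- sort(sample(0:n_fill, length(terms), replace = TRUE))
    out <- character()
    prev <- 0L
    for (k in seq_along(terms)) {
      out <- c(out, words[seq_len(slots[k] - prev) + prev], terms[k])
      prev <- slots[k]
    }
    words <- c(out, if (prev < n_fill) words[(prev + 1L):n_fill])
  }
  to_sentence_case(paste(words, collapse = " "))
}

to_sentence_case <- function(x, final = ".") {
  paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)), final)
}

#' A tiny fixed worked-example corpus
#'
#' Four published example sentences (two Population, two Intervention
#' candidates) embedded one per unstructured abstract among neutral
#' filler sentences, together with a hand-set lexicon bundle under which
#' each fires its fallback rule. Fully deterministic: no random number
#' generation is involved.
#'
#' @return A list with `corpus` (a [pico_corpus]) and `lexicons` (the
#'   matching `pico_lexicons` bundle).
#' @export
generate_worked_fixture <- function() {
  lexicons <- as_lexicons(list(
    PATIENT_DEMOGRAPHIC = c("patients"),
    DISORDERS = c("breast cancer", "ovarian", "heart failure", "spasticity"),
    PROCEDURES_DRUGS = c("tizanidine", "medication", "anesthesia", "therapy"),
    OUTCOME_CUES = c("improvement")))
  filler <- "The findings of this report are discussed in a wider context."
  closing <- "Further research along these lines is clearly warranted."
  mk <- function(id, title, texts, labels) {
    pico_abstract(id, title, sentence_table(texts, labels = labels))
  }
  corpus <- pico_corpus(list(
    mk("WF-P1", "Familial aggregation of breast cancer",
       c(paste("An estimated 20% of all breast cancer or ovarian and",
               "breast cancer cases have familial aggregation."),
         filler, closing),
       list("POPULATION", "OTHER", "OTHER")),
    mk("WF-P2", "Implantable defibrillators in heart failure",
       c(filler,
         paste("Clinical trials such as the Sudden Cardiac Death Heart",
               "Failure Trial (SCD-HeFT) are currently underway to",
               "investigate the role of the implantable defibrillator in",
               "patients with heart failure."),
         closing),
       list("OTHER", "POPULATION", "OTHER")),
    mk("WF-I1", "Tizanidine for spasticity",
       c(paste("Tizanidine hydrochloride is a very useful medication in",
               "patients suffering from spasticity caused by MS, acquired",
               "brain injury or spinal cord injury."),
         filler, closing),
       list("INTERVENTION", "OTHER", "OTHER")),
    mk("WF-I2", "Local anesthesia and back-muscle training",
       c(filler,
         paste("Here we describe the influence of local anesthesia and",
               "back-muscle-training therapy on subjective and objective",
               "pain parameters in 21 low-back-pain patients."),
         closing),
       list("OTHER", "INTERVENTION", "OTHER"))),
    provenance = "picosift worked fixture")
  list(corpus = corpus, lexicons = lexicons)
}
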