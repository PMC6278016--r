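#' CRF stage configuration
#'
#' Defaults follow the configuration that performed best in the underlying
#' experiments: Gaussian prior variance 10, full use of the training set,
#' and 3-fold repetition of every test sentence.
#'
#' @param gaussian_prior_variance Variance of the Gaussian (L2) prior on
#'   the weights; larger values regularize less.
#' @param training_proportion Fraction of training abstracts actually used
#'   (subsampled by `random_seed` when below 1).
#' @param test_repetitions How many consecutive copies of each test
#'   sentence are decoded; the candidate label set is the union over
#'   copies (plus the plain decode).
#' @param max_iterations L-BFGS iteration cap.
#' @param tolerance Relative convergence tolerance of the optimizer.
#' @param random_seed Seed for the (only) stochastic step, training-set
#'   subsampling.
#' @return A `crf_config` object.
#' @export
crf_config <- function(gaussian_prior_variance = 10,
                       training_proportion = 1.0,
                       test_repetitions = 3L,
                       max_iterations = 200L,
                       tolerance = 1e-4,
                       random_seed = 1L) {
  stopifnot(gaussian_prior_variance > 0,
            training_proportion > 0, training_proportion <= 1,
            test_repetitions >= 1L, max_iterations >= 1L, tolerance > 0)
  structure(list(gaussian_prior_variance = gaussian_prior_variance,
                 training_proportion = training_proportion,
                 test_repetitions = as.integer(test_repetitions),
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance,
                 random_seed = as.integer(random_seed)),
            class = "crf_config")
}

# Flatten a labeled corpus into CRF training sequences following the
# standard layout: one position per (sentence, gold label), multi-label
# sentences duplicated in place.
crf_training_positions <- function(corpus, vectors) {
  tokens <- list(); labels <- character(); seq_len_out <- integer()
  for (a in corpus$abstracts) {
    fvs <- vectors[[a$abstract_id]]
    if (is.null(fvs)) stop("no feature vectors for abstract ", a$abstract_id)
    count <- 0L
    for (i in seq_len(nrow(a$sentences))) {
      gold <- a$sentences$labels[[i]]
      if (!length(gold))
        stop("training sentence without gold label: ", a$abstract_id, " #", i)
      tok <- feature_tokens(fvs[[i]])
      for (lab in gold) {
        tokens[[length(tokens) + 1L]] <- tok
        labels <- c(labels, lab)
        count <- count + 1L
      }
    }
    seq_len_out <- c(seq_len_out, count)
  }
  list(tokens = tokens, labels = labels, lens = seq_len_out)
}

# sparse observation design matrix over a fixed alphabet (plus bias column)
crf_design <- function(token_list, alphabet) {
  lookup <- new.env(parent = emptyenv(), hash = TRUE)
  for (j in seq_along(alphabet)) assign(alphabet[j], j, envir = lookup)
  nbias <- length(alphabet) + 1L
  cols_per_row <- lapply(token_list, function(toks) {
    cols <- unlist(lapply(unique(toks), function(t) lookup[[t]]),
                   use.names = FALSE)
    c(cols, nbias)
  })
  nnz <- lengths(cols_per_row)
  Matrix::sparseMatrix(i = rep.int(seq_along(cols_per_row), nnz),
                       j = unlist(cols_per_row, use.names = FALSE),
                       x = 1, dims = c(length(token_list), nbias))
}

#' Train the linear-chain CRF
#'
#' Maximizes the penalized conditional log-likelihood of the gold label
#' sequences: emission weights tie each observation token to each label,
#' transition weights tie adjacent labels, and a Gaussian prior with the
#' configured variance shrinks all weights. Optimization is L-BFGS with
#' the analytic gradient from forward-backward. Training is deterministic
#' given the same corpus and configuration.
#'
#' @param train_corpus A [pico_corpus]; every sentence needs gold labels.
#' @param vectors Feature set from [extract_corpus_features()] for
#'   `train_corpus`.
#' @param config A [crf_config()].
#' @return A `pico_crf` model: emission weights, transition weights, the
#'   observation alphabet, the label set and a config snapshot.
#' @export
crf_train <- function(train_corpus, vectors, config = crf_config()) {
  if (!length(train_corpus$abstracts)) stop("empty training corpus")
  if (config$training_proportion < 1) {
    n <- length(train_corpus$abstracts)
    keep <- with_seed(config$random_seed,
                      sort(sample.int(n, max(1L, round(config$training_proportion * n)))))
    train_corpus <- pico_corpus(train_corpus$abstracts[keep],
                                train_corpus$provenance)
  }
  dat <- crf_training_positions(train_corpus, vectors)
  labels <- PICO_LABELS
  y <- match(dat$labels, labels)
  if (length(unique(y)) < 2L)
    stop("degenerate training corpus: only one distinct label present")
  L <- length(labels)
  alphabet <- sort(unique(unlist(dat$tokens)))
  X <- crf_design(dat$tokens, alphabet)
  nfeat <- ncol(X)
  starts <- cumsum(c(1L, dat$lens[-length(dat$lens)]))
  lens <- dat$lens
  npos <- nrow(X)

  Y <- Matrix::sparseMatrix(i = seq_len(npos), j = y, x = 1, dims = c(npos, L))
  obs_emit <- as.matrix(Matrix::crossprod(X, Y))
  obs_trans <- matrix(0, L, L)
  for (s in seq_along(starts)) {
    if (lens[s] < 2L) next
    idx <- starts[s]:(starts[s] + lens[s] - 1L)
    for (t in 2L:length(idx))
      obs_trans[y[idx[t - 1L]], y[idx[t]]] <-
        obs_trans[y[idx[t - 1L]], y[idx[t]]] + 1
  }
  gold_pairs <- cbind(seq_len(npos), y)
  var <- config$gaussian_prior_variance
  npar_w <- nfeat * L

  unpack <- function(par)
    list(W = matrix(par[seq_len(npar_w)], nfeat, L),
         A = matrix(par[npar_w + seq_len(L * L)], L, L))

  neg_obj <- function(par) {
    p <- unpack(par)
    E <- as.matrix(X %*% p$W)
    fb <- crf_forward_backward(E, starts, lens, p$A)
    loglik <- sum(E[gold_pairs]) + sum(obs_trans * p$A) - fb$logZ
    -(loglik - sum(par^2) / (2 * var))
  }
  neg_grad <- function(par) {
    p <- unpack(par)
    E <- as.matrix(X %*% p$W)
    fb <- crf_forward_backward(E, starts, lens, p$A)
    gW <- obs_emit - as.matrix(Matrix::crossprod(X, fb$marginals)) - p$W / var
    gA <- obs_trans - fb$expected_trans - p$A / var
    -c(gW, gA)
  }

  fit <- stats::optim(rep(0, npar_w + L * L), neg_obj, neg_grad,
                      method = "L-BFGS-B",
                      control = list(maxit = config$max_iterations,
                                     factr = config$tolerance / .Machine$double.eps / 100))
  p <- unpack(fit$par)
  structure(list(weights = p$W, trans = p$A, alphabet = alphabet,
                 labels = labels, config = config,
                 value = -fit$value, convergence = fit$convergence),
            class = "pico_crf")
}

#' @export
print.pico_crf <- function(x, ...) {
  cat("<pico_crf> ", length(x$alphabet), " observation features x ",
      length(x$labels), " labels; penalized loglik ",
      format(x$value, digits = 6), "\n", sep = "")
  invisible(x)
}

# Viterbi-decode one abstract given per-sentence token lists
crf_decode_tokens <- function(model, token_list) {
  X <- crf_design(token_list, model$alphabet)
  E <- as.matrix(X %*% model$weights)
  lab <- crf_viterbi(E, 1L, length(token_list), model$trans)
  model$labels[lab]
}

#' Plain CRF decoding of one abstract
#'
#' @param model A `pico_crf`.
#' @param abstract A [pico_abstract].
#' @param vectors The abstract's feature vectors (list, one per sentence).
#' @return Character vector: one decoded label per sentence.
#' @export
crf_predict <- function(model, abstract, vectors) {
  toks <- lapply(vectors, feature_tokens)
  crf_decode_tokens(model, toks)
}

#' Candidate label sets via test-sentence repetition
#'
#' Each sentence is duplicated `reps` times consecutively in the
#' abstract's sequence before Viterbi decoding; transition weights can
#' then assign different labels to identical copies. The candidate label
#' set of a sentence is the union of the labels decoded for its copies
#' and its plain (unrepeated) decode, so candidate sets are never empty
#' and always contain the plain prediction. With `reps = 1` this reduces
#' exactly to plain decoding.
#'
#' @param model A `pico_crf`.
#' @param abstract A [pico_abstract].
#' @param vectors The abstract's feature vectors.
#' @param reps Number of copies per sentence (default from the model's
#'   config).
#' @return List of character vectors: candidate labels per sentence.
#' @export
predict_with_repetition <- function(model, abstract, vectors,
                                    reps = model$config$test_repetitions) {
  stopifnot(reps >= 1L)
  toks <- lapply(vectors, feature_tokens)
  n <- length(toks)
  plain <- crf_decode_tokens(model, toks)
  if (reps == 1L) return(as.list(plain))
  rep_toks <- toks[rep(seq_len(n), each = reps)]
  rep_lab <- crf_decode_tokens(model, rep_toks)
  lapply(seq_len(n), function(i) {
    copies <- rep_lab[((i - 1L) * reps + 1L):(i * reps)]
    unique(c(plain[i], copies))
  })
}
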