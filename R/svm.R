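# Sentence-level CAN topic classification: unigram/bigram/trigram features
# and a linear support-vector machine (libsvm via e1071).

svm_tokens <- function(text) tolower(word_tokens(gsub("[-/]", " ", text)))

ngrams_of <- function(tokens, n_range) {
  out <- character()
  for (n in seq(n_range[1], n_range[2])) {
    if (length(tokens) < n) next
    if (n == 1) {
      out <- c(out, tokens)
    } else {
      idx <- seq_len(length(tokens) - n + 1)
      out <- c(out, vapply(idx, function(i) {
        paste(tokens[i:(i + n - 1)], collapse = "_")
      }, ""))
    }
  }
  out
}

#' Build an n-gram vocabulary from training sentences
#'
#' N-grams (default unigrams, bigrams and trigrams) over lowercased word
#' tokens, indexed in first-occurrence order. Build the vocabulary from the
#' training partition only, never from test sentences.
#'
#' @param sentences character vector of training sentences
#' @param n_range integer pair `(min_n, max_n)`, default `c(1, 3)`
#' @param min_count drop n-grams seen in fewer sentences (default 1)
#' @return object of class `ngram_vocab`
#' @export
build_vocabulary <- function(sentences, n_range = c(1, 3), min_count = 1) {
  sentences <- sentences[!is.na(sentences) & nzchar(trimws(sentences))]
  if (length(sentences) == 0) stop_fmt("no non-empty sentences supplied")
  per_sentence <- lapply(sentences, function(s) {
    unique(ngrams_of(svm_tokens(s), n_range))
  })
  all_grams <- unlist(per_sentence)
  first_seen <- unique(all_grams)
  if (min_count > 1) {
    counts <- table(all_grams)
    first_seen <- first_seen[counts[first_seen] >= min_count]
  }
  if (length(first_seen) == 0) {
    stop_fmt("empty vocabulary (min_count = %d too high?)", min_count)
  }
  idx <- seq_along(first_seen)
  names(idx) <- first_seen
  structure(list(index = idx, n_range = n_range, min_count = min_count),
            class = "ngram_vocab")
}

#' @export
print.ngram_vocab <- function(x, ...) {
  cat("<ngram_vocab>", length(x$index), "features, n =",
      paste(x$n_range, collapse = ".."), "\n")
  invisible(x)
}

#' Vectorize sentences against a vocabulary
#'
#' Binary presence features: entry (i, j) is 1 when sentence i contains
#' vocabulary n-gram j at least once. Out-of-vocabulary n-grams are
#' ignored; a sentence sharing nothing with the vocabulary yields an
#' all-zero row, not an error.
#'
#' @param sentences character vector
#' @param vocab `ngram_vocab` object
#' @return sparse `dgCMatrix`, one row per sentence
#' @export
vectorize <- function(sentences, vocab) {
  stopifnot(inherits(vocab, "ngram_vocab"))
  ii <- integer(); jj <- integer()
  for (i in seq_along(sentences)) {
    g <- unique(ngrams_of(svm_tokens(sentences[i]), vocab$n_range))
    j <- unname(vocab$index[g])
    j <- j[!is.na(j)]
    ii <- c(ii, rep.int(i, length(j)))
    jj <- c(jj, j)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                       dims = c(length(sentences), length(vocab$index)),
                       dimnames = list(NULL, names(vocab$index)))
}

#' Train a linear SVM sentence classifier
#'
#' Fits a linear-kernel support-vector machine (libsvm, via e1071) on
#' binary n-gram presence features. Labels are binary: 1 = CAN, 0 = non-CAN.
#' The decision threshold is 0; prediction is deterministic given the model.
#'
#' @param sentences character vector of training sentences
#' @param labels 0/1 vector, both classes represented
#' @param vocab optional prebuilt vocabulary (default: built from
#'   `sentences`)
#' @param C soft-margin cost (default 1.0, the libsvm default)
#' @param n_range n-gram range when building the vocabulary
#' @return object of class `can_svm` (vocabulary + weight vector + bias)
#' @export
svm_train <- function(sentences, labels, vocab = NULL, C = 1.0,
                      n_range = c(1, 3)) {
  stopifnot(length(sentences) == length(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop_fmt("labels must be 0/1")
  if (length(unique(labels)) < 2) {
    stop_fmt("training set must contain both classes")
  }
  if (is.null(vocab)) vocab <- build_vocabulary(sentences, n_range = n_range)
  x <- vectorize(sentences, vocab)
  # fit on a dense matrix: vocabularies here are small, and libsvm's sparse
  # path returns support vectors in a format that complicates weight
  # extraction
  xd <- as.matrix(x)
  fit <- e1071::svm(xd, factor(labels, levels = c(0, 1)), kernel = "linear",
                    cost = C, scale = FALSE)
  # flatten to an explicit linear decision function w.x + b for portability
  w <- as.numeric(crossprod(fit$SV, fit$coefs))
  b <- -fit$rho
  dec <- as.numeric(x %*% w) + b
  # align sign convention with libsvm's internal label ordering
  ref <- as.integer(as.character(predict(fit, xd)))
  flip_pred <- as.integer(dec <= 0)
  if (mean(flip_pred == ref) > mean(as.integer(dec > 0) == ref)) {
    w <- -w; b <- -b
  }
  structure(list(vocab = vocab, w = w, b = b, C = C), class = "can_svm")
}

#' @export
print.can_svm <- function(x, ...) {
  cat("<can_svm> linear SVM,", length(x$w), "features, C =", x$C, "\n")
  invisible(x)
}

#' Predict CAN labels for sentences
#'
#' @param model `can_svm` object
#' @param sentences character vector
#' @return integer 0/1 vector (decision value > 0 means CAN)
#' @export
svm_predict <- function(model, sentences) {
  stopifnot(inherits(model, "can_svm"))
  x <- vectorize(sentences, model$vocab)
  as.integer(as.numeric(x %*% model$w) + model$b > 0)
}

#' Decision values for sentences
#'
#' @param model `can_svm` object
#' @param sentences character vector
#' @return numeric vector of signed distances to the separating hyperplane
#' @export
svm_decision <- function(model, sentences) {
  stopifnot(inherits(model, "can_svm"))
  x <- vectorize(sentences, model$vocab)
  as.numeric(x %*% model$w) + model$b
}

#' Save / load an SVM model as a portable JSON bundle
#'
#' The bundle stores the vocabulary, weight vector, bias and configuration;
#' loading reproduces predictions exactly.
#'
#' @param model `can_svm` object
#' @param path JSON file path
#' @return `path` invisibly (`write_svm_model`); `can_svm`
#'   (`read_svm_model`)
#' @export
write_svm_model <- function(model, path) {
  stopifnot(inherits(model, "can_svm"))
  jsonlite::write_json(
    list(vocabulary = names(model$vocab$index),
         n_range = model$vocab$n_range,
         min_count = model$vocab$min_count,
         weights = model$w, bias = model$b, C = model$C),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_svm_model
#' @export
read_svm_model <- function(path) {
  y <- jsonlite::read_json(path, simplifyVector = TRUE)
  idx <- seq_along(y$vocabulary)
  names(idx) <- y$vocabulary
  vocab <- structure(list(index = idx, n_range = y$n_range,
                          min_count = y$min_count), class = "ngram_vocab")
  structure(list(vocab = vocab, w = as.numeric(y$weights),
                 b = as.numeric(y$bias), C = y$C), class = "can_svm")
}

#' Stratified train/test split of labeled sentences
#'
#' Allocates `n_test` held-out examples proportionally per class (nearest
#' integer, adjusted to sum), sampling within class with the given seed, so
#' both partitions keep the overall class balance.
#'
#' @param labels 0/1 vector
#' @param n_test held-out count (1 <= n_test < length(labels))
#' @param seed integer seed
#' @return list with integer index vectors `train` and `test`
#' @export
stratified_split <- function(labels, n_test, seed) {
  n <- length(labels)
  if (n_test < 1 || n_test >= n) {
    stop_fmt("n_test must be in [1, %d), got %d", n, n_test)
  }
  labels <- as.integer(labels)
  classes <- sort(unique(labels))
  alloc <- vapply(classes, function(cl) {
    round_half_up(n_test * sum(labels == cl) / n)
  }, 0)
  # adjust rounding drift onto the largest class
  drift <- n_test - sum(alloc)
  if (drift != 0) {
    big <- which.max(tabulate(labels + 1)[classes + 1])
    alloc[big] <- alloc[big] + drift
  }
  test <- integer()
  for (k in seq_along(classes)) {
    members <- which(labels == classes[k])
    if (alloc[k] < 1 || alloc[k] >= length(members)) {
      stop_fmt("infeasible stratification: class %d would have %d test / %d total",
               classes[k], alloc[k], length(members))
    }
    test <- c(test, withr::with_seed(seed + k,
                                     sample(members, alloc[k])))
  }
  test <- sort(test)
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Per-class performance report
#'
#' Confusion counts and the four derived metrics for a binary CAN / non-CAN
#' prediction: CAN predictive value TP/(TP+FP), non-CAN predictive value
#' TN/(TN+FN), sensitivity TP/(TP+FN), specificity TN/(TN+FP). Ratios with
#' zero denominator are reported as `NA` (not available), never as zero.
#'
#' @param pred,gold equal-length 0/1 vectors
#' @return list with `tp`, `fp`, `tn`, `fn`, `can_pv`, `noncan_pv`,
#'   `sensitivity`, `specificity`
#' @export
per_class_report <- function(pred, gold) {
  if (length(pred) == 0) stop_fmt("empty prediction vector")
  if (length(pred) != length(gold)) stop_fmt("pred/gold length mismatch")
  pred <- as.integer(pred); gold <- as.integer(gold)
  tp <- sum(pred == 1 & gold == 1)
  fp <- sum(pred == 1 & gold == 0)
  tn <- sum(pred == 0 & gold == 0)
  fn <- sum(pred == 0 & gold == 1)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       can_pv = ratio(tp, tp + fp),
       noncan_pv = ratio(tn, tn + fn),
       sensitivity = ratio(tp, tp + fn),
       specificity = ratio(tn, tn + fp))
}

#' Report from explicit confusion counts
#'
#' Convenience wrapper around the same arithmetic as [per_class_report()]
#' when only the confusion counts are known.
#'
#' @param tp,fp,tn,fn confusion counts
#' @return same structure as [per_class_report()]
#' @export
confusion_report <- function(tp, fp, tn, fn) {
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       can_pv = ratio(tp, tp + fp),
       noncan_pv = ratio(tn, tn + fn),
       sensitivity = ratio(tp, tp + fn),
       specificity = ratio(tn, tn + fp))
}
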