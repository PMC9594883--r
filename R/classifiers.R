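#' Class-imbalance handling configuration
#'
#' CRT reports are the rare class (~12% of the training corpus).  Two
#' complementary devices are applied: (1) random subsampling of the majority
#' class down to a target ratio, and (2) per-class example weights during
#' training.  The defaults are the chosen values of the published search:
#' sampling ratio 3411:589 (non-CRT:CRT) and balanced weights 0.59:3.4.
#'
#' @param sampling_ratio Length-2 numeric `c(n_majority_keep,
#'   n_minority_target)`; the majority class is subsampled to
#'   `round(n_minority * n_majority_keep / n_minority_target)` records.
#'   `NULL` disables subsampling.
#' @param class_weights `"balanced"` (weights `(n_maj + n_min) / (2 * n_c)`
#'   computed after subsampling), a length-2 numeric `c(w_majority,
#'   w_minority)`, or `NULL` for equal weights.
#' @param seed Integer seed for the subsample draw.
#' @return An object of class `"imbalance_config"`.
#' @export
imbalance_config <- function(sampling_ratio = c(3411, 589),
                             class_weights = "balanced", seed = 1L) {
  if (!is.null(sampling_ratio)) {
    stopifnot(length(sampling_ratio) == 2, all(sampling_ratio > 0))
  }
  if (is.numeric(class_weights))
    stopifnot(length(class_weights) == 2, all(class_weights > 0))
  structure(list(sampling_ratio = sampling_ratio,
                 class_weights = class_weights, seed = as.integer(seed)),
            class = "imbalance_config")
}

#' Subsample the majority class of a labeled corpus
#'
#' Keeps every minority-class record and a uniform random subsample (without
#' replacement) of the majority class, then shuffles the record order; both
#' draws are deterministic under `cfg$seed`.  If the requested majority count
#' exceeds what is available, all records are kept with a message.
#'
#' @param corpus List of labeled `token_document`s (`source_label` 0/1).
#' @param cfg An [imbalance_config()].
#' @return The subsampled, shuffled corpus.
#' @export
subsample_majority <- function(corpus, cfg = imbalance_config()) {
  labels <- vapply(corpus, `[[`, integer(1), "source_label")
  if (length(unique(labels)) < 2) stop2("corpus must contain both classes")
  tab <- table(labels)
  minority <- as.integer(names(tab)[which.min(tab)])
  n_min <- min(tab)
  i_min <- which(labels == minority)
  i_maj <- which(labels != minority)
  keep_maj <- i_maj
  if (!is.null(cfg$sampling_ratio)) {
    target <- round(n_min * cfg$sampling_ratio[1] / cfg$sampling_ratio[2])
    if (target < length(i_maj)) {
      rs <- local({
        set.seed(cfg$seed)
        sample(i_maj, target)
      })
      keep_maj <- sort(rs)
    } else {
      message("requested majority count (", target, ") exceeds available (",
              length(i_maj), "); keeping all")
    }
  }
  kept <- c(i_min, keep_maj)
  set.seed(cfg$seed + 1L)
  corpus[sample(kept)]
}

#' Balanced class weights
#'
#' The inverse-prevalence weighting `w_c = (n_majority + n_minority) /
#' (2 * n_c)`: each class contributes equally to the weighted loss.  On the
#' chosen 3411:589 training sample this yields weights 0.59 (majority) and
#' 3.4 (minority) at two significant figures.
#'
#' @param n_majority,n_minority Positive class counts.
#' @return Named numeric `c(w_majority, w_minority)`, full precision.
#' @export
balanced_class_weights <- function(n_majority, n_minority) {
  if (n_majority <= 0 || n_minority <= 0) stop2("class counts must be positive")
  n <- n_majority + n_minority
  c(w_majority = n / (2 * n_majority), w_minority = n / (2 * n_minority))
}

resolve_class_weights <- function(class_weights, n_neg, n_pos) {
  if (is.null(class_weights)) return(c(1, 1))
  if (identical(class_weights, "balanced")) {
    w <- balanced_class_weights(max(n_neg, n_pos), min(n_neg, n_pos))
    if (n_pos <= n_neg) c(w[["w_majority"]], w[["w_minority"]])
    else c(w[["w_minority"]], w[["w_majority"]])
  } else as.numeric(class_weights)   # (w_negative, w_positive)
}

#' Convolutional classifier configuration
#'
#' The two shipped presets are the chosen values of the published
#' hyperparameter search, one per embedding variant:
#'
#' * `"wholeword"`: batch 11, learning rate 0.0047, dropout 0.29,
#'   923 filters of width 8, 7 epochs;
#' * `"subword"`: batch 16, learning rate 0.0026, dropout 0.47,
#'   532 filters of width 11, 14 epochs.
#'
#' Both use max sequence length 300, the Adam optimizer, binary
#' cross-entropy, and a max-norm constraint of 2 on each convolution
#' filter.  Any field can be overridden for reduced-size runs.
#'
#' @param variant `"wholeword"` or `"subword"` — selects the preset and the
#'   embedding method.
#' @param max_length,batch_size,learning_rate,dropout_rate,n_filters,kernel_size,n_epochs,maxnorm_constraint
#'   Optional overrides of the preset values.
#' @param optimizer `"adam"` (default) or `"adadelta"`.
#' @param l1_strength Optional L1 penalty on the output layer (default 0,
#'   i.e. off — the search did not retain a value).
#' @param embedding An [embedding_config()]; defaults to the variant's
#'   method with dim 100, 10 epochs, skip-gram.
#' @param train_embedding Whether the embedding layer is updated during
#'   supervised training (default `TRUE`).
#' @param vocab_cap Sequence-encoder vocabulary cap (default 5000).
#' @param seed Integer seed.
#' @return An object of class `"cnn_config"`.
#' @export
cnn_config <- function(variant = c("wholeword", "subword"),
                       max_length = 300L, batch_size = NULL,
                       learning_rate = NULL, dropout_rate = NULL,
                       n_filters = NULL, kernel_size = NULL, n_epochs = NULL,
                       maxnorm_constraint = 2, optimizer = c("adam", "adadelta"),
                       l1_strength = 0, embedding = NULL,
                       train_embedding = TRUE, vocab_cap = 5000L, seed = 1L) {
  variant <- match.arg(variant)
  optimizer <- match.arg(optimizer)
  preset <- if (variant == "wholeword") {
    list(batch_size = 11L, learning_rate = 0.0047, dropout_rate = 0.29,
         n_filters = 923L, kernel_size = 8L, n_epochs = 7L)
  } else {
    list(batch_size = 16L, learning_rate = 0.0026, dropout_rate = 0.47,
         n_filters = 532L, kernel_size = 11L, n_epochs = 14L)
  }
  cfg <- list(variant = variant, max_length = as.integer(max_length),
              batch_size = as.integer(batch_size %||% preset$batch_size),
              learning_rate = learning_rate %||% preset$learning_rate,
              dropout_rate = dropout_rate %||% preset$dropout_rate,
              n_filters = as.integer(n_filters %||% preset$n_filters),
              kernel_size = as.integer(kernel_size %||% preset$kernel_size),
              n_epochs = as.integer(n_epochs %||% preset$n_epochs),
              maxnorm_constraint = maxnorm_constraint, optimizer = optimizer,
              loss = "binary cross-entropy", l1_strength = l1_strength,
              embedding = embedding %||% embedding_config(method = variant,
                                                          seed = seed),
              train_embedding = isTRUE(train_embedding),
              vocab_cap = as.integer(vocab_cap), seed = as.integer(seed))
  stopifnot(cfg$dropout_rate >= 0, cfg$dropout_rate < 1, cfg$n_filters > 0,
            cfg$kernel_size > 0, cfg$n_epochs > 0)
  structure(cfg, class = "cnn_config")
}

#' Support-vector classifier configuration
#'
#' Preset to the chosen values of the published grid search: radial basis
#' function kernel, kernel coefficient (gamma) 0.001, regularization
#' parameter C = 100, TF-IDF unigrams + bigrams.  Probability outputs come
#' from Platt sigmoid calibration fitted on held-in decision values.
#'
#' @param kernel `"radial"` (default), `"linear"`, `"polynomial"` or
#'   `"sigmoid"`.
#' @param gamma Kernel coefficient (default 0.001).
#' @param cost Regularization parameter C (default 100).
#' @param ngram_range TF-IDF n-gram range (default `c(1, 2)`).
#' @param max_features Cap on the TF-IDF vocabulary (default 5000).
#' @param use_idf `FALSE` switches to bag-of-words counts.
#' @param seed Integer seed.
#' @return An object of class `"svm_config"`.
#' @export
svm_config <- function(kernel = c("radial", "linear", "polynomial", "sigmoid"),
                       gamma = 0.001, cost = 100, ngram_range = c(1L, 2L),
                       max_features = 5000L, use_idf = TRUE, seed = 1L) {
  kernel <- match.arg(kernel)
  stopifnot(gamma > 0, cost > 0)
  structure(list(kernel = kernel, gamma = gamma, cost = cost,
                 ngram_range = as.integer(ngram_range),
                 max_features = as.integer(max_features),
                 use_idf = isTRUE(use_idf),
                 probability_calibration = "platt", seed = as.integer(seed)),
            class = "svm_config")
}

check_labeled <- function(corpus) {
  labels <- vapply(corpus, `[[`, integer(1), "source_label")
  if (anyNA(labels)) stop2("corpus contains unlabeled documents")
  if (length(unique(labels)) < 2)
    stop2("corpus contains a single class; both classes are required")
  labels
}

#' Train a convolutional member model
#'
#' Fits the architecture: embedding layer (initialized from `embedding`,
#' trainable) -> single 1-D convolution -> ReLU -> global max-pool ->
#' dropout -> sigmoid output, with minibatch Adam (or Adadelta), per-example
#' class weights, binary cross-entropy, and a max-norm constraint on every
#' convolution filter.  Fully seeded and single-threaded.
#'
#' @param corpus Labeled `token_document`s.
#' @param embedding An [embedding_model][train_embeddings] whose `dim`
#'   matches `cfg$embedding$dim`.
#' @param cfg A [cnn_config()].
#' @param imbalance An [imbalance_config()] or `NULL` (no subsampling,
#'   equal weights).
#' @param encoder Optional pre-built [build_sequence_encoder()]; built from
#'   `corpus` if `NULL`.
#' @return An object of class `"crt_member"` with `kind`
#'   `"cnn_wholeword"` or `"cnn_subword"`.
#' @export
train_cnn <- function(corpus, embedding, cfg = cnn_config(),
                      imbalance = NULL, encoder = NULL) {
  if (ncol(embedding$vectors) != cfg$embedding$dim)
    stop2("embedding dim (", ncol(embedding$vectors),
          ") does not match cfg (", cfg$embedding$dim, ")")
  check_labeled(corpus)
  if (!is.null(imbalance)) corpus <- subsample_majority(corpus, imbalance)
  labels <- vapply(corpus, `[[`, integer(1), "source_label")
  if (is.null(encoder))
    encoder <- build_sequence_encoder(corpus, cfg$vocab_cap, cfg$max_length)
  seqs <- encode_corpus(encoder, corpus)
  dim_e <- ncol(embedding$vectors)
  vocab <- names(encoder$vocabulary)
  E <- matrix(0, nrow = length(vocab) + 1L, ncol = dim_e)
  for (i in seq_along(vocab)) E[i + 1L, ] <- embed_token(embedding, vocab[i])
  w <- resolve_class_weights(if (is.null(imbalance)) NULL
                             else imbalance$class_weights,
                             sum(labels == 0), sum(labels == 1))
  fit <- cpp_train_cnn(seqs, as.numeric(labels), E, cfg$n_filters,
                       cfg$kernel_size, cfg$dropout_rate, cfg$learning_rate,
                       cfg$batch_size, cfg$n_epochs, cfg$maxnorm_constraint,
                       w[1], w[2], cfg$l1_strength, cfg$train_embedding,
                       cfg$optimizer, cfg$seed)
  structure(list(kind = paste0("cnn_", cfg$variant), fit = fit,
                 encoder = encoder, cfg = cfg, class_weights = w),
            class = "crt_member")
}

platt_fit <- function(decision, labels) {
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  t_pos <- (n_pos + 1) / (n_pos + 2); t_neg <- 1 / (n_neg + 2)
  target <- ifelse(labels == 1, t_pos, t_neg)
  nll <- function(par) {
    z <- par[1] * decision + par[2]
    p <- 1 / (1 + exp(-pmin(pmax(z, -30), 30)))
    -sum(target * log(p) + (1 - target) * log(1 - p))
  }
  fit <- stats::optim(c(1, 0), nll, method = "BFGS")
  fit$par
}

platt_apply <- function(par, decision) {
  z <- par[1] * decision + par[2]
  1 / (1 + exp(-pmin(pmax(z, -30), 30)))
}

#' Train the support-vector member model
#'
#' Fits a kernel support-vector classifier (libsvm via e1071) on TF-IDF
#' vectors, with the configured gamma/C/class weights, then calibrates
#' probabilities with a Platt sigmoid fitted on the held-in decision values.
#' Calibration is deterministic (no internal cross-validation draw).
#'
#' @param corpus Labeled `token_document`s.
#' @param tfidf A fitted [fit_tfidf()] model, or `NULL` to fit one on
#'   `corpus` under `cfg`.
#' @param cfg An [svm_config()].
#' @param imbalance An [imbalance_config()] or `NULL`.
#' @return An object of class `"crt_member"` with `kind = "svm"`.
#' @export
train_svm <- function(corpus, tfidf = NULL, cfg = svm_config(),
                      imbalance = NULL) {
  check_labeled(corpus)
  if (!is.null(imbalance)) corpus <- subsample_majority(corpus, imbalance)
  labels <- vapply(corpus, `[[`, integer(1), "source_label")
  if (is.null(tfidf))
    tfidf <- fit_tfidf(corpus, cfg$ngram_range, cfg$max_features,
                       use_idf = cfg$use_idf)
  X <- as.matrix(transform_tfidf(tfidf, corpus))
  w <- resolve_class_weights(if (is.null(imbalance)) NULL
                             else imbalance$class_weights,
                             sum(labels == 0), sum(labels == 1))
  y <- factor(labels, levels = c(0, 1))
  set.seed(cfg$seed)
  fit <- e1071::svm(x = X, y = y, kernel = cfg$kernel, gamma = cfg$gamma,
                    cost = cfg$cost, scale = FALSE,
                    class.weights = c("0" = w[1], "1" = w[2]))
  dec <- attr(predict(fit, X, decision.values = TRUE), "decision.values")[, 1]
  # orient decision values so larger means more CRT-like
  flip <- if (mean(dec[labels == 1]) < mean(dec[labels == 0])) -1 else 1
  platt <- platt_fit(flip * dec, labels)
  structure(list(kind = "svm", fit = fit, tfidf = tfidf, platt = platt,
                 flip = flip, cfg = cfg, class_weights = w),
            class = "crt_member")
}

#' Predict screening probabilities from one member model
#'
#' Deterministic at inference; one probability in \[0, 1\] per document,
#' order preserved.  Documents with no usable text (all-padding input)
#' still receive a valid probability, with a warning.
#'
#' @param object A `crt_member` from [train_cnn()] or [train_svm()].
#' @param docs A `token_document` or list of them.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.crt_member <- function(object, docs, ...) {
  if (inherits(docs, "token_document")) docs <- list(docs)
  n_empty <- sum(vapply(docs, function(d) length(d$tokens) == 0, logical(1)))
  if (n_empty > 0)
    warning(n_empty, " document(s) contain no usable text; ",
            "probabilities are based on empty input", call. = FALSE)
  if (object$kind == "svm") {
    X <- as.matrix(transform_tfidf(object$tfidf, docs))
    dec <- attr(predict(object$fit, X, decision.values = TRUE),
                "decision.values")[, 1]
    unname(platt_apply(object$platt, object$flip * dec))
  } else {
    seqs <- encode_corpus(object$encoder, docs)
    as.numeric(cpp_predict_cnn(seqs, object$fit$embedding, object$fit$Wc,
                               object$fit$bc, object$fit$wo, object$fit$bo,
                               object$cfg$kernel_size))
  }
}

#' @export
print.crt_member <- function(x, ...) {
  cat("<crt_member ", x$kind, ">\n", sep = "")
  invisible(x)
}
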